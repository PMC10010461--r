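#' Trial schedules for each experimental phase
#'
#' Builds the trial-type schedule of one experimental phase of the delayed
#' sequence-production paradigm: blocks of instructed Go trials (visually
#' guided), memory Go trials (produced from memory) and No-Go trials (sequence
#' cue without execution), with the four sequence conditions balanced within
#' each block. Go trials of each type divide evenly over the four sequences;
#' No-Go trials do too in every phase.
#'
#' Phase layout (trials per block x blocks; instructed / memory / No-Go per
#' block): `example` 12 x 1 (4/4/4), `pre_test` and `post_test` 32 x 4
#' (32/0/0), `training1` 20 x 12 (16/0/4), `training2` 20 x 12 (8/8/4),
#' `training3` 20 x 12 (0/16/4), `refresher` 20 x 2 (8/8/4), `fmri` 48 x 6
#' (0/24/24). The three training stages therefore have 240 trials each (720
#' in total) and the scanner session 288 trials at 50% Go / 50% No-Go.
#'
#' @param phase One of `"example"`, `"pre_test"`, `"training1"`,
#'   `"training2"`, `"training3"`, `"post_test"`, `"refresher"`, `"fmri"`.
#' @param n_conditions Number of sequence conditions (default 4 = 2 orders x
#'   2 timings).
#' @param shuffle If `TRUE`, randomize trial order within each block
#'   (requires `seed`); by default trials are listed in a deterministic
#'   condition-by-type order.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @return A data frame with columns `block`, `trial`, `trial_type`
#'   (`"instructed"`, `"memory"`, `"nogo"`) and `condition` (1-based sequence
#'   index), one row per trial.
#' @examples
#' sched <- build_schedule("fmri")
#' nrow(sched)              # 288
#' table(sched$trial_type)  # 144 memory, 144 nogo
#' @export
build_schedule <- function(phase, n_conditions = 4L, shuffle = FALSE, seed = NULL) {
  layouts <- list(
    example   = list(blocks = 1L,  instructed = 4L,  memory = 4L,  nogo = 4L),
    pre_test  = list(blocks = 4L,  instructed = 32L, memory = 0L,  nogo = 0L),
    training1 = list(blocks = 12L, instructed = 16L, memory = 0L,  nogo = 4L),
    training2 = list(blocks = 12L, instructed = 8L,  memory = 8L,  nogo = 4L),
    training3 = list(blocks = 12L, instructed = 0L,  memory = 16L, nogo = 4L),
    post_test = list(blocks = 4L,  instructed = 32L, memory = 0L,  nogo = 0L),
    refresher = list(blocks = 2L,  instructed = 8L,  memory = 8L,  nogo = 4L),
    fmri      = list(blocks = 6L,  instructed = 0L,  memory = 24L, nogo = 24L)
  )
  if (length(phase) != 1L || !phase %in% names(layouts))
    stop("unknown phase '", phase, "'; must be one of: ",
         paste(names(layouts), collapse = ", "))
  lay <- layouts[[phase]]
  n_conditions <- as.integer(n_conditions)

  block_types <- rep(c("instructed", "memory", "nogo"),
                     times = c(lay$instructed, lay$memory, lay$nogo))
  # balance conditions within block, separately per trial type
  block_cond <- unlist(lapply(c(lay$instructed, lay$memory, lay$nogo), function(k) {
    if (k == 0L) return(integer(0))
    if (k %% n_conditions != 0L)
      rep_len(seq_len(n_conditions), k)
    else
      rep(seq_len(n_conditions), each = k %/% n_conditions)
  }))

  one_block <- function(b, ord) {
    data.frame(block = b, trial = seq_along(block_types),
               trial_type = block_types[ord], condition = block_cond[ord],
               stringsAsFactors = FALSE)
  }
  if (shuffle) {
    if (is.null(seed)) stop("'seed' is required when shuffle = TRUE")
    sched <- with_seed(seed, {
      do.call(rbind, lapply(seq_len(lay$blocks), function(b)
        one_block(b, sample.int(length(block_types)))))
    })
  } else {
    sched <- do.call(rbind, lapply(seq_len(lay$blocks), function(b)
      one_block(b, seq_along(block_types))))
  }
  rownames(sched) <- NULL
  sched
}
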
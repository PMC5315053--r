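#' The six experimental conditions
#'
#' Conditions cross presentation format (Spoken, Written) with item meaning
#' (AUD = auditory-feature words, VIS = visual-feature words, NON =
#' meaningless non-words).
#'
#' @return Character vector of the six condition labels.
#' @export
task_conditions <- function() {
  c("Spoken-AUD", "Spoken-VIS", "Spoken-NON",
    "Written-AUD", "Written-VIS", "Written-NON")
}

condition_format <- function(cond) sub("-.*$", "", cond)
condition_feature <- function(cond) sub("^.*-", "", cond)

new_event_table <- function(df, conditions) {
  df <- df[order(df$run, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("EventTable", "data.frame"),
            conditions = conditions)
}

validate_event_table <- function(df, conditions = NULL,
                                 jitter = NULL, file = NULL) {
  where <- if (is.null(file)) "" else sprintf(" in '%s'", file)
  need <- c("onset", "duration", "trial_type", "run")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("event table%s is missing column(s): %s", where,
                 paste(missing_cols, collapse = ", ")))
  if (any(df$onset < 0))
    stop(sprintf("negative onset at row %d%s", which(df$onset < 0)[1], where))
  if (any(df$duration <= 0))
    stop(sprintf("non-positive duration at row %d%s",
                 which(df$duration <= 0)[1], where))
  if (!is.null(conditions)) {
    bad <- which(!(df$trial_type %in% conditions))
    if (length(bad))
      stop(sprintf("unknown condition '%s' at row %d%s",
                   df$trial_type[bad[1]], bad[1], where))
  }
  for (r in unique(df$run)) {
    sl <- df[df$run == r, , drop = FALSE]
    sl <- sl[order(sl$onset), , drop = FALSE]
    ends <- sl$onset + sl$duration
    if (nrow(sl) > 1 && any(sl$onset[-1] < ends[-nrow(sl)] - 1e-9)) {
      i <- which(sl$onset[-1] < ends[-nrow(sl)] - 1e-9)[1]
      stop(sprintf("overlapping blocks in run %s (block starting at %.2f s)%s",
                   r, sl$onset[i + 1], where))
    }
  }
  invisible(df)
}

# Pseudo-random sequence with exact per-condition counts and no immediate
# repetition, by rejection sampling (retry-capped).
no_repeat_sequence <- function(conditions, reps) {
  if (length(conditions) == 1L && reps >= 2L)
    stop("no valid no-repetition sequence exists for a single condition ",
         "with >= 2 repetitions")
  pool <- rep(conditions, each = reps)
  for (i in seq_len(10000L)) {
    cand <- sample(pool)
    if (!any(cand[-1] == cand[-length(cand)])) return(cand)
  }
  stop("failed to draw a no-repetition sequence within the retry cap")
}

#' Generate a jittered block design
#'
#' Builds an event table for a block design: per run, each condition occurs
#' exactly `reps_per_condition` times in a pseudo-random order with no
#' immediate repetition of conditions, and consecutive blocks are separated
#' by a rest gap drawn uniformly from the jitter interval.  The first block
#' is preceded by a lead-in gap drawn from the same interval.
#'
#' @param n_runs number of runs (default 4).
#' @param conditions condition labels (default [task_conditions()]).
#' @param reps_per_condition blocks per condition per run (default 2).
#' @param block_duration block length in seconds (default 20).
#' @param jitter length-2 numeric, min and max rest gap in s (default 4-8).
#' @param blocks_per_run optional consistency check; must equal
#'   `length(conditions) * reps_per_condition` if given.
#' @param seed integer RNG seed.
#' @return An `EventTable` data frame with columns onset, duration,
#'   trial_type, run.
#' @export
generate_block_design <- function(n_runs = 4, conditions = task_conditions(),
                                  reps_per_condition = 2, block_duration = 20,
                                  jitter = c(4, 8), blocks_per_run = NULL,
                                  seed = 1) {
  stopifnot(n_runs >= 1, reps_per_condition >= 1, block_duration > 0,
            length(jitter) == 2, jitter[1] >= 0, jitter[2] >= jitter[1])
  n_blocks <- length(conditions) * reps_per_condition
  if (!is.null(blocks_per_run) && blocks_per_run != n_blocks)
    stop(sprintf("blocks_per_run (%d) must equal |conditions| x reps (%d)",
                 blocks_per_run, n_blocks))
  rows <- with_seed(seed, {
    out <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      seq_r <- no_repeat_sequence(conditions, reps_per_condition)
      gaps <- stats::runif(n_blocks, jitter[1], jitter[2])
      onsets <- numeric(n_blocks)
      t <- 0
      for (b in seq_len(n_blocks)) {
        t <- t + gaps[b]
        onsets[b] <- t
        t <- t + block_duration
      }
      out[[r]] <- data.frame(onset = onsets, duration = block_duration,
                             trial_type = seq_r, run = r,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  validate_event_table(rows, conditions)
  new_event_table(rows, conditions)
}
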
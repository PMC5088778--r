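#' Generate a pseudorandomized factorial trial schedule
#'
#' Builds the trial table of the cued visual-search design: 2 cue-presence
#' levels (informative cue pointing at the target side with 100% validity,
#' or an uninformative cue) crossed with 4 distractor-similarity levels
#' (D1 most target-similar .. D4 least), balanced target sides and target
#' letters, with the distractor letter never equal to the target letter.
#'
#' Trials are pseudorandomized in passes: every distinct trial type
#' (cue-presence x distractor x side x letter, 48 types) occurs once, in
#' random order, before any type repeats. Blocks of 48 trials alternate the
#' target shape (diamond/square) so shape alone is never a stable cue.
#'
#' When `trials_per_condition` is not divisible by 6 (2 sides x 3 letters),
#' the excess trials within a cell are assigned round-robin over the
#' side-by-letter types in a fixed order, so cell totals are exact and the
#' imbalance is at most one trial per type.
#'
#' @param params A [sim_params()] object (only `trials_per_condition` is
#'   used).
#' @param seed Integer seed for the pass-order randomization; `NULL` leaves
#'   the RNG state alone.
#' @return A tibble with one row per trial: `trial`, `block`,
#'   `target_shape`, `cue` (`"left"`, `"right"`, `"uninformative"`),
#'   `cue_presence`, `distractor`, `target_side`, `target_letter`,
#'   `distractor_letter`.
#' @examples
#' sched <- generate_schedule(sim_params(trials_per_condition = 12), seed = 1)
#' dplyr::count(sched, cue_presence, distractor)
#' @export
generate_schedule <- function(params = sim_params(), seed = NULL) {
  tpc <- params$trials_per_condition
  letters3 <- c("A", "B", "C")
  sides <- c("left", "right")
  cells <- expand.grid(
    cue_presence = c("cued", "uncued"),
    distractor = c("D1", "D2", "D3", "D4"),
    stringsAsFactors = FALSE
  )

  # Per cell: balanced side x letter types, remainder round-robin; the
  # distractor letter alternates over the two letters != target letter.
  cell_rows <- function(cue_presence, distractor) {
    types <- expand.grid(
      target_side = sides, target_letter = letters3,
      stringsAsFactors = FALSE
    )
    counts <- rep(tpc %/% 6L, 6L)
    rem <- tpc %% 6L
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    rows <- types[rep(seq_len(6L), counts), , drop = FALSE]
    rows$rep_i <- unlist(lapply(counts, seq_len), use.names = FALSE)
    others <- lapply(rows$target_letter, function(l) setdiff(letters3, l))
    rows$distractor_letter <- mapply(
      function(o, k) o[(k - 1L) %% 2L + 1L], others, rows$rep_i
    )
    rows$cue_presence <- cue_presence
    rows$distractor <- distractor
    rows$rep_i <- NULL
    rows
  }

  pool <- do.call(rbind, Map(cell_rows, cells$cue_presence, cells$distractor))
  pool$type <- interaction(
    pool$cue_presence, pool$distractor, pool$target_side, pool$target_letter,
    drop = TRUE
  )

  ordered <- with_seed(seed, {
    queues <- split(seq_len(nrow(pool)), pool$type)
    out <- integer(nrow(pool))
    k <- 0L
    while (any(lengths(queues) > 0L)) {
      live <- which(lengths(queues) > 0L)
      for (q in sample(live)) {
        k <- k + 1L
        out[k] <- queues[[q]][1L]
        queues[[q]] <- queues[[q]][-1L]
      }
    }
    out
  })

  sched <- pool[ordered, , drop = FALSE]
  sched$type <- NULL
  n <- nrow(sched)
  sched$trial <- seq_len(n)
  sched$block <- (sched$trial - 1L) %/% 48L + 1L
  sched$target_shape <- ifelse(sched$block %% 2L == 1L, "diamond", "square")
  sched$cue <- ifelse(sched$cue_presence == "cued", sched$target_side,
                      "uninformative")
  tibble::as_tibble(sched)[, c(
    "trial", "block", "target_shape", "cue", "cue_presence", "distractor",
    "target_side", "target_letter", "distractor_letter"
  )]
}
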
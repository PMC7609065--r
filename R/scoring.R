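#' Sliding-window photobleaching detection
#'
#' Scans windows of `window` frames left to right over the per-frame
#' bleached-class probability; at the first window start where at least
#' `min_hits` frames carry a bleached probability above `p_thresh`, that
#' frame and everything after it is declared bleached. Windows truncated at
#' the end of the trace still require the full `min_hits`, so an isolated
#' single high-probability frame never triggers.
#'
#' @param p_bleached Numeric vector of per-frame bleached probabilities.
#' @param window Window length in frames.
#' @param min_hits Minimum qualifying frames per window.
#' @param p_thresh Probability above which a frame counts as bleached.
#' @return 1-based index of the first bleached frame, or `NA` if bleaching
#'   is never detected.
#' @examples
#' pb <- c(rep(0, 10), rep(0.9, 20))
#' detect_bleaching(pb)  # frame 8 (window [8, 14] holds 4 hits)
#' @export
detect_bleaching <- function(p_bleached, window = 7L, min_hits = 4L,
                             p_thresh = 0.5) {
  stopifnot(length(p_bleached) >= 1L)
  .window_scan_cpp(p_bleached > p_thresh, as.integer(window),
                   as.integer(min_hits))
}

#' Per-trace category scores and smFRET confidence
#'
#' Averages the per-frame class probabilities over the live (pre-bleach)
#' frames and renormalizes over the five non-bleached categories, giving
#' scores `P_A, P_N, P_X, P_S, P_D` that sum to 1. The smFRET confidence
#' score is `P_S + P_D`: the model's confidence that the trace is genuine
#' (static or dynamic) smFRET. If bleaching occurs before `min_live` frames
#' (or fewer than `min_live` live frames exist at all) the whole trace is
#' classified bleached with confidence 0, preventing artificially inflated
#' scores from a handful of good-looking frames.
#'
#' @param probs Numeric matrix (frames x 6) of per-frame class
#'   probabilities, columns ordered as [fret_classes()].
#' @param bleach_frame 1-based first bleached frame as returned by
#'   [detect_bleaching()], or `NA`/`NULL` for no bleaching.
#' @param min_live Minimum number of usable frames.
#' @return An object of class `category_scores`: list with `P` (named
#'   5-vector over A, N, X, S, D), `score` (the smFRET confidence),
#'   `bleach_frame`, `n_live` and `forced_bleached`.
#' @export
category_scores <- function(probs, bleach_frame = NA, min_live = 15L) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 6L) stop("probs must have 6 columns (B, A, N, X, S, D)")
  if (is.null(bleach_frame)) bleach_frame <- NA
  n <- nrow(probs)
  live <- if (is.na(bleach_frame)) seq_len(n) else seq_len(bleach_frame - 1L)
  n_live <- length(live)
  forced <- (!is.na(bleach_frame) && bleach_frame - 1L < min_live) ||
    n_live < min_live
  if (forced) {
    P <- setNames(rep(NA_real_, 5), c("A", "N", "X", "S", "D"))
    score <- 0
  } else {
    colsum <- colSums(probs[live, , drop = FALSE])
    five <- if (is.null(names(colsum))) colsum[2:6] else
      colsum[c("A", "N", "X", "S", "D")]
    P <- five / sum(five)
    names(P) <- c("A", "N", "X", "S", "D")
    score <- unname(P["S"] + P["D"])
  }
  structure(list(P = P, score = score,
                 bleach_frame = if (is.na(bleach_frame)) NA_integer_ else
                   as.integer(bleach_frame),
                 n_live = n_live, forced_bleached = forced),
            class = "category_scores")
}

#' @export
print.category_scores <- function(x, ...) {
  if (x$forced_bleached) {
    cat(sprintf("trace classified bleached (%d live frames); confidence 0\n",
                x$n_live))
  } else {
    cat(sprintf("smFRET confidence %.3f over %d live frames\n",
                x$score, x$n_live))
    print(round(x$P, 4))
  }
  invisible(x)
}

#' Accept or reject a trace on its confidence score
#'
#' A trace is accepted as smFRET when its confidence score (`P_S + P_D`) is
#' at or above the user threshold and it was not force-classified as
#' bleached. The assigned class is the argmax over the five category
#' scores; both static and dynamic count as smFRET for acceptance. The
#' recommended default threshold is 0.85.
#'
#' @param scores A [category_scores()] object.
#' @param threshold Confidence threshold in \[0, 1\].
#' @return List with `accepted` (logical), `class` (one of
#'   [fret_classes()]) and `score`.
#' @export
classify_trace <- function(scores, threshold = 0.85) {
  stopifnot(inherits(scores, "category_scores"))
  if (threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  if (scores$forced_bleached) {
    return(list(accepted = FALSE, class = "B", score = 0))
  }
  cls <- names(scores$P)[which.max(scores$P)]
  list(accepted = scores$score >= threshold, class = cls,
       score = scores$score)
}

#' Score a predicted trace end to end
#'
#' Convenience wrapper: bleaching detection on the bleached-class column,
#' category scores on the live frames, and the accept/reject decision.
#'
#' @param probs Per-frame probability matrix (frames x 6).
#' @param threshold Acceptance threshold.
#' @param min_live Minimum usable frames.
#' @inheritParams detect_bleaching
#' @return List with `bleach_frame`, `scores` ([category_scores()]),
#'   `class`, `accepted`.
#' @export
score_trace <- function(probs, threshold = 0.85, min_live = 15L,
                        window = 7L, min_hits = 4L, p_thresh = 0.5) {
  probs <- as.matrix(probs)
  bf <- detect_bleaching(probs[, 1L], window = window, min_hits = min_hits,
                         p_thresh = p_thresh)
  sc <- category_scores(probs, bleach_frame = bf, min_live = min_live)
  dec <- classify_trace(sc, threshold = threshold)
  list(bleach_frame = sc$bleach_frame, scores = sc, class = dec$class,
       accepted = dec$accepted)
}
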
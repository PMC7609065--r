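#' Plot a labelled trace
#'
#' Two stacked base-graphics panels: the channel intensities (DD green,
#' DA red, AA dark red) and the observable FRET efficiency with the
#' ground-truth ideal value overlaid; the detected class and bleach onset
#' are annotated.
#'
#' @param x A `labeled_trace` from [simulate_trace()].
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.labeled_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  tr <- x$trace
  f <- seq_len(tr$n_frames)
  ylim <- range(c(tr$dd, tr$da, tr$aa), na.rm = TRUE)
  graphics::plot(f, tr$dd, type = "l", col = "darkgreen", ylim = ylim,
                 xlab = "", ylab = "intensity (a.u.)",
                 main = sprintf("class %s", x$class))
  graphics::lines(f, tr$da, col = "red")
  if (!is.null(tr$aa)) graphics::lines(f, tr$aa, col = "darkred", lty = 3)
  if (x$first_dark <= tr$n_frames) {
    graphics::abline(v = x$first_dark, lty = 2, col = "grey40")
  }
  es <- observed_es(tr)
  graphics::plot(f, es$e, type = "l", col = "grey50", ylim = c(-0.2, 1.2),
                 xlab = "frame", ylab = "FRET efficiency")
  live <- f < x$first_dark
  graphics::lines(f[live], x$ideal_fret[live], col = "blue", lwd = 2)
  invisible(x)
}

#' Plot an HMM idealization
#'
#' The observed FRET efficiency with the Viterbi state path drawn as a
#' piecewise-constant idealized trace.
#'
#' @param x A `fret_hmm` from [fit_hmm()].
#' @param y Optional numeric vector of the observations that were fitted
#'   (first dimension); defaults to reconstructing nothing and plotting
#'   the idealized path alone.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.fret_hmm <- function(x, y = NULL, ...) {
  f <- seq_along(x$path)
  ideal <- x$means[x$path, 1]
  if (!is.null(y)) {
    graphics::plot(f, y, type = "l", col = "grey60", xlab = "frame",
                   ylab = "FRET efficiency",
                   main = sprintf("%d-state idealization", x$n_states))
    graphics::lines(f, ideal, col = "blue", lwd = 2)
  } else {
    graphics::plot(f, ideal, type = "s", col = "blue", lwd = 2,
                   xlab = "frame", ylab = "FRET efficiency",
                   main = sprintf("%d-state idealization", x$n_states))
  }
  invisible(x)
}

#' Plot training history
#'
#' Train and validation loss per epoch for a fitted classifier.
#'
#' @param x A `fret_nn` from [train_classifier()].
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.fret_nn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history recorded")
  ylim <- range(c(h$train_loss, h$val_loss))
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16, ylim = ylim,
                 xlab = "epoch", ylab = "cross-entropy loss")
  graphics::lines(h$epoch, h$val_loss, type = "b", pch = 1, col = "red")
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "red"), pch = c(16, 1), bty = "n")
  invisible(x)
}
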
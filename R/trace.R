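#' Construct an intensity trace
#'
#' A trace holds the background-corrected per-frame intensities of one
#' molecule: `dd` (donor excitation, donor emission), `da` (donor
#' excitation, acceptor emission) and, for ALEX data, `aa` (acceptor
#' excitation, acceptor emission). Intensities are in arbitrary units;
#' nothing in the package assumes a particular scale except the classifier,
#' which normalizes internally (see [normalize_trace()]).
#'
#' @param dd,da Numeric vectors of equal length.
#' @param aa Optional numeric vector (ALEX only).
#' @param meta Optional named list of metadata (e.g. source file header).
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(dd, da, aa = NULL, meta = list()) {
  dd <- as.numeric(dd)
  da <- as.numeric(da)
  if (length(dd) != length(da)) stop("dd and da must have equal length")
  if (!is.null(aa)) {
    aa <- as.numeric(aa)
    if (length(aa) != length(dd)) stop("aa must match dd/da length")
  }
  structure(list(dd = dd, da = da, aa = aa, n_frames = length(dd),
                 meta = meta),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("smFRET trace: %d frames, %s\n", x$n_frames,
              if (is.null(x$aa)) "2 channels (DD, DA)" else
                "3 channels (DD, DA, AA)"))
  invisible(x)
}

is_alex <- function(trace) !is.null(trace$aa)

#' Observable FRET efficiency and stoichiometry
#'
#' Computes the per-frame FRET efficiency `E = DA / (DD + DA)` and, for ALEX
#' traces, the stoichiometry `S = (DD + DA) / (DD + DA + AA)`. Frames whose
#' denominator is not strictly positive yield `NA` rather than an error:
#' after photobleaching both quantities are undefined.
#'
#' @param trace A [fret_trace()].
#' @return A list with numeric vectors `e` and `s` (`s` is all-`NA` for
#'   non-ALEX traces).
#' @examples
#' tr <- fret_trace(dd = 0.7, da = 0.3, aa = 1)
#' observed_es(tr)  # E = 0.3, S = 0.5
#' @export
observed_es <- function(trace) {
  stopifnot(inherits(trace, "fret_trace"))
  den_e <- trace$dd + trace$da
  e <- ifelse(den_e > 0, trace$da / den_e, NA_real_)
  if (is_alex(trace)) {
    den_s <- den_e + trace$aa
    s <- ifelse(den_s > 0, den_e / den_s, NA_real_)
  } else {
    s <- rep(NA_real_, trace$n_frames)
  }
  list(e = e, s = s)
}

#' Normalize a trace to its global maximum
#'
#' Divides all channels by the single maximum over all channels and frames,
#' so the largest value in the trace becomes exactly 1 while relative
#' intensities between channels are preserved. This is the only
#' preprocessing the classifier sees, which makes predictions independent of
#' instrument-specific intensity units.
#'
#' @param trace A [fret_trace()].
#' @return The rescaled `fret_trace`.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fret_trace"))
  m <- max(c(trace$dd, trace$da, trace$aa), na.rm = TRUE)
  if (!is.finite(m) || m <= 0) {
    stop("cannot normalize: trace has no strictly positive intensity")
  }
  trace$dd <- trace$dd / m
  trace$da <- trace$da / m
  if (!is.null(trace$aa)) trace$aa <- trace$aa / m
  trace
}
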
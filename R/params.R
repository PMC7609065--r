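#' Population priors for synthetic smFRET trace generation
#'
#' Collects every tunable prior of the trace generator into a validated
#' parameter object. The defaults are the ones used to train the shipped
#' classifier recipe and describe a heterogeneous TIRF field of view:
#' molecules carry up to four FRET states drawn uniformly on \[0, 1\]
#' (minimum separation 0.1 so that transitions are distinguishable from
#' noise), hop between states with a per-frame, per-destination probability
#' drawn uniformly on \[0, 0.2\], photobleach with exponential lifetimes of
#' mean 500 frames per fluorophore, and are contaminated by aggregates,
#' blinking, scrambled artifacts, acceptor-only mismatch, donor bleedthrough
#' and Gaussian (optionally gamma-skewed) detection noise.
#'
#' @param n_frames Trace length in frames.
#' @param max_states Maximum number of FRET states per molecule.
#' @param min_state_separation Minimum distance between any two FRET states.
#' @param trans_prob_range Uniform prior for the per-frame probability of
#'   jumping to each *other* state.
#' @param p_aggregate Probability that a trace is an aggregate (several
#'   donor/acceptor pairs in one spot).
#' @param p_blink Probability that a non-aggregate trace contains
#'   photoblinking.
#' @param p_scramble Probability that a trace is scrambled (non-FRET
#'   artifact).
#' @param p_scramble_colocalized Probability, given a scrambled trace, that
#'   the artifact is two incorrectly colocalized molecules.
#' @param aggregate_size_range Integer range of donor/acceptor pairs in an
#'   aggregate.
#' @param aa_mismatch_range Uniform prior for the direct acceptor-excitation
#'   intensity as a fraction of the unit signal.
#' @param bleedthrough_range Uniform prior for donor bleedthrough into the
#'   acceptor channel.
#' @param noise_sigma_range Uniform prior for the Gaussian noise sigma, in
#'   units of the maximum single-fluorophore intensity.
#' @param p_gamma_noise Probability that a centred Gamma(shape, scale) noise
#'   component is added on top of the Gaussian noise.
#' @param gamma_shape,gamma_scale Shape and scale of the gamma noise.
#' @param bleach_lifetime Mean of the exponential photobleaching lifetime,
#'   in frames (per fluorophore).
#' @param p_falloff Probability that the molecule falls off the surface at an
#'   exponentially distributed time.
#' @param falloff_lifetime Mean of the exponential fall-off time, frames.
#' @param blink_events_mean Poisson mean of the number of blinking events in
#'   a blinking trace.
#' @param blink_duration_mean Mean (exponential) blink duration, frames.
#' @param noisy_sigma_threshold Traces with noise sigma above this value are
#'   labelled noisy (`"N"`) rather than smFRET.
#' @param label_smoothing Label-smoothing strength used when one-hot frame
#'   labels are turned into training targets.
#' @param state_means Optional fixed FRET state values. When supplied, every
#'   simulated molecule uses exactly these states instead of drawing them
#'   from the uniform prior (used e.g. for benchmark ground-truth traces).
#' @param alex Logical; simulate ALEX data (DD, DA and AA channels) or
#'   non-ALEX (DD and DA only).
#'
#' @return An object of class `sim_params`.
#' @examples
#' p <- sim_params()
#' p$bleach_lifetime
#' @export
sim_params <- function(n_frames = 300L,
                       max_states = 4L,
                       min_state_separation = 0.1,
                       trans_prob_range = c(0, 0.2),
                       p_aggregate = 0.15,
                       p_blink = 0.20,
                       p_scramble = 0.15,
                       p_scramble_colocalized = 0.90,
                       aggregate_size_range = c(2L, 10L),
                       aa_mismatch_range = c(0.70, 1.30),
                       bleedthrough_range = c(0.00, 0.15),
                       noise_sigma_range = c(0.01, 0.30),
                       p_gamma_noise = 0.8,
                       gamma_shape = 1,
                       gamma_scale = 1.1,
                       bleach_lifetime = 500,
                       p_falloff = 0.1,
                       falloff_lifetime = 500,
                       blink_events_mean = 1,
                       blink_duration_mean = 5,
                       noisy_sigma_threshold = 0.25,
                       label_smoothing = 0.05,
                       state_means = NULL,
                       alex = TRUE) {
  p <- list(
    n_frames = as.integer(n_frames), max_states = as.integer(max_states),
    min_state_separation = min_state_separation,
    trans_prob_range = as.numeric(trans_prob_range),
    p_aggregate = p_aggregate, p_blink = p_blink, p_scramble = p_scramble,
    p_scramble_colocalized = p_scramble_colocalized,
    aggregate_size_range = as.integer(aggregate_size_range),
    aa_mismatch_range = as.numeric(aa_mismatch_range),
    bleedthrough_range = as.numeric(bleedthrough_range),
    noise_sigma_range = as.numeric(noise_sigma_range),
    p_gamma_noise = p_gamma_noise, gamma_shape = gamma_shape,
    gamma_scale = gamma_scale, bleach_lifetime = bleach_lifetime,
    p_falloff = p_falloff, falloff_lifetime = falloff_lifetime,
    blink_events_mean = blink_events_mean,
    blink_duration_mean = blink_duration_mean,
    noisy_sigma_threshold = noisy_sigma_threshold,
    label_smoothing = label_smoothing,
    state_means = if (is.null(state_means)) NULL else as.numeric(state_means),
    alex = isTRUE(alex)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$n_frames >= 1L, p$max_states >= 1L, p$bleach_lifetime > 0)
  probs <- c(p$p_aggregate, p$p_blink, p$p_scramble, p$p_scramble_colocalized,
             p$p_gamma_noise, p$p_falloff)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$p_aggregate + p$p_scramble > 1) {
    stop("p_aggregate + p_scramble must not exceed 1", call. = FALSE)
  }
  for (r in list(p$trans_prob_range, p$aa_mismatch_range,
                 p$bleedthrough_range, p$noise_sigma_range,
                 as.numeric(p$aggregate_size_range))) {
    if (length(r) != 2L || r[1] > r[2]) {
      stop("ranges must be ordered (low <= high) pairs", call. = FALSE)
    }
  }
  # feasibility of the minimum-separation rejection sampler
  if ((p$max_states - 1L) * p$min_state_separation > 1 + 1e-9) {
    stop("impossible state separation: (max_states - 1) * min_state_separation > 1",
         call. = FALSE)
  }
  if (!is.null(p$state_means)) {
    if (any(p$state_means < 0 | p$state_means > 1)) {
      stop("state_means must lie in [0, 1]", call. = FALSE)
    }
  }
  if (p$max_states > 1 && diff(p$trans_prob_range)[1] >= 0) {
    if (p$trans_prob_range[2] * (p$max_states - 1L) > 1) {
      stop("trans_prob * (n_states - 1) may exceed 1 under these priors",
           call. = FALSE)
    }
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic smFRET simulation priors\n")
  cat(sprintf("  %d frames/trace, up to %d states (min separation %.2f)\n",
              x$n_frames, x$max_states, x$min_state_separation))
  cat(sprintf("  transition prob ~ U(%.2f, %.2f); bleach lifetime %g frames\n",
              x$trans_prob_range[1], x$trans_prob_range[2], x$bleach_lifetime))
  cat(sprintf("  P(aggregate) = %.2f, P(scramble) = %.2f, P(blink) = %.2f\n",
              x$p_aggregate, x$p_scramble, x$p_blink))
  cat(sprintf("  noise sigma ~ U(%.2f, %.2f), noisy label above %.2f\n",
              x$noise_sigma_range[1], x$noise_sigma_range[2],
              x$noisy_sigma_threshold))
  cat(sprintf("  channels: %s\n", if (x$alex) "DD, DA, AA (ALEX)" else "DD, DA"))
  invisible(x)
}

#' Write / read simulation priors as JSON
#'
#' `write_params()` serializes a [sim_params()] object to a JSON file;
#' `read_params()` restores it (re-validating on the way in). Used by the
#' command-line interface so that every run can log its resolved
#' configuration.
#'
#' @param params A `sim_params` object.
#' @param path File path.
#' @return `read_params()` returns a `sim_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$state_means <- if (is.null(raw$state_means)) NULL else raw$state_means
  do.call(sim_params, raw)
}
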
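#' Draw the latent generative choices for one trace
#'
#' Samples a per-trace configuration from the population priors: trace class
#' (aggregate / scrambled / smFRET), number and values of FRET states
#' (uniform on \[0, 1\] with rejection until the minimum separation holds),
#' per-frame transition probability, noise level, detection artifacts,
#' photobleaching and fall-off times (exponential), blinking events and,
#' where applicable, aggregate size and scramble mode.
#'
#' Draws happen in a fixed, documented order so that a given RNG state
#' always produces the same configuration.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `trace_config`.
#' @export
sample_trace_config <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_frames

  # 1. trace class
  u <- runif(1)
  trace_class <- if (u < params$p_aggregate) {
    "aggregate"
  } else if (u < params$p_aggregate + params$p_scramble) {
    "scrambled"
  } else {
    "smFRET"
  }

  # 2-3. FRET states
  if (!is.null(params$state_means)) {
    fret_values <- params$state_means
    n_states <- length(fret_values)
  } else {
    n_states <- sample.int(params$max_states, 1L)
    fret_values <- draw_separated_fret(n_states, params$min_state_separation)
  }

  # 4-7. kinetics, noise, artifacts
  trans_prob <- runif(1, params$trans_prob_range[1], params$trans_prob_range[2])
  noise_sigma <- runif(1, params$noise_sigma_range[1],
                       params$noise_sigma_range[2])
  has_gamma_noise <- runif(1) < params$p_gamma_noise
  aa_mismatch <- runif(1, params$aa_mismatch_range[1],
                       params$aa_mismatch_range[2])
  bleedthrough <- runif(1, params$bleedthrough_range[1],
                        params$bleedthrough_range[2])

  # 8-9. photobleaching and fall-off (1-based index of first dark frame;
  # values beyond n_frames mean the event is not observed)
  donor_bleach <- floor(rexp(1, 1 / params$bleach_lifetime)) + 1
  acceptor_bleach <- floor(rexp(1, 1 / params$bleach_lifetime)) + 1
  falloff <- if (runif(1) < params$p_falloff) {
    floor(rexp(1, 1 / params$falloff_lifetime)) + 1
  } else {
    Inf
  }

  # 10. blinking (non-aggregate traces only); a blinking trace carries at
  # least one event so the stated prior is the probability of *containing*
  # photoblinking
  blink_events <- list()
  if (trace_class != "aggregate" && runif(1) < params$p_blink) {
    n_ev <- max(1L, rpois(1, params$blink_events_mean))
    if (n_ev > 0) {
      for (i in seq_len(n_ev)) {
        blink_events[[i]] <- list(
          start = sample.int(n, 1L),
          duration = max(1L, ceiling(rexp(1, 1 / params$blink_duration_mean))),
          channel = if (runif(1) < 0.5) "donor" else "acceptor"
        )
      }
    }
  }

  # 11. aggregate size
  aggregate_size <- if (trace_class == "aggregate") {
    sample(seq(params$aggregate_size_range[1], params$aggregate_size_range[2]),
           1L)
  } else {
    NA_integer_
  }

  # 12. scramble mode
  scramble_mode <- if (trace_class == "scrambled") {
    if (runif(1) < params$p_scramble_colocalized) {
      "miscolocalized"
    } else {
      sample(c("flip", "correlate", "bursts", "dark"), 1L)
    }
  } else {
    NA_character_
  }

  structure(list(
    trace_class = trace_class, n_states = n_states,
    fret_values = fret_values, trans_prob = trans_prob,
    noise_sigma = noise_sigma, has_gamma_noise = has_gamma_noise,
    aa_mismatch = aa_mismatch, bleedthrough = bleedthrough,
    donor_bleach = donor_bleach, acceptor_bleach = acceptor_bleach,
    falloff = falloff, blink_events = blink_events,
    aggregate_size = aggregate_size, scramble_mode = scramble_mode
  ), class = "trace_config")
}

draw_separated_fret <- function(n_states, min_sep, max_tries = 10000L) {
  if ((n_states - 1L) * min_sep > 1 + 1e-9) {
    stop("impossible state separation requested", call. = FALSE)
  }
  if (n_states == 1L) return(runif(1))
  for (i in seq_len(max_tries)) {
    v <- runif(n_states)
    if (min(diff(sort(v))) >= min_sep) return(v)
  }
  stop("could not draw separated FRET states", call. = FALSE)
}

#' Sample the hidden Markov state path of a molecule
#'
#' From any state the molecule jumps to each *other* state with probability
#' `trans_prob` per frame and stays put otherwise; with `k` states the total
#' leave probability is `trans_prob * (k - 1)` (e.g. at the prior maximum
#' 0.2 with four states: 0.6, i.e. a 0.4 probability of not transitioning).
#' The initial state is uniform.
#'
#' @param config A `trace_config` (or any list with `n_states` and
#'   `trans_prob`).
#' @param n_frames Number of frames to sample.
#' @return Integer vector of 1-based state indices.
#' @export
sample_state_sequence <- function(config, n_frames) {
  k <- config$n_states
  stopifnot(k >= 1L, config$trans_prob >= 0)
  if (config$trans_prob * (k - 1) > 1) {
    stop("trans_prob * (n_states - 1) exceeds 1")
  }
  .state_seq_cpp(as.integer(n_frames), as.integer(k), config$trans_prob)
}

#' Ideal (noise-free, unit-intensity) channel intensities
#'
#' Converts a state path plus FRET state values into ideal channel
#' intensities under unit total emission: `DD = 1 - E`,
#' `DA = -(DD * E) / (E - 1)` (which simplifies to `E`; the limiting value
#' `DA = 1` is used at `E = 1`), and `AA = 1` regardless of the FRET state.
#' Consequently `DD + DA = 1` exactly on every frame and the ideal
#' stoichiometry is 0.5.
#'
#' @param state_seq Integer state path (1-based).
#' @param fret_values FRET efficiency of each state.
#' @return List with numeric vectors `dd`, `da`, `aa` and `e`.
#' @export
ideal_intensities <- function(state_seq, fret_values) {
  if (any(state_seq < 1L | state_seq > length(fret_values))) {
    stop("state indices out of range of fret_values")
  }
  e <- fret_values[state_seq]
  dd <- 1 - e
  da <- ifelse(e == 1, 1, -(dd * e) / (e - 1))
  list(dd = dd, da = da, aa = rep(1, length(e)), e = e)
}

# Channel signal of a single donor/acceptor pair after photophysics.
# donor_b / acceptor_b / falloff are 1-based first-dark frames (may exceed
# the trace length). Donor bleach kills DD and DA (no excitation reaches
# the acceptor) while AA persists; acceptor bleach kills DA and AA and the
# donor recovers to full unit intensity; fall-off kills everything.
pair_signal <- function(e_ideal, donor_b, acceptor_b, falloff, blinks, n) {
  f <- seq_len(n)
  d_dark <- f >= donor_b | f >= falloff
  a_dark <- f >= acceptor_b | f >= falloff
  for (bl in blinks) {
    idx <- bl$start:min(n, bl$start + bl$duration - 1L)
    if (bl$channel == "donor") d_dark[idx] <- TRUE else a_dark[idx] <- TRUE
  }
  dd <- ifelse(d_dark, 0, ifelse(a_dark, 1, 1 - e_ideal))
  da <- ifelse(d_dark | a_dark, 0, e_ideal)
  aa <- ifelse(a_dark, 0, 1)
  list(dd = dd, da = da, aa = aa)
}

first_trailing_dark <- function(dd, da, aa) {
  total <- dd + da + aa
  live <- which(total > 0)
  if (length(live) == 0L) 1L else max(live) + 1L
}

#' Apply photobleaching, blinking, fall-off and aggregation
#'
#' Turns ideal unit intensities into the pre-noise signal of the molecule.
#' For aggregates, `aggregate_size` independent donor/acceptor pairs (same
#' FRET states and kinetics, independent state paths and bleach times) are
#' summed, producing the characteristic multi-step bleaching at
#' super-unitary intensity.
#'
#' @param ideal Output of [ideal_intensities()] for the primary pair.
#' @param config A `trace_config`.
#' @param params A [sim_params()] object.
#' @return List with `dd`, `da`, `aa` vectors and `first_dark`, the 1-based
#'   index of the first frame at which FRET observation is over (first
#'   bleach of either fluorophore or fall-off for single pairs; total signal
#'   loss for aggregates). `n_frames + 1` means the event is never observed.
#' @export
apply_photophysics <- function(ideal, config, params) {
  n <- params$n_frames
  sig <- pair_signal(ideal$e, config$donor_bleach, config$acceptor_bleach,
                     config$falloff, config$blink_events, n)
  if (config$trace_class == "aggregate") {
    for (j in seq_len(config$aggregate_size - 1L)) {
      st <- sample_state_sequence(config, n)
      ej <- config$fret_values[st]
      db <- floor(rexp(1, 1 / params$bleach_lifetime)) + 1
      ab <- floor(rexp(1, 1 / params$bleach_lifetime)) + 1
      pj <- pair_signal(ej, db, ab, config$falloff, list(), n)
      sig$dd <- sig$dd + pj$dd
      sig$da <- sig$da + pj$da
      sig$aa <- sig$aa + pj$aa
    }
    first_dark <- as.integer(min(first_trailing_dark(sig$dd, sig$da, sig$aa),
                                 config$falloff, n + 1L))
  } else {
    first_dark <- as.integer(min(config$donor_bleach,
                                 config$acceptor_bleach,
                                 config$falloff, n + 1L))
  }
  c(sig, list(first_dark = first_dark))
}

#' Scramble a trace into a non-FRET artifact
#'
#' Produces the "anything else" category the classifier must reject. Modes:
#' `miscolocalized` (DD from one molecule, DA/AA from an independent second
#' molecule, so bleaching steps are uncorrelated between channels), `flip`
#' (one channel time-reversed within its live window), `correlate` (DA
#' replaced by the rescaled product DD*DA, creating strong positive
#' correlation), `bursts` (random segments of high-amplitude noise) and
#' `dark` (random long dark segments).
#'
#' @param sig List with `dd`, `da`, `aa` and `first_dark` (as returned by
#'   [apply_photophysics()]).
#' @param config A `trace_config` with `trace_class == "scrambled"`.
#' @param params A [sim_params()] object.
#' @return Same shape as `sig`, with `first_dark` recomputed from the
#'   scrambled channels (first frame of the trailing all-dark run).
#' @export
apply_scramble <- function(sig, config, params) {
  stopifnot(config$trace_class == "scrambled")
  n <- params$n_frames
  mode <- config$scramble_mode
  live_end <- sig$first_dark - 1L

  if (mode == "miscolocalized") {
    # second, independent molecule supplies the acceptor-side channels
    k2 <- sample.int(params$max_states, 1L)
    f2 <- draw_separated_fret(k2, params$min_state_separation)
    tp2 <- runif(1, params$trans_prob_range[1], params$trans_prob_range[2])
    st2 <- .state_seq_cpp(n, k2, tp2)
    db2 <- floor(rexp(1, 1 / params$bleach_lifetime)) + 1
    ab2 <- floor(rexp(1, 1 / params$bleach_lifetime)) + 1
    p2 <- pair_signal(f2[st2], db2, ab2, config$falloff, list(), n)
    sig$da <- p2$da
    sig$aa <- p2$aa
  } else if (mode == "flip") {
    ch <- sample(c("dd", "da", "aa"), 1L)
    if (live_end >= 2L) sig[[ch]][1:live_end] <- rev(sig[[ch]][1:live_end])
  } else if (mode == "correlate") {
    if (live_end >= 1L) {
      idx <- 1:live_end
      prod <- sig$dd[idx] * sig$da[idx]
      m <- max(prod)
      sig$da[idx] <- if (m > 0) prod / m else prod
    }
  } else if (mode == "bursts") {
    n_seg <- 1L + rpois(1, 2)
    for (i in seq_len(n_seg)) {
      if (live_end < 1L) break
      s0 <- sample.int(live_end, 1L)
      len <- max(1L, ceiling(rexp(1, 1 / 20)))
      idx <- s0:min(live_end, s0 + len - 1L)
      for (ch in c("dd", "da", "aa")) {
        sig[[ch]][idx] <- sig[[ch]][idx] + abs(rnorm(length(idx), 0, 1))
      }
    }
  } else if (mode == "dark") {
    n_seg <- 1L + rpois(1, 1)
    for (i in seq_len(n_seg)) {
      if (live_end < 1L) break
      s0 <- sample.int(live_end, 1L)
      len <- max(1L, ceiling(rexp(1, 1 / 50)))
      idx <- s0:min(live_end, s0 + len - 1L)
      for (ch in c("dd", "da", "aa")) sig[[ch]][idx] <- 0
    }
  } else {
    stop("unknown scramble mode: ", mode)
  }

  sig$first_dark <- as.integer(min(first_trailing_dark(sig$dd, sig$da,
                                                       sig$aa),
                                   config$falloff, n + 1L))
  sig
}

#' Add detection artifacts and noise
#'
#' Applies the acceptor-only mismatch (AA multiplied by a factor in
#' \[0.7, 1.3\]), donor bleedthrough into the acceptor channel
#' (`DA <- DA + bleedthrough * DD`), and per-frame noise: Gaussian with the
#' trace's sigma (in units of the maximum single-fluorophore intensity),
#' plus, for most traces, a centred Gamma(1, 1.1) component scaled by the
#' same sigma to mimic the skewed tail of shot noise. Noise is added to
#' bleached frames too, as a real detector would.
#'
#' @param sig List with `dd`, `da`, `aa` channel vectors.
#' @param config A `trace_config`.
#' @param params A [sim_params()] object.
#' @return A [fret_trace()] (AA dropped when `params$alex` is `FALSE`).
#' @export
add_detection_artifacts <- function(sig, config, params) {
  n <- params$n_frames
  aa <- sig$aa * config$aa_mismatch
  da <- sig$da + config$bleedthrough * sig$dd
  dd <- sig$dd
  s <- config$noise_sigma
  noise <- function() {
    z <- rnorm(n, 0, s)
    if (config$has_gamma_noise) {
      z <- z + (rgamma(n, shape = params$gamma_shape,
                       scale = params$gamma_scale) -
                  params$gamma_shape * params$gamma_scale) * s
    }
    z
  }
  dd <- dd + noise()
  da <- da + noise()
  aa <- aa + noise()
  fret_trace(dd, da, if (params$alex) aa else NULL)
}

#' Ground-truth per-frame labels
#'
#' Assigns each frame one of the six classes. Frames at or after
#' `first_dark` are bleached (`"B"`). Live frames take the trace class:
#' aggregate (`"A"`) and scrambled (`"X"`) take precedence; smFRET traces
#' whose noise sigma exceeds the noisy threshold are `"N"`; the rest are
#' static (`"S"`) if only one state is visited within the observed (pre-
#' bleach) window and dynamic (`"D"`) otherwise, matching the notion of
#' "static within the experimental time frame".
#'
#' @param config A `trace_config`.
#' @param states Integer state path.
#' @param first_dark 1-based first bleached frame (`n_frames + 1` if none).
#' @param params A [sim_params()] object.
#' @return Factor of length `n_frames` with levels [fret_classes()].
#' @export
label_frames <- function(config, states, first_dark, params) {
  n <- params$n_frames
  lab <- rep("B", n)
  if (first_dark > 1L) {
    live <- seq_len(first_dark - 1L)
    cls <- if (config$trace_class == "aggregate") {
      "A"
    } else if (config$trace_class == "scrambled") {
      "X"
    } else if (config$noise_sigma > params$noisy_sigma_threshold) {
      "N"
    } else if (config$n_states == 1L ||
                 length(unique(states[live])) == 1L) {
      "S"
    } else {
      "D"
    }
    lab[live] <- cls
  }
  factor(lab, levels = FRET_CLASSES)
}

#' Smooth one-hot frame labels into training targets
#'
#' Label smoothing with strength `eps` over the six classes:
#' `(1 - eps) * onehot + eps / 6`, so e.g. at the default 0.05 the true
#' class gets 0.95833... and every other class 0.00833...
#'
#' @param labels Factor or character vector of frame labels.
#' @param eps Smoothing strength.
#' @return Numeric matrix (frames x 6), rows summing to 1; columns named
#'   after [fret_classes()].
#' @export
smooth_labels <- function(labels, eps = 0.05) {
  idx <- as.integer(factor(as.character(labels), levels = FRET_CLASSES))
  if (anyNA(idx)) stop("unknown labels present")
  m <- matrix(eps / 6, nrow = length(idx), ncol = 6,
              dimnames = list(NULL, FRET_CLASSES))
  m[cbind(seq_along(idx), idx)] <- (1 - eps) + eps / 6
  m
}

#' Simulate one labelled ground-truth trace
#'
#' Runs the full generative pipeline: configuration sampling, hidden state
#' path, ideal intensities, photophysics (bleaching, blinking, fall-off,
#' aggregation), optional scrambling, per-frame labelling, and finally
#' detection artifacts and noise.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional integer seed; when given, the trace is fully
#'   reproducible in isolation.
#' @return An object of class `labeled_trace`: a list with elements `trace`
#'   (a [fret_trace()]), `labels` (factor, one per frame), `class` (the
#'   trace-level label, i.e. the first-frame label), `config`, `states`,
#'   `ideal_fret` (ground-truth FRET value per frame) and `first_dark`.
#' @export
simulate_trace <- function(params = sim_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  config <- sample_trace_config(params)
  states <- sample_state_sequence(config, params$n_frames)
  ideal <- ideal_intensities(states, config$fret_values)
  sig <- apply_photophysics(ideal, config, params)
  if (config$trace_class == "scrambled") {
    sig <- apply_scramble(sig, config, params)
  }
  labels <- label_frames(config, states, sig$first_dark, params)
  trace <- add_detection_artifacts(sig, config, params)
  structure(list(
    trace = trace,
    labels = labels,
    class = as.character(labels[1]),
    config = config,
    states = states,
    ideal_fret = ideal$e,
    first_dark = sig$first_dark
  ), class = "labeled_trace")
}

#' @export
print.labeled_trace <- function(x, ...) {
  cat(sprintf("labelled trace: class %s, %d frames (%d live), %d state(s)\n",
              x$class, length(x$labels), x$first_dark - 1L,
              x$config$n_states))
  invisible(x)
}

#' Generate a (optionally class-balanced) labelled dataset
#'
#' Simulates `n` traces and, when `balance = TRUE`, (i) drops traces with
#' no live frame (first-frame label `"B"`) and (ii) under-samples so that
#' the five non-bleached classes have exactly the count of the rarest class,
#' judged by the first-frame label. Per-trace seeds are derived from `seed`
#' by a counter, so the dataset is bit-identical for a given seed and any
#' single trace can be regenerated in isolation.
#'
#' @param n Number of traces to simulate before balancing.
#' @param params A [sim_params()] object.
#' @param seed Integer seed (required for reproducibility; if `NULL` the
#'   current RNG stream is used and per-trace seeds are not recorded).
#' @param balance Under-sample to equal class counts?
#' @param keep `"full"` stores every labelled trace; `"summary"` stores only
#'   the per-trace summary table (class, noise, kinetics), which is enough
#'   for class-count studies and orders of magnitude lighter.
#' @return An object of class `fret_dataset`: list with `traces` (list of
#'   [simulate_trace()] results, or `NULL` for `keep = "summary"`),
#'   `summary` (data frame, one row per retained trace), `params`, `seed`.
#' @export
generate_dataset <- function(n, params = sim_params(), seed = NULL,
                             balance = TRUE, keep = c("full", "summary")) {
  keep <- match.arg(keep)
  n <- as.integer(n)
  store <- keep == "full"
  traces <- if (store) vector("list", n) else NULL
  cls <- character(n)
  sig <- numeric(n)
  nst <- integer(n)
  fd <- integer(n)
  tcl <- character(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      s_i <- if (is.null(seed)) NULL else (as.numeric(seed) + i) %% 2147483647
      lt <- simulate_trace(params, seed = s_i)
      if (store) traces[[i]] <- lt
      cls[i] <- lt$class
      sig[i] <- lt$config$noise_sigma
      nst[i] <- lt$config$n_states
      fd[i] <- lt$first_dark
      tcl[i] <- lt$config$trace_class
    }
  }
  summary <- data.frame(id = seq_len(n), class = cls, noise_sigma = sig,
                        n_states = nst, first_dark = fd, trace_class = tcl,
                        stringsAsFactors = FALSE)
  if (balance && n > 0) {
    keep_idx <- balance_first_frame(cls)
    summary <- summary[keep_idx, , drop = FALSE]
    if (store) traces <- traces[keep_idx]
  }
  structure(list(traces = traces, summary = summary, params = params,
                 seed = seed, balanced = balance),
            class = "fret_dataset")
}

# Under-sampling by first-frame class: each of the five non-bleached classes
# is cut to the size of the rarest one; bleached-from-frame-0 traces are
# dropped entirely.
balance_first_frame <- function(cls) {
  usable <- setdiff(FRET_CLASSES, "B")
  counts <- vapply(usable, function(k) sum(cls == k), integer(1))
  m <- min(counts)
  idx <- integer(0)
  for (k in usable) {
    idx <- c(idx, which(cls == k)[seq_len(min(m, sum(cls == k)))])
  }
  sort(idx)
}

#' @export
print.fret_dataset <- function(x, ...) {
  cat(sprintf("fret_dataset: %d trace(s)%s%s\n", nrow(x$summary),
              if (x$balanced) ", class-balanced" else "",
              if (is.null(x$traces)) " (summary only)" else ""))
  print(table(factor(x$summary$class, levels = FRET_CLASSES)))
  invisible(x)
}
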
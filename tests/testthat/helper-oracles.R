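# Independent brute-force oracles used across tests.

# Exhaustive sliding-window scan: first 1-based start i such that at least
# min_hits of the frames i..min(i+window-1, n) are hits.
brute_window_scan <- function(hit, window = 7L, min_hits = 4L) {
  n <- length(hit)
  for (i in seq_len(n)) {
    if (sum(hit[i:min(n, i + window - 1L)]) >= min_hits) return(i)
  }
  NA_integer_
}

# Direct counting of confusion cells from logical vectors.
brute_precision_recall <- function(accepted, truth) {
  tp <- sum(accepted & truth)
  fp <- sum(accepted & !truth)
  fn <- sum(!accepted & truth)
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

# A minimal hand-built trace_config for unit tests, bypassing the priors.
make_config <- function(trace_class = "smFRET", n_states = 1L,
                        fret_values = 0.5, trans_prob = 0,
                        noise_sigma = 0.05, has_gamma_noise = FALSE,
                        aa_mismatch = 1, bleedthrough = 0,
                        donor_bleach = Inf, acceptor_bleach = Inf,
                        falloff = Inf, blink_events = list(),
                        aggregate_size = NA_integer_,
                        scramble_mode = NA_character_) {
  structure(list(trace_class = trace_class, n_states = n_states,
                 fret_values = fret_values, trans_prob = trans_prob,
                 noise_sigma = noise_sigma,
                 has_gamma_noise = has_gamma_noise,
                 aa_mismatch = aa_mismatch, bleedthrough = bleedthrough,
                 donor_bleach = donor_bleach,
                 acceptor_bleach = acceptor_bleach, falloff = falloff,
                 blink_events = blink_events,
                 aggregate_size = aggregate_size,
                 scramble_mode = scramble_mode),
            class = "trace_config")
}

# Params used when tests need cheap, artifact-free smFRET traces.
clean_params <- function(...) {
  sim_params(p_aggregate = 0, p_scramble = 0, p_blink = 0, p_falloff = 0,
             p_gamma_noise = 0, ...)
}
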
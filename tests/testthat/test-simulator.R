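test_that("parameter validation rejects impossible priors", {
  expect_error(sim_params(p_aggregate = 1.2), "probabilities")
  expect_error(sim_params(noise_sigma_range = c(0.3, 0.1)), "ordered")
  expect_error(sim_params(max_states = 12L, min_state_separation = 0.1),
               "impossible")
  expect_error(sim_params(n_frames = 0), "n_frames")
  expect_s3_class(sim_params(), "sim_params")
})

test_that("sim_params round-trips through JSON", {
  p <- sim_params(p_aggregate = 0.3, state_means = c(0.2, 0.8),
                  noise_sigma_range = c(0.05, 0.11))
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(p2, p)
})

test_that("trace class priors follow the stated probabilities", {
  set.seed(101)
  p <- sim_params()
  n <- 4000L
  cls <- character(n)
  blink <- logical(n)
  for (i in seq_len(n)) {
    cfg <- sample_trace_config(p)
    cls[i] <- cfg$trace_class
    blink[i] <- cfg$trace_class != "aggregate" &&
      length(cfg$blink_events) > 0
  }
  se <- function(q) sqrt(q * (1 - q) / n)
  expect_lt(abs(mean(cls == "aggregate") - 0.15), 3 * se(0.15))
  expect_lt(abs(mean(cls == "scrambled") - 0.15), 3 * se(0.15))
  # degenerate prior: everything is an aggregate
  p1 <- sim_params(p_aggregate = 1, p_scramble = 0)
  cfgs <- replicate(50, sample_trace_config(p1)$trace_class)
  expect_true(all(cfgs == "aggregate"))
})

test_that("FRET states respect the minimum separation and range", {
  set.seed(7)
  p <- sim_params()
  for (i in 1:300) {
    cfg <- sample_trace_config(p)
    expect_true(all(cfg$fret_values >= 0 & cfg$fret_values <= 1))
    if (cfg$n_states > 1) {
      expect_gte(min(diff(sort(cfg$fret_values))), p$min_state_separation)
    }
    expect_length(cfg$fret_values, cfg$n_states)
  }
})

test_that("state sequences have the stated Markov kinetics", {
  set.seed(11)
  # no transitions
  cfg <- make_config(n_states = 3L, fret_values = c(0.1, 0.5, 0.9),
                     trans_prob = 0)
  expect_length(unique(sample_state_sequence(cfg, 500L)), 1L)
  # stay probability with 4 states at the prior maximum: 1 - 0.2*3 = 0.4
  cfg4 <- make_config(n_states = 4L, fret_values = c(0.1, 0.4, 0.7, 1.0),
                      trans_prob = 0.2)
  s <- sample_state_sequence(cfg4, 100000L)
  stay <- mean(s[-1] == s[-length(s)])
  expect_lt(abs(stay - 0.4), 0.01)
  # mean dwell length for 2 states at 0.1 is 10 frames (geometric)
  cfg2 <- make_config(n_states = 2L, fret_values = c(0.3, 0.7),
                      trans_prob = 0.1)
  s2 <- sample_state_sequence(cfg2, 100000L)
  d <- rle(s2)$lengths
  d <- d[-length(d)]  # final dwell is censored
  expect_lt(abs(mean(d) - 10) / 10, 0.05)
  # all states are visited roughly uniformly
  occ <- tabulate(s, 4) / length(s)
  expect_true(all(abs(occ - 0.25) < 0.02))
})

test_that("ideal intensities follow the unit-intensity FRET algebra", {
  out <- ideal_intensities(1L, 0.3)
  expect_equal(out$dd, 0.7)
  expect_equal(out$da, 0.3)
  expect_equal(out$aa, 1)
  # stoichiometry of the ideal trace is exactly 0.5
  tr <- fret_trace(out$dd, out$da, out$aa)
  expect_equal(observed_es(tr)$s, 0.5)
  # symmetry at E = 0.5
  out5 <- ideal_intensities(1L, 0.5)
  expect_equal(out5$dd, out5$da)
  # the explicit formula -(DD*E)/(E-1) equals the Eq-1 inversion E for a
  # grid of efficiencies, including the E = 1 limit
  es <- seq(0, 1, by = 0.05)
  out_grid <- ideal_intensities(seq_along(es), es)
  expect_equal(out_grid$da, es)
  expect_equal(out_grid$dd + out_grid$da, rep(1, length(es)))
})

test_that("conservation: DD + DA = 1 on live frames before artifacts", {
  set.seed(3)
  p <- clean_params()
  for (i in 1:20) {
    cfg <- sample_trace_config(p)
    st <- sample_state_sequence(cfg, p$n_frames)
    ideal <- ideal_intensities(st, cfg$fret_values)
    sig <- apply_photophysics(ideal, cfg, p)
    live <- seq_len(sig$first_dark - 1L)
    if (length(live)) {
      expect_equal(sig$dd[live] + sig$da[live], rep(1, length(live)))
    }
  }
})

test_that("photobleaching semantics per fluorophore", {
  p <- clean_params()
  n <- p$n_frames
  # acceptor bleaches at frame 101 (1-based): donor recovers fully,
  # DA and AA go dark, S becomes 1
  cfg <- make_config(fret_values = 0.3, acceptor_bleach = 101)
  ideal <- ideal_intensities(rep(1L, n), cfg$fret_values)
  sig <- apply_photophysics(ideal, cfg, p)
  expect_equal(sig$dd[101:n], rep(1, n - 100))
  expect_equal(sig$da[101:n], rep(0, n - 100))
  expect_equal(sig$aa[101:n], rep(0, n - 100))
  s_post <- observed_es(fret_trace(sig$dd, sig$da, sig$aa))$s[101]
  expect_equal(s_post, 1)
  expect_equal(sig$first_dark, 101L)
  # donor bleach: DD and DA dark, AA persists
  cfg_d <- make_config(fret_values = 0.3, donor_bleach = 51)
  sig_d <- apply_photophysics(ideal, cfg_d, p)
  expect_equal(sig_d$dd[51:n], rep(0, n - 50))
  expect_equal(sig_d$aa[51:n], rep(1, n - 50))
  expect_equal(sig_d$first_dark, 51L)
  # both bleach immediately: no live frame, everything labelled bleached
  cfg_0 <- make_config(donor_bleach = 1, acceptor_bleach = 1)
  sig_0 <- apply_photophysics(ideal, cfg_0, p)
  expect_true(all(sig_0$dd == 0 & sig_0$da == 0 & sig_0$aa == 0))
  lab <- label_frames(cfg_0, rep(1L, n), sig_0$first_dark, p)
  expect_true(all(lab == "B"))
})

test_that("aggregates sum independent pairs with stepwise bleaching", {
  set.seed(21)
  p <- sim_params()
  cfg <- make_config(trace_class = "aggregate", aggregate_size = 3L,
                     fret_values = 0.4, donor_bleach = 150,
                     acceptor_bleach = 400)
  ideal <- ideal_intensities(rep(1L, p$n_frames), cfg$fret_values)
  sig <- apply_photophysics(ideal, cfg, p)
  # donor-excited total starts at the number of pairs and only decreases
  tot <- sig$dd + sig$da
  expect_equal(tot[1], 3)
  expect_true(all(diff(tot) <= 1e-12))
  # direct acceptor excitation likewise decreases stepwise
  expect_true(all(diff(sig$aa) <= 1e-12))
})

test_that("scramble modes produce the stated artifacts", {
  p <- sim_params()
  n <- p$n_frames
  set.seed(5)
  # flip of a constant channel is a no-op
  cfg <- make_config(trace_class = "scrambled", scramble_mode = "flip",
                     fret_values = 0.5)
  sig <- list(dd = rep(0.5, n), da = rep(0.5, n), aa = rep(1, n),
              first_dark = n + 1L)
  out <- apply_scramble(sig, cfg, p)
  expect_equal(out[c("dd", "da", "aa")], sig[c("dd", "da", "aa")])
  # correlate mode: the acceptor channel becomes a rescaled copy of the
  # product, so with a steady acceptor it tracks the donor exactly
  cfg_c <- make_config(trace_class = "scrambled",
                       scramble_mode = "correlate")
  dd <- runif(n, 0.2, 1)
  sig_c <- list(dd = dd, da = rep(0.8, n), aa = rep(1, n),
                first_dark = n + 1L)
  out_c <- apply_scramble(sig_c, cfg_c, p)
  expect_gt(cor(out_c$dd, out_c$da), 0.9)
  expect_lte(max(out_c$da), 1)
})

test_that("mis-colocalized channels have independent bleach times", {
  set.seed(31)
  p <- sim_params(p_aggregate = 0, p_scramble = 1,
                  p_scramble_colocalized = 1, p_blink = 0, p_falloff = 0)
  n_tr <- 400L
  dd_end <- numeric(n_tr)
  aa_end <- numeric(n_tr)
  for (i in seq_len(n_tr)) {
    cfg <- sample_trace_config(p)
    st <- sample_state_sequence(cfg, p$n_frames)
    sig <- apply_photophysics(ideal_intensities(st, cfg$fret_values), cfg, p)
    sig <- apply_scramble(sig, cfg, p)
    last_on <- function(x) if (any(x > 0)) max(which(x > 0)) else 0L
    dd_end[i] <- last_on(sig$dd)
    aa_end[i] <- last_on(sig$aa)
  }
  # donor-side and acceptor-side survival are uncorrelated across molecules
  keep <- dd_end > 0 & dd_end < p$n_frames & aa_end > 0 &
    aa_end < p$n_frames
  expect_gt(sum(keep), 50)
  expect_lt(abs(cor(dd_end[keep], aa_end[keep])), 0.15)
})

test_that("detection artifacts: mismatch, bleedthrough and noise", {
  p <- sim_params()
  n <- p$n_frames
  sig <- list(dd = rep(1, n), da = rep(0, n), aa = rep(1, n))
  # sigma = 0, mismatch = 1, bleedthrough = 0: identity
  cfg_id <- make_config(noise_sigma = 0)
  tr <- add_detection_artifacts(sig, cfg_id, p)
  expect_equal(tr$dd, sig$dd)
  expect_equal(tr$da, sig$da)
  expect_equal(tr$aa, sig$aa)
  # 15% bleedthrough of a unit donor appears in the acceptor channel
  cfg_bt <- make_config(noise_sigma = 0, bleedthrough = 0.15)
  tr_bt <- add_detection_artifacts(sig, cfg_bt, p)
  expect_equal(tr_bt$da, rep(0.15, n))
  # Gaussian noise amplitude is as configured
  set.seed(9)
  p_long <- sim_params(n_frames = 10000L)
  sig_l <- list(dd = rep(1, 10000L), da = rep(0, 10000L),
                aa = rep(1, 10000L))
  cfg_n <- make_config(noise_sigma = 0.1)
  tr_n <- add_detection_artifacts(sig_l, cfg_n, p_long)
  expect_lt(abs(sd(tr_n$dd - 1) - 0.1) / 0.1, 0.02)
  # centred gamma component adds variance but keeps the mean at zero
  cfg_g <- make_config(noise_sigma = 0.1, has_gamma_noise = TRUE)
  tr_g <- add_detection_artifacts(sig_l, cfg_g, p_long)
  expect_lt(abs(mean(tr_g$dd - 1)), 0.01)
  expect_gt(sd(tr_g$dd - 1), 0.12)
})

test_that("frame labels follow the class priority rules", {
  p <- sim_params()
  n <- p$n_frames
  st1 <- rep(1L, n)
  # sigma just above the noisy threshold turns a clean single state noisy
  cfg_n <- make_config(noise_sigma = 0.26)
  lab <- label_frames(cfg_n, st1, n + 1L, p)
  expect_true(all(lab == "N"))
  # at/below the threshold it stays static
  cfg_s <- make_config(noise_sigma = 0.25)
  expect_true(all(label_frames(cfg_s, st1, n + 1L, p) == "S"))
  # a two-state trace whose only transition happens after bleaching is
  # static within the observation window
  st2 <- c(rep(1L, 100), rep(2L, n - 100))
  cfg_2 <- make_config(n_states = 2L, fret_values = c(0.3, 0.7),
                       donor_bleach = 51)
  lab2 <- label_frames(cfg_2, st2, 51L, p)
  expect_true(all(lab2[1:50] == "S"))
  expect_true(all(lab2[51:n] == "B"))
  # the same trace observed in full is dynamic
  expect_true(all(label_frames(cfg_2, st2, n + 1L, p)[1:n] == "D"))
  # aggregate and scrambled labels take precedence over noise
  cfg_a <- make_config(trace_class = "aggregate", noise_sigma = 0.29,
                       aggregate_size = 2L)
  expect_true(all(label_frames(cfg_a, st1, n + 1L, p) == "A"))
})

test_that("label smoothing arithmetic", {
  m <- smooth_labels(c("S", "B"), eps = 0.05)
  expect_equal(unname(m[1, "S"]), 0.95 + 0.05 / 6)
  expect_equal(unname(m[1, "B"]), 0.05 / 6)
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_equal(unname(m[1, "S"]), 0.9583333, tolerance = 1e-6)
  expect_equal(unname(m[1, "A"]), 0.008333333, tolerance = 1e-6)
})

test_that("dataset generation balances, under-samples and reproduces", {
  # empty request
  expect_equal(nrow(generate_dataset(0, sim_params(), seed = 1)$summary), 0L)
  # under-sampling oracle on forced class counts
  cls <- c(rep("A", 10), rep("N", 20), rep("X", 30), rep("S", 40),
           rep("D", 50), rep("B", 7))
  idx <- fretsort:::balance_first_frame(cls)
  expect_length(idx, 50L)
  expect_equal(as.integer(table(cls[idx])), rep(10L, 5))
  expect_false(any(cls[idx] == "B"))
  # determinism: identical seed gives a bit-identical dataset
  p <- sim_params()
  d1 <- generate_dataset(40, p, seed = 77)
  d2 <- generate_dataset(40, p, seed = 77)
  expect_identical(d1$summary, d2$summary)
  expect_identical(d1$traces, d2$traces)
  # summary mode matches the full run trace for trace
  d3 <- generate_dataset(40, p, seed = 77, keep = "summary")
  expect_identical(d3$summary, d1$summary)
})

test_that("observable E and S handle undefined denominators", {
  tr <- fret_trace(dd = c(0.7, 1, 0), da = c(0.3, 0, 0),
                   aa = c(1, 0, 0))
  es <- observed_es(tr)
  expect_equal(es$e, c(0.3, 0, NA))
  expect_equal(es$s, c(0.5, 1, NA))
  # non-ALEX: S undefined everywhere
  tr2 <- fret_trace(dd = c(0.7, 0.5), da = c(0.3, 0.5))
  expect_true(all(is.na(observed_es(tr2)$s)))
})
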
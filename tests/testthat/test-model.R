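test_that("normalization preserves ratios and hits a unit maximum", {
  tr <- fret_trace(dd = c(1000, 500, 20), da = c(400, 100, 4),
                   aa = c(800, 300, 2))
  nt <- normalize_trace(tr)
  expect_equal(max(c(nt$dd, nt$da, nt$aa)), 1)
  expect_equal(nt$da[1], 0.4)
  # channel ratios are untouched
  expect_equal(nt$dd / nt$da, tr$dd / tr$da)
  # idempotent
  nt2 <- normalize_trace(nt)
  expect_equal(nt2, nt)
  # impossible input is refused
  expect_error(normalize_trace(fret_trace(dd = c(-1, 0), da = c(0, 0),
                                          aa = c(0, 0))),
               "positive")
})

test_that("full-scale spec enumerates the filter/kernel schedule", {
  spec <- nn_spec_full()
  expect_equal(spec$filters,
               as.integer(rep(c(32, 64, 128, 256), each = 4)))
  expect_equal(spec$kernels, as.integer(rep(c(16, 12, 8, 4), each = 4)))
  expect_error(nn_spec(n_channels = 4), "must be 2 or 3")
  # kernel never shrinks below 4 even for deeper stacks
  deep <- nn_spec(n_res_blocks = 24, kernel_start = 16, kernel_step = 4)
  expect_gte(min(deep$kernels), 4)
})

test_that("untrained network outputs per-frame row-stochastic probabilities", {
  set.seed(1)
  spec <- nn_spec(n_channels = 3, n_res_blocks = 2, base_filters = 4,
                  lstm_units = 4)
  params <- fretsort:::init_nn_params(spec)
  rstats <- fretsort:::init_run_stats(spec)
  x <- array(rnorm(300 * 3 * 3), dim = c(300, 3, 3))
  out <- fretsort:::.nn_core_cpp(params, rstats,
                                 fretsort:::spec_for_cpp(spec), x, NULL,
                                 FALSE, FALSE)
  expect_equal(dim(out$probs), c(300, 6, 3))
  expect_true(all(abs(apply(out$probs, c(1, 3), sum) - 1) < 1e-5))
  expect_true(all(out$probs >= 0 & out$probs <= 1))
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  spec <- nn_spec(n_channels = 2, n_res_blocks = 2, base_filters = 3,
                  grow_every = 1, kernel_start = 5, kernel_step = 1,
                  lstm_units = 3, dropout = 0)
  params <- fretsort:::init_nn_params(spec)
  rstats <- fretsort:::init_run_stats(spec)
  cspec <- fretsort:::spec_for_cpp(spec)
  Tn <- 8L; B <- 2L
  x <- array(rnorm(Tn * 2 * B), dim = c(Tn, 2, B))
  y <- array(0, dim = c(Tn, 6, B))
  for (s in seq_len(B)) for (t in seq_len(Tn)) y[t, sample(6, 1), s] <- 1
  out <- fretsort:::.nn_core_cpp(params, rstats, cspec, x, y, TRUE, TRUE)
  lossfn <- function(pp) {
    fretsort:::.nn_core_cpp(pp, rstats, cspec, x, y, TRUE, FALSE)$loss
  }
  # the network computes in float32, so the finite-difference step and
  # tolerance are sized for single precision
  eps <- 1e-2
  for (nm in c("conv0_W", "b0_cA_W", "b1_bn1_g", "b1_proj_W",
               "lstm_f_Wx", "lstm_b_Wh", "dense_W")) {
    w <- params[[nm]]
    for (i in sample(length(w), 3)) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      ana <- out$grads[[nm]][i]
      expect_lt(abs(num - ana), 2e-3 + 0.02 * (abs(num) + abs(ana)))
    }
  }
})

test_that("predictions are per-trace independent and batch-order invariant", {
  set.seed(5)
  spec <- nn_spec(n_channels = 3, n_res_blocks = 2, base_filters = 4,
                  lstm_units = 4)
  model <- structure(list(params = fretsort:::init_nn_params(spec),
                          run_stats = fretsort:::init_run_stats(spec),
                          spec = spec, history = data.frame(),
                          classes = fret_classes()),
                     class = "fret_nn")
  mk <- function() {
    fret_trace(dd = runif(60), da = runif(60), aa = runif(60))
  }
  tr1 <- mk(); tr2 <- mk(); tr3 <- mk()
  # duplicated trace in a batch: identical outputs for both copies
  pr <- predict(model, list(tr1, tr2, tr1))
  # float32 compute: identical up to single-precision rounding
  expect_equal(pr[[1]], pr[[3]], tolerance = 1e-6)
  # shuffling batch order leaves each trace's prediction unchanged
  pr2 <- predict(model, list(tr3, tr1, tr2))
  expect_equal(pr2[[2]], pr[[1]], tolerance = 1e-6)
  expect_equal(pr2[[3]], pr[[2]], tolerance = 1e-6)
  # single-trace interface returns one matrix
  single <- predict(model, tr1)
  expect_equal(dim(single), c(60L, 6L))
  expect_equal(single, pr[[1]], tolerance = 1e-6)
  # channel mismatch is an explicit error
  expect_error(predict(model, fret_trace(dd = runif(60), da = runif(60))),
               "channel mismatch")
})

test_that("a short training run reduces the loss and reproduces", {
  set.seed(9)
  p <- sim_params()
  ds <- generate_dataset(120, p, seed = 31)
  spec <- nn_spec(n_channels = 3, n_res_blocks = 1, base_filters = 4,
                  lstm_units = 4, dropout = 0.1)
  cfg <- train_config(epochs = 3, batch_size = 16)
  m1 <- train_classifier(ds, spec, cfg, seed = 5, verbose = FALSE)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  # training is reproducible under a fixed seed
  m2 <- train_classifier(ds, spec, cfg, seed = 5, verbose = FALSE)
  expect_equal(m1$params, m2$params)
  expect_equal(m1$history, m2$history)
  # model bundle round trip re-validates the architecture digest
  f <- tempfile(fileext = ".rds")
  save_model(m1, f)
  m3 <- load_model(f)
  expect_equal(m3$params, m1$params)
  expect_error(train_classifier(list(x = array(0, c(10, 2, 4)),
                                     y = array(0, c(10, 6, 4))),
                                spec, cfg),
               "channel mismatch")
  # a dataset where every frame carries one class is degenerate
  y1 <- array(0, c(10, 6, 4)); y1[, 5, ] <- 1
  expect_warning(train_classifier(list(x = array(rnorm(120), c(10, 3, 4)),
                                       y = y1),
                                  spec, train_config(epochs = 1,
                                                     batch_size = 2),
                                  seed = 1, verbose = FALSE),
                 "degenerate")
})

test_that("label-smoothed training targets match the stated arithmetic", {
  ds <- structure(list(traces = list(structure(list(
    trace = fret_trace(dd = rep(0.5, 4), da = rep(0.5, 4),
                       aa = rep(1, 4)),
    labels = factor(c("S", "S", "B", "B"), levels = fret_classes())
  ), class = "labeled_trace")), summary = data.frame(id = 1),
  params = sim_params(), seed = 1, balanced = FALSE),
  class = "fret_dataset")
  arr <- training_arrays(ds, label_smoothing = 0.05)
  expect_equal(arr$y[1, 5, 1], 0.95 + 0.05 / 6)
  expect_equal(arr$y[1, 1, 1], 0.05 / 6)
  expect_equal(sum(arr$y[1, , 1]), 1)
})
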
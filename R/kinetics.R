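#' Fit a Gaussian-emission hidden Markov model to a trace
#'
#' Idealizes a FRET trace with a K-state HMM fitted by expectation-
#' maximization (Baum-Welch) with diagonal Gaussian emissions, followed by
#' Viterbi decoding of the most probable state path. The observation can
#' be the 1-D FRET efficiency series (`observation = "fret"`) or the 2-D
#' (DD, DA) channel series (`observation = "channels"`). Only live
#' (pre-bleach) frames should be supplied; for a `labeled_trace` the live
#' window is taken automatically.
#'
#' Initialization is deterministic: frames are ranked by the first
#' observation dimension and split into K contiguous groups whose means
#' seed the emission model, so repeated fits are identical. States are
#' reported sorted by ascending mean.
#'
#' @param x A [fret_trace()], `labeled_trace`, numeric vector (E series) or
#'   numeric matrix (frames x dims).
#' @param n_states Number of states K.
#' @param observation `"fret"` or `"channels"` (traces only).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return An object of class `fret_hmm`: state `means` (K x d), `vars`,
#'   row-stochastic `transition` matrix, `start` probabilities, Viterbi
#'   `path`, `log_likelihood`, `bic`, `n_states`, `n_obs`.
#' @examples
#' e <- rep(c(0.3, 0.7), each = 25)
#' fit <- fit_hmm(e + rnorm(50, 0, 0.01), n_states = 2)
#' fit$means
#' @export
fit_hmm <- function(x, n_states, observation = c("fret", "channels"),
                    max_iter = 200L, tol = 1e-6) {
  observation <- match.arg(observation)
  Y <- hmm_observations(x, observation)
  K <- as.integer(n_states)
  n <- nrow(Y)
  if (K < 1L) stop("n_states must be >= 1")
  if (n < K + 2L) stop("too few live frames to fit ", K, " states")
  fit <- gauss_hmm_em(Y, K, max_iter = max_iter, tol = tol)
  d <- ncol(Y)
  k_params <- K * (K - 1) + K * d + K * d + (K - 1)
  fit$bic <- -2 * fit$log_likelihood + k_params * log(n)
  fit$k_params <- k_params
  fit$n_obs <- n
  fit$observation <- observation
  class(fit) <- "fret_hmm"
  fit
}

hmm_observations <- function(x, observation) {
  if (inherits(x, "labeled_trace")) {
    live <- seq_len(min(x$first_dark - 1L, x$trace$n_frames))
    tr <- x$trace
    if (observation == "fret") {
      e <- observed_es(tr)$e[live]
      return(matrix(e[!is.na(e)], ncol = 1))
    }
    return(cbind(tr$dd[live], tr$da[live]))
  }
  if (inherits(x, "fret_trace")) {
    if (observation == "fret") {
      e <- observed_es(x)$e
      return(matrix(e[!is.na(e)], ncol = 1))
    }
    return(cbind(x$dd, x$da))
  }
  if (is.matrix(x)) return(x)
  matrix(as.numeric(x), ncol = 1)
}

gauss_hmm_em <- function(Y, K, max_iter = 200L, tol = 1e-6) {
  n <- nrow(Y)
  d <- ncol(Y)
  # deterministic quantile-style initialization: rank frames by the first
  # dimension and seed the K means from contiguous rank groups
  ord <- order(Y[, 1])
  grp <- rep(seq_len(K), each = ceiling(n / K), length.out = n)
  mu <- matrix(0, K, d)
  for (k in seq_len(K)) {
    mu[k, ] <- colMeans(Y[ord[grp == k], , drop = FALSE])
  }
  v0 <- pmax(apply(Y, 2, var) / K, 1e-6)
  sig <- matrix(rep(v0, each = K), nrow = K)
  A <- matrix(0.05 / max(1, K - 1), K, K)
  diag(A) <- if (K > 1) 0.95 else 1
  pi0 <- rep(1 / K, K)

  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # emission densities (diagonal Gaussian, log scale)
    logB <- matrix(0, n, K)
    for (k in seq_len(K)) {
      lk <- 0
      for (j in seq_len(d)) {
        lk <- lk + dnorm(Y[, j], mu[k, j], sqrt(sig[k, j]), log = TRUE)
      }
      logB[, k] <- lk
    }
    B <- exp(logB - apply(logB, 1, max))

    # scaled forward-backward
    alpha <- matrix(0, n, K)
    beta <- matrix(0, n, K)
    cscale <- numeric(n)
    a <- pi0 * B[1, ]
    cscale[1] <- sum(a)
    alpha[1, ] <- a / cscale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% A) * B[t, ]
      cscale[t] <- sum(a)
      alpha[t, ] <- a / cscale[t]
    }
    beta[n, ] <- 1
    for (t in (n - 1):1) {
      b <- A %*% (B[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b / cscale[t + 1]
    }
    loglik <- sum(log(cscale)) + sum(apply(logB, 1, max))

    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)

    # transition expectations
    if (K > 1) {
      xi_sum <- matrix(0, K, K)
      for (t in seq_len(n - 1)) {
        xi <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * A
        xi_sum <- xi_sum + xi / sum(xi)
      }
      A <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    }
    pi0 <- gamma[1, ]
    for (k in seq_len(K)) {
      w <- gamma[, k]
      sw <- sum(w)
      mu[k, ] <- colSums(Y * w) / sw
      for (j in seq_len(d)) {
        sig[k, j] <- max(sum(w * (Y[, j] - mu[k, j])^2) / sw, 1e-8)
      }
    }
    if (is.finite(loglik_old) &&
        abs(loglik - loglik_old) < tol * (abs(loglik_old) + 1)) {
      loglik_old <- loglik
      break
    }
    loglik_old <- loglik
  }

  # sort states by ascending mean of the first dimension
  ordk <- order(mu[, 1])
  mu <- mu[ordk, , drop = FALSE]
  sig <- sig[ordk, , drop = FALSE]
  A <- A[ordk, ordk, drop = FALSE]
  pi0 <- pi0[ordk]

  path <- viterbi_path(Y, mu, sig, A, pi0)
  list(means = mu, vars = sig, transition = A, start = pi0, path = path,
       log_likelihood = loglik_old, n_states = K, n_iter = iter)
}

viterbi_path <- function(Y, mu, sig, A, pi0) {
  n <- nrow(Y)
  K <- nrow(mu)
  d <- ncol(Y)
  logB <- matrix(0, n, K)
  for (k in seq_len(K)) {
    lk <- 0
    for (j in seq_len(d)) {
      lk <- lk + dnorm(Y[, j], mu[k, j], sqrt(sig[k, j]), log = TRUE)
    }
    logB[, k] <- lk
  }
  logA <- log(pmax(A, 1e-300))
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(pmax(pi0, 1e-300)) + logB[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (k in seq_len(K)) {
        cand <- delta[t - 1, ] + logA[, k]
        psi[t, k] <- which.max(cand)
        delta[t, k] <- cand[psi[t, k]] + logB[t, k]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' @export
print.fret_hmm <- function(x, ...) {
  cat(sprintf("Gaussian HMM fit: %d state(s), %d frames, logL = %.2f, BIC = %.2f\n",
              x$n_states, x$n_obs, x$log_likelihood, x$bic))
  cat("state means:", paste(sprintf("%.3f", x$means[, 1]), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
logLik.fret_hmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$k_params,
            nobs = object$n_obs, class = "logLik")
}

#' Select the number of FRET states by BIC
#'
#' Fits HMMs with `K = 1 .. k_max` states and picks the one minimizing the
#' Bayesian information criterion
#' `BIC = -2 logL + k_params * log(n_frames)`; ties break toward fewer
#' states.
#'
#' @inheritParams fit_hmm
#' @param k_max Largest state count to consider.
#' @return List with `best_k`, `bic` (per-K table), and `fits`.
#' @export
select_n_states <- function(x, k_max = 4L, observation = c("fret", "channels"),
                            ...) {
  observation <- match.arg(observation)
  fits <- lapply(seq_len(k_max), function(k) {
    fit_hmm(x, n_states = k, observation = observation, ...)
  })
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- which.min(bics)  # which.min returns the first (smallest K) on ties
  list(best_k = best, bic = data.frame(k = seq_len(k_max), bic = bics),
       fits = fits)
}

#' Dwell-time and transition-density statistics
#'
#' Segments the idealized state paths of one or more HMM fits into dwells,
#' flags the final dwell of each trace as right-censored (its true duration
#' is unknown), fits a per-state exponential lifetime by maximum likelihood
#' on the uncensored dwells, and collects the transition-density pairs
#' (mean FRET before, mean FRET after) for every transition.
#'
#' @param fits A `fret_hmm` fit or a list of them.
#' @return An object of class `dwell_stats`: `dwells` (data frame with
#'   trace, state, duration, censored), `lifetimes` (per-state exponential
#'   mean with normal-approximation 95% CI; `NA` when no uncensored dwells
#'   exist), and `tdp` (data frame of transitions with `e_before`,
#'   `e_after`).
#' @export
dwell_statistics <- function(fits) {
  if (inherits(fits, "fret_hmm")) fits <- list(fits)
  stopifnot(length(fits) >= 1L)
  dwell_rows <- list()
  tdp_rows <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    r <- rle(f$path)
    nseg <- length(r$lengths)
    dwell_rows[[i]] <- data.frame(
      trace = i, state = r$values, duration = r$lengths,
      censored = seq_len(nseg) == nseg
    )
    if (nseg > 1) {
      means <- f$means[, 1]
      tdp_rows[[i]] <- data.frame(
        trace = i,
        e_before = means[r$values[-nseg]],
        e_after = means[r$values[-1]]
      )
    }
  }
  dwells <- do.call(rbind, dwell_rows)
  tdp <- if (length(tdp_rows)) do.call(rbind, tdp_rows) else
    data.frame(trace = integer(0), e_before = numeric(0),
               e_after = numeric(0))
  states <- sort(unique(dwells$state))
  lifetimes <- do.call(rbind, lapply(states, function(s) {
    dur <- dwells$duration[dwells$state == s & !dwells$censored]
    n <- length(dur)
    if (n == 0L) {
      return(data.frame(state = s, n_dwells = 0L, mean = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    }
    m <- mean(dur)  # exponential MLE
    half <- 1.96 * m / sqrt(n)
    data.frame(state = s, n_dwells = n, mean = m,
               ci_low = m - half, ci_high = m + half)
  }))
  structure(list(dwells = dwells, lifetimes = lifetimes, tdp = tdp),
            class = "dwell_stats")
}

#' @export
print.dwell_stats <- function(x, ...) {
  cat(sprintf("dwell statistics: %d dwell(s), %d transition(s)\n",
              nrow(x$dwells), nrow(x$tdp)))
  print(x$lifetimes, row.names = FALSE)
  invisible(x)
}

#' Merge degenerate HMM states
#'
#' Post-hoc merge of fitted states whose means lie closer than `threshold`
#' (in FRET units) with overlapping emission uncertainty; the merged state
#' takes the occupancy-weighted mean. Useful when BIC slightly overfits
#' well-separated data.
#'
#' @param fit A `fret_hmm` object.
#' @param threshold Mean-separation threshold below which states merge.
#' @return A `fret_hmm` with possibly fewer states (path relabelled,
#'   means/vars recomputed; transition matrix re-estimated from the path).
#' @export
merge_degenerate_states <- function(fit, threshold = 0.05) {
  stopifnot(inherits(fit, "fret_hmm"))
  K <- fit$n_states
  if (K == 1L) return(fit)
  group <- seq_len(K)
  mu <- fit$means[, 1]
  sdv <- sqrt(fit$vars[, 1])
  occ <- tabulate(fit$path, K)
  se <- sdv / sqrt(pmax(occ, 1))
  for (k in 2:K) {
    close <- abs(mu[k] - mu[k - 1]) < threshold
    overlap <- abs(mu[k] - mu[k - 1]) < 1.96 * (se[k] + se[k - 1])
    if (close && overlap) group[k] <- group[k - 1]
  }
  group <- match(group, unique(group))
  K2 <- max(group)
  if (K2 == K) return(fit)
  path2 <- group[fit$path]
  mu2 <- vapply(seq_len(K2), function(g) {
    w <- occ[group == g]
    sum(w * mu[group == g]) / sum(w)
  }, numeric(1))
  var2 <- vapply(seq_len(K2), function(g) mean(fit$vars[group == g, 1]),
                 numeric(1))
  # re-estimate transitions from the merged path
  A2 <- matrix(1e-12, K2, K2)
  if (length(path2) > 1) {
    for (t in seq_len(length(path2) - 1)) {
      A2[path2[t], path2[t + 1]] <- A2[path2[t], path2[t + 1]] + 1
    }
  }
  A2 <- A2 / rowSums(A2)
  fit$means <- matrix(mu2, ncol = 1)
  fit$vars <- matrix(var2, ncol = 1)
  fit$transition <- A2
  fit$path <- path2
  fit$n_states <- K2
  fit
}
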
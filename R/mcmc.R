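# MCMC engine for the hierarchical log-Poisson (piecewise-exponential) model.
#
# Sampler: Metropolis-within-Gibbs.
#   * beta block      — Gamerman-style MH: the proposal is the Gaussian given
#                       by one iteratively-reweighted-least-squares step of
#                       the Poisson GLM at the current (and, for the reverse
#                       density, proposed) point. Near-Gibbs acceptance.
#   * log lambda_k,   — 1-d strictly concave conditionals of the form
#     u_h               d*x - A*exp(x) - (x-m0)^2/(2 v0); independence MH
#                       from a Gaussian at the conditional mode (Newton),
#                       which does not depend on the current state, so a
#                       single mode computation serves both densities.
#   * log sigma_u     — slice sampler (stepping out + shrinkage).
#
# All conditionals use grouped sufficient statistics (rowsum over interval /
# hospital indices), so an iteration costs a handful of O(n) passes.

# log target of the 1-d Poisson-gamma-type conditional
.cond_lp <- function(x, d, A, m0, v0) d * x - A * exp(x) - (x - m0)^2 / (2 * v0)

# Newton mode of the strictly concave 1-d conditional (damped steps and a
# bounded domain keep the iteration finite even for 0-event groups under a
# nearly flat prior)
.cond_mode <- function(x0, d, A, m0, v0) {
  x <- min(max(x0, -40), 40)
  for (i in 1:50) {
    g <- d - A * exp(x) - (x - m0) / v0
    h <- -A * exp(x) - 1 / v0
    step <- g / h
    if (!is.finite(step)) break
    step <- sign(step) * min(abs(step), 10)
    x <- min(max(x - step, -40), 40)
    if (abs(step) < 1e-9) break
  }
  x
}

# one independence-MH update of the 1-d conditional; returns new value
.mh_cond <- function(cur, d, A, m0 = 0, v0 = 100) {
  m <- .cond_mode(cur, d, A, m0, v0)
  s <- sqrt(1.44 / (A * exp(m) + 1 / v0))  # 1.2x sd inflation for tail safety
  prop <- rnorm(1, m, s)
  la <- .cond_lp(prop, d, A, m0, v0) - .cond_lp(cur, d, A, m0, v0) +
    dnorm(cur, m, s, log = TRUE) - dnorm(prop, m, s, log = TRUE)
  if (is.finite(la) && log(runif(1)) < la) prop else cur
}

# slice sampler for a 1-d log density (Neal 2003, stepping out + shrinkage)
.slice1 <- function(x0, logf, w = 1, m = 50) {
  f0 <- logf(x0)
  z <- f0 - rexp(1)
  L <- x0 - w * runif(1)
  R <- L + w
  j <- floor(m * runif(1)); k <- m - 1 - j
  while (j > 0 && logf(L) > z) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- L + runif(1) * (R - L)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Converged-IWLS Gaussian approximation at the conditional mode of beta:
# list(mean = mode, chol_prec). The mode does not depend on the starting
# point (concave likelihood), so the resulting Gaussian is a valid
# independence proposal.
.iwls_gauss <- function(beta, X, y, off, prior_prec, tol = 1e-8, maxit = 30) {
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(off + eta)
    Q <- crossprod(X * mu, X) + prior_prec
    b <- drop(crossprod(X, mu * eta + (y - mu)))
    R <- chol(Q)
    m <- backsolve(R, backsolve(R, b, transpose = TRUE))
    delta <- max(abs(m - beta))
    beta <- m
    if (delta < tol) break
  }
  list(m = m, R = R)
}

.lmvn <- function(x, g) {
  r <- drop(g$R %*% (x - g$m))
  sum(log(diag(g$R))) - 0.5 * sum(r * r)
}

.beta_loglik <- function(beta, X, y, off, prior_prec) {
  eta <- drop(X %*% beta)
  sum(y * eta) - sum(exp(off + eta)) - 0.5 * sum(beta^2 * diag(prior_prec))
}

# one independence-MH update of the beta block from the mode Gaussian
.mh_beta <- function(beta, X, y, off, prior_prec) {
  g <- .iwls_gauss(beta, X, y, off, prior_prec)
  prop <- g$m + backsolve(g$R, rnorm(length(beta)))
  la <- .beta_loglik(prop, X, y, off, prior_prec) -
    .beta_loglik(beta, X, y, off, prior_prec) +
    .lmvn(beta, g) - .lmvn(prop, g)
  if (is.finite(la) && log(runif(1)) < la) list(beta = prop, acc = TRUE)
  else list(beta = beta, acc = FALSE)
}

# group sum returning a full-length vector (absent groups contribute 0)
.gsum <- function(x, g, n) {
  t <- rowsum(x, g)
  out <- numeric(n)
  out[as.integer(rownames(t))] <- t
  out
}

# Run one chain; returns (warmup+iter) x npar matrix (warmup rows dropped).
.run_chain <- function(y, e, X, ki, hi, K, H, priors, warmup, iter) {
  p <- ncol(X)
  le <- log(e)
  dk <- .gsum(y, ki, K)                # events per interval
  dh <- .gsum(y, hi, H)                # events per hospital
  prior_prec <- diag(1 / priors$beta_sd^2, p)
  v_lam <- priors$loglam_sd^2

  A0 <- .gsum(e, ki, K)
  # intervals with no person-time carry no information; their hazard is
  # pinned at exp(-30) ~ 0 (nothing else conditions on them)
  live_k <- which(A0 > 0)
  loglam <- rep(-30, K)
  loglam[live_k] <- log((dk[live_k] + 0.5) / A0[live_k])
  u <- numeric(H)
  ls <- log(0.2)                       # log sigma_u
  # start beta at its conditional mode so the independence proposals mix
  # from the first iteration
  beta <- .iwls_gauss(numeric(p), X, y, le + loglam[ki], prior_prec)$m

  npar <- p + K + H + 1
  out <- matrix(NA_real_, iter, npar)
  for (it in seq_len(warmup + iter)) {
    eta_x <- drop(X %*% beta)
    # interval hazards
    A_k <- .gsum(e * exp(eta_x + u[hi]), ki, K)
    for (k in live_k) {
      loglam[k] <- .mh_cond(loglam[k], dk[k], A_k[k], 0, v_lam)
    }
    # hospital frailties
    E_h <- .gsum(e * exp(loglam[ki] + eta_x), hi, H)
    s2 <- exp(2 * ls)
    for (h in seq_len(H)) {
      u[h] <- .mh_cond(u[h], dh[h], E_h[h], 0, s2)
    }
    # location sweep along the likelihood-invariant ridge u -> u - c,
    # loglam -> loglam + c: exact Gibbs draw of c from its Gaussian
    # conditional under the priors (kills the frailty-mean / hazard-level
    # coupling that otherwise mixes slowly)
    s2 <- exp(2 * ls)
    prec_c <- H / s2 + length(live_k) / v_lam
    c0 <- rnorm(1, (sum(u) / s2 - sum(loglam[live_k]) / v_lam) / prec_c,
                1 / sqrt(prec_c))
    u <- u - c0
    loglam[live_k] <- loglam[live_k] + c0
    # frailty scale (sigma_u floored at 1e-4: below that the model is
    # numerically indistinguishable from sigma_u = 0 and conditionals for
    # zero-event hospitals degenerate)
    S2 <- sum(u * u)
    ls <- .slice1(ls, function(l) {
      -H * l - S2 / (2 * exp(2 * l)) + l - log1p((exp(l) / priors$sigma_scale)^2)
    })
    ls <- max(ls, log(1e-4))
    # regression block
    off <- le + loglam[ki] + u[hi]
    beta <- .mh_beta(beta, X, y, off, prior_prec)$beta
    if (it > warmup) out[it - warmup, ] <- c(beta, loglam, u, exp(ls))
  }
  out
}

#' Potential scale reduction factor
#'
#' Between/within variance ratio across chains; with `split = TRUE`
#' (the default used for fit summaries) each chain is first halved so
#' within-chain trends are also detected. Values below 1 (estimator noise)
#' are clipped to 1, so identical chains give exactly 1 without splitting.
#'
#' @param draws iterations x chains matrix for one parameter.
#' @param split Halve each chain before comparing (default TRUE).
#' @return R-hat (> 1.1 signals non-convergence; fits require < 1.01).
#' @export
rhat <- function(draws, split = TRUE) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (split) {
    half <- floor(n / 2)
    draws <- cbind(draws[seq_len(half), , drop = FALSE],
                   draws[(n - half + 1):n, , drop = FALSE])
    n <- half
  }
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  if (W == 0) return(1)
  max(1, sqrt(((n - 1) / n * W + B / n) / W))
}

#' Effective sample size across chains
#'
#' Autocorrelation-based ESS with Geyer's initial-positive-sequence
#' truncation, chain-averaged correlations and the multi-chain variance
#' correction.
#'
#' @param draws iterations x chains matrix for one parameter.
#' @return Estimated effective number of draws.
#' @export
ess <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  W <- mean(apply(draws, 2, var))
  if (W == 0) return(m * n)
  varplus <- W * (n - 1) / n + if (m > 1) var(colMeans(draws)) else 0
  maxlag <- min(n - 1, 500)
  rho_ch <- sapply(seq_len(m), function(j) {
    a <- acf(draws[, j], lag.max = maxlag, plot = FALSE, demean = TRUE)$acf[-1]
    a * var(draws[, j]) * (n - 1) / n
  })
  rho <- 1 - (W - rowMeans(as.matrix(rho_ch))) / varplus
  # Geyer: truncate at first negative sum of adjacent pairs
  s <- 0
  t <- 0
  while (t + 2 <= length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  max(1, m * n / (1 + 2 * s))
}
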
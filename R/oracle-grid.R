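# Brute-force validation of the Gibbs sampler on the intercept-only model.
# With subject slopes fixed at zero, the random intercepts a_i and the
# population mean alpha0 are jointly Gaussian and can be integrated out in
# closed form, leaving a 2-D posterior over (tau, sigma):
#
#   y | tau, sigma ~ N(0, sigma^2 I + tau^2 B + s0^2 J)
#
# where B is the block-diagonal ones matrix over subjects and J the all-ones
# matrix (from the N(0, s0^2) prior on alpha0). Numerical integration of
# this density times the two half-Cauchy priors over a grid gives marginal
# posteriors of tau and sigma against which the MCMC must be checked. This
# is deliberately a completely different computational route from the
# sampler and is only practical for toy instances (a handful of subjects).

#' Grid-integrated marginal posterior of (tau, sigma), intercept-only model
#'
#' @param visits data.frame with columns `subject_id`, `y` (slopes are
#'   treated as exactly zero, so `t` is ignored).
#' @param priors A [prior_config()].
#' @param tau_grid,sigma_grid Grid points (strictly positive).
#' @return List with `tau_median`, `sigma_median`, marginal weight vectors
#'   `tau_marginal`, `sigma_marginal`, and the grids.
#' @export
grid_posterior_tau_sigma <- function(visits, priors = prior_config(),
                                     tau_grid = seq(0.005, 2, length.out = 160),
                                     sigma_grid = seq(0.005, 2,
                                                      length.out = 160)) {
  sub <- factor(visits$subject_id)
  y <- visits$y
  n <- length(y)
  B <- outer(as.integer(sub), as.integer(sub), "==") * 1
  J <- matrix(1, n, n)
  s0sq <- priors$mean_prior_sd^2
  A <- priors$cauchy_scale
  log_hc <- function(s) -log1p((s / A)^2)  # half-Cauchy kernel
  lp <- matrix(NA_real_, length(tau_grid), length(sigma_grid))
  for (i in seq_along(tau_grid)) {
    for (j in seq_along(sigma_grid)) {
      V <- sigma_grid[j]^2 * diag(n) + tau_grid[i]^2 * B + s0sq * J
      ch <- chol(V)
      z <- backsolve(ch, y, transpose = TRUE)
      lp[i, j] <- -sum(log(diag(ch))) - 0.5 * sum(z^2) +
        log_hc(tau_grid[i]) + log_hc(sigma_grid[j])
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  marg_median <- function(grid, weights) {
    cw <- cumsum(weights)
    grid[which(cw >= 0.5)[1]]
  }
  tau_m <- rowSums(w)
  sigma_m <- colSums(w)
  list(tau_median = marg_median(tau_grid, tau_m),
       sigma_median = marg_median(sigma_grid, sigma_m),
       tau_marginal = tau_m, sigma_marginal = sigma_m,
       tau_grid = tau_grid, sigma_grid = sigma_grid)
}
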
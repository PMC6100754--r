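#' Bayesian random-effects pooling of study estimates
#'
#' Normal-normal random-effects model for several estimates of one quantity:
#' study k reports `y_k` with known standard deviation `sd_k`, and
#' y_k ~ N(mu, sd_k^2 + tau^2) given the overall effect mu and between-study
#' standard deviation tau. The prior on mu is flat; the prior on tau is one
#' of
#' \itemize{
#'   \item `uniform`: tau ~ U(0, 5 * max(sd_k)) (scale overridable),
#'   \item `half_normal`: tau ~ HN(scale = max(sd_k)),
#'   \item `dumouchel`: p(tau) = s0 / (s0 + tau)^2 with
#'     s0 = sqrt(harmonic mean of sd_k^2).
#' }
#' The posterior is computed by deterministic two-dimensional trapezoid
#' quadrature over (mu, tau) — reproducible, with no Monte Carlo noise — and
#' the returned cell estimate is the posterior mean and SD of mu. A single
#' input estimate is returned unchanged.
#'
#' @param estimates data.frame with columns `ln_mr` and `sd` (one row per
#'   study), or a numeric matrix/2-column structure coercible to it.
#' @param tau_prior prior family for tau.
#' @param prior_scale overrides the default scale of the tau prior
#'   (the uniform upper bound, the half-normal scale, or DuMouchel's s0).
#' @param grid number of quadrature nodes per dimension.
#' @return A list with `ln_mr` (posterior mean) and `sd` (posterior SD).
#' @examples
#' pool_random_effects(data.frame(ln_mr = c(0.2, 0.6), sd = c(0.1, 0.1)))
#' @export
pool_random_effects <- function(estimates,
                                tau_prior = c("dumouchel", "uniform", "half_normal"),
                                prior_scale = NULL, grid = 400L) {
  tau_prior <- match.arg(tau_prior)
  estimates <- as.data.frame(estimates)
  if (nrow(estimates) == 0L) stop("no estimates to pool")
  y <- as.numeric(estimates$ln_mr)
  sd <- as.numeric(estimates$sd)
  if (any(!is.finite(y)) || any(!is.finite(sd)) || any(sd <= 0))
    stop("estimates need finite ln_mr and positive sd")
  if (length(y) == 1L) return(list(ln_mr = y, sd = sd))

  s0 <- sqrt(length(sd) / sum(1 / sd^2))  # sqrt of harmonic mean variance
  tau_max <- switch(tau_prior,
                    uniform = if (is.null(prior_scale)) 5 * max(sd) else prior_scale,
                    half_normal = 6 * (if (is.null(prior_scale)) max(sd) else prior_scale),
                    dumouchel = 6 * (if (is.null(prior_scale)) s0 else prior_scale))
  log_prior <- switch(tau_prior,
    uniform = {
      ub <- if (is.null(prior_scale)) 5 * max(sd) else prior_scale
      function(tau) ifelse(tau <= ub, 0, -Inf)
    },
    half_normal = {
      sc <- if (is.null(prior_scale)) max(sd) else prior_scale
      function(tau) -tau^2 / (2 * sc^2)
    },
    dumouchel = {
      sc <- if (is.null(prior_scale)) s0 else prior_scale
      function(tau) log(sc) - 2 * log(sc + tau)
    })

  # generous mu range: cover every study mean out to 6 total-sd
  half <- 6 * sqrt(max(sd)^2 + tau_max^2)
  mu_grid <- seq(min(y) - half, max(y) + half, length.out = grid)
  tau_grid <- seq(0, tau_max, length.out = grid)

  # log joint on the grid (mu in rows)
  lj <- matrix(0, grid, grid)
  for (k in seq_along(y)) {
    v <- outer(rep(1, grid), sd[k]^2 + tau_grid^2)
    lj <- lj - 0.5 * log(2 * pi * v) - outer((y[k] - mu_grid)^2, 1 / (2 * (sd[k]^2 + tau_grid^2)))
  }
  lj <- lj + matrix(log_prior(tau_grid), grid, grid, byrow = TRUE)
  w <- exp(lj - max(lj[is.finite(lj)]))
  w[!is.finite(w)] <- 0
  trap <- function(n) { v <- rep(1, n); v[c(1, n)] <- 0.5; v }
  W <- outer(trap(grid), trap(grid))  # trapezoid weights
  w <- w * W
  z <- sum(w)
  mu_mean <- sum(w * mu_grid) / z
  mu_var <- sum(w * (mu_grid - mu_mean)^2) / z
  list(ln_mr = mu_mean, sd = sqrt(mu_var))
}
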
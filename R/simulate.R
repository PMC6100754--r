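#' Simulate a survival arm
#'
#' Draws iid event times from an exponential or Weibull distribution with
#' independent exponential right-censoring, emulating the per-arm structure
#' of the study data. The exponential default has a closed-form RMST,
#' scale * (1 - exp(-horizon/scale)), used by the validation tests; the
#' Weibull stresses non-proportional hazards.
#'
#' @param n arm size.
#' @param dist `"exponential"` or `"weibull"`.
#' @param scale distribution scale (mean for the exponential).
#' @param shape Weibull shape (ignored for exponential).
#' @param censor_rate rate of the independent exponential censoring time;
#'   0 disables censoring.
#' @param seed optional seed.
#' @param label arm label.
#' @return A [surv_arm()].
#' @export
simulate_arm <- function(n, dist = c("exponential", "weibull"), scale = 10,
                         shape = 1.5, censor_rate = 0, seed = NULL,
                         label = "simulated") {
  dist <- match.arg(dist)
  stopifnot(n >= 1, scale > 0, shape > 0, censor_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  tev <- switch(dist,
                exponential = stats::rexp(n, rate = 1 / scale),
                weibull = stats::rweibull(n, shape = shape, scale = scale))
  if (censor_rate > 0) {
    tcn <- stats::rexp(n, rate = censor_rate)
    surv_arm(pmin(tev, tcn), as.integer(tev <= tcn), label = label)
  } else {
    surv_arm(tev, rep(1L, n), label = label)
  }
}

#' Simulate an evidence grid from known ground truth
#'
#' Generative mirror of the hierarchical model: theta_ij = alpha_i +
#' gamma_j + N(0, sigma^2), and on observed cells y_ij = theta_ij +
#' N(0, c_ij^2). Returns both the data and the truth so fits can be scored.
#'
#' @param alpha_true,gamma_true species and intervention effects.
#' @param sigma_true potency-deviation scale (>= 0).
#' @param c matrix of cell standard deviations (scalar recycled).
#' @param mask logical matrix of observed cells; default all observed. Use
#'   `paper_mask()` for the shipped study pattern.
#' @param seed optional seed.
#' @param species,interventions labels.
#' @return list with `data` (an [evidence_matrix()]) and `truth`
#'   (list `theta`, `alpha`, `gamma`, `sigma`).
#' @export
simulate_table <- function(alpha_true, gamma_true, sigma_true = 0.3,
                           c = 0.15, mask = NULL, seed = NULL,
                           species = NULL, interventions = NULL) {
  stopifnot(sigma_true >= 0)
  if (!is.null(seed)) set.seed(seed)
  I <- length(alpha_true); J <- length(gamma_true)
  cmat <- matrix(c, I, J)
  if (any(cmat <= 0)) stop("cell standard deviations must be positive")
  if (is.null(mask)) mask <- matrix(TRUE, I, J)
  theta <- outer(alpha_true, gamma_true, "+") +
    matrix(stats::rnorm(I * J, 0, sigma_true), I, J)
  y <- theta + matrix(stats::rnorm(I * J), I, J) * cmat
  y[!mask] <- NA_real_
  if (is.null(species) && I == 5L) species <- SPECIES
  if (is.null(interventions) && J == 4L) interventions <- INTERVENTIONS
  list(data = evidence_matrix(y, cmat, species, interventions),
       truth = list(theta = theta, alpha = alpha_true, gamma = gamma_true,
                    sigma = sigma_true))
}

#' Missingness mask of the shipped study grid
#'
#' @return 5x4 logical matrix with the 12 observed cells of the packaged
#'   evidence matrix.
#' @export
paper_mask <- function() load_table2()$obs

#' Credible-interval coverage and bias of the fitter
#'
#' Repeatedly simulates evidence grids from known truth
#' ([simulate_table()]), fits each with the given prior, and scores per-cell
#' coverage of the 95% credible intervals for theta and the bias of the
#' posterior median. Nominal coverage near 95% on a well-specified prior is
#' the acceptance surface for the sampler.
#'
#' @param alpha_true,gamma_true,sigma_true,c,mask passed to
#'   [simulate_table()].
#' @param prior a [prior_spec()] or catalogue name.
#' @param replicates number of simulated tables (>= 50 recommended).
#' @param seed seed governing the whole experiment.
#' @param ... passed to [mrsynth()] (schedule arguments).
#' @return list with `coverage` (overall proportion of cells whose true
#'   theta fell in its 95% CrI), `bias` (median over cells of posterior
#'   median minus truth), and the per-replicate cell results.
#' @export
recovery_experiment <- function(alpha_true, gamma_true, sigma_true, prior,
                                replicates = 200, c = 0.15, mask = NULL,
                                seed = 1, ...) {
  if (is.character(prior)) prior <- make_prior(prior)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, replicates)
  cover <- numeric(0); bias <- numeric(0)
  for (r in seq_len(replicates)) {
    sim <- simulate_table(alpha_true, gamma_true, sigma_true, c = c,
                          mask = mask, seed = seeds[r])
    fit <- mrsynth(sim$data, prior, ...)
    lo <- apply(fit$draws$theta, 2, stats::quantile, 0.025)
    hi <- apply(fit$draws$theta, 2, stats::quantile, 0.975)
    md <- apply(fit$draws$theta, 2, stats::median)
    tv <- as.vector(sim$truth$theta)
    cover <- base::c(cover, tv >= lo & tv <= hi)
    bias <- base::c(bias, md - tv)
  }
  list(coverage = mean(cover), bias = stats::median(bias),
       n_cells = length(cover))
}
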
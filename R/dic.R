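#' Data-node deviance of a theta configuration
#'
#' Minus twice the log likelihood of the observed cells:
#' -2 sum over observed (i,j) of ln N(y_ij | theta_ij, c_ij^2). Missing
#' cells contribute nothing.
#'
#' @param theta matrix of true-effect values shaped like the data grid.
#' @param data an [evidence_matrix()].
#' @return The deviance (a scalar).
#' @export
deviance_obs <- function(theta, data) {
  stopifnot(inherits(data, "evidence_matrix"))
  theta <- matrix(as.numeric(theta), nrow(data$y), ncol(data$y))
  if (any(!is.finite(theta))) stop("theta must be finite")
  o <- data$obs
  sum(log(2 * pi * data$sd[o]^2) + (data$y[o] - theta[o])^2 / data$sd[o]^2)
}

#' Deviance information criterion of a fit
#'
#' DIC = Dbar + pD, where Dbar is the posterior mean of the data-node
#' deviance and the effective number of parameters is
#' pD = Dbar - D(posterior mean of theta) (plug-in at the posterior mean,
#' the BUGS convention).
#'
#' @param fit a fitted [mrsynth()] model.
#' @return An object of class `"mr_dic"`: `dbar`, `p_d`, `dic`, and
#'   `negative_p_d` flag (pD below zero indicates posterior-prior conflict).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "mrsynth"))
  if (length(fit$draws$deviance) < 100L)
    warning("fewer than 100 deviance draws; DIC will be noisy")
  dbar <- mean(fit$draws$deviance)
  dhat <- deviance_obs(colMeans(fit$draws$theta), fit$data)
  p_d <- dbar - dhat
  if (p_d < 0) warning("negative effective number of parameters")
  structure(list(dbar = dbar, p_d = p_d, dic = dbar + p_d,
                 negative_p_d = p_d < 0),
            class = "mr_dic")
}

#' @export
print.mr_dic <- function(x, ...) {
  cat(sprintf("DIC %.3f = Dbar %.3f + pD %.3f\n", x$dic, x$dbar, x$p_d))
  invisible(x)
}

#' Quasi-evidence threshold from effective parameter counts
#'
#' Under the DIC view of model comparison, model 1 is preferred over model 2
#' exactly when the likelihood ratio at the posterior-mean parameters
#' exceeds exp(pD1 - pD2); this function returns that threshold.
#'
#' @param p_d_1,p_d_2 effective numbers of parameters of the two models.
#' @return exp(p_d_1 - p_d_2).
#' @export
quasi_evidence_threshold <- function(p_d_1, p_d_2) exp(p_d_1 - p_d_2)

#' Differential entropy of the true-effect distribution
#'
#' Plug-in estimate 0.5 * ln(2 * pi * e * sigma2) of the differential
#' entropy of theta_ij given the potency-deviation variance, evaluated at a
#' posterior point estimate of the variance.
#'
#' @param sigma2 positive variance estimate (by convention the posterior
#'   median of the sigma^2 draws; `median(fit$draws$sigma^2)` or, as an
#'   alternative convention, `median(fit$draws$sigma)^2`).
#' @return The entropy in nats.
#' @export
entropy_sigma2 <- function(sigma2) {
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  0.5 * log(2 * pi * exp(1) * sigma2)
}

#' Compare the shipped prior catalogue by DIC and entropy
#'
#' Fits each requested prior to the data and tabulates Dbar, pD, DIC,
#' the plug-in entropy (posterior median of sigma^2) and the DIC difference
#' to the best model.
#'
#' @param data an [evidence_matrix()].
#' @param priors catalogue names; default all eleven.
#' @param ... passed to [mrsynth()] (e.g. `profile = "fast"`, `seed`).
#' @return A data.frame with one row per prior, ordered as given.
#' @export
compare_priors <- function(data = load_table2(), priors = prior_names(), ...) {
  rows <- lapply(priors, function(p) {
    fit <- mrsynth(data, p, ...)
    d <- dic(fit)
    data.frame(prior = p, dbar = d$dbar, p_d = d$p_d, dic = d$dic,
               sigma_median = stats::median(fit$draws$sigma),
               entropy = entropy_sigma2(stats::median(fit$draws$sigma^2)))
  })
  out <- do.call(rbind, rows)
  out$delta_dic <- out$dic - min(out$dic)
  out
}
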
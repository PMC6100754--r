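#' Prior specification for the hierarchical synthesis model
#'
#' Means and covariance matrices for the species effects alpha and
#' intervention effects gamma, plus the normal prior (mean, variance) on the
#' potency-deviation scale sigma (truncated at zero when sampled; sigma
#' enters the model only through sigma^2).
#'
#' @param name label.
#' @param mu_alpha,mu_gamma prior mean vectors.
#' @param Ralpha,Rgamma symmetric positive-semidefinite covariance matrices
#'   (entries are variances/covariances).
#' @param sigma_mean,sigma_var mean and variance of the sigma prior.
#' @return An object of class `"prior_spec"`.
#' @seealso [make_prior()] for the named catalogue.
#' @export
prior_spec <- function(name, mu_alpha, Ralpha, mu_gamma, Rgamma,
                       sigma_mean = 0.5, sigma_var = 0.01) {
  Ralpha <- as.matrix(Ralpha); Rgamma <- as.matrix(Rgamma)
  if (length(mu_alpha) != nrow(Ralpha) || length(mu_gamma) != nrow(Rgamma))
    stop("mean vector and covariance dimensions differ")
  for (m in list(Ralpha, Rgamma)) {
    chk <- validate_psd(m)
    if (!chk$psd)
      stop("covariance matrix not positive semidefinite (min eigenvalue ",
           signif(chk$min_eigenvalue, 3), ")")
    if (any(diag(m) <= 0)) stop("covariance diagonal must be positive")
  }
  if (sigma_var <= 0) stop("sigma_var must be positive")
  structure(list(name = name,
                 mu_alpha = as.numeric(mu_alpha), Ralpha = Ralpha,
                 mu_gamma = as.numeric(mu_gamma), Rgamma = Rgamma,
                 sigma_mean = sigma_mean, sigma_var = sigma_var),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Prior '%s'\n", x$name))
  cat("  mu_alpha:", paste(signif(x$mu_alpha, 4), collapse = ", "), "\n")
  cat("  mu_gamma:", paste(signif(x$mu_gamma, 4), collapse = ", "), "\n")
  cat(sprintf("  sigma ~ N(%g, %g), truncated at 0\n", x$sigma_mean, x$sigma_var))
  cat("  Ralpha:\n"); print(signif(x$Ralpha, 4))
  cat("  Rgamma:\n"); print(signif(x$Rgamma, 4))
  invisible(x)
}

#' Check positive semidefiniteness
#'
#' @param m square symmetric matrix.
#' @param tol eigenvalues above `-tol` count as nonnegative.
#' @return list with `psd` (logical) and `min_eigenvalue`.
#' @export
validate_psd <- function(m, tol = 1e-10) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  list(psd = min(ev) >= -tol, min_eigenvalue = min(ev))
}

#' Constants of the enthusiastic species prior
#'
#' The human-effect prior is centred on a 40% survival prolongation
#' (mean ln(1.4) = 0.336) with standard deviation
#' (ln 2 - ln 1.1)/(2 * 0.79) = 0.378, chosen so that roughly 43% of the
#' prior mass for the MR lies between 1.1 and 2. The mouse-effect prior is
#' centred on ln(1.124) = 0.117 with standard deviation 0.080, translated
#' from a meta-analysis of ketogenic-diet monotherapy in brain-tumor-bearing
#' mice.
#'
#' @return Named numeric vector `human_mean`, `human_sd`, `mouse_mean`,
#'   `mouse_sd`.
#' @export
ep_constants <- function() {
  c(human_mean = log(1.4),
    human_sd = (log(2) - log(1.1)) / (2 * 0.79),
    mouse_mean = log(1.124),
    mouse_sd = 0.080)
}

#' Names of the shipped prior catalogue
#' @return Character vector of the eleven catalogue names.
#' @export
prior_names <- function() {
  c("SP1", "SP2", "FSP", "RP1", "RP2", "RP3", "MP1", "MP2",
    "EP", "EP_MP1", "EP_MP2")
}

# gamma covariance of the relational priors: corr 0.9 between KD-CR and
# KD+-CR+ on variance 10
.rgamma_relational <- function() {
  m <- diag(10, 4)
  m[1, 3] <- m[3, 1] <- 9
  m[2, 4] <- m[4, 2] <- 9
  m
}

# mechanistic gamma covariances: gamma2 = gamma1 + eta, gamma4 = gamma3 + eta
# with eta ~ N(0.3, 0.3) on top of gamma_j ~ N(0, 1)
.rgamma_mp <- function(relational = FALSE) {
  if (!relational) return(diag(c(1, 1.3, 1, 1.3)))
  m <- diag(c(1, 1.3, 1, 1.3))
  m[1, 3] <- m[3, 1] <- 0.99
  m[2, 4] <- m[4, 2] <- 1.287
  m
}

# enthusiastic species covariance: informative human and mouse diagonals,
# near-unit correlation (covariance 0.0063) between mouse strains, weakly
# informative rats. The catalogue carries the rounded elicited constants
# (0.378^2, 0.08^2) exactly as specified; ep_constants() gives the defining
# expressions they come from.
.ralpha_ep <- function() {
  m <- diag(c(0.378^2, rep(0.08^2, 3), 1))
  blk <- matrix(0.0063, 3, 3)
  diag(blk) <- 0.08^2
  m[2:4, 2:4] <- blk
  m
}

#' Construct a named prior from the catalogue
#'
#' Eleven specifications spanning skeptical through enthusiastic beliefs
#' about ketogenic therapy, all sharing the sigma ~ N(0.5, 0.01) potency
#' prior:
#' \describe{
#'   \item{SP1, SP2}{skeptical, diagonal: alpha_i, gamma_j ~ N(0, 10)
#'     (SP1, vague) or N(0, 1) (SP2, weakly informative).}
#'   \item{FSP}{fundamentalist skeptical: alpha_i, gamma_j ~ N(-0.35, 1),
#'     expecting survival shortened by a factor of about 2.}
#'   \item{RP1}{relational: correlation 0.9 between KD and CR and between
#'     KD+ and CR+; correlation 0.9995 among the three mouse strains.}
#'   \item{RP2}{RP1 plus mouse-rat correlation 0.9.}
#'   \item{RP3}{RP2 plus a weak human-animal correlation 0.3
#'     (covariance 3).}
#'   \item{MP1}{mechanistic synergy: gamma means (0, 0.3, 0, 0.3), gamma
#'     variances (1, 1.3, 1, 1.3); unit-variance zero-mean species side.}
#'   \item{MP2}{MP1 with the relational gamma covariances (0.99, 1.287).}
#'   \item{EP}{enthusiastic species side (see [ep_constants()]); unit
#'     zero-mean intervention side.}
#'   \item{EP_MP1, EP_MP2}{EP's species side with MP1's/MP2's intervention
#'     side.}
#' }
#' The species order is Humans, Athymic mice, C57BL mice, SCID mice, Fisher
#' rats; the intervention order KD, KD+, CR, CR+.
#'
#' @param name one of [prior_names()].
#' @return A [prior_spec()].
#' @examples
#' make_prior("EP_MP2")
#' @export
make_prior <- function(name) {
  if (!name %in% prior_names()) stop("unknown prior name: ", name)
  z5 <- rep(0, 5); z4 <- rep(0, 4)
  mp_mu <- c(0, 0.3, 0, 0.3)
  ep_mu <- c(0.336, rep(0.117, 3), 0)  # rounded elicited means, cf. ep_constants()
  spec <- switch(name,
    SP1 = list(z5, diag(10, 5), z4, diag(10, 4)),
    SP2 = list(z5, diag(1, 5), z4, diag(1, 4)),
    FSP = list(rep(-0.35, 5), diag(1, 5), rep(-0.35, 4), diag(1, 4)),
    RP1 = {
      a <- diag(10, 5)
      a[2:4, 2:4] <- 9.995; diag(a) <- 10
      list(z5, a, z4, .rgamma_relational())
    },
    RP2 = {
      a <- diag(10, 5)
      a[2:4, 2:4] <- 9.995
      a[2:4, 5] <- a[5, 2:4] <- 9
      diag(a) <- 10
      list(z5, a, z4, .rgamma_relational())
    },
    RP3 = {
      a <- diag(10, 5)
      a[2:4, 2:4] <- 9.995
      a[2:4, 5] <- a[5, 2:4] <- 9
      a[1, 2:5] <- a[2:5, 1] <- 3
      diag(a) <- 10
      list(z5, a, z4, .rgamma_relational())
    },
    MP1 = list(z5, diag(1, 5), mp_mu, .rgamma_mp(FALSE)),
    MP2 = list(z5, diag(1, 5), mp_mu, .rgamma_mp(TRUE)),
    EP = list(ep_mu, .ralpha_ep(), z4, diag(1, 4)),
    EP_MP1 = list(ep_mu, .ralpha_ep(), mp_mu, .rgamma_mp(FALSE)),
    EP_MP2 = list(ep_mu, .ralpha_ep(), mp_mu, .rgamma_mp(TRUE)))
  dimnames(spec[[2]]) <- list(SPECIES, SPECIES)
  dimnames(spec[[4]]) <- list(INTERVENTIONS, INTERVENTIONS)
  prior_spec(name, spec[[1]], spec[[2]], spec[[3]], spec[[4]])
}
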
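#' Fixed vocabularies of the shipped synthesis
#'
#' Species and intervention labels of the glioma ketogenic-therapy grid, in
#' canonical order. `KD`/`CR` are ketogenic diet and calorie restriction as
#' monotherapy, `KD+`/`CR+` combined with another treatment.
#' @name vocab
#' @export
SPECIES <- c("Humans", "Athymic mice", "C57BL mice", "SCID mice", "Fisher rats")

#' @rdname vocab
#' @export
INTERVENTIONS <- c("KD", "KD+", "CR", "CR+")

#' Evidence matrix of log RMST ratios
#'
#' The model input: one ln(MR) estimate y_ij with known standard deviation
#' c_ij per species i and intervention j, with missing cells allowed.
#'
#' @param ln_mr numeric matrix (species x interventions) of ln(MR); `NA`
#'   marks a missing cell.
#' @param sd matrix of the same shape with the cell standard deviations;
#'   must be positive where `ln_mr` is observed.
#' @param species,interventions row/column labels; default taken from
#'   dimnames or the shipped vocabularies when shapes match.
#' @return An object of class `"evidence_matrix"` with fields `y`, `sd`,
#'   `obs` (logical mask), `species`, `interventions`.
#' @export
evidence_matrix <- function(ln_mr, sd,
                            species = NULL, interventions = NULL) {
  ln_mr <- as.matrix(ln_mr); sd <- as.matrix(sd)
  if (!all(dim(ln_mr) == dim(sd))) stop("ln_mr and sd shapes differ")
  if (is.null(species)) {
    species <- rownames(ln_mr)
    if (is.null(species))
      species <- if (nrow(ln_mr) == 5L) SPECIES else paste0("species", seq_len(nrow(ln_mr)))
  }
  if (is.null(interventions)) {
    interventions <- colnames(ln_mr)
    if (is.null(interventions))
      interventions <- if (ncol(ln_mr) == 4L) INTERVENTIONS else paste0("intervention", seq_len(ncol(ln_mr)))
  }
  obs <- !is.na(ln_mr)
  if (any(is.na(sd[obs])) || any(sd[obs] <= 0))
    stop("sd must be positive for every observed cell")
  dimnames(ln_mr) <- dimnames(sd) <- dimnames(obs) <-
    list(species, interventions)
  structure(list(y = ln_mr, sd = sd, obs = obs,
                 species = species, interventions = interventions),
            class = "evidence_matrix")
}

#' @export
print.evidence_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Evidence matrix: %d species x %d interventions, %d observed cells\n",
              length(x$species), length(x$interventions), sum(x$obs)))
  disp <- matrix("", nrow(x$y), ncol(x$y), dimnames = dimnames(x$y))
  disp[x$obs] <- sprintf("%.*f ± %.*f", digits, x$y[x$obs], digits, x$sd[x$obs])
  disp[!x$obs] <- "--"
  print(as.data.frame(disp))
  invisible(x)
}

#' @export
as.data.frame.evidence_matrix <- function(x, ...) {
  data.frame(species = rep(x$species, times = length(x$interventions)),
             intervention = rep(x$interventions, each = length(x$species)),
             ln_mr = as.vector(x$y), sd = as.vector(x$sd),
             observed = as.vector(x$obs))
}
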
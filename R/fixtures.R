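# Packaged study data for the glioma ketogenic-therapy synthesis.
# Values are transcribed per-study RMST summaries (column schema documented
# in load_table1); the assembled 5x4 grid of ln(MR) cells ships separately
# and is the canonical model input. One control RMST (De Feyter 9L) is a
# reconciled value: the published per-arm figure is inconsistent with the
# same row's published ratio and SE, which the reconciled value reproduces.

.t1_checksum <- 42105.88
.t2_checksum <- 6.3968

#' Named study-removal sets used in sensitivity analyses
#'
#' `replicate_studies` are animal experiments that replicated another
#' experiment's tumor model; `rieger_human_study` is the human ketogenic-diet
#' monotherapy study whose control group was not a standard-diet group.
#' @name removal_sets
#' @export
replicate_studies <- c("Stafford 2010", "Lussier 2016", "Marsh 2008")

#' @rdname removal_sets
#' @export
rieger_human_study <- "Rieger 2015"

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mrsynth")
  if (p == "") stop("fixture not found: ", file)
  p
}

#' Load the per-study survival summary table
#'
#' Twenty study arms-pairs (3 human, 17 animal): per study the treatment and
#' control RMST with standard errors, group sizes, species (merged to the
#' five modelled species), intervention class and the RMST ratio MR with its
#' delta-method standard error.
#'
#' @return A data.frame of 20 rows with columns `study`, `year`,
#'   `first_author`, `species_raw`, `species`, `tumor`, `intervention`,
#'   `n_treat`, `n_ctrl`, `rmst_treat`, `se_treat`, `rmst_ctrl`, `se_ctrl`,
#'   `mr`, `se_mr`, `source`.
#' @export
load_table1 <- function() {
  df <- utils::read.csv(fixture_path("table1_studies.csv"),
                        stringsAsFactors = FALSE)
  num <- unlist(df[c("year", "n_treat", "n_ctrl", "rmst_treat", "se_treat",
                     "rmst_ctrl", "se_ctrl", "mr", "se_mr")])
  if (nrow(df) != 20L || abs(sum(num) - .t1_checksum) > 1e-6)
    stop("table1 fixture corrupted (checksum mismatch)")
  if (!all(df$species %in% SPECIES) || !all(df$intervention %in% INTERVENTIONS))
    stop("table1 fixture has labels outside the fixed vocabularies")
  df
}

#' Load the species-by-intervention evidence grid
#'
#' The canonical model input: ln(MR) with standard deviation for the 12
#' observed cells of the 5 species x 4 interventions grid; 8 cells have no
#' study and are missing.
#'
#' @return An [evidence_matrix()].
#' @export
load_table2 <- function() {
  df <- utils::read.csv(fixture_path("table2_cells.csv"),
                        stringsAsFactors = FALSE)
  if (abs(sum(df$ln_mr, df$sd, na.rm = TRUE) - .t2_checksum) > 1e-6 ||
      sum(!is.na(df$ln_mr)) != 12L)
    stop("table2 fixture corrupted (checksum mismatch)")
  y <- matrix(NA_real_, 5, 4, dimnames = list(SPECIES, INTERVENTIONS))
  s <- y
  for (k in seq_len(nrow(df))) {
    y[df$species[k], df$intervention[k]] <- df$ln_mr[k]
    s[df$species[k], df$intervention[k]] <- df$sd[k]
  }
  evidence_matrix(y, s)
}

#' Remove named studies
#'
#' @param records a [load_table1()]-style data.frame.
#' @param names character vector of `study` labels to drop; must all exist.
#' @return The filtered data.frame.
#' @export
drop_studies <- function(records, names) {
  if (length(names) == 0L) return(records)
  unknown <- setdiff(names, records$study)
  if (length(unknown) > 0L)
    stop("unknown study labels: ", paste(unknown, collapse = ", "))
  records[!records$study %in% names, , drop = FALSE]
}

#' Assemble the evidence grid from per-study records
#'
#' Converts each study's MR to the log scale (delta method:
#' se(ln MR) = se(MR)/MR), then fills the species x intervention grid:
#' cells with a single study carry that study's estimate, cells with several
#' studies the posterior mean and SD from Bayesian random-effects pooling
#' ([pool_random_effects()]), and cells with no study stay missing. Intended
#' for new data and sensitivity reruns; the packaged grid ([load_table2()])
#' remains the canonical input for the shipped analysis.
#'
#' @param records a [load_table1()]-style data.frame.
#' @param tau_prior between-study-variance prior passed to the pooler.
#' @return An [evidence_matrix()].
#' @export
assemble_matrix <- function(records, tau_prior = c("dumouchel", "uniform", "half_normal")) {
  tau_prior <- match.arg(tau_prior)
  if (!all(records$species %in% SPECIES) ||
      !all(records$intervention %in% INTERVENTIONS))
    stop("unknown species or intervention label")
  if (any(!is.finite(records$mr)) || any(!is.finite(records$se_mr)))
    stop("every record needs a finite mr and se_mr")
  y <- matrix(NA_real_, 5, 4, dimnames = list(SPECIES, INTERVENTIONS))
  s <- y
  for (i in SPECIES) for (j in INTERVENTIONS) {
    r <- records[records$species == i & records$intervention == j, ]
    if (nrow(r) == 0L) next
    est <- data.frame(ln_mr = log(r$mr), sd = r$se_mr / r$mr)
    p <- pool_random_effects(est, tau_prior = tau_prior)
    y[i, j] <- p$ln_mr
    s[i, j] <- p$sd
  }
  evidence_matrix(y, s)
}
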
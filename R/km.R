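#' Survival arm
#'
#' Bundle the raw time-to-event records of a single study arm. Times must be
#' positive and share one unit within a study (days for the animal studies,
#' months for the human ones); the unit never matters downstream because the
#' RMST ratio is dimensionless.
#'
#' @param time positive event or censoring times.
#' @param event binary indicator, 1 = event observed, 0 = right-censored.
#' @param label arm label used in printed summaries.
#' @return An object of class `"surv_arm"` with fields `time`, `event`,
#'   `label`, ordered by nondecreasing time.
#' @examples
#' surv_arm(c(2, 4, 6), c(1, 1, 1))
#' @export
surv_arm <- function(time, event, label = "arm") {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) == 0L) stop("empty arm: no records")
  if (length(event) != length(time)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) stop("all times must be finite and > 0")
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  if (!any(event == 1L)) stop("all-censored arm: at least one event is required")
  ord <- order(time, -event)  # events precede censorings at tied times
  structure(list(time = time[ord], event = event[ord], label = label),
            class = "surv_arm")
}

#' @export
print.surv_arm <- function(x, ...) {
  cat(sprintf("Survival arm '%s': %d records, %d events, max time %g\n",
              x$label, length(x$time), sum(x$event), max(x$time)))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Nonparametric estimate of the survival function of one arm. The curve
#' steps only at distinct event times; a censored record removes its subject
#' from the risk set after its time, and at tied times events are processed
#' before censorings.
#'
#' @param arm a [surv_arm()].
#' @return An object of class `"km_curve"`: `time` (distinct event times),
#'   `surv` (survival probability just after each step), `n_risk`, `n_event`
#'   (risk set size and event count at each step), `n` (arm size) and
#'   `max_time` (last recorded time, event or censored).
#' @examples
#' km_fit(surv_arm(c(1, 2, 3), c(1, 0, 1)))
#' @export
km_fit <- function(arm) {
  stopifnot(inherits(arm, "surv_arm"))
  tt <- arm$time
  ev <- arm$event
  ut <- sort(unique(tt[ev == 1L]))
  n_event <- as.integer(tabulate(match(tt[ev == 1L], ut), length(ut)))
  # risk set: all records with time >= u (ties: censorings at u still at risk)
  n_risk <- as.numeric(length(tt) - findInterval(ut, tt, left.open = TRUE))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, surv = surv, n_risk = n_risk, n_event = n_event,
                 n = length(tt), max_time = max(tt), label = arm$label),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve '%s' (n = %d):\n", x$label, x$n))
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   surv = round(x$surv, 4)), row.names = FALSE)
  invisible(x)
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve up to a horizon `t*`:
#' RMST(t*) = E\[min(T, t*)\]. By default the horizon is the arm's last
#' recorded time, so that with complete follow-up the RMST equals the sample
#' mean survival time. The standard error is the Greenwood-type estimator
#' sqrt(sum_i A_i^2 d_i / (n_i (n_i - d_i))) over event times t_i <= t*,
#' where A_i is the area under the curve from t_i to the horizon; terms with
#' n_i = d_i are skipped.
#'
#' @param curve a [km_fit()] result.
#' @param horizon truncation time t*; defaults to the last recorded time of
#'   the arm and must not exceed it.
#' @return An object of class `"rmst_estimate"`: `value`, `se`, `horizon`.
#' @examples
#' rmst(km_fit(surv_arm(c(2, 4, 6), c(1, 1, 1))))
#' @export
rmst <- function(curve, horizon = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(horizon)) horizon <- curve$max_time
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (horizon > curve$max_time + 1e-12)
    stop("horizon exceeds the last recorded time of the arm")
  tt <- curve$time
  ss <- curve$surv
  # step function: S = 1 on [0, t_1), ss[k] on [t_k, t_{k+1})
  inside <- tt < horizon
  te <- tt[inside]
  sv <- ss[inside]
  value <- sum(c(1, sv) * diff(c(0, te, horizon)))
  # Greenwood-type variance: A_i = area under S from event time t_i to the
  # horizon, terms with an exhausted risk set (n_i = d_i) skipped
  seg <- sv * diff(c(te, horizon))
  tail_area <- rev(cumsum(rev(seg)))  # area from te[i] to horizon
  A <- rep(0, length(tt))
  A[inside] <- tail_area
  keep <- tt <= horizon & curve$n_risk > curve$n_event
  var <- sum((A^2 * curve$n_event /
                (curve$n_risk * (curve$n_risk - curve$n_event)))[keep])
  structure(list(value = value, se = sqrt(var), horizon = horizon),
            class = "rmst_estimate")
}

#' @export
print.rmst_estimate <- function(x, ...) {
  cat(sprintf("RMST(%g) = %.4f (se %.4f)\n", x$horizon, x$value, x$se))
  invisible(x)
}

#' RMST ratio between two arms
#'
#' The treatment-to-control ratio of restricted mean survival times (MR) and
#' its log, with delta-method standard errors: se(ln MR) =
#' sqrt((se_T/RMST_T)^2 + (se_C/RMST_C)^2) and se(MR) = MR * se(ln MR).
#' MR > 1 (ln MR > 0) indicates longer survival under treatment.
#'
#' @param treat,ctrl [rmst()] results, or numeric `c(value, se)` pairs.
#' @return An object of class `"mr_estimate"`: `mr`, `se_mr`, `ln_mr`,
#'   `se_ln_mr`.
#' @examples
#' rmst_ratio(c(41.36, 4.02), c(23.70, 2.85))
#' @export
rmst_ratio <- function(treat, ctrl) {
  as_pair <- function(x) {
    if (inherits(x, "rmst_estimate")) c(x$value, x$se) else as.numeric(x)[1:2]
  }
  tr <- as_pair(treat); ct <- as_pair(ctrl)
  if (any(!is.finite(c(tr, ct))) || tr[1] <= 0 || ct[1] <= 0)
    stop("RMST values must be positive and finite")
  if (tr[2] < 0 || ct[2] < 0) stop("standard errors must be nonnegative")
  mr <- tr[1] / ct[1]
  se_ln <- sqrt((tr[2] / tr[1])^2 + (ct[2] / ct[1])^2)
  structure(list(mr = mr, se_mr = mr * se_ln, ln_mr = log(mr), se_ln_mr = se_ln),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR = %.3f (se %.3f); ln MR = %.4f (se %.4f)\n",
              x$mr, x$se_mr, x$ln_mr, x$se_ln_mr))
  invisible(x)
}

#' Read a delimited survival table
#'
#' Expects a header and columns `study_id`, `arm` (`treatment`/`control`),
#' `time`, `event` (0/1); comma- or tab-delimited, autodetected.
#'
#' @param path file path.
#' @return A data.frame with the four columns, types validated.
#' @export
read_survival_table <- function(path) {
  head1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", head1)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("study_id", "arm", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$arm %in% c("treatment", "control")))
    stop("arm must be 'treatment' or 'control'")
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  df
}

#' Per-study RMST and MR summary of a survival table
#'
#' Fits a Kaplan-Meier curve per (study, arm), computes the RMST at each
#' arm's own last recorded time (or a shared horizon), and the
#' treatment/control MR per study.
#'
#' @param data a data.frame as returned by [read_survival_table()], or a path.
#' @param shared_horizon if `TRUE`, both arms of a study use the smaller of
#'   the two arms' last recorded times so the areas are comparable; default
#'   is a per-arm horizon.
#' @return A data.frame with one row per (study, arm): `study_id`, `arm`,
#'   `n`, `horizon`, `rmst`, `se`, and per study `mr`, `se_mr`, `ln_mr`,
#'   `se_ln_mr` (repeated on both arm rows).
#' @export
rmst_table <- function(data, shared_horizon = FALSE) {
  if (is.character(data)) data <- read_survival_table(data)
  out <- NULL
  for (sid in unique(data$study_id)) {
    d <- data[data$study_id == sid, ]
    arms <- lapply(c("treatment", "control"), function(a) {
      dd <- d[d$arm == a, ]
      if (nrow(dd) == 0L) stop("study ", sid, " lacks arm ", a)
      surv_arm(dd$time, dd$event, label = paste(sid, a))
    })
    curves <- lapply(arms, km_fit)
    hor <- vapply(curves, function(k) k$max_time, numeric(1))
    if (shared_horizon) hor <- rep(min(hor), 2L)
    ests <- Map(rmst, curves, as.list(hor))
    mr <- rmst_ratio(ests[[1]], ests[[2]])
    out <- rbind(out, data.frame(
      study_id = sid, arm = c("treatment", "control"),
      n = vapply(curves, function(k) k$n, numeric(1)),
      horizon = hor,
      rmst = vapply(ests, function(e) e$value, numeric(1)),
      se = vapply(ests, function(e) e$se, numeric(1)),
      mr = mr$mr, se_mr = mr$se_mr, ln_mr = mr$ln_mr, se_ln_mr = mr$se_ln_mr))
  }
  rownames(out) <- NULL
  out
}
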
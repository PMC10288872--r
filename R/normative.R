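## Normative analysis: regress each callosal surface on sex, age and total
## cortical surface in controls only, derive "residues" (observed minus
## predicted) for every subject, flag residues below the control 10th
## percentile, and test each patient group for an excess of flagged subjects.

#' Fit a normative (control-only) model for one surface
#'
#' OLS of the callosal surface on SEX, AGE and TCxS in the control group.
#' The flagging threshold is the empirical `percentile`-th percentile of the
#' in-sample control residues, using the linear-interpolation quantile
#' convention `q(p) = x_(1 + (n - 1) p)` on the ascending sort (R type 7;
#' configurable through `qtype`).
#'
#' @param cohort Cohort data frame (controls are selected internally).
#' @param surface `"total"` or a parcel name.
#' @param percentile Flagging percentile (default 10).
#' @param qtype Quantile algorithm type passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return An object of class `cc_normative`: `coefficients`, `threshold`,
#'   `residues` (in-sample control residues), `percentile`, `surface`.
#' @export
fit_normative <- function(cohort, surface = "total", percentile = 10,
                          qtype = 7L) {
  surface <- resolve_surface(surface)
  ctl <- cohort[cohort$group == "control", , drop = FALSE]
  if (nrow(ctl) < 10L) stop("need at least 10 controls")
  y <- ctl[[ccps_column(surface)]]
  X <- cbind(`(Intercept)` = 1, SEX = ctl$sex, AGE = ctl$age_years,
             TCxS = ctl$tcxs_cm2)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop("normative design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  res <- unname(fit$residuals)
  threshold <- unname(stats::quantile(res, percentile / 100, type = qtype))
  structure(list(coefficients = stats::setNames(unname(fit$coefficients),
                                                colnames(X)),
                 threshold = threshold, residues = res,
                 percentile = percentile, surface = surface),
            class = "cc_normative")
}

#' @export
print.cc_normative <- function(x, ...) {
  cat(sprintf("<cc_normative> %s: threshold %.3f mm^2 (P%g of %d controls)\n",
              x$surface, x$threshold, x$percentile, length(x$residues)))
  invisible(x)
}

#' Apply a normative model to a whole cohort
#'
#' Computes for every subject the residue (observed minus predicted, mm^2)
#' and flags residues *strictly below* the control threshold. A callosal
#' area of 0 (partial agenesis) yields a large negative residue and is
#' flagged like any other value.
#'
#' @param model A `cc_normative`.
#' @param cohort Cohort data frame (all groups).
#' @return Data frame: subject_id, group, surface, residue, flag.
#' @export
apply_normative <- function(model, cohort) {
  stopifnot(inherits(model, "cc_normative"))
  b <- model$coefficients
  pred <- b["(Intercept)"] + b["SEX"] * cohort$sex +
    b["AGE"] * cohort$age_years + b["TCxS"] * cohort$tcxs_cm2
  residue <- cohort[[ccps_column(model$surface)]] - pred
  data.frame(subject_id = cohort$subject_id, group = cohort$group,
             surface = model$surface, residue = unname(residue),
             flag = unname(residue < model$threshold))
}

#' Test a patient group for an excess of flagged subjects
#'
#' For each surface, a 2x2 table (group vs. control, flagged vs. not) is
#' tested with Fisher's exact test (two-sided); BH-FDR is applied across the
#' surfaces within the group.
#'
#' @param flags Data frame from [apply_normative()] (stacked over surfaces).
#' @param group Patient group name (`"FAS"` or `"NS-FASD"`).
#' @return Data frame per surface: counts, Fisher p, q.
#' @export
excess_test <- function(flags, group) {
  stopifnot(all(c("group", "surface", "flag") %in% names(flags)))
  surfaces <- unique(flags$surface)
  rows <- lapply(surfaces, function(s) {
    f <- flags[flags$surface == s, , drop = FALSE]
    pat <- f[f$group == group, , drop = FALSE]
    ctl <- f[f$group == "control", , drop = FALSE]
    a <- sum(pat$flag); b <- nrow(pat) - a
    c_ <- sum(ctl$flag); d <- nrow(ctl) - c_
    ft <- fisher_exact(a, b, c_, d)
    data.frame(group = group, surface = s,
               n_below = a, n_group = nrow(pat),
               n_below_control = c_, n_control = nrow(ctl),
               p = ft$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Run the full normative analysis
#'
#' Fits a control-only model per surface (total CC plus the seven parcels by
#' default), derives residues and flags for every subject, and tests each
#' patient group present in the cohort for an excess of flagged subjects.
#'
#' @param cohort Cohort data frame.
#' @param surfaces Surfaces to analyse (default total + 7 parcels).
#' @param percentile Flagging percentile (default 10).
#' @param qtype Quantile convention (see [fit_normative()]).
#' @return List of class `cc_normative_result`: `flags` (per subject x
#'   surface), `tests` (per group x surface), `models`.
#' @export
normative_analysis <- function(cohort, surfaces = c("total", parcel_names()),
                               percentile = 10, qtype = 7L) {
  surfaces <- vapply(surfaces, resolve_surface, character(1))
  models <- lapply(surfaces, fit_normative, cohort = cohort,
                   percentile = percentile, qtype = qtype)
  flags <- do.call(rbind, lapply(models, apply_normative, cohort = cohort))
  groups <- setdiff(unique(cohort$group), "control")
  tests <- do.call(rbind, lapply(groups, function(g) excess_test(flags, g)))
  structure(list(flags = flags, tests = tests, models = models),
            class = "cc_normative_result")
}
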
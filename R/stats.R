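## Group-comparison statistics: linear models of callosal / cortical parcel
## areas with diagnosis, sex, age and total cortical surface as covariates;
## eta-squared effect sizes; one-tailed diagnosis tests; BH-FDR; and the
## descriptive two-sample tests used on cohort characteristics.

#' One-tailed (lower) p-value for the diagnosis coefficient
#'
#' The alternative hypothesis for `DIAG` is a *smaller* surface in the
#' affected group, so its t statistic is tested against the lower tail.
#'
#' @param t t statistic.
#' @param df Residual degrees of freedom.
#' @return Lower-tail p-value.
#' @export
one_tailed_p <- function(t, df) stats::pt(t, df)

#' Fit a group-comparison linear model
#'
#' Ordinary least squares of a parcel surface on diagnosis and covariates:
#' * model 1: `CcPS ~ DIAG + SEX + AGE + TCxS` (response mm^2)
#' * model 2: `%CxPS ~ DIAG + SEX + AGE + TCxS` (response = 100 CxPS/TCxS)
#' * model 3: model 1 plus the matching parcel's `%CxPS` as covariate
#'
#' `DIAG` is 0 for controls and 1 for the affected groups; its p-value is
#' one-tailed (lower: the alternative is a *smaller* surface in patients).
#' All other coefficients are tested two-tailed. The effect size for `DIAG`
#' is eta-squared, the single-df type-III sum of squares of DIAG over the
#' total sum of squares (equivalently `t^2 (1 - R^2) / df_res`).
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param model Model id: 1, 2 or 3.
#' @param surface `"total"` or a parcel name (model 2 requires a parcel).
#' @param affected Groups coded DIAG = 1 (default both patient groups).
#' @return An object of class `cc_fit`: `coefficients` table (estimate, se,
#'   t, p), `df_res`, `r_squared`, `eta_squared` (for DIAG, as a
#'   proportion), `n`, `model`, `surface`.
#' @export
fit_cc_model <- function(cohort, model = 1L, surface = "total",
                         affected = c("FAS", "NS-FASD")) {
  stopifnot(model %in% 1:3)
  surface <- resolve_surface(surface)
  cohort <- cohort[cohort$group %in% c("control", affected), , drop = FALSE]
  diag_ <- as.integer(cohort$group %in% affected)
  if (length(unique(diag_)) < 2L || min(table(diag_)) < 2L)
    stop("need at least 2 subjects per DIAG level")
  if (model == 2L && surface == "total")
    stop("model 2 is defined per cortical parcel, not for the total CC")
  y <- if (model == 2L) {
    100 * cohort[[cxps_column(surface)]] / cohort$tcxs_cm2
  } else {
    cohort[[ccps_column(surface)]]
  }
  X <- cbind(`(Intercept)` = 1, DIAG = diag_, SEX = cohort$sex,
             AGE = cohort$age_years, TCxS = cohort$tcxs_cm2)
  if (model == 3L) {
    if (surface == "total")
      stop("model 3 is defined per parcel (needs the matching %CxPS)")
    X <- cbind(X, pct_CxPS = 100 * cohort[[cxps_column(surface)]] /
                 cohort$tcxs_cm2)
  }
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(X)[qr_$pivot[(qr_$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, y)
  n <- nrow(X)
  p <- ncol(X)
  df_res <- n - p
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("response has zero variance")
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df_res)
  pval["DIAG"] <- one_tailed_p(tval["DIAG"], df_res)
  r2 <- 1 - rss / tss
  eta2 <- unname(tval["DIAG"]^2 * (1 - r2) / df_res)
  structure(list(coefficients = data.frame(term = colnames(X),
                                           estimate = unname(fit$coefficients),
                                           se = unname(se),
                                           t = unname(tval),
                                           p = unname(pval)),
                 df_res = df_res, r_squared = r2, eta_squared = eta2,
                 n = n, model = model, surface = surface),
            class = "cc_fit")
}

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("<cc_fit> model %d, %s, n = %d, R^2 = %.3f, eta^2(DIAG) = %.3f\n",
              x$model, x$surface, x$n, x$r_squared, x$eta_squared))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Eta-squared effect size of the diagnosis term
#'
#' `SS_DIAG / SS_total` with `SS_DIAG` the single-df type-III sum of squares
#' of DIAG (`t^2 MSE`).
#'
#' @param fit A `cc_fit`.
#' @return Eta-squared as a proportion in \[0, 1\].
#' @export
eta_squared <- function(fit) {
  stopifnot(inherits(fit, "cc_fit"))
  fit$eta_squared
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q(k) = min over k' >= k of p(k') m / k'` on the ascending sort, clamped
#' at 1 and mapped back to the input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value, computed from group means, SDs and sizes (as
#' printed in cohort description tables).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return List of class `cc_test`: `statistic`, `df`, `p`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0 || sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(list(statistic = stat, df = df,
                 p = 2 * stats::pt(-abs(stat), df)),
            class = "cc_test")
}

#' Welch two-sample t-test from raw vectors
#'
#' @param x,y Numeric samples.
#' @return List of class `cc_test`: `statistic`, `df`, `p`.
#' @export
welch_t_raw <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(structure(list(statistic = 0, df = length(x) + length(y) - 2,
                          p = 1), class = "cc_test"))
  }
  welch_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Continuity-corrected chi-squared test for a 2x2 table
#'
#' Yates-corrected statistic
#' `X^2 = n (max(|ad - bc| - n/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))` with a
#' 1-df upper-tail p-value.
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return List of class `cc_test`: `statistic`, `df`, `p`.
#' @export
yates_chi2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("all table margins must be > 0")
  stat <- n * max(abs(a * d - b * c) - n / 2, 0)^2 / prod(margins)
  structure(list(statistic = stat, df = 1L,
                 p = stats::pchisq(stat, df = 1L, lower.tail = FALSE)),
            class = "cc_test")
}

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Sums, over all tables with the observed margins, the hypergeometric point
#' probabilities not exceeding that of the observed table.
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return List of class `cc_test`: `statistic` (the observed table
#'   probability), `df` (NA), `p`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be nonnegative integers")
  m <- a + b
  n <- c + d
  k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    return(structure(list(statistic = 1, df = NA, p = 1), class = "cc_test"))
  }
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d0 <- stats::dhyper(a, m, n, k)
  p <- sum(dens[dens <= d0 * (1 + 1e-7)])
  structure(list(statistic = d0, df = NA, p = min(p, 1)), class = "cc_test")
}

#' @export
print.cc_test <- function(x, ...) {
  cat(sprintf("<cc_test> statistic = %.4g, df = %s, p = %.4g\n",
              x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Raw-area group comparison across surfaces
#'
#' Two-sample Welch t-tests on raw areas (no covariates), one per surface,
#' with BH-FDR across the tested surfaces.
#'
#' @param cohort Cohort data frame.
#' @param surfaces Character vector of surfaces (`"total"` and/or parcel
#'   names); default all eight callosal surfaces.
#' @param affected Patient groups pooled against controls.
#' @return Data frame with one row per surface: statistic, df, p, q.
#' @export
compare_groups_raw <- function(cohort, surfaces = c("total", parcel_names()),
                               affected = c("FAS", "NS-FASD")) {
  cohort <- cohort[cohort$group %in% c("control", affected), , drop = FALSE]
  is_pat <- cohort$group %in% affected
  if (!any(is_pat) || !all(is_pat == (cohort$group != "control")) ||
      sum(!is_pat) == 0L)
    stop("need both a control and a patient group")
  rows <- lapply(surfaces, function(s) {
    s <- resolve_surface(s)
    v <- cohort[[ccps_column(s)]]
    tt <- welch_t_raw(v[is_pat], v[!is_pat])
    data.frame(surface = s, statistic = tt$statistic, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Full model table across surfaces with FDR
#'
#' Fits one model per callosal surface (all eight for models 1; the seven
#' parcels for models 2-3) and BH-adjusts the one-tailed DIAG p-values
#' across the surfaces of that model.
#'
#' @param cohort Cohort data frame.
#' @param model Model id (1, 2 or 3).
#' @param affected Groups coded DIAG = 1.
#' @return Data frame: surface, eta2 (percent), b_diag, t, df, p, q, r2, n.
#' @export
model_table <- function(cohort, model = 1L, affected = c("FAS", "NS-FASD")) {
  surfaces <- if (model == 1L) c("total", parcel_names()) else parcel_names()
  fits <- lapply(surfaces, fit_cc_model, cohort = cohort, model = model,
                 affected = affected)
  rows <- lapply(fits, function(f) {
    cf <- f$coefficients
    i <- match("DIAG", cf$term)
    data.frame(model = f$model, surface = f$surface,
               eta2_pct = 100 * f$eta_squared,
               b_diag = cf$estimate[i], se = cf$se[i], t = cf$t[i],
               df = f$df_res, p = cf$p[i], r2 = f$r_squared, n = f$n)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out[c("model", "surface", "eta2_pct", "b_diag", "se", "t", "df", "p", "q",
        "r2", "n")]
}
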
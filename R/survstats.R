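#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival estimate with Greenwood standard errors;
#' censoring at tied event times is handled events-first, as in the
#' standard estimator. The 5-year event-free survival is read off the
#' curve as the last estimate at or before 60 months.
#'
#' @param times non-negative follow-up times (months).
#' @param events binary event indicators.
#' @return list of class `"survival_curve"`: `event_times` (sorted distinct
#'   times with at least one event), `survival`, `at_risk`, `events`,
#'   `greenwood_se`, and `efs5` (survival at 60 months).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1L, all(times >= 0), all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  has_event <- fit$n.event > 0
  curve <- structure(
    list(event_times = fit$time[has_event],
         survival = fit$surv[has_event],
         at_risk = fit$n.risk[has_event],
         events = fit$n.event[has_event],
         greenwood_se = (fit$std.err * fit$surv)[has_event]),
    class = "survival_curve")
  curve$efs5 <- survival_at(curve, 60)
  curve
}

#' Evaluate a survival curve at a time point
#'
#' Step-function convention: the last product-limit estimate at or before
#' `t`; 1 before the first event.
#'
#' @param curve a `"survival_curve"`.
#' @param t time point (months).
#' @return survival probability.
#' @export
survival_at <- function(curve, t) {
  idx <- which(curve$event_times <= t)
  if (!length(idx)) return(1)
  curve$survival[max(idx)]
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$event_times), "event times, S(60) =",
      sprintf("%.3f", x$efs5), "\n")
  invisible(x)
}

#' k-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance, chi-square
#' with k - 1 degrees of freedom.
#'
#' @param groups group labels (coerced to factor; every level must be
#'   non-empty).
#' @param times follow-up times.
#' @param events binary event indicators.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 groups")
  if (any(table(g) == 0L)) stop("log-rank test: empty group level")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multiplicity correction
#'
#' Benjamini-Hochberg step-up (with enforced monotonicity) or Bonferroni
#' (`min(1, m * p)`); `m` may be declared larger than the number of
#' observed p values.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param method `"benjamini_hochberg"` or `"bonferroni"`.
#' @param m number of tests (default `length(p)`).
#' @return adjusted p values.
#' @export
adjust_pvalues <- function(p, method = c("benjamini_hochberg", "bonferroni"),
                           m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, benjamini_hochberg = "BH",
                                     bonferroni = "bonferroni"), n = m)
}

#' Pairwise Fisher co-segregation testing
#'
#' For every pair of lesions, a two-sided Fisher's exact test (sum of all
#' hypergeometric table probabilities at or below the observed table's) on
#' the 2x2 carrier table, Benjamini-Hochberg correction over pairs, and a
#' direction label — co-occurring when the odds ratio exceeds 1,
#' mutually exclusive below 1 — applied only to pairs significant after
#' correction. `odds_ratio` is the raw cross-product ratio (0 or Inf with a
#' zero cell); `odds_ratio_display` additionally applies the
#' Haldane-Anscombe 0.5 correction when a cell is zero — the p value never
#' does. Lesions present in no or in every patient are skipped with a
#' message.
#'
#' @param mat binary lesion-by-patient matrix (rows = lesions).
#' @param alpha significance level for the direction label.
#' @return data.frame with one row per tested pair: counts (`both`,
#'   `only_a`, `only_b`, `neither`), `odds_ratio`, `odds_ratio_display`,
#'   `p`, `q`, `significant_raw`, `direction`.
#' @export
fisher_cosegregation <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need at least 2 lesions")
  n <- ncol(mat)
  rs <- rowSums(mat)
  degenerate <- rownames(mat)[rs == 0L | rs == n]
  if (length(degenerate)) {
    message("skipping degenerate lesion(s): ",
            paste(degenerate, collapse = ", "))
    mat <- mat[!rownames(mat) %in% degenerate, , drop = FALSE]
  }
  lesions <- rownames(mat)
  if (length(lesions) < 2L) stop("fewer than 2 non-degenerate lesions")
  pairs <- utils::combn(lesions, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- mat[pairs[1L, k], ]; b <- mat[pairs[2L, k], ]
    tab <- c(both = sum(a & b), only_a = sum(a & !b),
             only_b = sum(!a & b), neither = sum(!a & !b))
    # fisher.test can return 1 + eps in floating point
    p <- min(1, stats::fisher.test(matrix(tab, 2L, byrow = TRUE))$p.value)
    or_raw <- tab[1] * tab[4] / (tab[2] * tab[3])
    or_disp <- if (any(tab == 0))
      (tab[1] + 0.5) * (tab[4] + 0.5) / ((tab[2] + 0.5) * (tab[3] + 0.5))
    else or_raw
    data.frame(lesion_a = pairs[1L, k], lesion_b = pairs[2L, k],
               both = tab[1], only_a = tab[2], only_b = tab[3],
               neither = tab[4], odds_ratio = unname(or_raw),
               odds_ratio_display = unname(or_disp), p = p,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, res)
  res$q <- adjust_pvalues(res$p, "benjamini_hochberg")
  res$significant_raw <- res$p < alpha
  res$direction <- ifelse(res$q >= alpha, "none",
                          ifelse(res$odds_ratio_display > 1, "co_occurring",
                                 "mutually_exclusive"))
  res
}
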
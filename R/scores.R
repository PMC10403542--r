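#' Univariate Cox proportional-hazards fit for one lesion
#'
#' Fits the partial likelihood of a single binary carrier covariate against
#' event-free survival, with the Efron correction for tied event times
#' (Breslow available). Monotone likelihoods (complete separation of events
#' by carrier status) are returned with the log hazard ratio capped at
#' +/- 10 and flagged rather than failing.
#'
#' @param carrier binary (0/1) vector, one element per patient.
#' @param efs_months non-negative follow-up times in months.
#' @param event binary event indicator.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return list of class `"cox_fit"`: `beta`, `hr`, `se_beta`, `ci95`
#'   (length-2), `p_value`, `n_carriers`, `n_events`, `flagged`.
#' @export
fit_univariate_cox <- function(carrier, efs_months, event,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(carrier) == length(efs_months),
            length(event) == length(efs_months),
            all(efs_months >= 0), all(event %in% c(0, 1)))
  if (sum(event) == 0) stop("cohort has zero events; cannot fit")
  if (length(unique(carrier)) < 2L) stop("carrier status is constant")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(efs_months, event) ~ carrier,
                    ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1L, 1L]))
  flagged <- FALSE
  if (!is.finite(beta) || abs(beta) > 10 || !is.finite(se)) {
    warning("monotone partial likelihood; log hazard ratio capped at +/-10",
            call. = FALSE)
    beta <- sign(beta) * 10
    flagged <- TRUE
  }
  z <- beta / se
  structure(list(beta = beta, hr = exp(beta), se_beta = se,
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = 2 * stats::pnorm(-abs(z)),
                 n_carriers = sum(carrier == 1),
                 n_events = sum(event), flagged = flagged),
            class = "cox_fit")
}

#' Select prognostically relevant lesions
#'
#' A lesion is retained iff its cohort frequency exceeds `f_min` (strict)
#' and its hazard ratio is either above `hr_hi` (strict, adverse) or at or
#' below `hr_lo` (inclusive, protective). Defaults are frequency > 1.5%
#' and HR > 1.5 or <= 0.66.
#'
#' @param fits named list of `"cox_fit"` objects (names = lesion ids).
#' @param cohort_n full cohort size (the frequency denominator).
#' @param f_min,hr_hi,hr_lo filter parameters.
#' @return character vector of selected lesion ids.
#' @export
select_prognostic_lesions <- function(fits, cohort_n, f_min = 0.015,
                                      hr_hi = 1.5, hr_lo = 0.66) {
  sel <- vapply(fits, function(f) {
    freq <- f$n_carriers / cohort_n
    freq > f_min && (f$hr > hr_hi || f$hr <= hr_lo)
  }, logical(1))
  names(fits)[sel]
}

#' Signed integer score for a selected lesion
#'
#' Default log-HR banding: magnitude `clamp(round(|ln HR| / ln 1.5), 1, 4)`;
#' protective lesions (HR <= 0.66) score positive, adverse lesions
#' (HR > 1.5) negative. Hazard ratios inside the neutral band must not be
#' scored and raise an error. The banding base and clamp are configurable,
#' and a hand-set table loaded from JSON can bypass derivation entirely.
#'
#' @param hr hazard ratio, or a `"cox_fit"`.
#' @param base banding base (default 1.5, one band per 1.5-fold hazard).
#' @param clamp maximum magnitude.
#' @param hr_hi,hr_lo the selection bands (for the neutral-band check).
#' @return signed integer score.
#' @export
assign_lesion_score <- function(hr, base = 1.5, clamp = 4L,
                                hr_hi = 1.5, hr_lo = 0.66) {
  if (inherits(hr, "cox_fit")) hr <- hr$hr
  stopifnot(is.numeric(hr), hr > 0)
  if (hr <= hr_hi && hr > hr_lo)
    stop("hazard ratio ", signif(hr, 4),
         " lies in the neutral band and must not be scored")
  magnitude <- min(max(round(abs(log(hr)) / log(base)), 1L), clamp)
  as.integer(if (hr <= hr_lo) magnitude else -magnitude)
}

#' Derivation configuration
#'
#' @param f_min,hr_hi,hr_lo selection filter (see
#'   [select_prognostic_lesions]).
#' @param ties tie handling for the Cox fits.
#' @param truncate_months administrative truncation of EFS for derivation;
#'   follow-up beyond this horizon is censored there (5-year EFS: 60).
#' @param score_base,score_clamp weighting scheme (see
#'   [assign_lesion_score]).
#' @param min_carriers lesions with fewer carriers are not fit at all.
#' @return list of class `"derive_config"`.
#' @export
derive_config <- function(f_min = 0.015, hr_hi = 1.5, hr_lo = 0.66,
                          ties = "efron", truncate_months = 60,
                          score_base = 1.5, score_clamp = 4L,
                          min_carriers = 2L) {
  structure(list(f_min = f_min, hr_hi = hr_hi, hr_lo = hr_lo, ties = ties,
                 truncate_months = truncate_months, score_base = score_base,
                 score_clamp = score_clamp,
                 min_carriers = as.integer(min_carriers)),
            class = "derive_config")
}

#' Derive a score table from a cohort
#'
#' Composes the fit / select / assign pipeline over every lesion observed
#' in the cohort's profiles: a univariate Cox model per lesion (EFS
#' censored at the 60-month horizon), the frequency + hazard-ratio
#' selection filter, and signed integer weight assignment. Composite
#' lesions (IKZF1plus, DT4_6, HHD, fusions) enter as first-class predicates
#' alongside gene CNAs. When both IKZF1plus and IKZF1:loss are selected,
#' the more specific IKZF1plus supersedes IKZF1:loss via an exclusion
#' group.
#'
#' @param profiles list of `"lesion_profile"` objects.
#' @param records cohort clinical data.frame with `patient_id`,
#'   `efs_months`, `event`.
#' @param config a [derive_config].
#' @return a [score_table] with per-entry selection metadata and a `fits`
#'   attribute holding every attempted `"cox_fit"`.
#' @export
derive_score_table <- function(profiles, records, config = derive_config()) {
  ids <- vapply(profiles, `[[`, "", "patient_id")
  if (!all(ids %in% records$patient_id))
    stop("profiles and clinical records do not align by patient_id")
  records <- records[match(ids, records$patient_id), ]
  tt <- pmin(records$efs_months, config$truncate_months)
  ev <- as.integer(records$event == 1 &
                   records$efs_months <= config$truncate_months)
  if (sum(ev) == 0) stop("cohort has zero events within the horizon")
  n <- length(profiles)

  m <- lesion_matrix(profiles)
  fits <- list()
  for (lesion in rownames(m)) {
    carrier <- m[lesion, ]
    nc <- sum(carrier)
    if (nc < config$min_carriers || nc > n - 1L) next
    f <- tryCatch(
      suppressWarnings(fit_univariate_cox(carrier, tt, ev, ties = config$ties)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[lesion]] <- f
  }
  selected <- select_prognostic_lesions(fits, n, config$f_min,
                                        config$hr_hi, config$hr_lo)
  entries <- do.call(rbind, lapply(selected, function(l) {
    f <- fits[[l]]
    data.frame(lesion = l,
               score = assign_lesion_score(f$hr, config$score_base,
                                           config$score_clamp,
                                           config$hr_hi, config$hr_lo),
               hr = f$hr, freq = f$n_carriers / n,
               ci_low = f$ci95[1L], ci_high = f$ci95[2L],
               provenance = "derived", stringsAsFactors = FALSE)
  }))
  if (is.null(entries))
    entries <- data.frame(lesion = character(0), score = integer(0),
                          hr = numeric(0), freq = numeric(0),
                          ci_low = numeric(0), ci_high = numeric(0),
                          provenance = character(0), stringsAsFactors = FALSE)
  excl <- list()
  if (all(c("IKZF1plus", "IKZF1:loss") %in% entries$lesion))
    excl <- list(c("IKZF1plus", "IKZF1:loss"))
  tab <- score_table(entries, excl)
  attr(tab, "fits") <- fits
  tab
}
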
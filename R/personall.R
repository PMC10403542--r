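#' Fit the PersonALL risk model on a cohort
#'
#' The central fitting function: derives the aberration score table from
#' the cohort (univariate Cox hazard ratio per lesion, frequency > 1.5%
#' and HR > 1.5 or <= 0.66 selection, signed log-HR weights), computes
#' every patient's cumulative score and four-group PersonALL class, the
#' cytogenetics-aware IKAROS group, per-group Kaplan-Meier curves and the
#' across-group log-rank test.
#'
#' @param profiles list of `"lesion_profile"` objects (see
#'   [build_profile] / [build_profiles]).
#' @param clinical cohort clinical data.frame: `patient_id`, `efs_months`,
#'   `event` (see [read_cohort]).
#' @param score_tab optional pre-specified [score_table] (e.g. loaded from
#'   JSON); when supplied, derivation is skipped and the table is applied
#'   as-is.
#' @param config a [derive_config].
#' @param ikaros an `"ikaros_matrix"`; [default_ikaros_matrix] by default.
#' @return object of class `"personall"`: list with `score_table`,
#'   `assignments` (data.frame `patient_id`, `score`, `personall_group`,
#'   `ikaros_group`), `curves` (per-group `"survival_curve"`), `logrank`,
#'   `clinical`, `ikaros_matrix`, `call`.
#' @seealso [predict.personall], [summary.personall], [plot.personall]
#' @export
personall <- function(profiles, clinical, score_tab = NULL,
                      config = derive_config(),
                      ikaros = default_ikaros_matrix()) {
  if (is.null(score_tab))
    score_tab <- derive_score_table(profiles, clinical, config)
  assignments <- .assign_risk(profiles, score_tab, ikaros)
  merged <- merge(assignments, clinical, by = "patient_id", sort = FALSE)

  groups_present <- levels(droplevels(merged$personall_group))
  curves <- lapply(stats::setNames(groups_present, groups_present),
                   function(g) {
                     sel <- merged$personall_group == g
                     km_estimate(merged$efs_months[sel], merged$event[sel])
                   })
  logrank <- if (length(groups_present) >= 2L)
    logrank_test(droplevels(merged$personall_group),
                 merged$efs_months, merged$event)
  else NULL

  structure(list(score_table = score_tab, assignments = assignments,
                 curves = curves, logrank = logrank, clinical = clinical,
                 ikaros_matrix = ikaros, config = config,
                 call = match.call()),
            class = "personall")
}

.assign_risk <- function(profiles, score_tab, ikaros) {
  rows <- lapply(profiles, function(p) {
    s <- cumulative_score(p, score_tab)
    ik <- if (!is.null(p$ikzf1_status) && !is.null(p$subtype))
      tryCatch(classify_ikaros(p$ikzf1_status, p$subtype, ikaros),
               error = function(e) NA_character_)
    else NA_character_
    data.frame(patient_id = p$patient_id, score = s,
               personall_group = NA, ikaros_group = ik,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$personall_group <- classify_personall(out$score)
  rownames(out) <- NULL
  out
}

#' @export
print.personall <- function(x, ...) {
  cat("PersonALL risk model\n")
  cat("  score table:", nrow(x$score_table$entries), "lesion predicates\n")
  cat("  patients:", nrow(x$assignments), "\n")
  print(table(x$assignments$personall_group))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank across groups: chi^2 = %.2f (df = %d), p = %.3g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  invisible(x)
}

#' Summarize a fitted PersonALL model
#'
#' @param object a `"personall"` fit.
#' @param ... unused.
#' @return list of class `"summary.personall"` with the score table, a
#'   per-group summary (size, fraction, events, 5-year EFS with Greenwood
#'   SE at the last event time before 60 months) and the log-rank test.
#' @export
summary.personall <- function(object, ...) {
  merged <- merge(object$assignments, object$clinical, by = "patient_id")
  groups <- levels(droplevels(merged$personall_group))
  tab <- do.call(rbind, lapply(groups, function(g) {
    sel <- merged$personall_group == g
    cv <- object$curves[[g]]
    data.frame(group = g, n = sum(sel),
               fraction = mean(merged$personall_group == g),
               events = sum(merged$event[sel]),
               efs5 = cv$efs5, stringsAsFactors = FALSE)
  }))
  ik <- table(factor(merged$ikaros_group, levels = c("low", "medium", "high")))
  structure(list(score_table = object$score_table, groups = tab,
                 ikaros = ik, logrank = object$logrank),
            class = "summary.personall")
}

#' @export
print.summary.personall <- function(x, ...) {
  print(x$score_table)
  cat("\nPersonALL risk groups:\n")
  print(x$groups, row.names = FALSE, digits = 3)
  cat("\nIKAROS groups:\n")
  print(x$ikaros)
  if (!is.null(x$logrank))
    cat(sprintf("\nLog-rank across PersonALL groups: chi^2 = %.2f (df = %d), p = %.3g\n",
                x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  invisible(x)
}

#' @export
coef.personall <- function(object, ...) {
  stats::setNames(object$score_table$entries$score,
                  object$score_table$entries$lesion)
}

#' Classify new patients with a fitted PersonALL model
#'
#' @param object a `"personall"` fit.
#' @param newdata list of `"lesion_profile"` objects (defaults to the
#'   training profiles' assignments being returned).
#' @param ... unused.
#' @return data.frame `patient_id`, `score`, `personall_group`,
#'   `ikaros_group`.
#' @export
predict.personall <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$assignments)
  .assign_risk(newdata, object$score_table, object$ikaros_matrix)
}

#' Plot per-group Kaplan-Meier curves of a PersonALL fit
#'
#' @param x a `"personall"` fit.
#' @param col per-group colors.
#' @param xlab,ylab,... passed to [graphics::plot].
#' @export
plot.personall <- function(x, col = c(excellent = "#1b7837", good = "#5aae61",
                                      high = "#f1a340", ultra_poor = "#b2182b"),
                           xlab = "Months from treatment start",
                           ylab = "Event-free survival", ...) {
  graphics::plot(NA, xlim = c(0, 60), ylim = c(0, 1), xlab = xlab,
                 ylab = ylab, ...)
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    tt <- c(0, rep(cv$event_times, each = 2), 60)
    ss <- c(1, 1, rep(cv$survival, each = 2))[seq_along(tt)]
    graphics::lines(tt, ss, col = col[[g]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(x$curves),
                   col = col[names(x$curves)], lwd = 2, bty = "n")
  invisible(x)
}
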
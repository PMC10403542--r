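#' Construct a validated score table
#'
#' A score table maps lesion predicates to signed non-zero integer scores.
#' Exclusion groups are ordered sets of predicates in which only the most
#' specific (first listed) lesion present in a patient contributes; a
#' superseded lesion scores 0. Selection metadata (frequency, hazard ratio,
#' confidence interval) travels with each entry.
#'
#' @param entries data.frame with columns `lesion` (character), `score`
#'   (non-zero integer) and optionally `hr`, `freq`, `ci_low`, `ci_high`,
#'   `provenance` (`"derived"` or `"config"`).
#' @param exclusion_groups list of character vectors; each vector is
#'   ordered most-specific first and may only reference lesions present in
#'   `entries`.
#' @return list of class `"score_table"`.
#' @export
score_table <- function(entries, exclusion_groups = list()) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("lesion", "score") %in% names(entries)))
    stop("score table entries need `lesion` and `score` columns")
  if (anyDuplicated(entries$lesion))
    stop("duplicate lesion predicate(s) in score table")
  if (any(entries$score == 0) || any(entries$score != round(entries$score)))
    stop("scores must be non-zero integers")
  entries$score <- as.integer(entries$score)
  if (is.null(entries$provenance)) entries$provenance <- "config"
  for (g in exclusion_groups) {
    unknown <- setdiff(g, entries$lesion)
    if (length(unknown))
      stop("exclusion group references unknown lesion(s): ",
           paste(unknown, collapse = ", "))
    if (length(g) < 2L) stop("exclusion groups need at least 2 members")
  }
  structure(list(entries = entries, exclusion_groups = exclusion_groups),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("Score table with", nrow(x$entries), "lesion predicates\n")
  print(x$entries, row.names = FALSE)
  if (length(x$exclusion_groups)) {
    cat("Exclusion groups (most specific first):\n")
    for (g in x$exclusion_groups) cat(" ", paste(g, collapse = " > "), "\n")
  }
  invisible(x)
}

#' Cumulative PersonALL score of one patient
#'
#' Sums the table scores of all lesion predicates matched by the patient's
#' profile, after applying the exclusion groups (within a group, only the
#' first-listed lesion present contributes). Lesions without a table entry
#' contribute 0.
#'
#' @param profile a `"lesion_profile"` or plain character vector of lesions.
#' @param table a [score_table].
#' @return integer cumulative score.
#' @export
cumulative_score <- function(profile, table) {
  lesions <- if (inherits(profile, "lesion_profile")) profile$lesions
  else as.character(profile)
  matched <- intersect(table$entries$lesion, lesions)
  for (g in table$exclusion_groups) {
    present <- g[g %in% matched]
    if (length(present) > 1L)
      matched <- setdiff(matched, present[-1L])
  }
  sum(table$entries$score[table$entries$lesion %in% matched])
}

#' PersonALL four-group classification from a cumulative score
#'
#' Thresholds: excellent for scores of at least 4, good for 0 to 3, high
#' for -3 to -1 and ultra-poor for -4 and below (the -4 boundary belongs to
#' the ultra-poor group, keeping the ranges disjoint).
#'
#' @param S integer cumulative score (vectorized).
#' @return factor with levels `excellent`, `good`, `high`, `ultra_poor`.
#' @export
classify_personall <- function(S) {
  stopifnot(is.numeric(S), all(S == round(S)))
  g <- ifelse(S >= 4, "excellent",
              ifelse(S >= 0, "good",
                     ifelse(S >= -3, "high", "ultra_poor")))
  factor(g, levels = c("excellent", "good", "high", "ultra_poor"))
}

#' Default IKAROS classification matrix
#'
#' Cytogenetic risk classes: good = ETV6-RUNX1 and HHD; poor = BCR-ABL1,
#' Ph-like, KMT2A-r and iAMP21; intermediate = everything else. The
#' (risk class x IKZF1 status) lookup sends IKZF1-normal patients to
#' IKAROS-low regardless of class, deletions in good-risk cytogenetics to
#' low, deletions elsewhere to medium, IKZF1-plus in good-risk cytogenetics
#' to medium and IKZF1-plus elsewhere to high. Fully overridable via JSON
#' config.
#'
#' @return list of class `"ikaros_matrix"` with `risk_class` (named
#'   character, subtype to class) and `mapping` (class x status matrix of
#'   group labels).
#' @export
default_ikaros_matrix <- function() {
  risk_class <- c("ETV6-RUNX1" = "good", "HHD" = "good",
                  "BCR-ABL1" = "poor", "Ph-like" = "poor",
                  "KMT2A-r" = "poor", "iAMP21" = "poor",
                  "TCF3-PBX1" = "intermediate", "B-other" = "intermediate")
  mapping <- matrix(c("low", "low", "medium",
                      "low", "medium", "high",
                      "low", "medium", "high"),
                    nrow = 3L, byrow = TRUE,
                    dimnames = list(c("good", "intermediate", "poor"),
                                    c("normal", "del", "plus")))
  structure(list(risk_class = risk_class, mapping = mapping),
            class = "ikaros_matrix")
}

#' Cytogenetics-aware IKAROS three-group classification
#'
#' Pure table lookup: the subtype is mapped to a cytogenetic risk class
#' (good / intermediate / poor) and the (class, IKZF1 status) cell of the
#' matrix gives the IKAROS group.
#'
#' @param status IKZF1 status: `"normal"`, `"del"` or `"plus"`.
#' @param subtype cytogenetic subtype label.
#' @param matrix an `"ikaros_matrix"`, by default [default_ikaros_matrix].
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
classify_ikaros <- function(status, subtype, matrix = default_ikaros_matrix()) {
  if (!status %in% colnames(matrix$mapping))
    stop("unknown IKZF1 status: ", status)
  if (!subtype %in% names(matrix$risk_class))
    stop("subtype not mapped to a cytogenetic risk class: ", subtype)
  cls <- matrix$risk_class[[subtype]]
  matrix$mapping[cls, status]
}

#' Read / write an IKAROS matrix as JSON
#' @param path file path.
#' @return an `"ikaros_matrix"`.
#' @export
read_ikaros_matrix <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!all(c("risk_class", "mapping") %in% names(x)))
    stop("IKAROS matrix JSON needs `risk_class` and `mapping`")
  need_cls <- c("good", "intermediate", "poor")
  need_st <- c("normal", "del", "plus")
  if (!all(need_cls %in% names(x$mapping)) ||
      !all(vapply(x$mapping, function(r) all(need_st %in% names(r)), logical(1))))
    stop("IKAROS mapping must be total over (risk class x status)")
  mp <- t(vapply(x$mapping[need_cls],
                 function(r) unlist(r)[need_st], character(3)))
  dimnames(mp) <- list(need_cls, need_st)
  structure(list(risk_class = unlist(x$risk_class), mapping = mp),
            class = "ikaros_matrix")
}

#' @rdname read_ikaros_matrix
#' @param matrix an `"ikaros_matrix"` to serialize.
#' @export
write_ikaros_matrix <- function(matrix, path) {
  mp <- apply(matrix$mapping, 1L, as.list, simplify = FALSE)
  jsonlite::write_json(
    list(risk_class = as.list(matrix$risk_class), mapping = mp),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
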
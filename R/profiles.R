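#' Determine IKZF1 status (normal / del / plus)
#'
#' IKZF1-plus is an IKZF1 deletion co-occurring with deletion of CDKN2A/B,
#' PAX5 or the PAR1 region in the absence of an ERG deletion; an IKZF1
#' deletion not meeting those criteria is `del`; otherwise `normal`.
#'
#' @param profile a `"lesion_profile"` from [build_profile], or any object
#'   with a `lesions` character set and an `assessed_loci` attribute listing
#'   the loci for which a call (possibly normal) is available.
#' @return `"normal"`, `"del"` or `"plus"`.
#' @export
assign_ikzf1_status <- function(profile) {
  required <- c("IKZF1", "CDKN2A/B", "PAX5", "PAR1", "ERG")
  assessed <- attr(profile, "assessed_loci")
  if (is.null(assessed) && is.list(profile)) assessed <- profile$assessed_loci
  miss <- setdiff(required, assessed)
  if (length(miss))
    stop("IKZF1 status needs calls for loci: ", paste(miss, collapse = ", "))
  lesions <- if (is.list(profile)) profile$lesions else profile
  has_loss <- function(g) paste0(g, ":loss") %in% lesions
  if (!has_loss("IKZF1")) return("normal")
  partner <- has_loss("CDKN2A/B") || has_loss("PAX5") || has_loss("PAR1")
  if (partner && !has_loss("ERG")) "plus" else "del"
}

#' Assign the cytogenetic subtype of one patient
#'
#' One label from BCR-ABL1, KMT2A-r, Ph-like, TCF3-PBX1, iAMP21,
#' ETV6-RUNX1, HHD (high-hyperdiploid karyotype) and the residual B-other
#' class. When several subgroup-defining markers co-occur the
#' highest-precedence (clinically most adverse fusion) label wins, in the
#' order listed above, and the conflict is reported as a warning.
#'
#' @param fusions character vector of fusion / signature markers
#'   (`"Ph-like-marker"` is accepted as a synonym of `"Ph-like"`).
#' @param karyotype a `"karyotype_estimate"` (or `NULL` for non-informative).
#' @return subtype label.
#' @export
assign_cytogenetic_subtype <- function(fusions, karyotype = NULL) {
  fusions <- sub("^Ph-like-marker$", "Ph-like", fusions)
  precedence <- c("BCR-ABL1", "KMT2A-r", "Ph-like", "TCF3-PBX1", "iAMP21",
                  "ETV6-RUNX1")
  hit <- precedence[precedence %in% fusions]
  if (length(hit) > 1L)
    warning("multiple subgroup-defining markers (",
            paste(hit, collapse = ", "), "); keeping ", hit[1L], call. = FALSE)
  if (length(hit)) return(hit[1L])
  if (!is.null(karyotype) && karyotype$ploidy_class == "high_hyperdiploid")
    return("HHD")
  "B-other"
}

#' Flag trisomy combinations
#'
#' A combination flag is true iff every chromosome of the set carries at
#' least three copies. The shipped default is the double trisomy of
#' chromosomes 4 and 6 (`DT4_6`), the favorable marker within
#' high-hyperdiploid B-ALL.
#'
#' @param karyotype a `"karyotype_estimate"`.
#' @param combos named list of character vectors of chromosome labels.
#' @return named logical vector, one entry per combination.
#' @export
detect_trisomy_combinations <- function(karyotype,
                                        combos = list(DT4_6 = c("4", "6"))) {
  cn <- karyotype$per_chromosome
  vapply(combos, function(set) {
    all(set %in% names(cn)) && all(cn[set] >= 3L)
  }, logical(1))
}

#' Build the genetic lesion profile of one patient
#'
#' Merges gene-level CNA calls, whole-chromosome gains, fusion markers and
#' the composite genotypes (IKZF1plus, trisomy combinations, HHD) into one
#' lesion set. Lesion identifiers are `"GENE:loss"`, `"GENE:gain"`,
#' `"GENE:multiple_gain"` (biallelic losses are recorded as `"GENE:loss"`
#' plus clonality/state detail), `"+4"`-style chromosome gains, fusion
#' names, and the composite flags `IKZF1plus`, `DT4_6`, `HHD`. The result
#' is independent of the order of the input call list.
#'
#' @param patient_id patient identifier.
#' @param calls data.frame of CNA calls for this patient (`locus`, `state`,
#'   `clonality`; the long format produced by [call_cna]).
#' @param karyotype a `"karyotype_estimate"` or `NULL`.
#' @param fusions character vector of fusion markers.
#' @param min_clonality `"subclonal"` (default: subclonal lesions count
#'   toward the profile) or `"clonal"` (clonal-only mode).
#' @param combos trisomy combinations passed to [detect_trisomy_combinations].
#' @return object of class `"lesion_profile"`: list with `patient_id`,
#'   `lesions` (sorted character set), `detail` (call-level data.frame),
#'   `subtype`, `ikzf1_status`; attribute `assessed_loci`.
#' @export
build_profile <- function(patient_id, calls, karyotype = NULL,
                          fusions = character(0),
                          min_clonality = c("subclonal", "clonal"),
                          combos = list(DT4_6 = c("4", "6"))) {
  min_clonality <- match.arg(min_clonality)
  if (is.null(calls) || !nrow(calls))
    calls <- data.frame(locus = character(0), state = character(0),
                        clonality = character(0), stringsAsFactors = FALSE)
  if (anyDuplicated(calls$locus)) {
    dup <- unique(calls$locus[duplicated(calls$locus)])
    conflicting <- vapply(dup, function(l)
      length(unique(calls$state[calls$locus == l])) > 1L, logical(1))
    if (any(conflicting))
      stop("conflicting duplicate calls for locus: ",
           paste(dup[conflicting], collapse = ", "))
    calls <- calls[!duplicated(calls$locus), ]
  }
  calls <- calls[order(calls$locus), , drop = FALSE]
  keep <- calls$state != "normal"
  if (min_clonality == "clonal") keep <- keep & calls$clonality == "clonal"
  aber <- calls[keep, , drop = FALSE]

  lesion_id <- function(locus, state)
    switch(state,
           loss = , biallelic_loss = paste0(locus, ":loss"),
           gain = paste0(locus, ":gain"),
           multiple_gain = paste0(locus, ":multiple_gain"),
           stop("unknown CNA state: ", state))
  lesions <- if (nrow(aber))
    mapply(lesion_id, aber$locus, aber$state, USE.NAMES = FALSE)
  else character(0)

  if (!is.null(karyotype)) {
    cn <- karyotype$per_chromosome
    gains <- names(cn)[cn >= 3L]
    lesions <- c(lesions, if (length(gains)) paste0("+", gains))
    tri <- detect_trisomy_combinations(karyotype, combos)
    lesions <- c(lesions, names(tri)[tri])
    if (karyotype$ploidy_class == "high_hyperdiploid") lesions <- c(lesions, "HHD")
  }
  fusions <- sub("^Ph-like-marker$", "Ph-like", fusions)
  lesions <- c(lesions, fusions)

  prof <- structure(
    list(patient_id = patient_id, lesions = sort(unique(lesions)),
         detail = aber, subtype = NULL, ikzf1_status = NULL),
    assessed_loci = unique(calls$locus), class = "lesion_profile")
  prof$subtype <- assign_cytogenetic_subtype(fusions, karyotype)
  if (all(c("IKZF1", "CDKN2A/B", "PAX5", "PAR1", "ERG") %in%
          attr(prof, "assessed_loci"))) {
    prof$ikzf1_status <- assign_ikzf1_status(prof)
    if (prof$ikzf1_status == "plus")
      prof$lesions <- sort(unique(c(prof$lesions, "IKZF1plus")))
  }
  prof
}

#' @export
print.lesion_profile <- function(x, ...) {
  cat("Lesion profile of patient", x$patient_id, "\n")
  cat("  subtype:", x$subtype %||% "unknown",
      " IKZF1:", x$ikzf1_status %||% "not assessed", "\n")
  cat("  lesions:", if (length(x$lesions)) paste(x$lesions, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build lesion profiles for a whole cohort
#'
#' @param records cohort clinical data.frame (see [read_cohort]): columns
#'   `patient_id`, `purity`, `fusions` (semicolon-separated tokens), ...
#' @param cna result of [call_cna] (calls + karyotypes) or `NULL` when
#'   profiles come from an external long table.
#' @param min_clonality,combos passed to [build_profile].
#' @return named list of `"lesion_profile"` objects, one per patient.
#' @export
build_profiles <- function(records, cna, min_clonality = "subclonal",
                           combos = list(DT4_6 = c("4", "6"))) {
  profs <- list()
  for (i in seq_len(nrow(records))) {
    pid <- records$patient_id[i]
    fus <- .parse_fusions(records$fusions[i])
    calls <- cna$calls[cna$calls$sample_id == pid, , drop = FALSE]
    kar <- cna$karyotypes[[pid]]
    profs[[pid]] <- build_profile(pid, calls, kar, fus,
                                  min_clonality = min_clonality,
                                  combos = combos)
  }
  profs
}

.parse_fusions <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(character(0))
  trimws(strsplit(s, ";", fixed = TRUE)[[1L]])
}

#' Lesion-by-patient carrier matrix
#'
#' @param profiles list of `"lesion_profile"` objects.
#' @param lesions optional character vector fixing the lesion universe and
#'   row order; defaults to all lesions observed across the profiles.
#' @return binary integer matrix, lesions x patients.
#' @export
lesion_matrix <- function(profiles, lesions = NULL) {
  if (is.null(lesions))
    lesions <- sort(unique(unlist(lapply(profiles, `[[`, "lesions"))))
  m <- matrix(0L, nrow = length(lesions), ncol = length(profiles),
              dimnames = list(lesions,
                              vapply(profiles, `[[`, "", "patient_id")))
  for (p in profiles)
    m[intersect(p$lesions, lesions), p$patient_id] <- 1L
  m
}
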
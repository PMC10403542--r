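#' Caller configuration
#'
#' Numeric thresholds of the copy-number caller. Defaults mirror common
#' MLPA practice; every value can be overridden or loaded from JSON.
#'
#' @param normal_band_floor a probe is aberrant when `|dq - 1|` reaches
#'   `max(normal_band_floor, robust_sd_mult * per-probe robust SD)` across
#'   reference samples. The floor is closed: `|dq - 1| = 0.15` counts.
#' @param robust_sd_mult multiplier on the per-probe robust SD (MAD).
#' @param level_tolerance half-width, in dosage-quotient units, for matching
#'   the purity-expected clonal levels.
#' @param min_consecutive minimum run of consecutive aberrant probes for a
#'   call when a locus has two or more probes.
#' @param single_probe_band deviation required of a single-probe locus.
#' @param control_cv_max per-sample QC: maximum coefficient of variation of
#'   control-probe relative counts.
#' @return a list of class `"caller_config"`.
#' @export
caller_config <- function(normal_band_floor = 0.15, robust_sd_mult = 3,
                          level_tolerance = 0.10, min_consecutive = 2L,
                          single_probe_band = 0.30, control_cv_max = 0.25) {
  stopifnot(normal_band_floor > 0, level_tolerance > 0, min_consecutive >= 1)
  structure(list(normal_band_floor = normal_band_floor,
                 robust_sd_mult = robust_sd_mult,
                 level_tolerance = level_tolerance,
                 min_consecutive = as.integer(min_consecutive),
                 single_probe_band = single_probe_band,
                 control_cv_max = control_cv_max),
            class = "caller_config")
}

#' Expected dosage-quotient levels at a given blast purity
#'
#' A specimen with blast purity `p` is a mixture of leukemic and normal
#' cells, so the observed dosage quotient of a clonal lesion is diluted
#' toward 1: monoallelic loss sits at `1 - p/2`, biallelic loss at `1 - p`,
#' one-copy gain at `1 + p/2` and a two-copy (or higher) gain at `1 + p`
#' or above.
#'
#' @param purity blast fraction in (0, 1].
#' @return named numeric vector of expected levels.
#' @export
expected_dq_levels <- function(purity) {
  stopifnot(is.numeric(purity), length(purity) == 1L, purity > 0, purity <= 1)
  c(biallelic_loss = 1 - purity, loss = 1 - purity / 2, normal = 1,
    gain = 1 + purity / 2, multiple_gain = 1 + purity)
}

#' Two-step read-count normalization to dosage quotients
#'
#' Step one divides every probe count by the median reference-probe count of
#' the same sample (intra-sample normalization); step two divides the
#' resulting relative count by the median relative count of the same probe
#' over the reference (copy-number-neutral) samples. The dosage quotient of
#' an unaffected locus is therefore close to 1.0. Medians are used at both
#' steps for outlier robustness.
#'
#' Samples whose total reference-probe count is zero are excluded with a
#' per-sample failure flag; control probes never enter the normalization and
#' are summarized as a per-sample coefficient of variation for QC.
#'
#' @param counts non-negative integer matrix, probes x samples, with probe
#'   ids as row names and sample ids as column names.
#' @param panel a [probe_panel] covering every row of `counts`.
#' @param reference_samples character vector of column names used as the
#'   copy-number-neutral reference set.
#' @param config a [caller_config].
#' @return an object of class `"dosage_matrix"`: list with `dq` (matrix for
#'   the retained samples), `reference_samples`, `excluded_samples`,
#'   `probe_sd` (per-probe robust SD of dq across reference samples) and
#'   `qc` (data.frame `sample_id`, `control_cv`, `pass`).
#' @export
normalize_read_counts <- function(counts, panel, reference_samples,
                                  config = caller_config()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must carry probe ids as row names and sample ids as column names")
  if (any(counts < 0)) stop("read counts must be non-negative")
  unknown <- setdiff(rownames(counts), panel$probe_id)
  if (length(unknown))
    stop("probe(s) absent from panel: ", paste(unknown, collapse = ", "))
  if (!length(reference_samples))
    stop("`reference_samples` must be non-empty")
  missing_ref <- setdiff(reference_samples, colnames(counts))
  if (length(missing_ref))
    stop("reference sample(s) not in counts: ", paste(missing_ref, collapse = ", "))

  ref_probes <- intersect(panel$probe_id[panel$role == "reference"], rownames(counts))
  ctrl_probes <- intersect(panel$probe_id[panel$role == "control"], rownames(counts))
  if (!length(ref_probes)) stop("no reference probes present in counts")

  ref_med <- apply(counts[ref_probes, , drop = FALSE], 2L, stats::median)
  failed <- colnames(counts)[colSums(counts[ref_probes, , drop = FALSE]) == 0]
  if (length(failed))
    message("excluding sample(s) with zero reference-probe counts: ",
            paste(failed, collapse = ", "))
  keep <- setdiff(colnames(counts), failed)
  if (any(reference_samples %in% failed))
    stop("reference sample(s) failed reference-probe QC: ",
         paste(intersect(reference_samples, failed), collapse = ", "))

  rel <- sweep(counts[, keep, drop = FALSE], 2L, ref_med[keep], "/")
  ref_profile <- apply(rel[, reference_samples, drop = FALSE], 1L, stats::median)
  if (any(ref_profile == 0))
    ref_profile[ref_profile == 0] <- NA_real_  # probe dead in all references
  dq <- sweep(rel, 1L, ref_profile, "/")

  probe_sd <- apply(dq[, reference_samples, drop = FALSE], 1L, stats::mad)

  cv <- rep(NA_real_, length(keep))
  if (length(ctrl_probes) >= 2L) {
    ctrl <- rel[ctrl_probes, , drop = FALSE]
    cv <- apply(ctrl, 2L, function(v) stats::sd(v) / mean(v))
  }
  qc <- data.frame(sample_id = keep, control_cv = cv,
                   pass = is.na(cv) | cv <= config$control_cv_max,
                   stringsAsFactors = FALSE)

  structure(list(dq = dq, reference_samples = reference_samples,
                 excluded_samples = failed, probe_sd = probe_sd, qc = qc),
            class = "dosage_matrix")
}

# closed-floor aberrance band per probe
.aberrance_band <- function(probe_sd, config) {
  pmax(config$normal_band_floor, config$robust_sd_mult * probe_sd)
}

#' Call the copy-number state of one locus in one sample
#'
#' Classifies the mean dosage quotient of the supporting probes against the
#' purity-expected clonal levels (see [expected_dq_levels]). Probes are
#' aberrant when their deviation from 1 reaches the normal band
#' (`max(0.15, 3 x robust SD)` by default). A multi-probe locus needs at
#' least `min_consecutive` consecutive aberrant probes in the same
#' direction; a single-probe locus needs a deviation above
#' `single_probe_band`. A lesion whose mean sits unambiguously outside the
#' normal band but significantly short of the expected clonal level —
#' above monoallelic loss for losses, below one-copy gain for gains — is
#' reported as subclonal. Aberrant probes pointing in opposite directions
#' yield a `normal` call with a `"discordant"` flag.
#'
#' @param dq_values numeric vector of dosage quotients, one per probe of the
#'   locus, in genomic order.
#' @param purity blast purity in (0, 1].
#' @param config a [caller_config].
#' @param probe_sd optional per-probe robust SD (same length), defaults to 0
#'   so the band floor applies.
#' @return list of class `"cna_call"` with `state`, `clonality`,
#'   `n_probes_supporting`, `mean_dq`, `flags`.
#' @export
call_gene_cna <- function(dq_values, purity, config = caller_config(),
                          probe_sd = NULL) {
  stopifnot(length(dq_values) >= 1L, all(is.finite(dq_values)))
  if (is.null(probe_sd)) probe_sd <- rep(0, length(dq_values))
  lv <- expected_dq_levels(purity)
  band <- .aberrance_band(probe_sd, config)
  dev <- dq_values - 1
  aberrant <- abs(dev) >= band
  flags <- character(0)

  .call <- function(state, clonality, n, m)
    structure(list(state = state, clonality = clonality,
                   n_probes_supporting = as.integer(n), mean_dq = m,
                   flags = flags), class = "cna_call")

  if (!any(aberrant))
    return(.call("normal", "clonal", 0L, mean(dq_values)))

  dirs <- unique(sign(dev[aberrant]))
  if (length(dirs) > 1L) {
    flags <- c(flags, "discordant")
    return(.call("normal", "clonal", 0L, mean(dq_values)))
  }

  if (length(dq_values) == 1L) {
    if (abs(dev) <= config$single_probe_band)
      return(.call("normal", "clonal", 0L, dq_values))
    run_idx <- 1L
  } else {
    r <- rle(aberrant)
    if (max(r$lengths[r$values]) < config$min_consecutive)
      return(.call("normal", "clonal", 0L, mean(dq_values)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- which(r$values)[which.max(r$lengths[r$values])]
    run_idx <- seq(starts[best], ends[best])
  }
  m <- mean(dq_values[run_idx])
  n_sup <- length(run_idx)
  tol <- config$level_tolerance

  if (m < 1) {
    if (m > lv[["loss"]] + tol)
      return(.call("loss", "subclonal", n_sup, m))
    state <- if (abs(m - lv[["biallelic_loss"]]) < abs(m - lv[["loss"]]))
      "biallelic_loss" else "loss"  # ties resolve to the less extreme state
    return(.call(state, "clonal", n_sup, m))
  }
  if (m < lv[["gain"]] - tol)
    return(.call("gain", "subclonal", n_sup, m))
  state <- if (abs(m - lv[["multiple_gain"]]) < abs(m - lv[["gain"]]))
    "multiple_gain" else "gain"
  .call(state, "clonal", n_sup, m)
}

#' Label IKZF1 deletion patterns at exon resolution
#'
#' The panel covers IKZF1 with two upstream probes (about 4 and 2 kb before
#' the coding sequence) and one unit per exon 1-8. Deleted units (state
#' `loss` or `biallelic_loss`) are merged into maximal contiguous intervals
#' and labelled `"ex4-7"`, `"ex1-7"`, `"upstream+ex1-8"`, `"upstream"`, ...;
#' non-contiguous deletions return one label per interval.
#'
#' @param states character vector of per-unit call states in the genomic
#'   order `up1, up2, ex1, ..., ex8`.
#' @return character vector of interval labels, or `"none"`.
#' @export
ikzf1_deletion_pattern <- function(states) {
  units <- c("up1", "up2", paste0("ex", 1:8))
  if (length(states) != length(units))
    stop("expected ", length(units), " IKZF1 unit states (up1, up2, ex1-ex8)")
  del <- states %in% c("loss", "biallelic_loss")
  if (!any(del)) return("none")
  r <- rle(del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  labels <- character(0)
  for (i in which(r$values)) {
    idx <- seq(starts[i], ends[i])
    has_up <- any(idx <= 2L)
    ex <- idx[idx > 2L] - 2L
    lab <- if (length(ex) == 0L) "upstream"
    else {
      ex_lab <- if (length(ex) == 1L) paste0("ex", ex)
      else paste0("ex", min(ex), "-", max(ex))
      if (has_up) paste0("upstream+", ex_lab) else ex_lab
    }
    labels <- c(labels, lab)
  }
  labels
}

#' Estimate a digital karyotype from arm-level dosage quotients
#'
#' Converts purity-corrected arm dosage quotients into integer chromosome
#' copy numbers: `cn = round(2 * (dq - (1 - p)) / p)` per arm, where `p` is
#' the blast purity. Chromosomes whose two arms disagree are flagged
#' `"structural"`, counted as two copies and excluded from the modal-number
#' increment. The modal number is the sum of copy numbers over the 23
#' chromosome slots (autosomes 1-22 plus one sex-chromosome slot at a
#' diploid baseline), so an unaffected genome yields 46. Ploidy classes:
#' modal 51-67 is high-hyperdiploid, 68 and above near-triploid, 46-50
#' non-hyperdiploid, below 46 `"other"`.
#'
#' @param arm_dq named numeric vector of per-arm dosage quotients, names
#'   like `"1p"`, `"1q"`, ..., `"Xq"`; acrocentric chromosomes (13, 14, 15,
#'   21, 22) may carry only a q arm.
#' @param purity blast purity in (0, 1].
#' @return list of class `"karyotype_estimate"` with `per_chromosome`
#'   (named integer vector), `modal_number`, `ploidy_class`, `structural`
#'   (chromosomes with discordant arms).
#' @export
digital_karyotype <- function(arm_dq, purity) {
  stopifnot(length(arm_dq) >= 1L, !is.null(names(arm_dq)))
  chrom <- sub("[pq]$", "", names(arm_dq))
  cn_arm <- pmax(0, round(2 * (arm_dq - (1 - purity)) / purity))
  per_chr <- integer(0)
  structural <- character(0)
  for (ch in unique(chrom)) {
    v <- unique(cn_arm[chrom == ch])
    if (length(v) == 1L) {
      per_chr[ch] <- as.integer(v)
    } else {
      warning("discordant arm copy numbers on chromosome ", ch,
              "; flagged structural", call. = FALSE)
      structural <- c(structural, ch)
      per_chr[ch] <- 2L
    }
  }
  modal <- sum(per_chr)
  ploidy <- if (modal >= 68) "near_triploid"
  else if (modal >= 51) "high_hyperdiploid"
  else if (modal >= 46) "non_hyperdiploid"
  else "other"
  structure(list(per_chromosome = per_chr, modal_number = modal,
                 ploidy_class = ploidy, structural = structural),
            class = "karyotype_estimate")
}

#' Call gene CNAs and digital karyotypes for a whole cohort
#'
#' Runs [call_gene_cna] on every target gene of every retained sample of a
#' [normalize_read_counts] result, and [digital_karyotype] on the
#' reference-probe (arm) dosage quotients. IKZF1 is additionally called per
#' probe unit so its deletion pattern can be reported.
#'
#' @param dosage a `"dosage_matrix"` from [normalize_read_counts].
#' @param panel the [probe_panel] used for normalization.
#' @param purity named numeric vector of blast purities per sample;
#'   reference samples default to 1.
#' @param config a [caller_config].
#' @return list with `calls` (data.frame `sample_id, locus, state,
#'   clonality, n_probes, mean_dq`), `karyotypes` (named list of
#'   `"karyotype_estimate"`), `ikzf1_patterns` (named character), `qc`.
#' @export
call_cna <- function(dosage, panel, purity, config = caller_config()) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  samples <- setdiff(colnames(dosage$dq), dosage$reference_samples)
  missing_p <- setdiff(samples, names(purity))
  if (length(missing_p))
    stop("missing purity for sample(s): ", paste(missing_p, collapse = ", "))
  tgt <- panel[panel$role == "target", ]
  genes <- unique(tgt$gene)
  ref_probes <- panel$probe_id[panel$role == "reference"]
  ref_probes <- intersect(ref_probes, rownames(dosage$dq))
  arm_of <- stats::setNames(panel$arm, panel$probe_id)

  out <- list(); karyotypes <- list(); ik_patterns <- character(0)
  for (s in samples) {
    p <- purity[[s]]
    for (g in genes) {
      probes <- tgt$probe_id[tgt$gene == g]
      probes <- probes[order(tgt$position[match(probes, tgt$probe_id)])]
      probes <- intersect(probes, rownames(dosage$dq))
      if (!length(probes)) next
      cc <- call_gene_cna(dosage$dq[probes, s], p, config,
                          probe_sd = dosage$probe_sd[probes])
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, locus = g, state = cc$state, clonality = cc$clonality,
        n_probes = cc$n_probes_supporting, mean_dq = cc$mean_dq,
        stringsAsFactors = FALSE)
    }
    # per-unit IKZF1 states for deletion-pattern mapping
    ik <- tgt[tgt$gene == "IKZF1", ]
    if (nrow(ik) == 10L) {
      ik <- ik[order(ik$position), ]
      unit_states <- vapply(ik$probe_id, function(pr)
        call_gene_cna(dosage$dq[pr, s], p, config,
                      probe_sd = dosage$probe_sd[pr])$state, character(1))
      ik_patterns[s] <- paste(ikzf1_deletion_pattern(unname(unit_states)),
                              collapse = ",")
    }
    arm_dq <- dosage$dq[ref_probes, s]
    names(arm_dq) <- arm_of[ref_probes]
    arm_dq <- tapply(arm_dq, names(arm_dq), stats::median)
    karyotypes[[s]] <- digital_karyotype(arm_dq, p)
  }
  calls <- if (length(out)) do.call(rbind, out)
  else data.frame(sample_id = character(0), locus = character(0),
                  state = character(0), clonality = character(0),
                  n_probes = integer(0), mean_dq = numeric(0))
  list(calls = calls, karyotypes = karyotypes,
       ikzf1_patterns = ik_patterns, qc = dosage$qc)
}
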
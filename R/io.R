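#' Read and validate a cohort clinical table
#'
#' CSV with header `patient_id,age,sex,purity,fusions,efs_months,event`;
#' `fusions` holds semicolon-separated markers. Malformed values are
#' rejected, never coerced, with the offending row and field named.
#' A missing purity is imputed as 0.79 (a typical cohort mean blast
#' fraction) with a prominent warning; set `impute_purity = FALSE` to
#' reject instead.
#'
#' @param path CSV file path.
#' @param impute_purity replace missing purity by 0.79 (default TRUE).
#' @return validated data.frame of patient records.
#' @export
read_cohort <- function(path, impute_purity = TRUE) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  required <- c("patient_id", "purity", "fusions", "efs_months", "event")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$patient_id))
    stop("duplicate patient_id(s): ",
         paste(unique(x$patient_id[duplicated(x$patient_id)]), collapse = ", "))
  num_field <- function(v, field) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(out))
    if (length(bad))
      stop("row ", bad[1L], ": field `", field, "` is not numeric (\"",
           v[bad[1L]], "\")")
    out
  }
  x$efs_months <- num_field(x$efs_months, "efs_months")
  bad <- which(is.na(x$efs_months) | x$efs_months < 0)
  if (length(bad))
    stop("row ", bad[1L], ": field `efs_months` must be a non-negative number")
  x$event <- num_field(x$event, "event")
  bad <- which(!x$event %in% c(0, 1))
  if (length(bad))
    stop("row ", bad[1L], ": field `event` must be 0 or 1")
  x$purity <- num_field(x$purity, "purity")
  missing_p <- is.na(x$purity)
  if (any(missing_p)) {
    if (!impute_purity)
      stop("row ", which(missing_p)[1L], ": field `purity` is missing")
    warning("imputing missing blast purity as 0.79 for ",
            sum(missing_p), " patient(s)", call. = FALSE)
    x$purity[missing_p] <- 0.79
  }
  bad <- which(x$purity <= 0 | x$purity > 1)
  if (length(bad))
    stop("row ", bad[1L], ": field `purity` must lie in (0, 1] (\"",
         x$purity[bad[1L]], "\")")
  if ("age" %in% names(x)) x$age <- num_field(x$age, "age")
  x
}

#' Write a cohort clinical table
#' @param records data.frame of patient records.
#' @param path CSV file path.
#' @export
write_cohort <- function(records, path) {
  cols <- intersect(c("patient_id", "age", "sex", "purity", "fusions",
                      "efs_months", "event"), names(records))
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a probe read-count matrix from TSV
#'
#' Tab-separated, probes in rows, first column `probe_id`, one column per
#' sample.
#'
#' @param path TSV file path.
#' @return integer matrix with probe ids as row names.
#' @export
read_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(x)[1L] != "probe_id") stop("first column must be `probe_id`")
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$probe_id
  if (any(is.na(m)) || any(m < 0))
    stop("read counts must be non-negative numbers")
  storage.mode(m) <- "integer"
  m
}

#' Write a read-count matrix to TSV
#' @param counts probes x samples matrix.
#' @param path TSV file path.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(probe_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a score table as JSON
#'
#' The JSON layout is
#' `{"entries": [{"lesion": "IKZF1:loss", "score": -2, ...}],
#'   "exclusion_groups": [["IKZF1plus", "IKZF1:loss"]]}`.
#' Round-trips are lossless; unknown top-level or entry keys, zero or
#' non-integer scores, and exclusion groups referencing unknown lesions
#' are rejected.
#'
#' @param path JSON file path.
#' @return a [score_table].
#' @export
read_score_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  unknown <- setdiff(names(x), c("entries", "exclusion_groups"))
  if (length(unknown))
    stop("unknown score-table key(s): ", paste(unknown, collapse = ", "))
  if (is.null(x$entries)) stop("score table JSON needs `entries`")
  allowed <- c("lesion", "score", "hr", "freq", "ci_low", "ci_high",
               "provenance")
  entries <- do.call(rbind, lapply(x$entries, function(e) {
    bad <- setdiff(names(e), allowed)
    if (length(bad))
      stop("unknown entry key(s): ", paste(bad, collapse = ", "))
    data.frame(lesion = e$lesion, score = e$score,
               hr = e$hr %||% NA_real_, freq = e$freq %||% NA_real_,
               ci_low = e$ci_low %||% NA_real_,
               ci_high = e$ci_high %||% NA_real_,
               provenance = e$provenance %||% "config",
               stringsAsFactors = FALSE)
  }))
  groups <- lapply(x$exclusion_groups, function(g) unlist(g, use.names = FALSE))
  score_table(entries, groups)
}

#' @rdname read_score_table
#' @param table a [score_table] to serialize.
#' @export
write_score_table <- function(table, path) {
  entries <- lapply(seq_len(nrow(table$entries)), function(i) {
    e <- as.list(table$entries[i, ])
    e[!vapply(e, function(v) is.na(v) || is.null(v), logical(1))]
  })
  jsonlite::write_json(list(entries = entries,
                            exclusion_groups = table$exclusion_groups),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write CNA calls to TSV
#'
#' Long format `sample_id  locus  state  clonality  n_probes  mean_dq`.
#'
#' @param calls data.frame of calls (see [call_cna]).
#' @param path TSV file path.
#' @export
write_calls <- function(calls, path) {
  cols <- c("sample_id", "locus", "state", "clonality", "n_probes", "mean_dq")
  utils::write.table(calls[, intersect(cols, names(calls))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read lesion profiles as a long TSV
#'
#' Two columns, `patient_id` and `lesion`; patients without lesions appear
#' with the sentinel lesion `"."` so the patient set round-trips.
#'
#' @param profiles list of `"lesion_profile"` objects.
#' @param path TSV file path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    lesions <- if (length(p$lesions)) p$lesions else "."
    data.frame(patient_id = p$patient_id, lesion = lesions,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @return `read_profiles`: named list of `"lesion_profile"` objects (no
#'   call-level detail; subtype/IKZF1 status are not recomputable from the
#'   long format unless the composite lesions are present).
#' @export
read_profiles <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "lesion") %in% names(x)))
    stop("profile table needs `patient_id` and `lesion` columns")
  profs <- lapply(split(x$lesion, x$patient_id), function(l) sort(setdiff(l, ".")))
  out <- list()
  for (pid in unique(x$patient_id)) {
    out[[pid]] <- structure(list(patient_id = pid, lesions = profs[[pid]],
                                 detail = NULL, subtype = NULL,
                                 ikzf1_status = NULL),
                            class = "lesion_profile")
  }
  out
}

#' Emit a run manifest
#'
#' JSON record of a pipeline invocation: command, package version,
#' timestamp, seed, MD5 hashes of every input file and of the serialized
#' configuration.
#'
#' @param command subcommand name.
#' @param inputs named character vector of input file paths.
#' @param config optional configuration object (hashed via its JSON
#'   serialization).
#' @param seed optional integer seed.
#' @param path output JSON path.
#' @export
run_manifest <- function(command, inputs = character(0), config = NULL,
                         seed = NULL, path) {
  input_hashes <- if (length(inputs))
    as.list(tools::md5sum(unname(inputs))) else list()
  config_hash <- NULL
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE,
                         digits = NA)
    config_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(command = command,
                   tool_version = as.character(utils::packageVersion("personALL")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed, input_hashes = input_hashes,
                   config_hash = config_hash)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

#' Read / write a caller configuration as JSON
#' @param path JSON file path.
#' @return a [caller_config].
#' @export
read_caller_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(caller_config, x[intersect(names(x), names(formals(caller_config)))])
}
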
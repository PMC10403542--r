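#' Construct and validate a probe panel
#'
#' A probe panel describes every probe of a digitalMLPA-style assay: its
#' genomic target (gene and optional exon, or a chromosome arm) and its role.
#' Target probes interrogate loci recurrently altered in B-ALL; reference
#' probes (digital-karyotyping probes on copy-number-stable regions of all
#' chromosome arms) drive normalization and gross aneuploidy detection;
#' control probes are used only for per-sample quality control.
#'
#' @param x data.frame with columns `probe_id`, `chrom`, `position`, `arm`,
#'   `gene`, `exon`, `role`. `role` must be one of `"target"`, `"reference"`,
#'   `"control"`. `exon` may be `NA` (whole-gene or arm probes); coordinates
#'   are 1-based.
#' @return the validated data.frame with class `"probe_panel"`.
#' @export
probe_panel <- function(x) {
  required <- c("probe_id", "chrom", "position", "arm", "gene", "exon", "role")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("probe panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x$probe_id <- as.character(x$probe_id)
  x$role <- as.character(x$role)
  if (anyDuplicated(x$probe_id))
    stop("duplicate probe_id(s): ",
         paste(unique(x$probe_id[duplicated(x$probe_id)]), collapse = ", "))
  bad_role <- setdiff(unique(x$role), c("target", "reference", "control"))
  if (length(bad_role))
    stop("unknown probe role(s): ", paste(bad_role, collapse = ", "))
  ref <- x[x$role == "reference", ]
  if (nrow(ref) < 8L)
    stop("panel must contain at least 8 reference probes (found ", nrow(ref), ")")
  if (length(unique(ref$arm)) < 2L)
    stop("reference probes must span at least 2 chromosome arms")
  tgt <- x[x$role == "target", ]
  if (nrow(tgt) && any(!nzchar(tgt$gene) | is.na(tgt$gene)))
    stop("every target probe must carry a gene (or region) symbol")
  if (!is.numeric(x$position) || any(x$position < 1, na.rm = TRUE))
    stop("positions must be 1-based positive integers")
  class(x) <- c("probe_panel", "data.frame")
  x
}

#' Read a probe panel from TSV
#'
#' Expects the tab-separated header
#' `probe_id  chrom  position  arm  gene  exon  role`.
#'
#' @param path file path.
#' @return a [probe_panel].
#' @export
read_panel <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  probe_panel(x)
}

#' Write a probe panel to TSV
#' @param panel a [probe_panel].
#' @param path file path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic B-ALL probe panel
#'
#' Builds an in-silico panel mirroring the composition of a B-ALL
#' digitalMLPA probemix: 2-4 target probes per recurrently deleted or gained
#' gene, exon-resolution coverage of IKZF1 (two upstream probes at roughly
#' -4 kb and -2 kb, then one probe per exon 1-8), digital-karyotyping
#' reference probes on both arms of every chromosome (one arm for the
#' acrocentrics 13, 14, 15, 21, 22), and internal control probes. All
#' coordinates are synthetic placeholders on a 1-based scale.
#'
#' @param genes character vector of target genes; the default covers the
#'   recurrent B-ALL CNA targets used throughout the package.
#' @param probes_per_gene number of probes per non-IKZF1 target gene.
#' @param n_controls number of internal control probes.
#' @return a [probe_panel].
#' @export
default_panel <- function(genes = c("CDKN2A/B", "ETV6", "PAX5", "PAR1",
                                    "ERG", "VPREB1", "BTG1", "RB1",
                                    "MLLT3", "TBL1XR1", "RUNX1", "EBF1"),
                          probes_per_gene = 3L, n_controls = 6L) {
  gene_chrom <- c("CDKN2A/B" = "9", "ETV6" = "12", "PAX5" = "9", "PAR1" = "X",
                  "ERG" = "21", "VPREB1" = "22", "BTG1" = "12", "RB1" = "13",
                  "MLLT3" = "9", "TBL1XR1" = "3", "RUNX1" = "21", "EBF1" = "5",
                  "IKZF1" = "7")
  rows <- list()
  # IKZF1: two upstream probes + exons 1-8
  ik_units <- c("up1", "up2", paste0("ex", 1:8))
  ik_pos <- c(50344000L, 50346000L, seq(50348000L, by = 15000L, length.out = 8L))
  rows[[1]] <- data.frame(
    probe_id = paste0("IKZF1_", ik_units),
    chrom = "7", position = ik_pos, arm = "7p",
    gene = "IKZF1", exon = c(NA, NA, 1:8), role = "target",
    stringsAsFactors = FALSE)
  genes <- setdiff(genes, "IKZF1")
  for (g in genes) {
    chrom <- if (g %in% names(gene_chrom)) gene_chrom[[g]] else "1"
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = paste0(gsub("[^A-Za-z0-9]", "", g), "_p", seq_len(probes_per_gene)),
      chrom = chrom,
      position = seq(1e6L, by = 5000L, length.out = probes_per_gene),
      arm = paste0(chrom, "q"),
      gene = g, exon = NA_integer_, role = "target",
      stringsAsFactors = FALSE)
  }
  # digital-karyotyping reference probes, both arms (q only for acrocentrics)
  acrocentric <- c("13", "14", "15", "21", "22")
  chroms <- c(as.character(1:22), "X")
  arm_rows <- list()
  for (ch in chroms) {
    arms <- if (ch %in% acrocentric) "q" else c("p", "q")
    for (a in arms) {
      arm_rows[[length(arm_rows) + 1L]] <- data.frame(
        probe_id = paste0("ref_", ch, a),
        chrom = ch, position = if (a == "p") 2e6L else 8e7L,
        arm = paste0(ch, a), gene = NA_character_, exon = NA_integer_,
        role = "reference", stringsAsFactors = FALSE)
    }
  }
  rows[[length(rows) + 1L]] <- do.call(rbind, arm_rows)
  rows[[length(rows) + 1L]] <- data.frame(
    probe_id = paste0("ctrl_", seq_len(n_controls)),
    chrom = "1", position = seq(1e5L, by = 1e4L, length.out = n_controls),
    arm = "1p", gene = NA_character_, exon = NA_integer_, role = "control",
    stringsAsFactors = FALSE)
  probe_panel(do.call(rbind, rows))
}
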
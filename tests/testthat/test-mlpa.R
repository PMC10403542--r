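# Copy-number caller: normalization, purity-aware state calls, IKZF1
# deletion patterns, digital karyotyping.

make_tiny_panel <- function() {
  probe_panel(data.frame(
    probe_id = c(paste0("g1_", 1:3), paste0("g2_", 1:2), "g3_1",
                 paste0("ref_", 1:8), "ctrl_1", "ctrl_2"),
    chrom = c(rep("1", 3), rep("2", 2), "3", rep("4", 4), rep("5", 4),
              "6", "6"),
    position = seq(1000, by = 1000, length.out = 16),
    arm = c(rep("1q", 3), rep("2q", 2), "3q", rep("4p", 2), rep("4q", 2),
            rep("5p", 2), rep("5q", 2), "6p", "6p"),
    gene = c(rep("G1", 3), rep("G2", 2), "G3", rep(NA, 10)),
    exon = NA, role = c(rep("target", 6), rep("reference", 8),
                        rep("control", 2)),
    stringsAsFactors = FALSE))
}

tiny_counts <- function(panel, samples, base = 1000L) {
  m <- matrix(base, nrow = nrow(panel), ncol = length(samples),
              dimnames = list(panel$probe_id, samples))
  m
}

test_that("uniform counts normalize to dosage quotient 1 everywhere", {
  panel <- make_tiny_panel()
  counts <- tiny_counts(panel, c("R1", "R2", "S1"))
  dq <- normalize_read_counts(counts, panel, c("R1", "R2"))
  expect_true(all(abs(dq$dq - 1) < 1e-12))
})

test_that("doubling one probe in one sample doubles exactly that dosage quotient", {
  panel <- make_tiny_panel()
  counts <- tiny_counts(panel, c("R1", "R2", "S1"))
  counts["g1_1", "S1"] <- 2000L
  dq <- normalize_read_counts(counts, panel, c("R1", "R2"))
  expect_equal(dq$dq["g1_1", "S1"], 2)
  expect_true(all(abs(dq$dq[rownames(dq$dq) != "g1_1", ] - 1) < 1e-12))
  expect_true(all(abs(dq$dq["g1_1", c("R1", "R2")] - 1) < 1e-12))
})

test_that("normalization matches the literal two-loop oracle on heterogeneous depths", {
  panel <- make_tiny_panel()
  set.seed(42)
  for (rep in 1:5) {
    counts <- matrix(sample(100:5000, 16 * 3, replace = TRUE), nrow = 16,
                     dimnames = list(panel$probe_id, c("R1", "R2", "S1")))
    got <- normalize_read_counts(counts, panel, c("R1", "R2"))$dq
    ref_probes <- panel$probe_id[panel$role == "reference"]
    want <- oracle_dq(counts, ref_probes, c("R1", "R2"))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("normalization is idempotent on an already-normalized matrix", {
  panel <- make_tiny_panel()
  counts <- tiny_counts(panel, c("R1", "R2", "S1"))
  counts["g2_1", "S1"] <- 1500L
  dq1 <- normalize_read_counts(counts, panel, c("R1", "R2"))$dq
  # feed the dq matrix back (scaled to integer counts)
  dq2 <- normalize_read_counts(round(dq1 * 1000), panel, c("R1", "R2"))$dq
  expect_equal(dq2, dq1, tolerance = 1e-12)
})

test_that("samples with zero reference counts are excluded; unknown probes are an error", {
  panel <- make_tiny_panel()
  counts <- tiny_counts(panel, c("R1", "R2", "S1", "S2"))
  counts[panel$probe_id[panel$role == "reference"], "S2"] <- 0L
  expect_message(dq <- normalize_read_counts(counts, panel, c("R1", "R2")),
                 "S2")
  expect_identical(dq$excluded_samples, "S2")
  expect_false("S2" %in% colnames(dq$dq))

  bad <- rbind(counts, alien = 500L)
  expect_error(normalize_read_counts(bad, panel, c("R1", "R2")), "alien")
})

test_that("control-probe QC flags high-CV samples", {
  panel <- make_tiny_panel()
  counts <- tiny_counts(panel, c("R1", "R2", "S1"))
  counts["ctrl_1", "S1"] <- 100L   # CV far above 0.25
  dq <- normalize_read_counts(counts, panel, c("R1", "R2"))
  expect_false(dq$qc$pass[dq$qc$sample_id == "S1"])
  expect_true(all(dq$qc$pass[dq$qc$sample_id != "S1"]))
})

test_that("state calls follow the purity mixture levels", {
  cfg <- caller_config()
  # normal
  cc <- call_gene_cna(rep(1.00, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "normal")
  expect_identical(cc$clonality, "clonal")
  # clonal monoallelic loss at the expected level 1 - p/2
  cc <- call_gene_cna(rep(0.60, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "loss")
  expect_identical(cc$clonality, "clonal")
  # subclonal loss: outside the normal band, above the monoallelic level
  cc <- call_gene_cna(rep(0.85, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "loss")
  expect_identical(cc$clonality, "subclonal")
  # biallelic loss at 1 - p
  cc <- call_gene_cna(rep(0.22, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "biallelic_loss")
  # gains
  cc <- call_gene_cna(rep(1.40, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "gain")
  expect_identical(cc$clonality, "clonal")
  cc <- call_gene_cna(rep(1.80, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "multiple_gain")
  cc <- call_gene_cna(rep(1.25, 3), purity = 0.80, cfg)
  expect_identical(cc$state, "gain")
  expect_identical(cc$clonality, "subclonal")
})

test_that("purity monotonicity: the same lesion fades toward dq 1 and the caller tracks it", {
  # clonal monoallelic loss observed at its expected level for each purity
  for (p in c(0.9, 0.7, 0.5, 0.35)) {
    dq <- 1 - p / 2
    cc <- call_gene_cna(rep(dq, 3), purity = p)
    expect_identical(cc$state, "loss")
    expect_identical(cc$clonality, "clonal")
  }
  # a fixed dq of 0.85 is clonal loss at low purity, subclonal at high
  expect_identical(call_gene_cna(rep(0.85, 2), purity = 0.30)$clonality,
                   "clonal")
  expect_identical(call_gene_cna(rep(0.85, 2), purity = 0.80)$clonality,
                   "subclonal")
})

test_that("discordant probe directions yield a flagged normal call", {
  cc <- call_gene_cna(c(0.6, 1.5, 0.6), purity = 0.8)
  expect_identical(cc$state, "normal")
  expect_true("discordant" %in% cc$flags)
})

test_that("single aberrant probes are suppressed unless extreme", {
  # two probes, only one aberrant: below the consecutive-probe rule
  cc <- call_gene_cna(c(0.6, 1.0), purity = 0.8)
  expect_identical(cc$state, "normal")
  # single-probe gene needs |dq - 1| > 0.3
  expect_identical(call_gene_cna(0.75, purity = 0.8)$state, "normal")
  expect_identical(call_gene_cna(0.60, purity = 0.8)$state, "loss")
})

test_that("IKZF1 deletion patterns are labelled by contiguous intervals", {
  st <- rep("normal", 10)
  st[c(6, 7, 8, 9)] <- "loss"          # ex4-7
  expect_identical(ikzf1_deletion_pattern(st), "ex4-7")
  st <- c(rep("normal", 2), rep("loss", 7), "normal")  # ex1-7
  expect_identical(ikzf1_deletion_pattern(st), "ex1-7")
  st <- rep("loss", 10)                 # whole gene incl. upstream
  expect_identical(ikzf1_deletion_pattern(st), "upstream+ex1-8")
  expect_identical(ikzf1_deletion_pattern(rep("normal", 10)), "none")
  st <- rep("normal", 10); st[3] <- "loss"
  expect_identical(ikzf1_deletion_pattern(st), "ex1")
  st <- rep("normal", 10); st[c(3, 4, 7, 8)] <- "loss"
  expect_identical(ikzf1_deletion_pattern(st), c("ex1-2", "ex5-6"))
})

arm_dq_for <- function(gained = character(0), level = 1.5,
                       extra = character(0), extra_level = 2.0) {
  acro <- c("13", "14", "15", "21", "22")
  arms <- unlist(lapply(c(as.character(1:22), "X"), function(ch)
    if (ch %in% acro) paste0(ch, "q") else paste0(ch, c("p", "q"))))
  dq <- setNames(rep(1, length(arms)), arms)
  for (ch in gained) dq[grep(paste0("^", ch, "[pq]$"), arms)] <- level
  for (ch in extra) dq[grep(paste0("^", ch, "[pq]$"), arms)] <- extra_level
  dq
}

test_that("digital karyotype counts chromosomes and classifies ploidy", {
  k <- digital_karyotype(arm_dq_for(), purity = 1)
  expect_identical(k$modal_number, 46L)
  expect_identical(k$ploidy_class, "non_hyperdiploid")

  gained <- c("4", "6", "10", "14", "17", "18", "21", "X")
  k <- digital_karyotype(arm_dq_for(gained), purity = 1)
  expect_identical(k$modal_number, 54L)
  expect_identical(k$ploidy_class, "high_hyperdiploid")
  expect_true(all(k$per_chromosome[gained] == 3L))

  # near-triploid: 14 trisomies plus 6 tetrasomies = 72 chromosomes
  all_ch <- c(as.character(1:22), "X")
  k <- digital_karyotype(
    arm_dq_for(setdiff(all_ch, c("1", "2", "3")),
               extra = c("21", "14", "X", "18", "6", "10")), purity = 1)
  expect_identical(k$modal_number, 72L)
  expect_identical(k$ploidy_class, "near_triploid")
})

test_that("purity correction recovers integer copy numbers from diluted dq", {
  p <- 0.6
  dq <- arm_dq_for()
  dq[c("4p", "4q", "6p", "6q")] <- 1 + p / 2   # trisomy at purity 0.6
  k <- digital_karyotype(dq, purity = p)
  expect_identical(unname(k$per_chromosome[c("4", "6")]), c(3L, 3L))
  expect_identical(k$modal_number, 48L)
})

test_that("discordant arms are flagged structural and kept out of the modal count", {
  dq <- arm_dq_for()
  dq["1p"] <- 1.5; dq["1q"] <- 0.5
  expect_warning(k <- digital_karyotype(dq, purity = 1), "structural")
  expect_identical(k$structural, "1")
  expect_identical(k$modal_number, 46L)
})

test_that("panel validation enforces reference-probe requirements", {
  p <- make_tiny_panel()
  expect_s3_class(p, "probe_panel")
  few_refs <- p[p$role != "reference" | p$probe_id %in% paste0("ref_", 1:4), ]
  expect_error(probe_panel(few_refs), "8 reference probes")
  one_arm <- p
  one_arm$arm[one_arm$role == "reference"] <- "4p"
  expect_error(probe_panel(one_arm), "2 chromosome arms")
  dup <- p; dup$probe_id[2] <- dup$probe_id[1]
  expect_error(probe_panel(dup), "duplicate")
})
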
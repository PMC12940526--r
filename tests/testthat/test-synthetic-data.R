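# Synthetic-data generator: determinism, the observation model, annotation
# layout, and planted clinical odds ratios.

small_cfg <- function(...) {
  args <- utils::modifyList(list(n_genes = 4L, protein_length = c(80L, 120L),
                                 n_clinical = 300L), list(...))
  do.call(synthetic_config, args)
}

test_that("generators are deterministic in (config, seed) down to the written bytes", {
  cfg <- small_cfg(seed = 9L)
  d1 <- tempfile(); d2 <- tempfile()
  b1 <- generate_bundle(cfg, d1)
  b2 <- generate_bundle(cfg, d2)
  for (f in c("cds_fasta", "population_vcf", "annotations", "clinical_tsv", "truth")) {
    expect_identical(readLines(b1[[f]]), readLines(b2[[f]]), label = f)
  }
  # a different seed changes the data
  b3 <- generate_bundle(small_cfg(seed = 10L), tempfile())
  expect_false(identical(readLines(b1$cds_fasta), readLines(b3$cds_fasta)))
})

test_that("generated transcripts are valid and an empty config yields an empty set", {
  txs <- generate_transcripts(small_cfg(seed = 2L))
  expect_length(txs, 4L)
  for (tx in txs) {
    expect_s3_class(tx, "transcript")
    # re-translation round trip (would error on any invalid CDS)
    expect_identical(translate_cds(tx$cds), tx$protein)
  }
  expect_length(generate_transcripts(small_cfg(n_genes = 0L)), 0L)
})

test_that("the observation model thins missense only, controlled by delta", {
  # delta = 0 with p_obs = 1: MTR is exactly 0 at fully-interior residues
  cfg <- synthetic_config(n_genes = 1L, protein_length = c(200L, 200L),
                          p_obs = 1, nonpass_fraction = 0,
                          depletion_regions = data.frame(
                            gene_index = 1L, start = 81L, end = 140L, delta = 0),
                          seed = 3L)
  txs <- generate_transcripts(cfg)
  variants <- generate_population_variants(cfg, txs)
  recs <- data.frame(gene_id = variants$gene_id, cds_pos = variants$cds_pos,
                     ref_base = variants$ref, alt_base = variants$alt,
                     consequence = variants$consequence,
                     protein_pos = variants$cds_pos %/% 3L + 1L,
                     aa_ref = "X", aa_alt = "X", clinical_class = "none",
                     passed_filter = TRUE, stringsAsFactors = FALSE)
  prof <- mtr_profile(txs[[1]], recs)
  interior <- 96:125   # windows fully inside the depleted region
  expect_true(all(prof$mtr[interior] == 0))
  flank <- c(1:50, 171:200)
  expect_true(all(prof$mtr[flank] > 0.9))
})

test_that("non-PASS decoys are emitted at the configured fraction and filtered out", {
  cfg <- synthetic_config(n_genes = 3L, protein_length = c(150L, 150L),
                          p_obs = 0.2, nonpass_fraction = 0.2, seed = 4L)
  txs <- generate_transcripts(cfg)
  variants <- generate_population_variants(cfg, txs)
  frac <- mean(variants$filter != "PASS")
  expect_gt(frac, 0.15); expect_lt(frac, 0.25)
  vcf <- tempfile(fileext = ".vcf")
  write_population_vcf(variants, txs, vcf)
  recs <- suppressMessages(read_population_vcf(vcf, txs))
  expect_identical(nrow(recs), sum(variants$filter == "PASS"))
})

test_that("annotation layout realizes the configured state fractions in aggregate", {
  cfg <- synthetic_config(n_genes = 30L, protein_length = c(400L, 600L),
                          state_fractions = c(order = 0.7, disorder = 0.3,
                                              missing_residues = 0,
                                              structural_transition = 0),
                          seed = 5L)
  txs <- generate_transcripts(cfg)
  ann <- generate_annotations(cfg, txs)
  comp <- state_composition(ann$states)
  dis <- comp$fraction[comp$state == "disorder"]
  expect_gt(dis, 0.28); expect_lt(dis, 0.32)
  # regions are in bounds and reconstruct the truth states exactly
  for (g in names(txs)) {
    a <- ann$annotations[ann$annotations$gene_id == g, , drop = FALSE]
    expect_true(all(a$start >= 1L & a$end <= txs[[g]]$n_res))
    expect_identical(assign_states(txs[[g]]$n_res, a), ann$states[[g]])
  }
  # 100% order: no annotations at all
  cfg0 <- synthetic_config(n_genes = 3L, protein_length = c(100L, 100L),
                           state_fractions = c(order = 1, disorder = 0,
                                               missing_residues = 0,
                                               structural_transition = 0),
                           seed = 6L)
  ann0 <- generate_annotations(cfg0, generate_transcripts(cfg0))
  expect_identical(nrow(ann0$annotations), 0L)
})

test_that("the class-probability solver hits planted odds ratios exactly", {
  w <- c(order = 0.7, disorder = 0.2, missing_residues = 0.08,
         structural_transition = 0.02)
  base <- c(pathogenic = 0.25, benign = 0.3, vus = 0.45)
  tg <- data.frame(state = c("order", "disorder"),
                   class = c("pathogenic", "pathogenic"), log2_or = c(2, -2))
  sol <- solve_state_class_probs(tg, w, base)
  expect_equal(sol$realized["order", "pathogenic"], 2, tolerance = 1e-6)
  expect_equal(sol$realized["disorder", "pathogenic"], -2, tolerance = 1e-6)
  expect_equal(unname(rowSums(sol$probs)), rep(1, 4))
  expect_true(all(sol$probs > 0 & sol$probs < 1))
})

test_that("zero planted odds ratios give state-independent class frequencies", {
  cfg <- synthetic_config(n_genes = 6L, protein_length = c(200L, 300L),
                          clinical_targets = data.frame(
                            state = character(0), class = character(0),
                            log2_or = numeric(0)),
                          n_clinical = 3000L, seed = 7L)
  txs <- generate_transcripts(cfg)
  ann <- generate_annotations(cfg, txs)
  clin <- generate_clinical_labels(cfg, txs, ann$states)
  cl <- parse_clinical_class(clin$clinical_significance)
  tab <- table(clin$state, cl)
  tab <- tab[rowSums(tab) > 100, , drop = FALSE]  # skip sparse states
  chi <- suppressWarnings(chisq.test(tab))
  expect_gt(chi$p.value, 0.001)
  # truth table carries realized odds ratios for every cell
  truth <- attr(clin, "truth")
  expect_identical(nrow(truth), 12L)
  expect_true(all(abs(truth$realized_log2_or) < 1e-6))
})

test_that("an empty clinical catalog propagates to an all-NA enrichment", {
  cfg <- small_cfg(n_clinical = 0L, seed = 8L)
  txs <- generate_transcripts(cfg)
  ann <- generate_annotations(cfg, txs)
  clin <- generate_clinical_labels(cfg, txs, ann$states)
  expect_identical(nrow(clin), 0L)
  en <- clinvar_state_enrichment(
    data.frame(state = character(0), clinical_class = character(0)))
  expect_true(all(is.na(en$log2_or)))
})
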
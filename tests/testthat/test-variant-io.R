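# Variant readers, filters, coordinate projection, and observed tallies.

test_that("clinical significance strings map to the three analyzed classes", {
  expect_identical(parse_clinical_class("Pathogenic"), "pathogenic")
  expect_identical(parse_clinical_class("Likely_pathogenic"), "pathogenic")
  expect_identical(parse_clinical_class("Pathogenic/Likely_pathogenic"), "pathogenic")
  expect_identical(parse_clinical_class("Likely_benign"), "benign")
  expect_identical(parse_clinical_class("BENIGN"), "benign")
  expect_identical(parse_clinical_class("Uncertain_significance"), "vus")
  expect_identical(parse_clinical_class("Conflicting_classifications_of_pathogenicity"),
                   "excluded")
  expect_identical(parse_clinical_class(c("risk_factor", NA, "")),
                   rep("excluded", 3))
})

test_that("variant classification by re-translation matches the genetic code", {
  expect_identical(classify_variant(transcript("g", "GGGTAA"), 2L, "A"), "synonymous")
  expect_identical(classify_variant(transcript("g", "TTATAA"), 1L, "A"), "stop")
  expect_identical(classify_variant(transcript("g", "ATGTAA"), 0L, "G"), "missense")
  expect_error(classify_variant(transcript("g", "ATGTAA"), 0L, "A"),
               class = "mtr_invalid_variant")
  expect_error(classify_variant(transcript("g", "ATGTAA"), 5L, "C"),
               class = "mtr_coordinate_error")
})

test_that("classification agrees with brute-force mutate-and-translate at every site", {
  set.seed(41)
  tx <- random_tx(n_res = 25L)
  tab <- possible_snv_table(tx)
  for (i in seq_len(nrow(tab))) {
    expect_identical(classify_variant(tx, tab$cds_pos[i], tab$alt[i]),
                     oracle_classify(tx$cds, tab$cds_pos[i], tab$alt[i]))
  }
  # exhaustiveness: 3 alternatives per coding position
  expect_identical(nrow(tab), 9L * tx$n_res)
})

test_that("population VCF reading applies PASS/SNV filters and decomposes multi-allelics", {
  tx <- transcript("G1", "ATGGGGTTATAA")
  vcf <- tempfile(fileext = ".vcf")
  write_test_vcf(c(
    "G1\t1\t.\tA\tG\t.\tPASS\t.",          # missense M1V
    "G1\t2\t.\tT\tA\t.\tAC0\t.",           # non-PASS: excluded
    "G1\t3\t.\tG\tGT\t.\tPASS\t.",         # insertion: excluded
    "G1\t6\t.\tG\tA,C\t.\tPASS\t.",        # multi-allelic: two records
    "G1\t7\t.\tC\tA\t.\tPASS\t.",          # REF mismatch (CDS has T): dropped
    "G2\t1\t.\tA\tC\t.\tPASS\t."           # unknown gene: dropped
  ), vcf, contigs = "G1")
  expect_warning(
    recs <- suppressMessages(read_population_vcf(vcf, list(G1 = tx))),
    "REF mismatching")
  expect_identical(nrow(recs), 3L)
  expect_setequal(recs$alt_base[recs$cds_pos == 5L], c("A", "C"))
  expect_identical(recs$consequence[recs$cds_pos == 0L], "missense")
  expect_true(all(recs$passed_filter))
  log <- attr(recs, "log")
  expect_identical(log$dropped_non_pass, 1L)
  expect_identical(log$dropped_non_snv, 1L)
})

test_that("genomic-mode projection is a strand-aware round trip", {
  set.seed(43)
  # plus strand over two exons
  tx_p <- transcript("P1", "ATGGGGTTATAA",
                     exon_map = data.frame(chrom = "chr1", start = c(101, 301),
                                           end = c(106, 306), strand = "+"))
  # minus strand: genomic sequence is the reverse complement
  tx_m <- transcript("M1", "ATGGGGTTATAA",
                     exon_map = data.frame(chrom = "chr2", start = c(201, 101),
                                           end = c(206, 106), strand = "-"))
  coords_p <- cds_genomic_coords(tx_p)
  coords_m <- cds_genomic_coords(tx_m)
  # one PASS SNV per coding base, alt chosen cyclically, written in genomic terms
  body <- character(0)
  for (i in 1:9) {
    ref <- substr(tx_p$cds, i, i)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1 + (i %% 3)]
    body <- c(body,
              sprintf("chr1\t%d\t.\t%s\t%s\t.\tPASS\t.", coords_p[i], ref, alt),
              sprintf("chr2\t%d\t.\t%s\t%s\t.\tPASS\t.", coords_m[i],
                      chartr("ACGT", "TGCA", ref), chartr("ACGT", "TGCA", alt)))
  }
  vcf <- tempfile(fileext = ".vcf")
  write_test_vcf(body, vcf, contigs = c("chr1", "chr2"))
  recs <- suppressMessages(
    read_population_vcf(vcf, list(P1 = tx_p, M1 = tx_m), coords = "genomic"))
  expect_identical(nrow(recs), 18L)
  # both strands recover identical CDS-space variants
  p <- recs[recs$gene_id == "P1", ]; m <- recs[recs$gene_id == "M1", ]
  p <- p[order(p$cds_pos), ]; m <- m[order(m$cds_pos), ]
  expect_identical(p$cds_pos, 0:8)
  expect_identical(m$cds_pos, 0:8)
  expect_identical(p$alt_base, m$alt_base)
  expect_identical(p$consequence, m$consequence)
})

test_that("observed tallies conserve record counts and count distinct alleles once", {
  tx <- transcript("G1", "ATGGGGTTATAA")
  recs <- data.frame(
    gene_id = "G1",
    cds_pos = c(0L, 0L, 0L, 5L, 7L),
    ref_base = c("A", "A", "A", "G", "T"),
    alt_base = c("G", "C", "G", "A", "C"),   # duplicate (0, G) collapses
    consequence = c("missense", "missense", "missense", "synonymous", "missense"),
    protein_pos = c(1L, 1L, 1L, 2L, 3L),
    aa_ref = "X", aa_alt = "X", clinical_class = "none",
    passed_filter = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  tal <- tally_observed(recs, tx)
  expect_identical(nrow(tal), 9L)
  expect_identical(tal$n_obs_missense[1], 2L)        # two distinct ALTs
  expect_identical(tal$n_obs_synonymous[6], 1L)
  expect_identical(sum(tal$n_obs_missense) + sum(tal$n_obs_synonymous), 3L)
  # no variants -> all-zero tallies of CDS length
  tal0 <- tally_observed(recs[0, ], tx)
  expect_true(all(tal0$n_obs_missense == 0L) && all(tal0$n_obs_synonymous == 0L))
})

test_that("clinical TSV reading validates the reference amino acid", {
  tx <- transcript("G1", "ATGGGGTTATAA")  # protein MGL
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tprotein_pos\taa_ref\taa_alt\tclinical_significance",
               "G1\t1\tM\tV\tPathogenic",
               "G1\t2\tA\tV\tBenign",       # aa_ref mismatch (protein has G)
               "G1\t3\tL\tP\tUncertain_significance"), tsv)
  expect_warning(cl <- read_clinical_tsv(tsv, list(G1 = tx)), "aa_ref mismatches")
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$clinical_class, c("pathogenic", "vus"))
})

test_that("clinical VCF reading takes significance from INFO and keeps missense only", {
  tx <- transcript("G1", "ATGGGGTTATAA")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               '##INFO=<ID=CLNSIG,Number=.,Type=String,Description="sig">',
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "G1\t1\t.\tA\tG\t.\t.\tCLNSIG=Pathogenic",
               "G1\t6\t.\tG\tA\t.\t.\tCLNSIG=Benign"), vcf)  # synonymous: dropped
  cl <- read_clinical_vcf(vcf, list(G1 = tx))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$clinical_class, "pathogenic")
  expect_identical(cl$aa_alt, "V")
})
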
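# Statistical primitives: Fisher/HA, Wilson, two-proportion z,
# Kruskal-Wallis + Dunn letters, Mann-Whitney, BH-FDR, descriptive moments,
# and clinical-class enrichment by state.

test_that("fisher_ha matches frozen examples and the enumeration oracle", {
  bal <- fisher_ha(5, 5, 5, 5)
  expect_equal(bal$log2_or, 0)
  expect_equal(bal$p, 1)
  expect_equal(fisher_ha(0, 10, 5, 5)$log2_or, log2(0.5 / 10.5), tolerance = 1e-12)
  expect_true(all(is.na(unlist(fisher_ha(0, 0, 0, 0)))))

  set.seed(81)
  for (i in 1:200) {
    cells <- as.integer(sample(0:12, 4, replace = TRUE))
    if (all(cells == 0)) next
    got <- fisher_ha(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got$p, oracle_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("fisher_ha p-values agree with stats::fisher.test", {
  set.seed(82)
  for (i in 1:100) {
    cells <- as.integer(sample(0:15, 4, replace = TRUE))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    got <- fisher_ha(cells[1], cells[2], cells[3], cells[4])
    want <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(got$p, want, tolerance = 1e-9)
  }
})

test_that("Wilson intervals collapse correctly at the boundaries", {
  expect_equal(wilson_ci(0, 10)[["lower"]], 0)
  expect_equal(wilson_ci(10, 10)[["upper"]], 1)
  ci <- wilson_ci(5, 10)
  # independent oracle: numeric inversion of the score inequality
  z <- qnorm(0.975)
  f <- function(p0) (0.5 - p0)^2 - z^2 * p0 * (1 - p0) / 10
  lo <- uniroot(f, c(1e-9, 0.5), tol = 1e-12)$root
  hi <- uniroot(f, c(0.5, 1 - 1e-9), tol = 1e-12)$root
  expect_equal(ci[["lower"]], lo, tolerance = 1e-6)
  expect_equal(ci[["upper"]], hi, tolerance = 1e-6)
  expect_true(all(is.na(wilson_ci(0, 0))))
})

test_that("two-proportion z follows the pooled formula and is antisymmetric", {
  eq <- two_prop_z(5, 10, 50, 100)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  big <- two_prop_z(90, 100, 10, 100)
  expect_equal(big$z, 0.8 / sqrt(0.5 * 0.5 * (1 / 100 + 1 / 100)), tolerance = 1e-12)
  swapped <- two_prop_z(10, 100, 90, 100)
  expect_equal(swapped$z, -big$z)
  expect_equal(swapped$p, big$p)
  expect_warning(deg <- two_prop_z(0, 10, 0, 10), "degenerate")
  expect_equal(deg$z, 0)
})

test_that("BH q-values match brute-force step-up and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mtr_input_error")
  set.seed(83)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    expect_true(all(diff(sort(q)[order(order(sort(p)))]) >= -1e-12))
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
})

test_that("Mann-Whitney handles ties, separation, and sample exchange", {
  tied <- mann_whitney(rep(1, 4), rep(1, 6))
  expect_equal(tied$U, 12)
  expect_equal(tied$p, 1)
  sep <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(sep$U, 0)
  set.seed(84)
  a <- rnorm(15); b <- rnorm(12, 1)
  f <- mann_whitney(a, b); r <- mann_whitney(b, a)
  expect_equal(r$U, 15 * 12 - f$U)
  expect_equal(r$p, f$p)
})

test_that("descriptive moments use bias-corrected conventions and degrade to NA", {
  d <- descriptive(c(-1, 0, 1))
  expect_equal(d$skewness, 0)
  expect_equal(d$stddev, 1)
  const <- descriptive(rep(2, 10))
  expect_equal(const$stddev, 0)
  expect_true(is.na(const$skewness) && is.na(const$kurtosis))
  # raw-moment oracle before bias correction
  set.seed(85)
  x <- rnorm(200)
  n <- length(x)
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  g1 <- m3 / m2^1.5
  b1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  expect_equal(descriptive(x)$skewness, b1, tolerance = 1e-12)
  m4 <- mean((x - mean(x))^4)
  g2 <- m4 / m2^2 - 3
  b2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  expect_equal(descriptive(x)$kurtosis, b2, tolerance = 1e-12)
})

test_that("Kruskal-Wallis/Dunn letters join identical groups and split shifted ones", {
  set.seed(86)
  # all identical values: one shared letter
  same <- kruskal_dunn(rep(1, 40), rep(c("a", "b", "c", "d"), each = 10))
  expect_equal(same$H, 0)
  expect_true(all(same$letters == "a"))

  # two groups 10 SDs apart: distinct letters
  x <- c(rnorm(100), rnorm(100, 10))
  g <- rep(c("g1", "g2"), each = 100)
  kd <- kruskal_dunn(x, g)
  expect_true(kd$p < 1e-10)
  expect_false(kd$letters[["g1"]] == kd$letters[["g2"]])

  # letters are consistent under group relabeling
  g2 <- ifelse(g == "g1", "zzz", "aaa")
  kd2 <- kruskal_dunn(x, g2)
  expect_false(kd2$letters[["zzz"]] == kd2$letters[["aaa"]])
})

test_that("planted two-pair group structure reproduces an {a,b,b,a} letter pattern", {
  set.seed(87)
  x <- c(rnorm(300, 0.86, 0.14), rnorm(300, 0.91, 0.11),
         rnorm(300, 0.91, 0.11), rnorm(300, 0.86, 0.14))
  g <- factor(rep(c("order", "disorder", "missing_residues",
                    "structural_transition"), each = 300),
              levels = c("order", "disorder", "missing_residues",
                         "structural_transition"))
  kd <- kruskal_dunn(x, g)
  expect_identical(kd$letters[["order"]], kd$letters[["structural_transition"]])
  expect_identical(kd$letters[["disorder"]], kd$letters[["missing_residues"]])
  expect_false(kd$letters[["order"]] == kd$letters[["disorder"]])
})

test_that("clinical enrichment recovers planted direction and flags empty states", {
  # all pathogenic in order, all benign in disorder
  v <- data.frame(state = c(rep("order", 50), rep("disorder", 50)),
                  clinical_class = c(rep("pathogenic", 50), rep("benign", 50)),
                  stringsAsFactors = FALSE)
  en <- clinvar_state_enrichment(v)
  expect_true(en$log2_or[en$state == "order" & en$clinical_class == "pathogenic"] > 0)
  expect_true(en$log2_or[en$state == "order" & en$clinical_class == "benign"] < 0)
  expect_true(all(is.na(en$log2_or[en$state == "structural_transition"])))
  def <- !is.na(en$p)
  expect_true(all(en$q[def] >= en$p[def]))

  # uniform class distribution across states: all log2 OR ~ 0
  v2 <- expand.grid(state = c("order", "disorder"),
                    clinical_class = rep(c("pathogenic", "benign", "vus"), 20),
                    stringsAsFactors = FALSE)
  en2 <- clinvar_state_enrichment(v2)
  def2 <- !is.na(en2$log2_or)
  expect_true(all(abs(en2$log2_or[def2]) < 1e-9))
})
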
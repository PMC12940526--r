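# Reusable statistical primitives: two-sided Fisher tests with the
# Haldane-Anscombe odds-ratio correction, Wilson intervals, two-proportion
# z-tests, Kruskal-Wallis + Dunn post hoc with compact letters, Mann-Whitney,
# BH-FDR, descriptive moments, and the clinical-class-by-state enrichment.

#' Two-sided Fisher exact test with Haldane-Anscombe log2 odds ratio
#'
#' The p-value follows the probability-ordering rule: the sum over all
#' tables with the observed margins whose hypergeometric probability does
#' not exceed the observed table's (within a 1e-7 relative tolerance, the
#' convention used by \code{stats::fisher.test}). The odds ratio is the
#' sample OR, with 0.5 added to all four cells when any cell is zero
#' (Haldane-Anscombe), reported on the log2 scale.
#'
#' @param a,b,c,d Cell counts: rows are the two outcome groups, columns the
#'   two classes, i.e. the table is \code{rbind(c(a, b), c(c, d))}.
#' @return list with `log2_or` and `p` (both NA for an all-zero table).
#' @export
fisher_ha <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)))
  if (all(cells == 0)) return(list(log2_or = NA_real_, p = NA_real_))
  if (any(cells == 0)) cells_or <- cells + 0.5 else cells_or <- cells
  log2_or <- log2((cells_or[1] * cells_or[4]) / (cells_or[2] * cells_or[3]))
  # probability-ordering two-sided p from the hypergeometric distribution
  m <- a + b       # margin of row 1
  n2 <- c + d      # margin of row 2
  k <- a + c       # margin of column 1
  support <- max(0L, k - n2):min(k, m)
  dens <- stats::dhyper(support, m, n2, k)
  p <- sum(dens[dens <= dens[support == a] * (1 + 1e-7)])
  list(log2_or = log2_or, p = min(1, p))
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return c(lower, upper); both NA when n = 0.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Two-proportion z-test (pooled)
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return list with `z` and `p` (two-sided). A degenerate pooled proportion
#'   (0 or 1) yields z = 0, p = 1 with a warning.
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool == 0 || p_pool == 1) {
    warning("pooled proportion is degenerate (0 or 1); z set to 0", call. = FALSE)
    return(list(z = 0, p = 1))
  }
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (k1 / n1 - k2 / n2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment (via \code{stats::p.adjust}); q_i >= p_i elementwise
#' and sorted q-values are nondecreasing.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    mtr_error("p-values must lie in [0, 1] with no NA", "mtr_input_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Mann-Whitney U test (two-sided)
#'
#' Wraps \code{stats::wilcox.test}: exact p for small tie-free samples,
#' normal approximation with tie correction otherwise. Fully tied input is
#' handled explicitly (U = n1*n2/2, p = 1).
#'
#' @param a,b Non-empty numeric samples.
#' @return list with `U` (for sample `a`) and `p`.
#' @export
mann_whitney <- function(a, b) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (length(unique(c(a, b))) == 1L) {
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL, correct = TRUE))
  p <- w$p.value
  if (is.na(p) || is.nan(p)) p <- 1
  list(U = unname(w$statistic), p = p)
}

#' Descriptive moments with bias-corrected higher moments
#'
#' Sample mean, sample standard deviation (n - 1), adjusted Fisher-Pearson
#' skewness and bias-corrected excess kurtosis (both the "type 2"
#' definitions); the conventions are recorded in the result so the kurtosis
#' scale is never ambiguous.
#'
#' @param x Numeric vector, n >= 1.
#' @return list: n, mean, stddev, skewness, kurtosis, conventions.
#' @export
descriptive <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  stopifnot(n >= 1L)
  s <- if (n >= 2L) stats::sd(x) else NA_real_
  sk <- if (n >= 3L && isTRUE(s > 0)) e1071::skewness(x, type = 2) else NA_real_
  ku <- if (n >= 4L && isTRUE(s > 0)) e1071::kurtosis(x, type = 2) else NA_real_
  list(n = n, mean = mean(x), stddev = s, skewness = sk, kurtosis = ku,
       conventions = c(skewness = "adjusted Fisher-Pearson (type 2)",
                       kurtosis = "bias-corrected excess (type 2)"))
}

#' Kruskal-Wallis test with FDR-corrected Dunn post hoc and compact letters
#'
#' Tie-corrected Kruskal-Wallis H, Dunn pairwise z statistics from pooled
#' ranks with tie correction, BH adjustment across pairs, and a compact
#' letter display: two groups share a letter iff their adjusted pairwise p
#' is >= alpha. Letters come from the maximal cliques of the
#' non-significance graph, ordered by first group appearance.
#'
#' @param x Numeric values.
#' @param g Group labels (coerced to factor; level order fixes letter order).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return list: H, p, pairwise (data.frame g1, g2, z, p, q), letters
#'   (named character vector per group).
#' @export
kruskal_dunn <- function(x, g, alpha = 0.05) {
  g <- droplevels(as.factor(g))
  stopifnot(length(x) == length(g), nlevels(g) >= 2L, all(table(g) >= 1L))
  lev <- levels(g)
  pairs <- utils::combn(seq_along(lev), 2)
  if (length(unique(x)) == 1L) {
    pw <- data.frame(g1 = lev[pairs[1, ]], g2 = lev[pairs[2, ]],
                     z = 0, p = 1, q = 1, stringsAsFactors = FALSE)
    letters_out <- stats::setNames(rep("a", length(lev)), lev)
    return(list(H = 0, p = 1, pairwise = pw, letters = letters_out))
  }
  kw <- stats::kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  nn <- tabulate(g)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  sig2 <- (N * (N + 1) / 12) - tie_term / (12 * (N - 1))
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) /
    sqrt(sig2 * (1 / nn[pairs[1, ]] + 1 / nn[pairs[2, ]]))
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_fdr(p)
  pw <- data.frame(g1 = lev[pairs[1, ]], g2 = lev[pairs[2, ]],
                   z = as.numeric(z), p = as.numeric(p), q = as.numeric(q),
                   stringsAsFactors = FALSE)
  letters_out <- .compact_letters(lev, pw, alpha)
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pw,
       letters = letters_out)
}

# Compact letter display from the non-significance graph: every maximal
# clique gets a letter, so significant pairs never share one and
# non-significant pairs always do. Cliques are ordered by their earliest
# group (in input level order) for deterministic lettering.
.compact_letters <- function(lev, pairwise, alpha) {
  k <- length(lev)
  adj <- matrix(FALSE, k, k, dimnames = list(lev, lev))
  diag(adj) <- TRUE
  nonsig <- pairwise$q >= alpha
  for (i in which(nonsig)) {
    adj[pairwise$g1[i], pairwise$g2[i]] <- TRUE
    adj[pairwise$g2[i], pairwise$g1[i]] <- TRUE
  }
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  cl <- lapply(igraph::max_cliques(gr), function(v) sort(as.integer(v)))
  cl <- cl[order(vapply(cl, min, 0L), vapply(cl, function(v) paste(v, collapse = ","), ""))]
  out <- stats::setNames(rep("", k), lev)
  for (i in seq_along(cl)) {
    out[cl[[i]]] <- paste0(out[cl[[i]]], letters[i])
  }
  out
}

#' Clinical-class enrichment by structural state
#'
#' For every (state, clinical class) pair, a 2x2 table of class-in-state vs
#' other-classes-in-state vs class-elsewhere vs rest ("each state vs all
#' other states combined"), a Haldane-Anscombe log2 odds ratio with a
#' two-sided Fisher p, and BH q-values across all tests in the run.
#' Positive log2 OR means enrichment of the class in the state.
#'
#' @param variants data.frame with columns `state` and `clinical_class`
#'   (excluded/none classes are dropped).
#' @param states States to test (default the four structural states).
#' @param classes Classes to test (default pathogenic, benign, vus).
#' @return data.frame: state, clinical_class, a, b, c, d, log2_or, p, q,
#'   significance stars. States with zero variants give NA rows.
#' @export
clinvar_state_enrichment <- function(variants, states = STATE_LEVELS,
                                     classes = c("pathogenic", "benign", "vus")) {
  v <- variants[variants$clinical_class %in% classes, , drop = FALSE]
  grid <- expand.grid(state = states, clinical_class = classes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$state[i]; cl <- grid$clinical_class[i]
    in_state <- v$state == s
    is_class <- v$clinical_class == cl
    a <- sum(in_state & is_class); b <- sum(in_state & !is_class)
    c_ <- sum(!in_state & is_class); d <- sum(!in_state & !is_class)
    if (a + b == 0L || nrow(v) == 0L) {
      return(data.frame(state = s, clinical_class = cl, a = a, b = b, c = c_,
                        d = d, log2_or = NA_real_, p = NA_real_))
    }
    f <- fisher_ha(a, b, c_, d)
    data.frame(state = s, clinical_class = cl, a = a, b = b, c = c_, d = d,
               log2_or = f$log2_or, p = f$p)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  def <- !is.na(out$p)
  if (any(def)) out$q[def] <- bh_fdr(out$p[def])
  out$significance <- significance_stars(out$q)
  out
}

significance_stars <- function(q) {
  ifelse(is.na(q), "", ifelse(q < 0.001, "***", ifelse(q < 0.01, "**",
                                                       ifelse(q < 0.05, "*", ""))))
}
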
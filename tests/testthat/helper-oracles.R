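# Shared fixtures and independent oracles used across test files.

# Random valid transcript (sense codons + terminal stop), seeded by caller.
random_tx <- function(gene_id = "TX1", n_res = 40L) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  cds <- paste(c(sample(sense, n_res, replace = TRUE),
                 sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
  transcript(gene_id, cds)
}

# Brute-force SNV classifier: mutates the full CDS string and re-translates
# the affected codon through Biostrings machinery (independent of the
# package's precomputed lookup tables).
oracle_classify <- function(cds, pos0, alt) {
  mut <- cds
  substr(mut, pos0 + 1L, pos0 + 1L) <- alt
  ci <- pos0 %/% 3L
  ref_codon <- substr(cds, 3L * ci + 1L, 3L * ci + 3L)
  mut_codon <- substr(mut, 3L * ci + 1L, 3L * ci + 3L)
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), no.init.codon = TRUE))
  a1 <- tr(ref_codon); a2 <- tr(mut_codon)
  if (a1 == "*" || a2 == "*") "stop" else if (a1 == a2) "synonymous" else "missense"
}

# Brute-force per-position possible-change tallies for a coding sequence
# (terminal stop excluded by the caller passing only coding bases).
oracle_enumerate <- function(cds_coding) {
  L <- nchar(cds_coding)
  bases <- c("A", "C", "G", "T")
  out <- data.frame(cds_pos = 0:(L - 1L), n_possible_missense = 0L,
                    n_possible_synonymous = 0L, n_possible_stop = 0L)
  for (p in 0:(L - 1L)) {
    ref <- substr(cds_coding, p + 1L, p + 1L)
    for (b in setdiff(bases, ref)) {
      cls <- oracle_classify(cds_coding, p, b)
      col <- paste0("n_possible_", cls)
      out[p + 1L, col] <- out[p + 1L, col] + 1L
    }
  }
  out
}

# Brute-force BH step-up q-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (j in (m - 1):1) {
    if (m == 1) break
    q_sorted[j] <- min(q_sorted[j], q_sorted[j + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Hypergeometric pmf via choose(), avoiding dhyper: independent enumeration
# oracle for the two-sided Fisher p-value (probability-ordering rule).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0L, k - n2):min(k, m)
  pmf <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  sum(pmf[pmf <= pmf[support == a] * (1 + 1e-7)])
}

# Position-by-position segment scan: the brute-force counterpart of
# extract_segments, keeping only classified residues.
oracle_segments <- function(records) {
  r <- records[order(records$gene_id, records$protein_pos), , drop = FALSE]
  segs <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) segs[[length(segs) + 1L]] <<- cur
    cur <<- NULL
  }
  for (i in seq_len(nrow(r))) {
    if (!r$constraint_class[i] %in% c("Intolerant", "Tolerant")) {
      flush(); next
    }
    if (!is.null(cur) && cur$gene_id == r$gene_id[i] &&
        cur$state == r$state[i] && cur$class == r$constraint_class[i] &&
        cur$end == r$protein_pos[i] - 1L) {
      cur$end <- r$protein_pos[i]
      cur$len <- cur$len + 1L
    } else {
      flush()
      cur <- list(gene_id = r$gene_id[i], state = r$state[i],
                  class = r$constraint_class[i], start = r$protein_pos[i],
                  end = r$protein_pos[i], len = 1L)
    }
  }
  flush()
  do.call(rbind, lapply(segs, function(s)
    data.frame(gene_id = s$gene_id, state = s$state, constraint_class = s$class,
               start = s$start, end = s$end, length = s$len,
               stringsAsFactors = FALSE)))
}

# Empty variant-record frame with the canonical columns.
empty_recs <- function() {
  data.frame(gene_id = character(0), cds_pos = integer(0),
             ref_base = character(0), alt_base = character(0),
             consequence = character(0), protein_pos = integer(0),
             aa_ref = character(0), aa_alt = character(0),
             clinical_class = character(0), passed_filter = logical(0),
             stringsAsFactors = FALSE)
}

# Minimal hand-written VCF for reader tests.
write_test_vcf <- function(lines_body, path,
                           contigs = character(0)) {
  hdr <- c("##fileformat=VCFv4.2",
           vapply(contigs, function(x) sprintf("##contig=<ID=%s>", x), ""),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines_body), path)
  path
}
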
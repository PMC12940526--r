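# Missense Tolerance Ratio engine: sliding-window counts, the MTR ratio,
# one-sided exact binomial depletion tests, and BH-FDR'd per-residue profiles.

CONSTRAINT_LEVELS <- c("Intolerant", "Tolerant", "Unclassified")

#' Build residue-centred sliding-window counts
#'
#' For residue i the window covers codons [i - (w-1)/2, i + (w-1)/2]
#' intersected with [1, protein length] (truncated at the termini, so every
#' residue is scored). Observed and possible counts are aggregated over the
#' window's CDS positions.
#'
#' @param tx A `transcript`.
#' @param observed Per-position observed tallies from [tally_observed()].
#' @param possible Per-position possible tallies from
#'   [enumerate_possible_snvs()].
#' @param window_size Odd window width in residues (default 31).
#' @return data.frame with one row per residue: `gene_id`, `center_residue`,
#'   `window_start_res`, `window_end_res`, `O_m`, `O_s`, `E_m`, `E_s`.
#' @export
build_windows <- function(tx, observed, possible, window_size = 31L) {
  if (length(window_size) != 1L || window_size < 1L || window_size %% 2L != 1L) {
    mtr_error("window_size must be a positive odd integer", "mtr_config_error")
  }
  n <- tx$n_res
  half <- (window_size - 1L) %/% 2L
  res_of <- observed$cds_pos %/% 3L + 1L
  obs_m <- rowsum(observed$n_obs_missense, res_of)[, 1]
  obs_s <- rowsum(observed$n_obs_synonymous, res_of)[, 1]
  exp_m <- rowsum(possible$n_possible_missense, possible$cds_pos %/% 3L + 1L)[, 1]
  exp_s <- rowsum(possible$n_possible_synonymous, possible$cds_pos %/% 3L + 1L)[, 1]
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  wsum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[hi + 1L] - cs[lo]
  }
  data.frame(
    gene_id = tx$gene_id, center_residue = i,
    window_start_res = lo, window_end_res = hi,
    O_m = wsum(obs_m), O_s = wsum(obs_s),
    E_m = wsum(exp_m), E_s = wsum(exp_s)
  )
}

#' Missense Tolerance Ratio of window counts
#'
#' MTR = [O_m/(O_m+O_s)] / [E_m/(E_m+E_s)]. Windows with no observed
#' variants get NA rather than a pseudo-counted score: a tolerance estimate
#' from zero data would be manufactured, not measured.
#'
#' @param O_m,O_s Observed missense/synonymous counts (vectors).
#' @param E_m,E_s Enumerated possible missense/synonymous counts.
#' @return Numeric vector of MTR values (NA where O_m + O_s = 0).
#' @export
mtr_score <- function(O_m, O_s, E_m, E_s) {
  n <- O_m + O_s
  out <- rep(NA_real_, length(n))
  def <- n > 0
  out[def] <- (O_m[def] / n[def]) / (E_m[def] / (E_m[def] + E_s[def]))
  out
}

#' One-sided exact binomial depletion test for a window
#'
#' Probability of observing at most `O_m` missense among `n = O_m + O_s`
#' variants when each is missense with the enumerated expected proportion
#' E_m/(E_m+E_s). One-sided in the depletion direction, because the test is
#' used solely to flag significantly intolerant regions.
#'
#' @inheritParams mtr_score
#' @return p-values (NA where n = 0).
#' @export
intolerance_test <- function(O_m, O_s, E_m, E_s) {
  n <- O_m + O_s
  p_exp <- E_m / (E_m + E_s)
  out <- rep(NA_real_, length(n))
  def <- n > 0
  out[def] <- stats::pbinom(O_m[def], n[def], p_exp[def])
  out
}

#' Classify residues at an MTR threshold
#' @param mtr MTR values (NA allowed).
#' @param threshold Intolerant/Tolerant split (default 0.4): Intolerant when
#'   MTR < threshold, Tolerant when MTR >= threshold, Unclassified when NA.
#' @return Character vector over Intolerant/Tolerant/Unclassified.
#' @export
classify_constraint <- function(mtr, threshold = 0.4) {
  ifelse(is.na(mtr), "Unclassified", ifelse(mtr < threshold, "Intolerant", "Tolerant"))
}

#' Per-residue MTR profile for one gene (no FDR)
#'
#' @param tx A `transcript`.
#' @param records Population variant records (any genes; filtered internally).
#' @param window_size Odd window width in residues.
#' @return data.frame: gene_id, protein_pos, aa, window counts, mtr,
#'   p_binomial.
#' @export
mtr_profile <- function(tx, records, window_size = 31L) {
  obs <- tally_observed(records, tx)
  pos <- enumerate_possible_snvs(tx)
  w <- build_windows(tx, obs, pos, window_size)
  data.frame(
    gene_id = tx$gene_id, protein_pos = w$center_residue,
    aa = strsplit(tx$protein, "")[[1]],
    O_m = w$O_m, O_s = w$O_s, E_m = w$E_m, E_s = w$E_s,
    mtr = mtr_score(w$O_m, w$O_s, w$E_m, w$E_s),
    p_binomial = intolerance_test(w$O_m, w$O_s, w$E_m, w$E_s),
    stringsAsFactors = FALSE
  )
}

#' MTR profiles with FDR and constraint classes for a gene set
#'
#' Computes per-gene profiles, then Benjamini-Hochberg q-values. The default
#' FDR family is all tested residues across the whole gene set in one run;
#' `fdr_family = "per_gene"` adjusts within each gene instead.
#'
#' @param transcripts Named list of `transcript` objects.
#' @param records Population variant records.
#' @param window_size Odd window width in residues (default 31).
#' @param mtr_threshold Intolerant/Tolerant split (default 0.4).
#' @param fdr_family "global" (default) or "per_gene".
#' @return data.frame with one row per residue across all genes, adding
#'   `q_fdr` and `constraint_class` to the [mtr_profile()] columns.
#' @export
mtr_profile_set <- function(transcripts, records, window_size = 31L,
                            mtr_threshold = 0.4,
                            fdr_family = c("global", "per_gene")) {
  fdr_family <- match.arg(fdr_family)
  prof <- do.call(rbind, c(lapply(transcripts, mtr_profile, records = records,
                                  window_size = window_size),
                           list(make.row.names = FALSE)))
  prof$q_fdr <- NA_real_
  def <- !is.na(prof$p_binomial)
  if (any(def)) {
    if (fdr_family == "global") {
      prof$q_fdr[def] <- bh_fdr(prof$p_binomial[def])
    } else {
      prof$q_fdr[def] <- stats::ave(prof$p_binomial[def], prof$gene_id[def],
                                    FUN = bh_fdr)
    }
  }
  prof$constraint_class <- classify_constraint(prof$mtr, mtr_threshold)
  prof
}
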
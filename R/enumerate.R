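# Exhaustive enumeration of possible single-nucleotide substitutions in a
# CDS and the expected missense proportion they imply.

#' Enumerate possible SNVs per CDS position
#'
#' For every coding nucleotide, counts how many of the 3 alternative bases
#' yield a missense, synonymous, or stop-class change (stop-gain/stop-loss;
#' the stop class is excluded from both MTR classes). The terminal stop
#' codon, which encodes no residue, is excluded from enumeration.
#'
#' @param tx A `transcript`.
#' @return data.frame with one row per coding position: `cds_pos` (0-based),
#'   `n_possible_missense`, `n_possible_synonymous`, `n_possible_stop`.
#' @export
enumerate_possible_snvs <- function(tx) {
  stopifnot(inherits(tx, "transcript"))
  n_res <- tx$n_res
  L <- coding_length(tx)
  codons <- substring(tx$cds, seq(1L, L, 3L), seq(3L, L, 3L))
  ci <- match(codons, rownames(codon_change_counts()$missense))
  idx <- cbind(rep(ci, each = 3L), rep.int(1:3, n_res))
  cc <- codon_change_counts()
  data.frame(
    cds_pos = 0:(L - 1L),
    n_possible_missense = cc$missense[idx],
    n_possible_synonymous = cc$synonymous[idx],
    n_possible_stop = cc$stop[idx]
  )
}

#' Allele-level table of every possible SNV in the coding region
#'
#' One row per (position, alternative base) pair with its consequence and
#' amino-acid change. The site-level [enumerate_possible_snvs()] tallies are
#' the per-position class counts of this table.
#'
#' @param tx A `transcript`.
#' @return data.frame: `cds_pos` (0-based), `ref`, `alt`, `consequence`,
#'   `protein_pos`, `aa_ref`, `aa_alt`.
#' @export
possible_snv_table <- function(tx) {
  n_res <- tx$n_res
  L <- coding_length(tx)
  codons <- substring(tx$cds, seq(1L, L, 3L), seq(3L, L, 3L))
  arr <- snv_class_array()
  aa_arr <- snv_mut_aa_array()
  ci <- rep(match(codons, rownames(arr)), each = 12L)
  wpos <- rep(rep(1:3, each = 4L), n_res)
  ai <- rep.int(seq_along(BASES), 3L * n_res)
  idx <- cbind(ci, wpos, ai)
  cls <- arr[idx]
  keep <- cls != "identical"
  pos0 <- rep(0:(L - 1L), each = 4L)[keep]
  data.frame(
    cds_pos = pos0,
    ref = substring(tx$cds, pos0 + 1L, pos0 + 1L),
    alt = rep.int(BASES, 3L * n_res)[keep],
    consequence = cls[keep],
    protein_pos = pos0 %/% 3L + 1L,
    aa_ref = substring(tx$protein, pos0 %/% 3L + 1L, pos0 %/% 3L + 1L),
    aa_alt = aa_arr[idx][keep]
  )
}

#' Expected missense proportion over a CDS window
#'
#' Sum of possible missense changes over the window divided by the sum of
#' possible missense plus synonymous changes; stop-class changes are excluded
#' from numerator and denominator.
#'
#' @param tallies data.frame from [enumerate_possible_snvs()].
#' @param from,to 0-based inclusive CDS positions delimiting the window.
#' @return Fraction in (0, 1].
#' @export
expected_proportion <- function(tallies, from, to) {
  if (to < from) mtr_error("empty window", "mtr_window_error")
  sel <- tallies$cds_pos >= from & tallies$cds_pos <= to
  if (!any(sel)) mtr_error("window outside CDS", "mtr_window_error")
  m <- sum(tallies$n_possible_missense[sel])
  s <- sum(tallies$n_possible_synonymous[sel])
  if (m + s == 0) {
    # every codon admits at least one non-stop change; reaching here means
    # the tallies are corrupt
    mtr_error("zero possible missense+synonymous changes in window", "mtr_internal_error")
  }
  m / (m + s)
}
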
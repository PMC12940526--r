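# Residue-level analytics: joining structural states with MTR constraint
# classes, amino-acid composition enrichment, biophysical descriptors, and
# segment-level patterning.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AROMATIC <- c("F", "Y", "W")

# Side-chain charge at neutral pH. Histidine defaults to 0; a fractional
# protonation (+0.1) is available through the histidine_charge argument of
# the functions that consume this map.
aa_charge_map <- function(histidine_charge = 0) {
  ch <- stats::setNames(rep(0, 20), AA20)
  ch[c("K", "R")] <- 1
  ch[c("D", "E")] <- -1
  ch["H"] <- histidine_charge
  ch
}

#' Join transcripts, MTR profiles and structural states into a residue table
#'
#' One row per residue across all genes: the unit of all downstream
#' composition, segment and enrichment statistics.
#'
#' @param transcripts Named list of `transcript` objects.
#' @param profile Profile data.frame from [mtr_profile_set()].
#' @param states_list Named list of per-residue state vectors (missing genes
#'   default to ordered-only).
#' @return data.frame: gene_id, protein_pos, aa, state, mtr, p_binomial,
#'   q_fdr, constraint_class.
#' @export
residue_table <- function(transcripts, profile, states_list = list()) {
  parts <- lapply(transcripts, function(tx) {
    st <- states_list[[tx$gene_id]]
    if (is.null(st)) st <- rep("order", tx$n_res)
    if (length(st) != tx$n_res) {
      mtr_error(sprintf("state vector for %s has length %d, protein has %d residues",
                        tx$gene_id, length(st), tx$n_res), "mtr_annotation_error")
    }
    p <- profile[profile$gene_id == tx$gene_id, , drop = FALSE]
    p <- p[order(p$protein_pos), , drop = FALSE]
    if (nrow(p) != tx$n_res) {
      mtr_error(sprintf("profile for %s has %d rows, protein has %d residues",
                        tx$gene_id, nrow(p), tx$n_res), "mtr_join_error")
    }
    data.frame(gene_id = tx$gene_id, protein_pos = p$protein_pos, aa = p$aa,
               state = st, mtr = p$mtr, p_binomial = p$p_binomial,
               q_fdr = p$q_fdr, constraint_class = p$constraint_class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Amino-acid composition enrichment, Intolerant vs Tolerant, per state
#'
#' For each structural state and amino acid a, a 2x2 table of (a vs not-a) x
#' (Intolerant vs Tolerant) residues, tested with a two-sided Fisher exact
#' test; odds ratios use the Haldane-Anscombe correction and are reported as
#' log2 OR (positive = enriched among Intolerant). BH q-values are computed
#' within each state across the 20 amino acids. A state with no Intolerant
#' (or no Tolerant) residues yields NA rows: with an empty column the
#' contrast does not exist.
#'
#' @param records Residue table from [residue_table()] (Unclassified
#'   residues are excluded).
#' @return data.frame: state, aa, n_intolerant, n_tolerant, log2_or, p, q.
#' @export
composition_enrichment <- function(records) {
  r <- records[records$constraint_class %in% c("Intolerant", "Tolerant"), , drop = FALSE]
  parts <- lapply(STATE_LEVELS, function(s) {
    rs <- r[r$state == s, , drop = FALSE]
    n_int <- sum(rs$constraint_class == "Intolerant")
    n_tol <- sum(rs$constraint_class == "Tolerant")
    out <- data.frame(state = s, aa = AA20,
                      n_intolerant = NA_integer_, n_tolerant = NA_integer_,
                      log2_or = NA_real_, p = NA_real_, q = NA_real_,
                      stringsAsFactors = FALSE)
    if (n_int == 0L || n_tol == 0L) return(out)
    for (i in seq_along(AA20)) {
      a_int <- sum(rs$aa == AA20[i] & rs$constraint_class == "Intolerant")
      a_tol <- sum(rs$aa == AA20[i] & rs$constraint_class == "Tolerant")
      f <- fisher_ha(a_int, n_int - a_int, a_tol, n_tol - a_tol)
      out$n_intolerant[i] <- a_int; out$n_tolerant[i] <- a_tol
      out$log2_or[i] <- f$log2_or; out$p[i] <- f$p
    }
    out$q <- bh_fdr(out$p)
    out
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Biophysical summary of a residue set
#'
#' Mean side-chain charge (K/R +1, D/E -1, H configurable, others 0), mean
#' Kyte-Doolittle hydropathy, and aromatic (F/Y/W) fraction.
#'
#' @param aa Character vector of one-letter amino acids.
#' @param histidine_charge Charge assigned to histidine (default 0).
#' @return Named numeric vector (mean_charge, mean_hydropathy,
#'   aromatic_fraction); all NA for an empty set.
#' @export
biophysical_summary <- function(aa, histidine_charge = 0) {
  if (length(aa) == 0L) {
    return(c(mean_charge = NA_real_, mean_hydropathy = NA_real_,
             aromatic_fraction = NA_real_))
  }
  stopifnot(all(aa %in% AA20))
  ch <- aa_charge_map(histidine_charge)
  c(mean_charge = mean(ch[aa]),
    mean_hydropathy = mean(KD_HYDROPATHY[aa]),
    aromatic_fraction = mean(aa %in% AROMATIC))
}

#' Mean spacing between consecutive aromatic residues
#'
#' Mean positional difference between consecutive F/Y/W residues in
#' segment-local coordinates; NA with fewer than two aromatics.
#'
#' @param aa One-letter amino acids of a segment (vector or single string).
#' @return Numeric spacing or NA.
#' @export
aromatic_spacing <- function(aa) {
  if (length(aa) == 1L && nchar(aa[1]) > 1L) aa <- strsplit(aa, "")[[1]]
  pos <- which(aa %in% AROMATIC)
  if (length(pos) < 2L) return(NA_real_)
  mean(diff(pos))
}

#' Extract maximal same-state, same-class segments
#'
#' Maximal runs of consecutive residues sharing (gene, state, constraint
#' class). Unclassified residues carry no constraint information and break
#' runs without forming segments. Each segment is annotated with its
#' biophysical summary and aromatic spacing.
#'
#' @param records Residue table from [residue_table()], sorted by gene and
#'   position.
#' @param histidine_charge Passed to [biophysical_summary()].
#' @return data.frame: gene_id, state, constraint_class, start, end, length,
#'   mean_charge, mean_hydropathy, aromatic_fraction, aromatic_spacing, seq.
#' @export
extract_segments <- function(records, histidine_charge = 0) {
  r <- records[order(records$gene_id, records$protein_pos), , drop = FALSE]
  keep <- r$constraint_class %in% c("Intolerant", "Tolerant")
  r <- r[keep, , drop = FALSE]
  if (nrow(r) == 0L) {
    return(data.frame(gene_id = character(0), state = character(0),
                      constraint_class = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      mean_charge = numeric(0), mean_hydropathy = numeric(0),
                      aromatic_fraction = numeric(0),
                      aromatic_spacing = numeric(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  n <- nrow(r)
  new_run <- c(TRUE, r$gene_id[-1] != r$gene_id[-n] |
                 r$state[-1] != r$state[-n] |
                 r$constraint_class[-1] != r$constraint_class[-n] |
                 r$protein_pos[-1] != r$protein_pos[-n] + 1L)
  run_id <- cumsum(new_run)
  parts <- lapply(split(seq_len(n), run_id), function(ii) {
    bio <- biophysical_summary(r$aa[ii], histidine_charge)
    data.frame(gene_id = r$gene_id[ii[1]], state = r$state[ii[1]],
               constraint_class = r$constraint_class[ii[1]],
               start = r$protein_pos[ii[1]], end = r$protein_pos[ii[length(ii)]],
               length = length(ii),
               mean_charge = bio[["mean_charge"]],
               mean_hydropathy = bio[["mean_hydropathy"]],
               aromatic_fraction = bio[["aromatic_fraction"]],
               aromatic_spacing = aromatic_spacing(r$aa[ii]),
               seq = paste(r$aa[ii], collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

# Properties contrasted between Intolerant and Tolerant segments.
SEGMENT_PROPERTIES <- c("mean_charge", "mean_hydropathy", "aromatic_fraction",
                        "length", "aromatic_spacing")

#' Intolerant - Tolerant contrasts per structural state
#'
#' For every state and segment-level property, Delta = mean(Intolerant) -
#' mean(Tolerant) with a two-sided Mann-Whitney p. NA (with a warning) when
#' either class has no segments in the state.
#'
#' @param segments Segment table from [extract_segments()].
#' @return data.frame: state, property, n_intolerant, n_tolerant, delta, p.
#' @export
delta_contrast <- function(segments) {
  grid <- expand.grid(state = STATE_LEVELS, property = SEGMENT_PROPERTIES,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$state[i]; pr <- grid$property[i]
    xi <- segments[segments$state == s & segments$constraint_class == "Intolerant", pr]
    xt <- segments[segments$state == s & segments$constraint_class == "Tolerant", pr]
    xi <- xi[!is.na(xi)]; xt <- xt[!is.na(xt)]
    if (length(xi) == 0L || length(xt) == 0L) {
      return(data.frame(state = s, property = pr, n_intolerant = length(xi),
                        n_tolerant = length(xt), delta = NA_real_, p = NA_real_))
    }
    mw <- mann_whitney(xi, xt)
    data.frame(state = s, property = pr, n_intolerant = length(xi),
               n_tolerant = length(xt), delta = mean(xi) - mean(xt), p = mw$p)
  })
  out <- do.call(rbind, rows)
  if (any(is.na(out$delta))) {
    warning("some state/property contrasts have an empty constraint class (NA rows)",
            call. = FALSE)
  }
  out
}
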
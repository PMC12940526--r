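# Genetic-code primitives: CDS translation and exhaustive single-nucleotide
# substitution classification (missense / synonymous / stop).

BASES <- c("A", "C", "G", "T")

.mtr_cache <- new.env(parent = emptyenv())

mtr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mtr_error")))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translates an in-frame CDS. A terminal stop codon is allowed and dropped
#' from the returned protein; an internal stop is an error, because a
#' transcript carrying one cannot be scored residue by residue.
#'
#' @param cds Single string over A/C/G/T whose length is divisible by 3.
#' @return Amino-acid string (one-letter code), without the terminal stop.
#' @examples
#' translate_cds("ATGGGG")   # "MG"
#' translate_cds("ATGTAA")   # "M": terminal stop dropped
#' @export
translate_cds <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L || is.na(cds)) {
    mtr_error("cds must be a single character string", "mtr_invalid_sequence")
  }
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    mtr_error("cds contains characters outside {A,C,G,T}", "mtr_invalid_sequence")
  }
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L) {
    mtr_error("cds length must be a positive multiple of 3", "mtr_frame_error")
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  k <- length(aa)
  if (k > 1L && any(aa[-k] == "*")) {
    mtr_error("internal stop codon in cds", "mtr_internal_stop")
  }
  if (aa[k] == "*") aa <- aa[-k]
  if (length(aa) == 0L) {
    mtr_error("cds encodes no residue (stop codon only)", "mtr_frame_error")
  }
  paste(aa, collapse = "")
}

# 64 x 3 x 4 array of consequence classes: [codon, position-in-codon, alt base].
# "identical" marks alt == ref (not a variant). Any change creating or removing
# a stop codon is the "stop" class; it is excluded from both MTR classes.
snv_class_array <- function() {
  if (!is.null(.mtr_cache$class_arr)) return(.mtr_cache$class_arr)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  arr <- array(NA_character_, dim = c(64L, 3L, 4L),
               dimnames = list(codons, NULL, BASES))
  aa_arr <- array(NA_character_, dim = c(64L, 3L, 4L),
                  dimnames = list(codons, NULL, BASES))
  for (cd in codons) {
    ref_aa <- gc[[cd]]
    for (p in 1:3) {
      ref_b <- substr(cd, p, p)
      for (b in BASES) {
        if (b == ref_b) {
          arr[cd, p, b] <- "identical"
          aa_arr[cd, p, b] <- ref_aa
          next
        }
        mut <- cd
        substr(mut, p, p) <- b
        mut_aa <- gc[[mut]]
        aa_arr[cd, p, b] <- mut_aa
        arr[cd, p, b] <- if (ref_aa == "*" || mut_aa == "*") {
          "stop"
        } else if (ref_aa == mut_aa) {
          "synonymous"
        } else {
          "missense"
        }
      }
    }
  }
  .mtr_cache$class_arr <- arr
  .mtr_cache$mut_aa_arr <- aa_arr
  arr
}

# Mutant amino acid lookup with the same indexing as snv_class_array().
snv_mut_aa_array <- function() {
  snv_class_array()
  .mtr_cache$mut_aa_arr
}

# Per-codon, per-position possible-change counts (64 x 3 matrices).
codon_change_counts <- function() {
  if (!is.null(.mtr_cache$counts)) return(.mtr_cache$counts)
  arr <- snv_class_array()
  counts <- list(
    missense   = apply(arr == "missense", c(1, 2), sum),
    synonymous = apply(arr == "synonymous", c(1, 2), sum),
    stop       = apply(arr == "stop", c(1, 2), sum)
  )
  .mtr_cache$counts <- counts
  counts
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

complement_bases <- function(x) chartr("ACGT", "TGCA", x)

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains.
rbind_frames <- function(parts) {
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) return(NULL)
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}
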
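# Transcript container: a gene's canonical CDS, its protein translation, and
# an optional exon map tying CDS bases to genomic coordinates.

#' Construct a transcript
#'
#' Validates the CDS (in frame, no internal stop), translates it, and stores
#' an optional exon map. CDS positions are 0-based internally; protein
#' positions are 1-based everywhere in outputs.
#'
#' @param gene_id Gene/transcript identifier.
#' @param cds Coding sequence (A/C/G/T), optionally ending in a stop codon.
#' @param exon_map Optional data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive genomic coordinates), `strand` ("+" or "-"); rows must
#'   be in CDS order (first row contains the first coding base) and cover
#'   exactly `nchar(cds)` bases without overlap.
#' @return An object of class `transcript`.
#' @export
transcript <- function(gene_id, cds, exon_map = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  cds <- toupper(cds)
  protein <- translate_cds(cds)
  n_res <- nchar(protein)
  has_stop <- nchar(cds) == 3L * n_res + 3L
  if (!is.null(exon_map)) {
    exon_map <- validate_exon_map(exon_map, nchar(cds), gene_id)
  }
  structure(
    list(gene_id = gene_id, cds = cds, protein = protein, n_res = n_res,
         has_stop = has_stop, exon_map = exon_map),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s: %d nt CDS, %d residues%s%s>\n",
              x$gene_id, nchar(x$cds), x$n_res,
              if (x$has_stop) ", terminal stop" else "",
              if (!is.null(x$exon_map)) sprintf(", %d exon(s)", nrow(x$exon_map)) else ""))
  invisible(x)
}

validate_exon_map <- function(em, cds_len, gene_id) {
  req <- c("chrom", "start", "end", "strand")
  if (!is.data.frame(em) || !all(req %in% names(em))) {
    mtr_error(sprintf("exon map for %s needs columns %s", gene_id,
                      paste(req, collapse = ", ")), "mtr_exon_map_error")
  }
  em$start <- as.integer(em$start); em$end <- as.integer(em$end)
  if (any(em$end < em$start)) {
    mtr_error(sprintf("exon map for %s has end < start", gene_id), "mtr_exon_map_error")
  }
  if (!all(em$strand %in% c("+", "-")) || length(unique(em$strand)) != 1L) {
    mtr_error(sprintf("exon map for %s must have one consistent strand", gene_id),
              "mtr_exon_map_error")
  }
  if (sum(em$end - em$start + 1L) != cds_len) {
    mtr_error(sprintf("exon map for %s covers %d bases, CDS has %d", gene_id,
                      sum(em$end - em$start + 1L), cds_len), "mtr_exon_map_error")
  }
  iv <- unlist(Map(seq.int, em$start, em$end))
  if (anyDuplicated(paste(rep(em$chrom, em$end - em$start + 1L), iv))) {
    mtr_error(sprintf("exon map for %s has overlapping exons", gene_id),
              "mtr_exon_map_error")
  }
  em
}

#' Genomic coordinate of every CDS base, in CDS order
#'
#' On the minus strand each exon is walked from its end to its start
#' (transcription order), so element i is the genomic position of CDS base i.
#'
#' @param tx A `transcript` with an exon map.
#' @return Integer vector of genomic positions, length `nchar(tx$cds)`.
#' @export
cds_genomic_coords <- function(tx) {
  em <- tx$exon_map
  if (is.null(em)) mtr_error(sprintf("%s has no exon map", tx$gene_id), "mtr_exon_map_error")
  if (em$strand[1] == "+") {
    unlist(Map(seq.int, em$start, em$end))
  } else {
    unlist(Map(function(s, e) seq.int(e, s), em$start, em$end))
  }
}

# Coding-only CDS length (terminal stop codon excluded from all scoring).
coding_length <- function(tx) 3L * tx$n_res

#' Read CDS sequences from a FASTA file
#'
#' One transcript per record; the record id is the gene id. Sequences that
#' fail validation (non-ACGT characters, out-of-frame length, internal stop)
#' are rejected with a warning naming the gene, not silently dropped.
#'
#' @param path FASTA file of coding sequences.
#' @param exon_maps Optional named list of exon-map data.frames keyed by gene id.
#' @return Named list of `transcript` objects.
#' @export
read_cds_fasta <- function(path, exon_maps = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- list()
  for (i in seq_along(seqs)) {
    tx <- tryCatch(
      transcript(ids[i], as.character(seqs[[i]]), exon_map = exon_maps[[ids[i]]]),
      mtr_error = function(e) {
        warning(sprintf("rejecting %s: %s", ids[i], conditionMessage(e)), call. = FALSE)
        NULL
      }
    )
    if (!is.null(tx)) out[[ids[i]]] <- tx
  }
  out
}

#' Write transcripts to a CDS FASTA file
#' @param transcripts Named list of `transcript` objects.
#' @param path Output path.
#' @export
write_cds_fasta <- function(transcripts, path) {
  x <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "cds"))
  names(x) <- vapply(transcripts, `[[`, "", "gene_id")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read exon maps from GFF3 or BED
#'
#' GFF3 uses 1-based inclusive coordinates and BED 0-based half-open; both are
#' normalized to the internal 1-based inclusive convention. For GFF3 only rows
#' of type `CDS` are used and the gene id is taken from the `Parent` (or `ID`)
#' attribute; for BED the `name` column is the gene id.
#'
#' @param path GFF3 or BED file.
#' @param format "auto" (by extension), "gff3" or "bed".
#' @return Named list of exon-map data.frames in CDS order.
#' @export
read_exon_map <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df)) df <- df[df$type == "CDS", , drop = FALSE]
    id <- if ("Parent" %in% names(df)) as.character(unlist(df$Parent)) else df$ID
  } else {
    id <- df$name
  }
  em <- data.frame(gene_id = id, chrom = as.character(df$seqnames),
                   start = df$start, end = df$end,
                   strand = as.character(df$strand), stringsAsFactors = FALSE)
  split_em <- split(em[c("chrom", "start", "end", "strand")], em$gene_id)
  lapply(split_em, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (d$strand[1] == "-") d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
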
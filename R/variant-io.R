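# Reading population (gnomAD-style) and clinical (ClinVar-style) variant
# files, projecting them onto transcript coordinates, and tallying observed
# missense/synonymous counts per CDS position.

CLINICAL_LEVELS <- c("pathogenic", "benign", "vus", "none", "excluded")

#' Classify a single-nucleotide substitution by re-translation
#'
#' Mutates the codon containing `cds_pos`, re-translates it, and compares to
#' the reference: identical amino acid is synonymous, a created or removed
#' stop is the stop class, anything else is missense.
#'
#' @param tx A `transcript`.
#' @param cds_pos 0-based CDS position (within the coding region).
#' @param alt_base Alternative base, different from the reference base.
#' @return One of "missense", "synonymous", "stop".
#' @export
classify_variant <- function(tx, cds_pos, alt_base) {
  L <- coding_length(tx)
  if (any(cds_pos < 0L | cds_pos >= L)) {
    mtr_error("cds_pos outside coding region", "mtr_coordinate_error")
  }
  ref <- substring(tx$cds, cds_pos + 1L, cds_pos + 1L)
  if (any(ref == alt_base)) {
    mtr_error("alt base equals reference base", "mtr_invalid_variant")
  }
  codon_i <- cds_pos %/% 3L
  codon <- substring(tx$cds, 3L * codon_i + 1L, 3L * codon_i + 3L)
  arr <- snv_class_array()
  arr[cbind(match(codon, rownames(arr)), cds_pos %% 3L + 1L, match(alt_base, BASES))]
}

#' Map raw clinical-significance strings to analysis classes
#'
#' Case-insensitive: Pathogenic / Likely_pathogenic (and their combined form)
#' map to "pathogenic", the benign counterparts to "benign",
#' Uncertain_significance to "vus". Everything else (conflicting, risk
#' factor, absent, ...) is "excluded" and not counted in enrichment.
#'
#' @param raw Character vector of raw significance strings.
#' @return Character vector over pathogenic/benign/vus/excluded.
#' @export
parse_clinical_class <- function(raw) {
  x <- tolower(trimws(as.character(raw)))
  x <- gsub("[ /]", "_", x)
  out <- rep("excluded", length(x))
  out[x %in% c("pathogenic", "likely_pathogenic", "pathogenic_likely_pathogenic")] <- "pathogenic"
  out[x %in% c("benign", "likely_benign", "benign_likely_benign")] <- "benign"
  out[x %in% c("uncertain_significance", "vus")] <- "vus"
  out[is.na(raw) | !nzchar(trimws(as.character(raw)))] <- "excluded"
  out
}

# Vectorized consequence + mutant-aa lookup for one transcript.
.classify_bulk <- function(tx, cds_pos, alt) {
  codon_i <- cds_pos %/% 3L
  codons <- substring(tx$cds, 3L * codon_i + 1L, 3L * codon_i + 3L)
  arr <- snv_class_array()
  idx <- cbind(match(codons, rownames(arr)), cds_pos %% 3L + 1L, match(alt, BASES))
  list(consequence = arr[idx], aa_alt = snv_mut_aa_array()[idx],
       aa_ref = substring(tx$protein, codon_i + 1L, codon_i + 1L),
       protein_pos = codon_i + 1L)
}

#' Read a population VCF and project variants onto transcripts
#'
#' Keeps only FILTER = PASS single-nucleotide substitutions falling inside a
#' known coding region; multi-allelic records are decomposed into one record
#' per ALT allele. In `coords = "cds"` mode CHROM is the gene id and POS the
#' 1-based CDS position; in `coords = "genomic"` mode variants are projected
#' through each transcript's exon map, with REF/ALT complemented on the minus
#' strand. Records whose REF disagrees with the transcript base are dropped
#' with a warning. A count of records in/out of each filter is attached as
#' attribute `"log"` and reported via `message()`.
#'
#' @param path VCF file (plain text or gzipped).
#' @param transcripts Named list of `transcript` objects.
#' @param coords Coordinate mode, "cds" or "genomic".
#' @return data.frame of variant records (gene_id, cds_pos, ref_base,
#'   alt_base, consequence, protein_pos, aa_ref, aa_alt, clinical_class,
#'   passed_filter).
#' @export
read_population_vcf <- function(path, transcripts, coords = c("cds", "genomic")) {
  coords <- match.arg(coords)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) mtr_error(
                  sprintf("cannot read VCF %s: %s", path, conditionMessage(e)),
                  "mtr_format_error"))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  log <- list(records_in = nrow(fix))
  # decompose multi-allelic ALTs
  alts <- strsplit(fix$ALT %||% character(0), ",", fixed = TRUE)
  ii <- rep(seq_len(nrow(fix)), lengths(alts))
  d <- data.frame(chrom = fix$CHROM[ii], pos = as.integer(fix$POS[ii]),
                  ref = fix$REF[ii], alt = unlist(alts),
                  filter = fix$FILTER[ii], stringsAsFactors = FALSE)
  log$alleles_in <- nrow(d)
  pass <- !is.na(d$filter) & d$filter == "PASS"
  log$dropped_non_pass <- sum(!pass)
  d <- d[pass, , drop = FALSE]
  snv <- d$ref %in% BASES & d$alt %in% BASES
  log$dropped_non_snv <- sum(!snv)
  d <- d[snv, , drop = FALSE]

  if (coords == "cds") {
    d$gene_id <- d$chrom
    d$cds_pos <- d$pos - 1L
  } else {
    proj <- .genomic_index(transcripts)
    key <- paste(d$chrom, d$pos)
    hit <- match(key, proj$key)
    d$gene_id <- proj$gene[hit]
    d$cds_pos <- proj$cds_pos[hit]
    flip <- !is.na(hit) & proj$minus[hit]
    d$ref[flip] <- complement_bases(d$ref[flip])
    d$alt[flip] <- complement_bases(d$alt[flip])
  }
  known <- !is.na(d$gene_id) & d$gene_id %in% names(transcripts)
  in_cds <- known
  in_cds[known] <- d$cds_pos[known] >= 0L &
    d$cds_pos[known] < vapply(transcripts[d$gene_id[known]], coding_length, 0L)
  log$dropped_outside_cds <- sum(!in_cds)
  d <- d[in_cds, , drop = FALSE]

  out <- lapply(split(d, d$gene_id), function(dd) {
    tx <- transcripts[[dd$gene_id[1]]]
    ref_tx <- substring(tx$cds, dd$cds_pos + 1L, dd$cds_pos + 1L)
    ok <- dd$ref == ref_tx
    if (any(!ok)) {
      warning(sprintf("%s: dropping %d variant(s) with REF mismatching the CDS",
                      tx$gene_id, sum(!ok)), call. = FALSE)
      dd <- dd[ok, , drop = FALSE]
    }
    same <- dd$ref == dd$alt
    dd <- dd[!same, , drop = FALSE]
    if (nrow(dd) == 0L) return(NULL)
    cl <- .classify_bulk(tx, dd$cds_pos, dd$alt)
    data.frame(gene_id = dd$gene_id, cds_pos = dd$cds_pos,
               ref_base = dd$ref, alt_base = dd$alt,
               consequence = cl$consequence, protein_pos = cl$protein_pos,
               aa_ref = cl$aa_ref, aa_alt = cl$aa_alt,
               clinical_class = "none", passed_filter = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- rbind_frames(out)
  if (is.null(res)) {
    res <- empty_variant_records()
  }
  log$records_out <- nrow(res)
  message(sprintf(
    "read_population_vcf: %d record(s) in, %d allele(s); dropped %d non-PASS, %d non-SNV, %d outside CDS; %d retained",
    log$records_in, log$alleles_in, log$dropped_non_pass, log$dropped_non_snv,
    log$dropped_outside_cds, log$records_out))
  attr(res, "log") <- log
  res
}

empty_variant_records <- function() {
  data.frame(gene_id = character(0), cds_pos = integer(0),
             ref_base = character(0), alt_base = character(0),
             consequence = character(0), protein_pos = integer(0),
             aa_ref = character(0), aa_alt = character(0),
             clinical_class = character(0), passed_filter = logical(0),
             stringsAsFactors = FALSE)
}

# chrom/pos -> (gene, cds_pos) lookup over all transcripts with exon maps.
.genomic_index <- function(transcripts) {
  parts <- lapply(transcripts, function(tx) {
    if (is.null(tx$exon_map)) return(NULL)
    g <- cds_genomic_coords(tx)
    data.frame(key = paste(tx$exon_map$chrom[1], g),
               gene = tx$gene_id, cds_pos = seq_along(g) - 1L,
               minus = tx$exon_map$strand[1] == "-", stringsAsFactors = FALSE)
  })
  rbind_frames(parts)
}

#' Read clinically labeled variants from a TSV
#'
#' Expected columns: `gene_id`, `protein_pos`, `aa_ref`, `aa_alt`,
#' `clinical_significance` (raw strings, mapped with
#' [parse_clinical_class()]). Rows whose `aa_ref` disagrees with the
#' transcript protein are dropped with a warning (guards against
#' transcript-version drift).
#'
#' @param path TSV file.
#' @param transcripts Named list of `transcript` objects.
#' @return data.frame of variant records (protein-level; `cds_pos` is NA).
#' @export
read_clinical_tsv <- function(path, transcripts) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "protein_pos", "aa_ref", "aa_alt", "clinical_significance")
  if (!all(req %in% names(d))) {
    mtr_error(sprintf("clinical TSV must have columns %s", paste(req, collapse = ", ")),
              "mtr_format_error")
  }
  known <- d$gene_id %in% names(transcripts)
  if (any(!known)) {
    warning(sprintf("dropping %d clinical variant(s) in unknown genes", sum(!known)),
            call. = FALSE)
    d <- d[known, , drop = FALSE]
  }
  prot <- vapply(transcripts[d$gene_id], `[[`, "", "protein")
  nres <- nchar(prot)
  ok <- d$protein_pos >= 1L & d$protein_pos <= nres
  ok[ok] <- substring(prot[ok], d$protein_pos[ok], d$protein_pos[ok]) == d$aa_ref[ok]
  if (any(!ok)) {
    warning(sprintf("dropping %d clinical variant(s) whose aa_ref mismatches the protein",
                    sum(!ok)), call. = FALSE)
    d <- d[ok, , drop = FALSE]
  }
  data.frame(gene_id = d$gene_id, cds_pos = NA_integer_,
             ref_base = NA_character_, alt_base = NA_character_,
             consequence = "missense", protein_pos = as.integer(d$protein_pos),
             aa_ref = d$aa_ref, aa_alt = d$aa_alt,
             clinical_class = parse_clinical_class(d$clinical_significance),
             passed_filter = TRUE, stringsAsFactors = FALSE)
}

#' Read clinically labeled variants from a VCF
#'
#' CDS-relative coordinates (CHROM = gene id, POS = 1-based CDS position);
#' the clinical significance is taken from the INFO key `info_key`
#' (default "CLNSIG"). Variants whose annotated consequence is not missense
#' after re-translation are dropped.
#'
#' @inheritParams read_population_vcf
#' @param info_key INFO field holding the raw clinical significance.
#' @return data.frame of variant records.
#' @export
read_clinical_vcf <- function(path, transcripts, info_key = "CLNSIG") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) mtr_error(
                  sprintf("cannot read VCF %s: %s", path, conditionMessage(e)),
                  "mtr_format_error"))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sig <- vcfR::extract.info(v, element = info_key)
  keep <- fix$CHROM %in% names(transcripts) & fix$REF %in% BASES & fix$ALT %in% BASES
  fix <- fix[keep, , drop = FALSE]; sig <- sig[keep]
  if (nrow(fix) == 0L) return(empty_variant_records())
  parts <- lapply(split(seq_len(nrow(fix)), fix$CHROM), function(ii) {
    tx <- transcripts[[fix$CHROM[ii[1]]]]
    pos0 <- as.integer(fix$POS[ii]) - 1L
    ok <- pos0 >= 0L & pos0 < coding_length(tx) &
      substring(tx$cds, pos0 + 1L, pos0 + 1L) == fix$REF[ii]
    ii <- ii[ok]; pos0 <- pos0[ok]
    if (length(ii) == 0L) return(NULL)
    cl <- .classify_bulk(tx, pos0, fix$ALT[ii])
    data.frame(gene_id = tx$gene_id, cds_pos = pos0,
               ref_base = fix$REF[ii], alt_base = fix$ALT[ii],
               consequence = cl$consequence, protein_pos = cl$protein_pos,
               aa_ref = cl$aa_ref, aa_alt = cl$aa_alt,
               clinical_class = parse_clinical_class(sig[ii]),
               passed_filter = TRUE, stringsAsFactors = FALSE)
  })
  res <- rbind_frames(parts)
  if (is.null(res)) return(empty_variant_records())
  res[res$consequence == "missense", , drop = FALSE]
}

#' Tally observed missense/synonymous variants per CDS position
#'
#' Counts retained PASS SNVs by CDS position for one gene. Distinct ALT
#' alleles at one site each count once; duplicate (position, alt) pairs are
#' collapsed. Stop-class and other consequences are excluded.
#'
#' @param records Variant records for one gene (from [read_population_vcf()]).
#' @param tx The gene's `transcript`.
#' @return data.frame of length `coding_length(tx)`: `cds_pos`,
#'   `n_obs_missense`, `n_obs_synonymous`.
#' @export
tally_observed <- function(records, tx) {
  L <- coding_length(tx)
  out <- data.frame(cds_pos = 0:(L - 1L),
                    n_obs_missense = 0L, n_obs_synonymous = 0L)
  if (nrow(records) > 0L) {
    r <- records[records$passed_filter &
                   records$consequence %in% c("missense", "synonymous") &
                   records$gene_id == tx$gene_id, , drop = FALSE]
    r <- r[!duplicated(paste(r$cds_pos, r$alt_base)), , drop = FALSE]
    m <- r[r$consequence == "missense", ]
    s <- r[r$consequence == "synonymous", ]
    out$n_obs_missense <- tabulate(m$cds_pos + 1L, nbins = L)
    out$n_obs_synonymous <- tabulate(s$cds_pos + 1L, nbins = L)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
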
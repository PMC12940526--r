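# End-to-end orchestration: read inputs, compute MTR profiles, assign
# states, run the composition/segment/clinical statistics, and write the
# stable tabular outputs.

#' Pipeline run configuration
#'
#' @param cds_fasta CDS FASTA path (required).
#' @param population_vcf Population VCF path (optional; without it every
#'   residue is Unclassified).
#' @param clinical_tsv,clinical_vcf At most one clinical-variant source.
#' @param annotations Structural annotation TSV (optional; genes default to
#'   ordered-only).
#' @param exon_map Optional GFF3/BED exon map (switches the population VCF
#'   to genomic coordinates).
#' @param out_dir Output directory.
#' @param window_size Sliding-window width in residues (odd, default 31).
#' @param mtr_threshold Intolerant/Tolerant split (default 0.4).
#' @param fdr_alpha FDR level reported in summaries (default 0.05).
#' @param fdr_family "global" or "per_gene" binomial-test FDR family.
#' @param clinvar_info_key INFO key for clinical significance in a clinical
#'   VCF (default "CLNSIG").
#' @param histidine_charge Histidine side-chain charge (default 0).
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(cds_fasta, population_vcf = NULL,
                            clinical_tsv = NULL, clinical_vcf = NULL,
                            annotations = NULL, exon_map = NULL,
                            out_dir = "mtr_out", window_size = 31L,
                            mtr_threshold = 0.4, fdr_alpha = 0.05,
                            fdr_family = c("global", "per_gene"),
                            clinvar_info_key = "CLNSIG",
                            histidine_charge = 0) {
  fdr_family <- match.arg(fdr_family)
  if (window_size < 1L || window_size %% 2L != 1L) {
    mtr_error("window_size must be a positive odd integer", "mtr_config_error")
  }
  if (mtr_threshold <= 0) mtr_error("mtr_threshold must be > 0", "mtr_config_error")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) mtr_error("fdr_alpha must be in (0, 1)", "mtr_config_error")
  if (!is.null(clinical_tsv) && !is.null(clinical_vcf)) {
    mtr_error("give at most one of clinical_tsv / clinical_vcf", "mtr_config_error")
  }
  structure(list(cds_fasta = cds_fasta, population_vcf = population_vcf,
                 clinical_tsv = clinical_tsv, clinical_vcf = clinical_vcf,
                 annotations = annotations, exon_map = exon_map,
                 out_dir = out_dir, window_size = as.integer(window_size),
                 mtr_threshold = mtr_threshold, fdr_alpha = fdr_alpha,
                 fdr_family = fdr_family, clinvar_info_key = clinvar_info_key,
                 histidine_charge = histidine_charge),
            class = "run_config")
}

#' Read a pipeline configuration from JSON or YAML
#' @param path Config file (.json, .yaml or .yml).
#' @return `run_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Table-style per-state MTR summary with Dunn letters
#'
#' Per state: residue count, mean, standard deviation, adjusted skewness,
#' excess kurtosis of the MTR distribution, and the compact Dunn letter at
#' the given FDR level. Residues with undefined MTR are excluded.
#'
#' @param residues Residue table from [residue_table()].
#' @param alpha FDR level for the letter display (default 0.05).
#' @return data.frame: state, n, mean, stddev, skewness, kurtosis,
#'   dunn_group.
#' @export
summarize_states <- function(residues, alpha = 0.05) {
  r <- residues[!is.na(residues$mtr), , drop = FALSE]
  present <- STATE_LEVELS[STATE_LEVELS %in% unique(r$state)]
  out <- data.frame(state = STATE_LEVELS, n = 0L, mean = NA_real_,
                    stddev = NA_real_, skewness = NA_real_,
                    kurtosis = NA_real_, dunn_group = NA_character_,
                    stringsAsFactors = FALSE)
  for (s in present) {
    x <- r$mtr[r$state == s]
    d <- descriptive(x)
    i <- match(s, out$state)
    out$n[i] <- d$n; out$mean[i] <- d$mean; out$stddev[i] <- d$stddev
    out$skewness[i] <- d$skewness; out$kurtosis[i] <- d$kurtosis
  }
  if (length(present) >= 2L) {
    kd <- kruskal_dunn(r$mtr, factor(r$state, levels = present), alpha = alpha)
    out$dunn_group[match(present, out$state)] <- kd$letters[present]
  } else if (length(present) == 1L) {
    out$dunn_group[match(present, out$state)] <- "a"
  }
  out
}

#' Run the full pipeline
#'
#' Reads the configured inputs, computes per-residue MTR profiles with
#' FDR-adjusted depletion tests, assigns structural states, and writes the
#' result surfaces as TSVs with fixed column order and "NA" missing markers
#' (bit-stable across reruns): residue profile, per-state summary,
#' composition log2 OR matrix, Delta contrasts, segments, clinical
#' enrichment, and a run manifest with the config hash.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return Invisible list of all result tables and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  exon_maps <- if (!is.null(config$exon_map)) read_exon_map(config$exon_map)
  transcripts <- read_cds_fasta(config$cds_fasta, exon_maps = exon_maps)
  if (length(transcripts) == 0L) mtr_error("no valid transcripts", "mtr_input_error")

  if (!is.null(config$population_vcf)) {
    records <- read_population_vcf(config$population_vcf, transcripts,
                                   coords = if (is.null(exon_maps)) "cds" else "genomic")
  } else {
    records <- empty_variant_records()
  }
  if (nrow(records) == 0L) {
    warning("no population variants retained: all MTR values will be NA",
            call. = FALSE)
  }
  profile <- mtr_profile_set(transcripts, records,
                             window_size = config$window_size,
                             mtr_threshold = config$mtr_threshold,
                             fdr_family = config$fdr_family)

  states_list <- list()
  annotations <- NULL
  if (!is.null(config$annotations)) {
    annotations <- read_annotations_tsv(config$annotations)
    missing_genes <- setdiff(unique(annotations$gene_id), names(transcripts))
    if (length(missing_genes) > 0L) {
      mtr_error(sprintf("annotations reference unknown gene(s): %s",
                        paste(missing_genes, collapse = ", ")), "mtr_join_error")
    }
    for (g in names(transcripts)) {
      states_list[[g]] <- assign_states(transcripts[[g]]$n_res,
                                        annotations[annotations$gene_id == g, , drop = FALSE])
    }
  } else {
    for (g in names(transcripts)) {
      states_list[[g]] <- rep("order", transcripts[[g]]$n_res)
    }
  }

  residues <- residue_table(transcripts, profile, states_list)
  state_summary <- summarize_states(residues, alpha = config$fdr_alpha)
  composition <- composition_enrichment(residues)
  segments <- extract_segments(residues, histidine_charge = config$histidine_charge)
  contrasts <- suppressWarnings(delta_contrast(segments))

  clinical <- NULL; enrichment <- NULL
  if (!is.null(config$clinical_tsv) || !is.null(config$clinical_vcf)) {
    clinical <- if (!is.null(config$clinical_tsv)) {
      read_clinical_tsv(config$clinical_tsv, transcripts)
    } else {
      read_clinical_vcf(config$clinical_vcf, transcripts,
                        info_key = config$clinvar_info_key)
    }
    clinical$state <- mapply(function(g, p) states_list[[g]][p],
                             clinical$gene_id, clinical$protein_pos)
    enrichment <- clinvar_state_enrichment(clinical)
  }

  paths <- list(
    residue_profile = .write_tsv(residues, file.path(config$out_dir, "residue_profile.tsv")),
    state_summary = .write_tsv(state_summary, file.path(config$out_dir, "state_summary.tsv")),
    composition = .write_tsv(composition, file.path(config$out_dir, "composition_log2or.tsv")),
    contrasts = .write_tsv(contrasts, file.path(config$out_dir, "delta_contrast.tsv")),
    segments = .write_tsv(segments[names(segments) != "seq"],
                          file.path(config$out_dir, "segments.tsv"))
  )
  if (!is.null(enrichment)) {
    paths$enrichment <- .write_tsv(enrichment, file.path(config$out_dir, "clinvar_enrichment.tsv"))
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null",
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(tool = "mtrscape",
                   version = as.character(utils::packageVersion("mtrscape")),
                   config = unclass(config),
                   config_md5 = unname(tools::md5sum(tmp)),
                   n_genes = length(transcripts), n_residues = nrow(residues),
                   n_population_records = nrow(records),
                   n_clinical_records = if (is.null(clinical)) 0L else nrow(clinical))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  paths$manifest <- file.path(config$out_dir, "manifest.json")

  invisible(list(transcripts = transcripts, records = records,
                 profile = profile, residues = residues,
                 state_summary = state_summary, composition = composition,
                 segments = segments, contrasts = contrasts,
                 clinical = clinical, enrichment = enrichment, paths = paths))
}
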
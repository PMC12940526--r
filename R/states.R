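# Four-state structural annotation: consolidating curated and predicted
# disorder regions, structural transitions, and PDB-missing residues into
# one mutually exclusive state per residue.

#' The four structural states, in canonical order
#' @export
STATE_LEVELS <- c("order", "disorder", "structural_transition", "missing_residues")
ANNOTATION_LABELS <- c("disorder", "structural_transition", "missing_residues", "order")
ANNOTATION_SOURCES <- c("curated", "predicted", "derived_pdb")

# Overlap resolution, highest precedence first. Curated evidence outranks
# prediction; the transition label is the most specific curated call.
DEFAULT_PRECEDENCE <- c("structural_transition", "curated_disorder",
                        "predicted_disorder", "missing_residues", "order")

validate_annotations <- function(ann) {
  req <- c("gene_id", "start", "end", "label", "source")
  if (!is.data.frame(ann) || !all(req %in% names(ann))) {
    mtr_error(sprintf("annotations need columns %s", paste(req, collapse = ", ")),
              "mtr_annotation_error")
  }
  if (!all(ann$label %in% ANNOTATION_LABELS)) {
    mtr_error("unknown annotation label", "mtr_annotation_error")
  }
  if (!all(ann$source %in% ANNOTATION_SOURCES)) {
    mtr_error("unknown annotation source", "mtr_annotation_error")
  }
  bad <- (ann$label == "structural_transition" & ann$source != "curated") |
    (ann$label == "missing_residues" & ann$source != "derived_pdb")
  if (any(bad)) {
    mtr_error("invalid label/source combination (transition must be curated; missing residues must be derived_pdb)",
              "mtr_annotation_error")
  }
  ann
}

#' Assign one structural state per residue
#'
#' Paints regions onto an all-`order` baseline in increasing precedence
#' order, so at overlaps the higher-precedence label wins regardless of the
#' order annotations arrive in. A gene with no annotations is ordered-only.
#'
#' @param protein_length Protein length in residues.
#' @param annotations data.frame for one gene with columns `gene_id`,
#'   `start`, `end` (1-based inclusive), `label`, `source`.
#' @param precedence Character vector, highest precedence first, over
#'   `structural_transition`, `curated_disorder`, `predicted_disorder`,
#'   `missing_residues`, `order`.
#' @return Character vector of length `protein_length` over the four states.
#' @export
assign_states <- function(protein_length, annotations = NULL,
                          precedence = DEFAULT_PRECEDENCE) {
  stopifnot(protein_length >= 1L)
  if (!setequal(precedence, DEFAULT_PRECEDENCE)) {
    mtr_error("precedence must be a permutation of the five annotation layers",
              "mtr_config_error")
  }
  states <- rep("order", protein_length)
  if (is.null(annotations) || nrow(annotations) == 0L) return(states)
  ann <- validate_annotations(annotations)
  if (any(ann$start < 1L | ann$end > protein_length | ann$start > ann$end)) {
    bad <- which(ann$start < 1L | ann$end > protein_length | ann$start > ann$end)[1]
    mtr_error(sprintf("annotation out of bounds: %s [%d, %d] on protein of length %d",
                      ann$gene_id[bad], ann$start[bad], ann$end[bad], protein_length),
              "mtr_annotation_error")
  }
  layer <- ifelse(ann$label == "disorder",
                  paste0(ann$source, "_disorder"), ann$label)
  layer[layer == "derived_pdb_disorder"] <- "predicted_disorder"
  state_of <- c(structural_transition = "structural_transition",
                curated_disorder = "disorder", predicted_disorder = "disorder",
                missing_residues = "missing_residues", order = "order")
  for (lyr in rev(setdiff(precedence, "order"))) {
    rows <- which(layer == lyr)
    for (r in rows) states[ann$start[r]:ann$end[r]] <- state_of[[lyr]]
  }
  states
}

#' Residue counts and fractions per structural state
#'
#' @param states_list List (or single vector) of per-residue state vectors,
#'   one per gene.
#' @return data.frame: state, n_residues, fraction (NA fractions for an
#'   empty gene set).
#' @export
state_composition <- function(states_list) {
  if (is.character(states_list)) states_list <- list(states_list)
  all_states <- unlist(states_list, use.names = FALSE)
  n <- vapply(STATE_LEVELS, function(s) sum(all_states == s), 0L)
  total <- length(all_states)
  data.frame(state = STATE_LEVELS, n_residues = unname(n),
             fraction = if (total == 0L) NA_real_ else unname(n) / total)
}

#' Per-gene annotation presence matrix (UpSet-style)
#'
#' Which of the four annotation types each gene carries, plus counts of
#' exact presence combinations.
#'
#' @param annotations data.frame of annotations across genes.
#' @param gene_ids Optional character vector of all genes (so genes with no
#'   annotations contribute an all-absent row).
#' @return list with `presence` (gene x type logical data.frame) and
#'   `combinations` (exact-combination counts).
#' @export
annotation_overlap_summary <- function(annotations, gene_ids = NULL) {
  ann <- if (nrow(annotations) > 0L) validate_annotations(annotations) else annotations
  genes <- sort(unique(c(gene_ids, ann$gene_id)))
  types <- c(curated_disorder = NA, predicted_disorder = NA,
             structural_transition = NA, missing_residues = NA)
  pres <- data.frame(gene_id = genes)
  pres$curated_disorder <- genes %in% ann$gene_id[ann$label == "disorder" & ann$source == "curated"]
  pres$predicted_disorder <- genes %in% ann$gene_id[ann$label == "disorder" & ann$source == "predicted"]
  pres$structural_transition <- genes %in% ann$gene_id[ann$label == "structural_transition"]
  pres$missing_residues <- genes %in% ann$gene_id[ann$label == "missing_residues"]
  key <- apply(pres[-1], 1, function(r) paste(as.integer(r), collapse = ""))
  comb <- as.data.frame(table(combination = key), stringsAsFactors = FALSE)
  names(comb)[2] <- "n_genes"
  list(presence = pres, combinations = comb)
}

#' Term-to-gene-count table from annotation function terms
#' @param annotations data.frame with optional `term` column (GO/IDPO-style).
#' @return data.frame: term, n_genes, sorted by count.
#' @export
term_gene_counts <- function(annotations) {
  if (!"term" %in% names(annotations)) {
    return(data.frame(term = character(0), n_genes = integer(0)))
  }
  a <- annotations[!is.na(annotations$term) & nzchar(annotations$term), , drop = FALSE]
  tab <- tapply(a$gene_id, a$term, function(g) length(unique(g)))
  out <- data.frame(term = names(tab), n_genes = as.integer(tab))
  out[order(-out$n_genes, out$term), , drop = FALSE]
}

#' Read structural annotations from TSV
#'
#' Columns: gene_id, start, end, label, source, and optionally term.
#' @param path TSV file.
#' @return Validated annotation data.frame.
#' @export
read_annotations_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"term" %in% names(d)) d$term <- NA_character_
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  validate_annotations(d)
}

#' Read structural annotations from a DisProt-style JSON region list
#'
#' Expects a JSON array of region objects; the object keys holding the gene
#' id, start, end, label, source and term are configurable through `fields`.
#'
#' @param path JSON file.
#' @param fields Named list mapping internal names to JSON keys.
#' @return Validated annotation data.frame.
#' @export
read_annotations_json <- function(path,
                                  fields = list(gene_id = "acc", start = "start",
                                                end = "end", label = "label",
                                                source = "source", term = "term")) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  d <- data.frame(
    gene_id = raw[[fields$gene_id]],
    start = as.integer(raw[[fields$start]]),
    end = as.integer(raw[[fields$end]]),
    label = raw[[fields$label]],
    source = raw[[fields$source]],
    term = if (!is.null(raw[[fields$term]])) raw[[fields$term]] else NA_character_,
    stringsAsFactors = FALSE
  )
  validate_annotations(d)
}

#' Write annotations to TSV
#' @param annotations Annotation data.frame.
#' @param path Output path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
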
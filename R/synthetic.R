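# Synthetic-data generator: transcripts with realistic codon composition,
# a per-allele Bernoulli observation model for population variants with
# region-specific missense depletion, four-state structural annotations at
# configurable proportions, and clinical labels with planted state-dependent
# odds ratios. Every generator output is a pure function of (config, seed).

#' Synthetic study configuration
#'
#' Defaults emulate the statistical structure of the real inputs: the state
#' mix matches the residue shares reported for curated NDD proteins (order
#' 0.685, disorder 0.250, missing 0.063, transition 0.002), protein lengths
#' are uniform on 300-700 residues, and each possible SNV allele is observed
#' independently with probability `p_obs` (presence/absence, no allele
#' frequencies). Depletion regions thin missense emission only, leaving
#' synonymous variation as the neutral yardstick, so a region's expected MTR
#' is controlled by its retention factor delta.
#'
#' @param n_genes Number of genes (default 50).
#' @param protein_length c(min, max) residues, uniform (default c(300, 700)).
#' @param state_fractions Named fractions over the four states (must sum
#'   to 1).
#' @param p_obs Per-allele observation probability (default 0.15).
#' @param depletion_regions data.frame(gene_index, start, end, delta) of
#'   planted constrained regions (residue coordinates); delta in [0, 1] is
#'   the missense retention factor.
#' @param nonpass_fraction Fraction of emitted VCF records carrying a
#'   non-PASS FILTER, to exercise quality filtering (default 0.1).
#' @param clinical_targets data.frame(state, class, log2_or) of planted
#'   clinical odds ratios; states/classes not listed are left at baseline.
#' @param clinical_baseline Named baseline class probabilities (pathogenic,
#'   benign, vus).
#' @param n_clinical Number of clinical variants to sample (default 10000).
#' @param codon_weights Optional named weights over the 61 sense codons
#'   (default uniform); disorder-like composition can be emulated by
#'   upweighting codons for S, P, E, K, Q, G.
#' @param seed Base seed; each generator stage derives its own stream from
#'   it (default 1).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 50L,
                             protein_length = c(300L, 700L),
                             state_fractions = c(order = 0.685, disorder = 0.250,
                                                 missing_residues = 0.063,
                                                 structural_transition = 0.002),
                             p_obs = 0.15,
                             depletion_regions = NULL,
                             nonpass_fraction = 0.1,
                             clinical_targets = data.frame(
                               state = c("order", "disorder"),
                               class = c("pathogenic", "pathogenic"),
                               log2_or = c(2, -2)),
                             clinical_baseline = c(pathogenic = 0.25,
                                                   benign = 0.30, vus = 0.45),
                             n_clinical = 10000L,
                             codon_weights = NULL,
                             seed = 1L) {
  stopifnot(n_genes >= 0L, length(protein_length) == 2L,
            protein_length[1] >= 1L, protein_length[2] >= protein_length[1],
            p_obs >= 0, p_obs <= 1, nonpass_fraction >= 0, nonpass_fraction < 1,
            n_clinical >= 0L)
  if (!setequal(names(state_fractions), STATE_LEVELS)) {
    mtr_error("state_fractions must name the four structural states", "mtr_config_error")
  }
  if (abs(sum(state_fractions) - 1) > 1e-8) {
    mtr_error("state_fractions must sum to 1", "mtr_config_error")
  }
  if (!is.null(depletion_regions)) {
    stopifnot(all(c("gene_index", "start", "end", "delta") %in% names(depletion_regions)),
              all(depletion_regions$delta >= 0 & depletion_regions$delta <= 1))
  }
  if (abs(sum(clinical_baseline) - 1) > 1e-8) {
    mtr_error("clinical_baseline must sum to 1", "mtr_config_error")
  }
  structure(list(n_genes = as.integer(n_genes),
                 protein_length = as.integer(protein_length),
                 state_fractions = state_fractions[STATE_LEVELS],
                 p_obs = p_obs, depletion_regions = depletion_regions,
                 nonpass_fraction = nonpass_fraction,
                 clinical_targets = clinical_targets,
                 clinical_baseline = clinical_baseline,
                 n_clinical = as.integer(n_clinical),
                 codon_weights = codon_weights, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Distinct deterministic RNG stream per generator stage (kept < 2^31).
.stage_seed <- function(cfg, stage) {
  (cfg$seed %% 20000000L) * 100L + stage
}

#' Generate random coding transcripts
#'
#' Sense codons drawn independently (uniform by default, or with
#' `codon_weights`), so no internal stop can arise; a terminal stop codon is
#' appended. Deterministic given the config.
#'
#' @param cfg A `synthetic_config`.
#' @return Named list of `transcript` objects.
#' @export
generate_transcripts <- function(cfg) {
  set.seed(.stage_seed(cfg, 0L))
  sense <- sense_codons()
  w <- cfg$codon_weights
  if (!is.null(w)) w <- w[sense]
  out <- list()
  if (cfg$n_genes == 0L) return(out)
  rng <- cfg$protein_length[1]:cfg$protein_length[2]
  lens <- rng[sample.int(length(rng), cfg$n_genes, replace = TRUE)]
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("GENE%03d", i)
    cds <- paste(c(sample(sense, lens[i], replace = TRUE, prob = w),
                   sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
    out[[gid]] <- transcript(gid, cds)
  }
  out
}

#' Generate a population variant catalog under the observation model
#'
#' Every possible SNV allele is emitted independently with probability
#' `p_obs`; missense alleles inside a depletion region are emitted with
#' probability `p_obs * delta` while synonymous alleles are untouched.
#' A further `nonpass_fraction` of the emitted records carry FILTER "AC0"
#' (drawn from alleles not already emitted as PASS) to exercise the
#' PASS-only inclusion rule.
#'
#' @param cfg A `synthetic_config`.
#' @param transcripts Output of [generate_transcripts()].
#' @return data.frame of emitted alleles: gene_id, cds_pos, ref, alt,
#'   consequence, filter.
#' @export
generate_population_variants <- function(cfg, transcripts) {
  set.seed(.stage_seed(cfg, 1L))
  parts <- lapply(seq_along(transcripts), function(i) {
    tx <- transcripts[[i]]
    tab <- possible_snv_table(tx)
    p <- rep(cfg$p_obs, nrow(tab))
    dr <- cfg$depletion_regions
    if (!is.null(dr)) {
      for (j in which(dr$gene_index == i)) {
        in_reg <- tab$protein_pos >= dr$start[j] & tab$protein_pos <= dr$end[j] &
          tab$consequence == "missense"
        p[in_reg] <- p[in_reg] * dr$delta[j]
      }
    }
    drawn <- stats::runif(nrow(tab)) < p
    tab$gene_id <- tx$gene_id
    tab$drawn <- drawn
    tab
  })
  tab <- rbind_frames(parts)
  pass <- tab[tab$drawn, , drop = FALSE]
  pass$filter <- "PASS"
  f <- cfg$nonpass_fraction
  extra <- NULL
  if (f > 0 && nrow(pass) > 0L) {
    n_extra <- round(f / (1 - f) * nrow(pass))
    pool <- which(!tab$drawn)
    extra <- tab[sample(pool, min(n_extra, length(pool))), , drop = FALSE]
    extra$filter <- "AC0"
  }
  out <- rbind(pass, extra)
  out <- out[order(out$gene_id, out$cds_pos, out$alt),
             c("gene_id", "cds_pos", "ref", "alt", "consequence", "filter")]
  rownames(out) <- NULL
  out
}

#' Write a population variant catalog as a CDS-relative VCF
#'
#' CHROM is the gene id, POS the 1-based CDS position.
#'
#' @param variants data.frame from [generate_population_variants()].
#' @param transcripts The generating transcripts (for contig headers).
#' @param path Output path.
#' @export
write_population_vcf <- function(variants, transcripts, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=mtrscape-synthetic",
           '##FILTER=<ID=PASS,Description="All filters passed">',
           '##FILTER=<ID=AC0,Description="No high-quality genotype">',
           vapply(transcripts, function(tx)
             sprintf("##contig=<ID=%s,length=%d>", tx$gene_id, nchar(tx$cds)), ""),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.",
                  variants$gene_id, variants$cds_pos + 1L, variants$ref,
                  variants$alt, variants$filter)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Split `total` into k parts of size >= 1 (uniform composition).
.rand_composition <- function(total, k) {
  if (k <= 1L || total <= k) return(rep(max(1L, total %/% max(1L, k)), min(k, total)))
  cuts <- sort(sample(seq_len(total - 1L), k - 1L))
  as.integer(diff(c(0L, cuts, total)))
}

#' Generate four-state structural annotations
#'
#' Per gene, each non-order state receives `round(fraction * length)`
#' residues laid out as contiguous blocks (disorder possibly split into up
#' to three blocks) placed in shuffled order between order stretches, so the
#' aggregate state mix tracks the configured fractions closely. Disorder
#' blocks are emitted as curated or predicted regions; some curated blocks
#' also carry an overlapping predicted sub-region to exercise precedence
#' resolution.
#'
#' @param cfg A `synthetic_config`.
#' @param transcripts Output of [generate_transcripts()].
#' @return list: `annotations` (data.frame) and `states` (named list of
#'   per-residue truth vectors, identical to what [assign_states()]
#'   reconstructs from the annotations).
#' @export
generate_annotations <- function(cfg, transcripts) {
  set.seed(.stage_seed(cfg, 2L))
  fr <- cfg$state_fractions
  go_terms <- c("protein binding", "flexible linker/spacer",
                "molecular adaptor activity", "DNA binding",
                "regulation of transcription")
  ann_parts <- list()
  states <- list()
  for (tx in transcripts) {
    L <- tx$n_res
    n_dis <- as.integer(round(fr[["disorder"]] * L))
    n_mis <- as.integer(round(fr[["missing_residues"]] * L))
    n_tra <- as.integer(round(fr[["structural_transition"]] * L))
    blocks <- list()
    if (n_dis > 0L) {
      k <- sample(1:min(3L, n_dis), 1L)
      for (sz in .rand_composition(n_dis, k)) {
        blocks <- c(blocks, list(list(state = "disorder", size = sz)))
      }
    }
    if (n_mis > 0L) blocks <- c(blocks, list(list(state = "missing_residues", size = n_mis)))
    if (n_tra > 0L) blocks <- c(blocks, list(list(state = "structural_transition", size = n_tra)))
    blocks <- blocks[sample.int(length(blocks))]
    n_order <- L - sum(vapply(blocks, `[[`, 0L, "size"))
    # distribute order residues into the gaps around the blocks
    gaps <- .rand_composition(n_order + length(blocks) + 1L, length(blocks) + 1L) - 1L
    st <- character(0)
    ann <- list()
    pos <- 1L
    for (b in seq_along(blocks)) {
      st <- c(st, rep("order", gaps[b]))
      pos <- pos + gaps[b]
      bl <- blocks[[b]]
      start <- pos; end <- pos + bl$size - 1L
      st <- c(st, rep(bl$state, bl$size))
      pos <- end + 1L
      if (bl$state == "disorder") {
        src <- sample(c("curated", "predicted"), 1L, prob = c(0.7, 0.3))
        ann <- c(ann, list(data.frame(
          gene_id = tx$gene_id, start = start, end = end, label = "disorder",
          source = src,
          term = if (src == "curated") sample(go_terms, 1L) else NA_character_,
          stringsAsFactors = FALSE)))
        if (src == "curated" && bl$size >= 4L && stats::runif(1) < 0.5) {
          # overlapping predicted sub-region: same painted state, exercises
          # the curated > predicted precedence rule
          s2 <- start + sample.int(bl$size %/% 2L, 1L) - 1L
          ann <- c(ann, list(data.frame(
            gene_id = tx$gene_id, start = s2, end = end, label = "disorder",
            source = "predicted", term = NA_character_, stringsAsFactors = FALSE)))
        }
      } else if (bl$state == "structural_transition") {
        ann <- c(ann, list(data.frame(
          gene_id = tx$gene_id, start = start, end = end,
          label = "structural_transition", source = "curated",
          term = sample(go_terms, 1L), stringsAsFactors = FALSE)))
      } else {
        ann <- c(ann, list(data.frame(
          gene_id = tx$gene_id, start = start, end = end,
          label = "missing_residues", source = "derived_pdb",
          term = NA_character_, stringsAsFactors = FALSE)))
      }
    }
    st <- c(st, rep("order", gaps[length(gaps)]))
    stopifnot(length(st) == L)
    states[[tx$gene_id]] <- st
    ann_parts <- c(ann_parts, ann)
  }
  annotations <- rbind_frames(ann_parts)
  if (is.null(annotations)) {
    annotations <- data.frame(gene_id = character(0), start = integer(0),
                              end = integer(0), label = character(0),
                              source = character(0), term = character(0),
                              stringsAsFactors = FALSE)
  }
  list(annotations = annotations, states = states)
}

#' Solve per-state clinical class probabilities for target odds ratios
#'
#' Finds class probabilities P(class | state) such that, given the state
#' residue weights, the realized (state vs rest) odds ratios match the
#' planted targets. Damped fixed-point iteration on the log-odds tilt of
#' each targeted cell; untargeted cells stay at the baseline tilt.
#'
#' @param targets data.frame(state, class, log2_or) of planted targets.
#' @param weights Named residue-share weights per state (sum to 1).
#' @param baseline Named baseline class probabilities.
#' @return list: `probs` (state x class matrix), `realized` (state x class
#'   matrix of implied log2 ORs for every cell).
#' @export
solve_state_class_probs <- function(targets, weights, baseline) {
  classes <- names(baseline)
  states <- names(weights)
  tilt <- matrix(0, length(states), length(classes),
                 dimnames = list(states, classes))
  tgt <- matrix(NA_real_, length(states), length(classes),
                dimnames = list(states, classes))
  if (!is.null(targets) && nrow(targets) > 0L) {
    for (i in seq_len(nrow(targets))) {
      if (!targets$state[i] %in% states || !targets$class[i] %in% classes) {
        mtr_error("clinical target names an unknown state or class", "mtr_config_error")
      }
      tgt[targets$state[i], targets$class[i]] <- targets$log2_or[i]
    }
    tilt[!is.na(tgt)] <- tgt[!is.na(tgt)]
  }
  probs_of <- function(tilt) {
    p <- sweep(2^tilt, 2, baseline, "*")
    p / rowSums(p)
  }
  realized_of <- function(P) {
    out <- matrix(NA_real_, length(states), length(classes),
                  dimnames = list(states, classes))
    for (s in states) {
      w_rest <- weights[setdiff(states, s)]
      for (cl in classes) {
        ps <- P[s, cl]
        pr <- sum(w_rest * P[setdiff(states, s), cl]) / sum(w_rest)
        out[s, cl] <- log2((ps / (1 - ps)) / (pr / (1 - pr)))
      }
    }
    out
  }
  P <- probs_of(tilt)
  for (it in seq_len(500L)) {
    realized <- realized_of(P)
    err <- tgt - realized
    err[is.na(err)] <- 0
    if (max(abs(err)) < 1e-8) break
    tilt <- tilt + 0.5 * err
    P <- probs_of(tilt)
    if (any(!is.finite(P))) {
      mtr_error("clinical odds-ratio targets are infeasible", "mtr_config_error")
    }
  }
  realized <- realized_of(P)
  chk <- abs(tgt - realized); chk[is.na(chk)] <- 0
  if (max(chk) > 1e-6) {
    mtr_error("clinical odds-ratio targets did not converge (infeasible combination)",
              "mtr_config_error")
  }
  list(probs = P, realized = realized)
}

#' Generate clinical labels with planted state-dependent odds ratios
#'
#' Samples `n_clinical` missense positions uniformly over all residues,
#' draws each variant's class from the per-state probabilities solved from
#' the planted odds-ratio targets, and picks a concrete missense
#' substitution at the sampled codon. The planted and realized log2 ORs are
#' attached as the `"truth"` attribute, sufficient to score recovery
#' without re-reading the config.
#'
#' @param cfg A `synthetic_config`.
#' @param transcripts Output of [generate_transcripts()].
#' @param states Named list of per-residue truth states.
#' @return data.frame: gene_id, protein_pos, aa_ref, aa_alt,
#'   clinical_significance, state; attribute `"truth"` holds the planted
#'   odds-ratio table.
#' @export
generate_clinical_labels <- function(cfg, transcripts, states) {
  set.seed(.stage_seed(cfg, 3L))
  empty <- data.frame(gene_id = character(0), protein_pos = integer(0),
                      aa_ref = character(0), aa_alt = character(0),
                      clinical_significance = character(0), state = character(0),
                      stringsAsFactors = FALSE)
  if (cfg$n_clinical == 0L || length(transcripts) == 0L) {
    attr(empty, "truth") <- data.frame(state = character(0), class = character(0),
                                       target_log2_or = numeric(0),
                                       realized_log2_or = numeric(0))
    return(empty)
  }
  pool <- do.call(rbind, c(lapply(transcripts, function(tx) {
    data.frame(gene_id = tx$gene_id, protein_pos = seq_len(tx$n_res),
               state = states[[tx$gene_id]], stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  w <- tapply(rep(1, nrow(pool)), factor(pool$state, STATE_LEVELS), sum)
  w[is.na(w)] <- 0
  w <- w / sum(w)
  # targets for states with no residues cannot be realized
  if (!is.null(cfg$clinical_targets) && nrow(cfg$clinical_targets) > 0L &&
      any(w[cfg$clinical_targets$state] == 0)) {
    mtr_error("clinical target planted in a state with no residues", "mtr_config_error")
  }
  sol <- solve_state_class_probs(cfg$clinical_targets, w, cfg$clinical_baseline)
  idx <- sample.int(nrow(pool), cfg$n_clinical, replace = TRUE)
  d <- pool[idx, , drop = FALSE]
  d$clinical_class <- NA_character_
  for (s in STATE_LEVELS) {
    ii <- which(d$state == s)
    if (length(ii) == 0L) next
    d$clinical_class[ii] <- sample(colnames(sol$probs), length(ii),
                                   replace = TRUE, prob = sol$probs[s, ])
  }
  raw_of <- list(
    pathogenic = c("Pathogenic", "Likely_pathogenic", "Pathogenic/Likely_pathogenic"),
    benign = c("Benign", "Likely_benign", "Benign/Likely_benign"),
    vus = "Uncertain_significance")
  d$clinical_significance <- vapply(d$clinical_class, function(cl)
    sample(raw_of[[cl]], 1L), "")
  # concrete missense substitution at the sampled residue
  aa_ref <- character(nrow(d)); aa_alt <- character(nrow(d))
  for (g in unique(d$gene_id)) {
    tx <- transcripts[[g]]
    ii <- which(d$gene_id == g)
    mis <- possible_snv_table(tx)
    mis <- mis[mis$consequence == "missense", , drop = FALSE]
    pick <- vapply(d$protein_pos[ii], function(pp) {
      cand <- which(mis$protein_pos == pp)
      cand[sample.int(length(cand), 1L)]
    }, 0L)
    aa_ref[ii] <- mis$aa_ref[pick]
    aa_alt[ii] <- mis$aa_alt[pick]
  }
  d$aa_ref <- aa_ref; d$aa_alt <- aa_alt
  out <- d[c("gene_id", "protein_pos", "aa_ref", "aa_alt",
             "clinical_significance", "state")]
  rownames(out) <- NULL
  truth <- expand.grid(state = rownames(sol$realized),
                       class = colnames(sol$realized), stringsAsFactors = FALSE)
  truth$target_log2_or <- NA_real_
  if (!is.null(cfg$clinical_targets)) {
    m <- match(paste(truth$state, truth$class),
               paste(cfg$clinical_targets$state, cfg$clinical_targets$class))
    truth$target_log2_or <- cfg$clinical_targets$log2_or[m]
  }
  truth$realized_log2_or <- sol$realized[cbind(truth$state, truth$class)]
  attr(out, "truth") <- truth
  out
}

#' Generate and write a complete synthetic input bundle
#'
#' Writes the CDS FASTA, population VCF, annotation TSV, clinical TSV, the
#' planted-truth table, and a manifest JSON tying the files to the seed and
#' a config hash.
#'
#' @param cfg A `synthetic_config`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths plus the in-memory objects.
#' @export
generate_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  txs <- generate_transcripts(cfg)
  variants <- generate_population_variants(cfg, txs)
  ann <- generate_annotations(cfg, txs)
  clinical <- generate_clinical_labels(cfg, txs, ann$states)
  paths <- list(
    cds_fasta = file.path(dir, "transcripts.fa"),
    population_vcf = file.path(dir, "population.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    clinical_tsv = file.path(dir, "clinical.tsv"),
    truth = file.path(dir, "clinical_truth.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_cds_fasta(txs, paths$cds_fasta)
  write_population_vcf(variants, txs, paths$population_vcf)
  write_annotations_tsv(ann$annotations, paths$annotations)
  utils::write.table(clinical[c("gene_id", "protein_pos", "aa_ref", "aa_alt",
                                "clinical_significance")],
                     paths$clinical_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(attr(clinical, "truth"), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null",
                               digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(seed = cfg$seed, config = unclass(cfg),
                   config_md5 = unname(tools::md5sum(tmp)),
                   files = lapply(paths[names(paths) != "manifest"], basename))
  unlink(tmp)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  c(paths, list(transcripts = txs, variants = variants,
                annotations = ann$annotations, states = ann$states,
                clinical = clinical))
}
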
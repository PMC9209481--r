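NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          c("TAA", "TAG", "TGA"))

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate the
#' study conditions the pipeline targets: a UV-like spectrum (roughly 58% C>T
#' overall, with most C>T at dipyrimidines, under `uv_weight = 0.5`), a 24%
#' coding-strand excess (`strand_excess = 1.24`), CC>TT dinucleotide variants
#' predominantly on the coding strand (`dnv_coding_frac = 0.824`), VAFs
#' log-uniform over the observed range 0.0023-0.11, positive selection on
#' driver genes (`selection_weight = 3`, neutral elsewhere), and barcode
#' families for hotspot consensus. The panel is scaled down from the study's
#' 153 genes to keep simulation tractable while preserving the gene-set
#' structure.
#'
#' @param seed Mandatory integer seed; all generator output is a pure
#'   function of (config, seed).
#' @param n_driver,n_immune,n_housekeeping Number of genes per set.
#' @param cds_codons Range (min, max) of CDS lengths in codons (including the
#'   stop codon).
#' @param uv_weight Mixing weight u in \[0, 1\] of the UV-like class profile
#'   (C>T with a 5' pyrimidine) against a uniform profile.
#' @param strand_excess Multiplier b >= 1 on substitution sites whose
#'   mutated pyrimidine lies on the coding strand.
#' @param dnv_rate Fraction of eligible C>T draws extended to CC>TT
#'   dinucleotide variants (emitted as phase-tagged SNV pairs).
#' @param dnv_coding_frac Fraction of injected DNVs placed with the CC on the
#'   coding strand.
#' @param selection_weight Acceptance weight w >= 1 on nonsynonymous draws in
#'   driver genes; w = 1 is exactly neutral.
#' @param nonsense_only If `TRUE`, `selection_weight` applies to nonsense
#'   draws only.
#' @param n_samples,muts_per_sample Sample count and mutations per sample.
#' @param vaf_range VAF range (log-uniform).
#' @param score_shape_driver,score_shape_other Beta shape parameters of the
#'   missense impact-score distributions per gene set.
#' @param impact_bias Extra acceptance weight on driver missense draws whose
#'   impact score is at least `impact_threshold` (1 = off).
#' @param impact_threshold Score threshold for `impact_bias`.
#' @param umi List of barcode-read parameters: `n_families`, `family_size`
#'   (mean; sizes are Poisson unless `family_size_fixed`), `family_size_fixed`
#'   (logical), `error_rate` (per-read probability of one random substituted
#'   base), `true_vaf`, `barcode_len`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_driver = 10L, n_immune = 4L, n_housekeeping = 4L,
                       cds_codons = c(120L, 300L),
                       uv_weight = 0.5,
                       strand_excess = 1.24,
                       dnv_rate = 0.04,
                       dnv_coding_frac = 0.824,
                       selection_weight = 3,
                       nonsense_only = FALSE,
                       n_samples = 12L,
                       muts_per_sample = 76L,
                       vaf_range = c(0.0023, 0.11),
                       score_shape_driver = c(0.6, 0.6),
                       score_shape_other = c(0.6, 0.6),
                       impact_bias = 4,
                       impact_threshold = 0.8,
                       umi = list()) {
  if (is.null(seed)) stop("a seed is mandatory")
  umi_defaults <- list(n_families = 1000L, family_size = 30,
                       family_size_fixed = FALSE, error_rate = 0.005,
                       true_vaf = 0.01, barcode_len = 12L)
  umi <- utils::modifyList(umi_defaults, umi)
  cfg <- list(seed = as.integer(seed), n_driver = n_driver,
              n_immune = n_immune, n_housekeeping = n_housekeeping,
              cds_codons = cds_codons, uv_weight = uv_weight,
              strand_excess = strand_excess, dnv_rate = dnv_rate,
              dnv_coding_frac = dnv_coding_frac,
              selection_weight = selection_weight,
              nonsense_only = nonsense_only, n_samples = n_samples,
              muts_per_sample = muts_per_sample, vaf_range = vaf_range,
              score_shape_driver = score_shape_driver,
              score_shape_other = score_shape_other,
              impact_bias = impact_bias,
              impact_threshold = impact_threshold, umi = umi)
  stopifnot(uv_weight >= 0, uv_weight <= 1, strand_excess >= 1,
            dnv_rate >= 0, dnv_rate <= 1, dnv_coding_frac >= 0,
            dnv_coding_frac <= 1, selection_weight >= 1,
            vaf_range[1] > 0, vaf_range[2] <= 1,
            vaf_range[1] <= vaf_range[2], impact_bias >= 1,
            umi$error_rate >= 0, umi$error_rate <= 1,
            umi$true_vaf >= 0, umi$true_vaf <= 1)
  structure(cfg, class = "sim_config")
}

#' UV-like substitution-class profile
#'
#' Probability mass concentrated uniformly on the eight C>T classes with a 5'
#' pyrimidine flank (`C[C>T]N`, `T[C>T]N`), qualitatively mirroring the
#' dominant peaks of the UV single-base-substitution signature.
#'
#' @return A [spectrum_prior].
#' @export
uv_class_profile <- function() {
  labels <- sbs96_labels()
  p <- setNames(rep(0, 96), labels)
  uv <- labels[grepl("^[CT]\\[C>T\\]", labels)]
  p[uv] <- 1 / length(uv)
  spectrum_prior(p, "UV-like")
}

#' Mixture prior used by the generator
#'
#' `u * UV-like + (1 - u) * uniform` over the 96 classes.
#'
#' @param uv_weight Mixing weight u, or a `sim_config`.
#' @return A [spectrum_prior].
#' @export
mixture_prior <- function(uv_weight) {
  if (inherits(uv_weight, "sim_config")) uv_weight <- uv_weight$uv_weight
  p <- uv_weight * as.numeric(uv_class_profile()) + (1 - uv_weight) / 96
  spectrum_prior(setNames(p, sbs96_labels()),
                 sprintf("UV-mixture(u=%.2f)", uv_weight))
}

#' Generate a random gene panel
#'
#' Random coding sequences with an ATG start, no internal stop codons in
#' frame, and a terminal stop, plus random single-base flanks, labelled with
#' the configured gene-set sizes.
#'
#' @param config A [sim_config].
#' @return A `gene_panel`.
#' @export
generate_panel <- function(config) {
  set.seed(config$seed)
  sets <- rep(c("driver", "immune", "housekeeping"),
              c(config$n_driver, config$n_immune, config$n_housekeeping))
  ids <- c(sprintf("DRV%02d", seq_len(config$n_driver)),
           sprintf("IMM%02d", seq_len(config$n_immune)),
           sprintf("HKG%02d", seq_len(config$n_housekeeping)))
  panel <- lapply(seq_along(ids), function(i) {
    rng <- config$cds_codons
    n_codons <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
    if (n_codons < 2L) stop("infeasible CDS length")
    cds <- paste0("ATG",
                  paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    gene_model(ids[i], cds, flank5 = sample(DNA_BASES, 1L),
               flank3 = sample(DNA_BASES, 1L), gene_set = sets[i])
  })
  names(panel) <- ids
  structure(panel, class = "gene_panel")
}

#' Simulate a reference mutation catalogue
#'
#' Draws substitution classes from the generator's mixture profile and emits
#' a MAF-like table of contexts and alleles from which [estimate_prior()] can
#' recover the class frequencies. Intended as the stand-in for an external
#' tumor catalogue; drawn with a seed independent of the mutation simulation
#' so prior estimation and mutation generation are decoupled.
#'
#' @param config A [sim_config].
#' @param n Number of catalogue records.
#' @param seed Seed (default derived from the config seed).
#' @return Data frame with `context`, `ref`, `alt`.
#' @export
simulate_catalogue <- function(config, n = 50000L, seed = config$seed + 7777L) {
  set.seed(seed)
  labels <- sbs96_labels()
  cls <- sample(labels, n, replace = TRUE,
                prob = as.numeric(mixture_prior(config)))
  data.frame(context = paste0(substr(cls, 1, 1), substr(cls, 3, 3),
                              substr(cls, 7, 7)),
             ref = substr(cls, 3, 3), alt = substr(cls, 5, 5),
             stringsAsFactors = FALSE)
}

site_weights <- function(st, config, scores = NULL) {
  prior <- mixture_prior(config)
  w <- as.numeric(prior)[match(st$class96, sbs96_labels())]
  w <- w * ifelse(st$ref %in% c("C", "T"), config$strand_excess, 1)
  target <- if (config$nonsense_only) st$consequence == "nonsense"
            else st$consequence != "synonymous"
  w <- w * ifelse(st$gene_set == "driver" & target, config$selection_weight, 1)
  if (!is.null(scores) && config$impact_bias != 1) {
    sc <- lookup_scores(scores, st$gene_id, st$pos, st$alt)
    hi <- !is.na(sc) & sc >= config$impact_threshold &
      st$gene_set == "driver" & st$consequence == "missense"
    w <- w * ifelse(hi, config$impact_bias, 1)
  }
  w
}

#' Simulate a somatic mutation table
#'
#' Draws mutations from the panel's possible substitutions with class weights
#' from the configured UV/uniform mixture, a coding-strand excess on
#' pyrimidine-reference sites, and acceptance reweighting of nonsynonymous
#' draws in driver genes (weight w; w = 1 is exactly neutral). VAFs are
#' log-uniform over the configured range. A configured fraction of C>T draws
#' in a CC run is extended to a CC>TT dinucleotide variant, emitted as two
#' phase-tagged SNV records for [merge_phased()] to merge.
#'
#' @param panel A `gene_panel` (typically from [generate_panel()]).
#' @param config A [sim_config].
#' @param scores Optional score table enabling the impact bias on high-score
#'   driver missense sites.
#' @param seed Seed (default derived from the config seed).
#' @return Mutation table with `sample_id`, `gene_id`, `pos`, `ref`, `alt`,
#'   `vaf`, `phase_tag`.
#' @export
simulate_mutations <- function(panel, config, scores = NULL,
                               seed = config$seed + 1L) {
  if (!length(panel)) stop("empty panel")
  set.seed(seed)
  st <- panel_site_table(panel)
  w <- site_weights(st, config, scores)
  n_tot <- config$n_samples * config$muts_per_sample
  idx <- sample.int(nrow(st), n_tot, replace = TRUE, prob = w)
  muts <- data.frame(
    sample_id = rep(sprintf("S%02d", seq_len(config$n_samples)),
                    each = config$muts_per_sample),
    gene_id = st$gene_id[idx], pos = st$pos[idx], ref = st$ref[idx],
    alt = st$alt[idx],
    vaf = exp(runif(n_tot, log(config$vaf_range[1]),
                    log(config$vaf_range[2]))),
    phase_tag = NA_character_, stringsAsFactors = FALSE)
  if (config$dnv_rate > 0)
    muts <- inject_dnvs(muts, panel, config)
  rownames(muts) <- NULL
  muts
}

# Extend a fraction of C>T draws inside CC (coding) or GG (template) runs
# into phase-tagged adjacent pairs that merge_phased() turns into CC>TT /
# GG>AA DNVs.
inject_dnvs <- function(muts, panel, config) {
  cds_at <- function(gene_id, pos) {
    out <- rep(NA_character_, length(pos))
    ok <- pos >= 1L
    for (g in unique(gene_id[ok])) {
      i <- which(ok & gene_id == g)
      L <- nchar(panel[[g]]$cds)
      valid <- i[pos[i] <= L]
      out[valid] <- substring(panel[[g]]$cds, pos[valid], pos[valid])
    }
    out
  }
  coding_ok <- muts$ref == "C" & muts$alt == "T" &
    !is.na(cds_at(muts$gene_id, muts$pos + 1L)) &
    cds_at(muts$gene_id, muts$pos + 1L) == "C"
  template_ok <- muts$ref == "G" & muts$alt == "A" &
    !is.na(cds_at(muts$gene_id, muts$pos - 1L)) &
    cds_at(muts$gene_id, muts$pos - 1L) == "G"
  n_ct <- sum(muts$ref %in% c("C", "G") & muts$alt %in% c("T", "A"))
  n_dnv <- rbinom(1L, n_ct, config$dnv_rate)
  if (n_dnv == 0) return(muts)
  n_coding <- rbinom(1L, n_dnv, config$dnv_coding_frac)
  pick <- function(eligible, k) {
    cand <- which(eligible)
    if (!length(cand)) return(integer(0))
    cand[sample.int(length(cand), min(k, length(cand)))]
  }
  anchors <- c(pick(coding_ok, n_coding), pick(template_ok, n_dnv - n_coding))
  if (!length(anchors)) return(muts)
  # greedily keep anchors whose (pos, partner pos) pair is free within the
  # sample/gene, so no position lands in two merge groups
  is_coding <- muts$ref[anchors] == "C"
  ppos <- muts$pos[anchors] + ifelse(is_coding, 1L, -1L)
  key <- paste(muts$sample_id[anchors], muts$gene_id[anchors], sep = "\r")
  used <- list()
  keep <- logical(length(anchors))
  for (k in seq_along(anchors)) {
    pair <- c(muts$pos[anchors[k]], ppos[k])
    if (!any(pair %in% used[[key[k]]])) {
      keep[k] <- TRUE
      used[[key[k]]] <- c(used[[key[k]]], pair)
    }
  }
  anchors <- anchors[keep]; is_coding <- is_coding[keep]; ppos <- ppos[keep]
  if (!length(anchors)) return(muts)
  partner <- data.frame(
    sample_id = muts$sample_id[anchors], gene_id = muts$gene_id[anchors],
    pos = ppos,
    ref = ifelse(is_coding, "C", "G"), alt = ifelse(is_coding, "T", "A"),
    vaf = muts$vaf[anchors],
    phase_tag = sprintf("dnv%04d", seq_along(anchors)),
    stringsAsFactors = FALSE)
  muts$phase_tag[anchors] <- partner$phase_tag
  out <- rbind(muts, partner)
  # drop untagged draws that duplicate a tagged position
  tagged_key <- paste(out$sample_id, out$gene_id, out$pos)[!is.na(out$phase_tag)]
  drop <- is.na(out$phase_tag) &
    paste(out$sample_id, out$gene_id, out$pos) %in% tagged_key
  out[!drop, , drop = FALSE]
}

#' Simulate an impact-score table
#'
#' Gives every missense-producing substitution in the panel a score drawn
#' from a Beta distribution whose shape parameters depend on the gene set,
#' enabling both a shared PolyPhen-like U-shaped score landscape and
#' configurations where driver-gene substitutions score systematically
#' higher.
#'
#' @param panel A `gene_panel`.
#' @param config A [sim_config].
#' @param seed Seed (default derived from the config seed).
#' @return Score table with `gene_id`, `pos`, `alt`, `score`.
#' @export
simulate_scores <- function(panel, config, seed = config$seed + 2L) {
  set.seed(seed)
  st <- panel_site_table(panel)
  st <- st[st$consequence == "missense", , drop = FALSE]
  drv <- st$gene_set == "driver"
  score <- numeric(nrow(st))
  score[drv] <- rbeta(sum(drv), config$score_shape_driver[1],
                      config$score_shape_driver[2])
  score[!drv] <- rbeta(sum(!drv), config$score_shape_other[1],
                       config$score_shape_other[2])
  data.frame(gene_id = st$gene_id, pos = st$pos, alt = st$alt,
             score = score, stringsAsFactors = FALSE)
}

random_barcodes <- function(n, len) {
  repeat {
    bc <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate barcoded amplicon reads over a hotspot
#'
#' Each barcode family derives from one template molecule: mutant (alternate
#' base at every hotspot position) with probability `true_vaf`, wild type
#' otherwise. Family sizes are Poisson around the configured mean (or fixed),
#' and each read independently suffers one random substituted base with the
#' configured per-read error probability.
#'
#' @param hotspot A [hotspot_def].
#' @param config A [sim_config] (UMI parameters under `config$umi`).
#' @param seed Seed (default derived from the config seed).
#' @return Data frame with `read_id`, `barcode`, `seq`; attribute
#'   `truth` records the mutant-family count.
#' @export
simulate_umi_reads <- function(hotspot, config, seed = config$seed + 3L) {
  set.seed(seed)
  u <- config$umi
  n_fam <- u$n_families
  sizes <- if (isTRUE(u$family_size_fixed)) rep(u$family_size, n_fam)
           else pmax(1L, rpois(n_fam, u$family_size))
  barcodes <- random_barcodes(n_fam, u$barcode_len)
  mut_template <- hotspot$ref
  for (p in hotspot$mut_pos) substr(mut_template, p, p) <- hotspot$alt
  is_mut <- runif(n_fam) < u$true_vaf
  templates <- ifelse(is_mut, mut_template, hotspot$ref)
  seqs <- rep(templates, sizes)
  bc <- rep(barcodes, sizes)
  n_reads <- length(seqs)
  L <- nchar(hotspot$ref)
  hit <- which(runif(n_reads) < u$error_rate)
  if (length(hit)) {
    pos <- sample.int(L, length(hit), replace = TRUE)
    for (k in seq_along(hit)) {
      i <- hit[k]; p <- pos[k]
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(DNA_BASES[DNA_BASES != cur], 1L)
    }
  }
  out <- data.frame(read_id = sprintf("r%06d", seq_len(n_reads)),
                    barcode = bc, seq = seqs, stringsAsFactors = FALSE)
  attr(out, "truth") <- list(n_mutant_families = sum(is_mut),
                             n_families = n_fam)
  out
}

#' Write barcoded reads as FASTQ
#'
#' The barcode is written either as a leading sequence prefix or as a
#' `UMI:<barcode>` tag in the header.
#'
#' @param reads Data frame with `read_id`, `barcode`, `seq`.
#' @param path Output path.
#' @param style `"prefix"` or `"header"`.
#' @return The path, invisibly.
#' @export
write_barcoded_fastq <- function(reads, path, style = c("prefix", "header")) {
  style <- match.arg(style)
  if (style == "prefix") {
    seqs <- paste0(reads$barcode, reads$seq)
    ids <- reads$read_id
  } else {
    seqs <- reads$seq
    ids <- paste0(reads$read_id, " UMI:", reads$barcode)
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(seqs))))
  invisible(path)
}

#' Built-in small reference signature matrix
#'
#' Four synthetic signatures for refitting exercises: a UV-like column
#' (C>T at 5'-pyrimidine contexts), a flat column, a smoking-like C>A column
#' and a T>C column. Real signature matrices (e.g. COSMIC) can be supplied as
#' TSV via [read_signature_matrix()].
#'
#' @return Numeric 96 x 4 matrix with class labels as rownames.
#' @export
reference_signatures <- function() {
  labels <- sbs96_labels()
  one_type <- function(pattern) {
    p <- setNames(rep(0, 96), labels)
    sel <- grepl(pattern, labels)
    p[sel] <- 1 / sum(sel)
    p
  }
  cbind(UVlike = as.numeric(uv_class_profile()),
        Flat = rep(1 / 96, 96),
        SmokingLike = one_type("\\[C>A\\]"),
        TtoC = one_type("\\[T>C\\]")) -> m
  rownames(m) <- labels
  m
}

#' Write every pipeline input for one synthetic study
#'
#' Emits a complete, self-consistent study directory in exactly the formats
#' the readers consume: panel FASTA + metadata TSV, mutation table TSV,
#' reference catalogue TSV, impact-score TSV, sample sheet TSV, signature
#' matrix TSV, and a barcoded hotspot FASTQ. Byte-identical output under the
#' same config.
#'
#' @param config A [sim_config].
#' @param dir Output directory (created if needed).
#' @return Named list of the written file paths, invisibly.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  panel <- generate_panel(config)
  seqs <- Biostrings::DNAStringSet(vapply(panel, `[[`, "", "cds"))
  names(seqs) <- names(panel)
  Biostrings::writeXStringSet(seqs, path("panel.fasta"))
  meta <- data.frame(gene_id = names(panel),
                     gene_set = vapply(panel, `[[`, "", "gene_set"),
                     strand = vapply(panel, `[[`, "", "strand"),
                     flank5 = vapply(panel, `[[`, "", "flank5"),
                     flank3 = vapply(panel, `[[`, "", "flank3"))
  write.table(meta, path("panel_metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  scores <- simulate_scores(panel, config)
  write.table(scores, path("scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  muts <- simulate_mutations(panel, config, scores = scores)
  write.table(muts, path("mutations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  cat_df <- simulate_catalogue(config)
  write.table(cat_df, path("catalogue.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(config$n_samples)),
                        tissue = "skin", diameter_mm = 5,
                        area_mm2 = NA_real_)
  write.table(samples, path("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write_signature_matrix(reference_signatures(), path("signatures.tsv"))
  reads <- simulate_umi_reads(rpl13a_hotspot(), config)
  write_barcoded_fastq(reads, path("hotspot_reads.fastq"), style = "header")
  invisible(list(panel = path("panel.fasta"),
                 metadata = path("panel_metadata.tsv"),
                 mutations = path("mutations.tsv"),
                 catalogue = path("catalogue.tsv"),
                 scores = path("scores.tsv"),
                 samples = path("samples.tsv"),
                 signatures = path("signatures.tsv"),
                 fastq = path("hotspot_reads.fastq")))
}
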
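#' Read a somatic mutation table
#'
#' Tab-separated with header `sample_id gene_id pos ref alt vaf` and an
#' optional `phase_tag` column (empty = not co-read).
#'
#' @param path File path.
#' @return Mutation data frame.
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("sample_id", "gene_id", "pos", "ref", "alt", "vaf")
  if (!all(req %in% names(df)))
    stop("mutation table must have columns: ", paste(req, collapse = ", "))
  if (!"phase_tag" %in% names(df)) df$phase_tag <- NA_character_
  df$phase_tag <- as.character(df$phase_tag)
  df[c(req, "phase_tag")]
}

#' Read mutations from a minimal VCF
#'
#' Reads a VCF whose CHROM column carries the gene id, POS the 1-based CDS
#' position, and whose INFO field supplies `VAF=` and optionally `SAMPLE=`
#' and `PHASE=` tags. Uses the VariantAnnotation parser when available.
#'
#' @param path VCF file path.
#' @param sample_id Fallback sample id when the INFO field has no `SAMPLE=`.
#' @return Mutation data frame as from [read_mutations()].
#' @export
read_mutations_vcf <- function(path, sample_id = "sample1") {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    info <- VariantAnnotation::info(vcf)
    alt <- vapply(as.list(rr$ALT), function(a) as.character(a[[1]]), "")
    df <- data.frame(
      sample_id = if ("SAMPLE" %in% names(info)) as.character(info$SAMPLE)
                  else sample_id,
      gene_id = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      ref = as.character(rr$REF), alt = alt,
      vaf = as.numeric(info$VAF),
      phase_tag = if ("PHASE" %in% names(info)) as.character(info$PHASE)
                  else NA_character_,
      stringsAsFactors = FALSE)
    rownames(df) <- NULL
    return(df)
  }
  # fallback: parse the fixed columns directly
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body, "\t")
  get_info <- function(info, tag) {
    m <- regmatches(info, regexpr(paste0(tag, "=[^;]+"), info))
    if (length(m)) sub(paste0(tag, "="), "", m) else NA_character_
  }
  do.call(rbind, lapply(f, function(x) {
    data.frame(sample_id = {
      s <- get_info(x[8], "SAMPLE"); if (is.na(s)) sample_id else s
    }, gene_id = x[1], pos = as.integer(x[2]), ref = x[4], alt = x[5],
    vaf = as.numeric(get_info(x[8], "VAF")),
    phase_tag = get_info(x[8], "PHASE"), stringsAsFactors = FALSE)
  }))
}

#' Read a reference mutation catalogue
#'
#' MAF-like TSV used for prior estimation. Accepts either the compact
#' `context` / `ref` / `alt` header or MAF-style `Reference_Allele` /
#' `Tumor_Seq_Allele2` / `CONTEXT` columns.
#'
#' @param path File path.
#' @return Data frame with `context`, `ref`, `alt`.
#' @export
read_catalogue <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (all(c("Reference_Allele", "Tumor_Seq_Allele2", "CONTEXT") %in% names(df)))
    df <- data.frame(context = df$CONTEXT, ref = df$Reference_Allele,
                     alt = df$Tumor_Seq_Allele2, stringsAsFactors = FALSE)
  if (!all(c("context", "ref", "alt") %in% names(df)))
    stop("catalogue must have columns context, ref, alt (or MAF equivalents)")
  df
}

write_report_tsv <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-sample and per-gene mutation burden summary
#'
#' Counts mutations per sample stratified by gene set, and ranks genes by
#' average mutations per sample (mps = total mutations in the gene divided by
#' the number of samples).
#'
#' @param mutations Mutation table.
#' @param panel A `gene_panel`.
#' @param n_samples Number of samples (default: distinct sample ids in the
#'   table).
#' @return List with `per_sample` (sample x gene-set count matrix) and
#'   `per_gene` (data frame `gene_id`, `gene_set`, `n`, `mps`, ranked by
#'   mps).
#' @export
burden_summary <- function(mutations, panel, n_samples = NULL) {
  if (is.null(n_samples)) n_samples <- length(unique(mutations$sample_id))
  if (n_samples == 0)
    stop("burden summary needs at least one sample")
  sets <- vapply(panel, `[[`, "", "gene_set")
  ms <- sets[mutations$gene_id]
  per_sample <- table(factor(mutations$sample_id),
                      factor(ms, levels = c("driver", "immune", "housekeeping")))
  n_gene <- table(factor(mutations$gene_id, levels = names(panel)))
  per_gene <- data.frame(gene_id = names(panel), gene_set = unname(sets),
                         n = as.integer(n_gene),
                         mps = as.numeric(n_gene) / n_samples,
                         stringsAsFactors = FALSE)
  per_gene <- per_gene[order(-per_gene$mps, per_gene$gene_id), ]
  rownames(per_gene) <- NULL
  list(per_sample = unclass(per_sample), per_gene = per_gene)
}

six_type_spectrum <- function(mutations) {
  snv <- mutations[!is.na(mutations$class96) & mutations$var_class == "SNV", ,
                   drop = FALSE]
  type <- substr(snv$class96, 3, 5)
  table(factor(snv$sample_id), factor(type, levels = SBS_TYPES))
}

#' Run the full analysis over one study directory
#'
#' Orchestrates the four analysis stages on file inputs: (1) mutation-table
#' consumption with proximity flagging, phase merging and consequence
#' annotation; (2) selection analysis (dN/dS family and, when a score table
#' is present, the impact-score test); (3) clone-size/occupancy inference for
#' positively selected genes; (4) UV characterization (6- and 96-type
#' spectra, dipyrimidine fraction, strand bias, CC>TT DNV analysis, signature
#' refitting). Writes headered TSV reports plus a run log and returns the
#' results invisibly. Output is deterministic given the seed.
#'
#' @param paths Named list of input paths: `panel`, `metadata`, `mutations`,
#'   `catalogue`, `samples`; optional `scores`, `signatures` (as written by
#'   [simulate_study()]).
#' @param out_dir Output directory.
#' @param seed Integer seed for the impact-score null sampler.
#' @param fdr FDR threshold for selection calls (default 0.1).
#' @param impact_draws Null draws per gene for the impact test.
#' @return List with all result tables, invisibly.
#' @export
run_study <- function(paths, out_dir, seed = 1L, fdr = 0.1,
                      impact_draws = 20000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  note("run_study seed=%d fdr=%.3f", seed, fdr)

  panel <- stage("read_panel", read_panel(paths$panel, paths$metadata))
  raw <- stage("read_mutations", read_mutations(paths$mutations))
  note("inputs: %d genes, %d raw mutation records", length(panel), nrow(raw))

  flagged <- stage("flag_proximal", flag_proximal(raw))
  merged <- stage("merge_phased", merge_phased(raw))
  muts <- stage("annotate", annotate_mutations(merged, panel))
  n_multi <- sum(muts$var_class != "SNV")
  note("merge: %d proximal pairs flagged; %d DNV/MNV records after merging",
       nrow(flagged), n_multi)

  prior <- stage("prior",
                 estimate_prior(read_catalogue(paths$catalogue), "catalogue"))
  burden <- stage("burden", burden_summary(muts, panel))
  spec96 <- compute_spectrum(muts)
  spec6 <- six_type_spectrum(muts)

  sel <- list()
  for (g in c("global", "gene_set", "gene"))
    sel[[g]] <- stage(paste0("selection_", g),
                      run_selection(muts, panel, prior, grouping = g, fdr = fdr))

  impact <- NULL
  if (!is.null(paths$scores) && file.exists(paths$scores)) {
    impact <- stage("impact", run_impact_selection(
      muts, panel, prior, read_score_table(paths$scores), grouping = "gene",
      n_draws = impact_draws, seed = seed, fdr = fdr))
  } else note("impact stage skipped: no score table supplied")

  samples <- stage("samples", read_sample_sheet(paths$samples))
  called <- unique(c(
    sel$gene$scope[!is.na(sel$gene$called) & sel$gene$called],
    if (!is.null(impact)) impact$scope[impact$called]))
  clones <- if (length(called))
    stage("clonality", clone_table(muts, samples, called)) else NULL
  note("clonality: %d positively selected genes", length(called))

  uv <- list(
    dipyrimidine_fraction = tryCatch(dipyrimidine_fraction(muts),
                                     error = function(e) NA_real_),
    strand_bias = tryCatch(strand_bias_test(strand_counts(muts, "C>T")),
                           error = function(e) NULL),
    dnv = tryCatch(dnv_strand_analysis(muts), error = function(e) NULL))
  exposures <- NULL
  if (!is.null(paths$signatures) && file.exists(paths$signatures)) {
    exposures <- stage("signatures", refit_signatures(
      spec96, read_signature_matrix(paths$signatures)))
  } else note("signature stage skipped: no signature matrix supplied")

  # reports
  out <- function(f) file.path(out_dir, f)
  write_report_tsv(muts, out("mutations_annotated.tsv"),
                   "annotated mutation table (post merge)")
  write_report_tsv(burden$per_gene, out("burden_per_gene.tsv"),
                   "per-gene burden; mps = mutations per sample")
  write_report_tsv(data.frame(class = names(spec96),
                              count = as.integer(spec96)),
                   out("spectrum96.tsv"), "96-class spectrum, SNVs only")
  write_report_tsv(as.data.frame.matrix(spec6), out("spectrum6.tsv"),
                   "per-sample 6-type spectrum")
  sel_all <- do.call(rbind, c(
    list(cbind(grouping = "global", sel$global)),
    list(cbind(grouping = "gene_set", sel$gene_set)),
    list(cbind(grouping = "gene", sel$gene))))
  write_report_tsv(sel_all, out("selection_dnds.tsv"), c(
    "context-normalized dN/dS selection tests",
    "test: one-sided binomial, P[X >= n], X ~ Bin(n+s, pi) with",
    "pi = sum(N_i P_i) / (sum(N_i P_i) + sum(S_i P_i));",
    sprintf("BH FDR per metric within grouping; calls at q < %.2f", fdr)))
  if (!is.null(impact))
    write_report_tsv(impact, out("selection_impact.tsv"), c(
      "impact-score selection tests",
      "test: one-sided Wilcoxon rank-sum, observed vs simulated null scores",
      sprintf("null draws per gene: %d; seed %d; BH FDR, calls at q < %.2f",
              impact_draws, seed, fdr)))
  if (!is.null(clones))
    write_report_tsv(clones, out("clone_report.tsv"), c(
      "clone report for positively selected genes",
      "clone size = 2 x VAF x biopsy area (diploid heterozygous)",
      if (length(attr(clones, "excluded_samples")))
        paste("samples excluded (unknown area):",
              paste(attr(clones, "excluded_samples"), collapse = ", "))))
  uv_df <- data.frame(
    statistic = c("dipyrimidine_fraction_CtoT", "strand_ratio",
                  "strand_excess_percent", "strand_p",
                  "dnv_fraction_coding", "dnv_p"),
    value = c(uv$dipyrimidine_fraction,
              if (is.null(uv$strand_bias)) c(NA, NA, NA)
              else c(uv$strand_bias$ratio, uv$strand_bias$excess_percent,
                     uv$strand_bias$p),
              if (is.null(uv$dnv)) c(NA, NA)
              else c(uv$dnv$fraction_coding, uv$dnv$p)))
  write_report_tsv(uv_df, out("uv_characterization.tsv"), c(
    "UV characterization; strand test: exact conditional binomial",
    "(two-sided) on coding vs template pyrimidine counts;",
    "DNV test: one-sided exact binomial on CC>TT coding fraction vs 0.5"))
  if (!is.null(exposures))
    write_report_tsv(data.frame(signature = names(exposures),
                                exposure = as.numeric(exposures)),
                     out("signature_exposures.tsv"),
                     "signature refitting by non-negative least squares")
  note("counts: %d input records = %d analyzed SNVs + %d merged into %d DNV/MNV records",
       nrow(raw), sum(muts$var_class == "SNV"),
       sum(nchar(muts$ref[muts$var_class != "SNV"])), n_multi)
  writeLines(log_lines, log_path)
  invisible(list(panel = panel, mutations = muts, flagged = flagged,
                 prior = prior, burden = burden, spectrum96 = spec96,
                 spectrum6 = spec6, selection = sel, impact = impact,
                 clones = clones, uv = uv, exposures = exposures,
                 log = log_lines))
}
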
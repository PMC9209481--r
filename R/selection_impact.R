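#' Read an impact-score table
#'
#' Tab-separated table mapping substitutions to functional impact scores
#' (e.g. PolyPhen-2-like probabilities of damage), with columns `gene_id`,
#' `pos`, `alt`, `score`. Scores must lie in \[0, 1\].
#'
#' @param path File path.
#' @return Data frame with the four columns.
#' @export
read_score_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "pos", "alt", "score")
  if (!all(req %in% names(df)))
    stop("score table must have columns: ", paste(req, collapse = ", "))
  if (any(df$score < 0 | df$score > 1))
    stop("impact scores must lie in [0, 1]")
  df[req]
}

score_key <- function(gene_id, pos, alt) paste(gene_id, pos, alt, sep = "\r")

lookup_scores <- function(score_table, gene_id, pos, alt) {
  score_table$score[match(score_key(gene_id, pos, alt),
                          score_key(score_table$gene_id, score_table$pos,
                                    score_table$alt))]
}

#' Sample the neutral expected impact-score distribution of a gene
#'
#' Draws random point mutations within the gene, with each possible
#' substitution weighted by the background probability of its substitution
#' class, and returns their impact scores. Only substitutions that have a
#' score are sampled (scores typically exist for missense changes only), so
#' the null is directly comparable to observed scored mutations.
#'
#' @param gene A [gene_model].
#' @param prior A [spectrum_prior].
#' @param score_table Score table (see [read_score_table()]).
#' @param n_draws Number of random mutations to draw (default 1e5).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_draws` scores.
#' @export
sample_expected_scores <- function(gene, prior, score_table,
                                   n_draws = 1e5, seed = NULL) {
  st <- gene_site_table(gene)
  st$score <- lookup_scores(score_table, st$gene_id, st$pos, st$alt)
  st <- st[!is.na(st$score), , drop = FALSE]
  if (!nrow(st))
    stop("gene ", gene$gene_id, " has no scoreable substitutions")
  w <- as.numeric(prior)[match(st$class96, sbs96_labels())]
  if (sum(w) <= 0)
    stop("prior puts no mass on the scoreable substitutions of gene ",
         gene$gene_id)
  if (!is.null(seed)) set.seed(seed)
  st$score[sample.int(nrow(st), n_draws, replace = TRUE, prob = w)]
}

#' Compare observed impact scores with their simulated neutral expectation
#'
#' One-sided Wilcoxon rank-sum test of whether the observed scores are
#' stochastically larger than the expected (simulated) scores, plus the delta
#' statistic: median observed minus median expected.
#'
#' @param observed_scores Non-empty numeric vector of observed scores.
#' @param expected_scores Numeric vector of null scores (e.g. from
#'   [sample_expected_scores()]).
#' @return List with `median_observed`, `median_expected`, `delta`, `p`,
#'   `n_observed`, `n_expected`.
#' @export
impact_test <- function(observed_scores, expected_scores) {
  if (!length(observed_scores))
    stop("observed score set is empty")
  if (!length(expected_scores))
    stop("expected score set is empty")
  p <- wilcox.test(observed_scores, expected_scores,
                   alternative = "greater", exact = NULL)$p.value
  list(median_observed = median(observed_scores),
       median_expected = median(expected_scores),
       delta = median(observed_scores) - median(expected_scores),
       p = p, n_observed = length(observed_scores),
       n_expected = length(expected_scores))
}

#' Run the impact-score selection analysis
#'
#' For each scope (gene or gene set), compares the impact scores of observed
#' mutations against a per-gene simulated neutral score distribution using the
#' one-sided rank-sum test, then applies Benjamini-Hochberg correction within
#' the grouping family. Mutations without a score are excluded from testing
#' and tallied in the `coverage` attribute; scopes without scoreable observed
#' mutations are omitted and listed in the `omitted` attribute.
#'
#' @param mutations Annotated mutation table.
#' @param panel A `gene_panel`.
#' @param prior A [spectrum_prior].
#' @param score_table Score table (see [read_score_table()]).
#' @param grouping `"gene"`, `"gene_set"` or `"global"`.
#' @param n_draws Null draws per gene (default 1e5).
#' @param seed Optional base seed; gene-specific seeds are derived from it.
#' @param fdr FDR threshold (default 0.1).
#' @return Data frame with one row per scope: `scope`, `n_observed`,
#'   `median_observed`, `median_expected`, `delta`, `p`, `q`, `called`;
#'   attributes `coverage` (scored vs unscored counts) and `omitted`.
#' @export
run_impact_selection <- function(mutations, panel, prior, score_table,
                                 grouping = c("gene", "gene_set", "global"),
                                 n_draws = 1e5, seed = NULL, fdr = 0.1) {
  grouping <- match.arg(grouping)
  snv <- mutations[!is.na(mutations$consequence) & mutations$var_class == "SNV", ,
                   drop = FALSE]
  snv$score <- lookup_scores(score_table, snv$gene_id, snv$pos, snv$alt)
  coverage <- c(scored = sum(!is.na(snv$score)),
                unscored = sum(is.na(snv$score)))
  scored <- snv[!is.na(snv$score), , drop = FALSE]
  scopes <- switch(grouping,
    global = list(global = names(panel)),
    gene_set = split(names(panel), vapply(panel, `[[`, "", "gene_set")),
    gene = setNames(as.list(names(panel)), names(panel)))
  omitted <- character(0)
  rows <- list()
  for (sc in names(scopes)) {
    ids <- scopes[[sc]]
    obs <- scored$score[scored$gene_id %in% ids]
    if (!length(obs)) {
      omitted <- c(omitted, sc)
      next
    }
    # pool per-gene nulls, draws allocated by each gene's prior-weighted
    # scoreable mass so the pooled null matches random mutagenesis of the scope
    genes_with <- ids[ids %in% unique(score_table$gene_id)]
    masses <- vapply(genes_with, function(g) {
      st <- gene_site_table(panel[[g]])
      s <- lookup_scores(score_table, st$gene_id, st$pos, st$alt)
      sum(as.numeric(prior)[match(st$class96[!is.na(s)], sbs96_labels())])
    }, numeric(1))
    genes_with <- genes_with[masses > 0]
    masses <- masses[masses > 0]
    if (!length(genes_with)) {
      omitted <- c(omitted, sc)
      next
    }
    alloc <- as.vector(rmultinom2(n_draws, masses / sum(masses),
                                  seed = if (is.null(seed)) NULL
                                         else seed + match(sc, names(scopes))))
    expected <- unlist(lapply(seq_along(genes_with), function(i) {
      if (alloc[i] == 0) return(numeric(0))
      sample_expected_scores(panel[[genes_with[i]]], prior, score_table,
                             n_draws = alloc[i],
                             seed = if (is.null(seed)) NULL
                                    else seed + 1000L + match(sc, names(scopes)) + i)
    }), use.names = FALSE)
    t <- impact_test(obs, expected)
    rows[[sc]] <- data.frame(scope = sc, n_observed = t$n_observed,
                             median_observed = t$median_observed,
                             median_expected = t$median_expected,
                             delta = t$delta, p = t$p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no scope has scoreable observed mutations")
  res <- do.call(rbind, rows)
  adj <- bh_fdr(res$p, threshold = fdr)
  res$q <- adj$q
  res$called <- adj$called
  rownames(res) <- NULL
  attr(res, "coverage") <- coverage
  attr(res, "omitted") <- omitted
  res
}

rmultinom2 <- function(n, prob, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rmultinom(1, n, prob)
}
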
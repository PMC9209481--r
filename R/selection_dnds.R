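#' Count synonymous and nonsynonymous sites per substitution class
#'
#' Assigns every one of the 3L possible single-base substitutions of a gene to
#' a substitution class and a consequence, producing the per-class counts of
#' synonymous (S_i), missense, nonsense and stoploss sites that enter the
#' dN/dS expectation. Nonsynonymous sites N_i are missense + nonsense +
#' stoploss.
#'
#' @param gene A [gene_model], or a site table from [gene_site_table()] /
#'   pooled tables for a gene set.
#' @return Integer matrix 96 x 4 with columns `syn`, `missense`, `nonsense`,
#'   `stoploss` and class labels as rownames (class `site_counts`).
#' @export
enumerate_sites <- function(gene) {
  st <- if (inherits(gene, "gene_model")) gene_site_table(gene) else gene
  labels <- sbs96_labels()
  cons_levels <- c(syn = "synonymous", missense = "missense",
                   nonsense = "nonsense", stoploss = "stoploss")
  m <- table(factor(st$class96, levels = labels),
             factor(st$consequence, levels = cons_levels))
  m <- matrix(as.integer(m), nrow = 96L,
              dimnames = list(labels, names(cons_levels)))
  structure(m, class = c("site_counts", "matrix"))
}

site_counts_n <- function(sites, metric = c("all", "missense", "nonsense")) {
  metric <- match.arg(metric)
  switch(metric,
         all = rowSums(sites[, c("missense", "nonsense", "stoploss")]),
         missense = sites[, "missense"],
         nonsense = sites[, "nonsense"])
}

#' Prior-weighted expected nonsynonymous/synonymous site ratio
#'
#' Computes `sum_i(N_i P_i) / sum_i(S_i P_i)`: the ratio of nonsynonymous to
#' synonymous mutations expected under the background substitution-class
#' probabilities P_i in the absence of selection. Substituting missense or
#' nonsense site counts for N_i yields the expectations for the restricted
#' statistics dMiss/dS and dNons/dS.
#'
#' @param sites A `site_counts` matrix from [enumerate_sites()].
#' @param prior A [spectrum_prior].
#' @param metric `"all"`, `"missense"` or `"nonsense"` numerator sites.
#' @return Scalar expected ratio.
#' @export
expected_ns_ratio <- function(sites, prior, metric = "all") {
  p <- as.numeric(prior)
  s_mass <- sum(sites[, "syn"] * p)
  if (s_mass <= 0)
    stop("prior puts no mass on synonymous sites; expected ratio undefined")
  sum(site_counts_n(sites, metric) * p) / s_mass
}

#' Context-normalized dN/dS statistic
#'
#' The observed nonsynonymous/synonymous mutation ratio divided by its
#' expectation under the background model: `(n/s) / (sum N_i P_i / sum S_i
#' P_i)`. Values above 1 indicate an excess of nonsynonymous mutations, i.e.
#' positive selection.
#'
#' @param n Observed nonsynonymous (or missense/nonsense) mutation count.
#' @param s Observed synonymous mutation count (> 0).
#' @param expected_ratio Expected ratio from [expected_ns_ratio()].
#' @return Scalar dN/dS.
#' @export
global_dnds <- function(n, s, expected_ratio) {
  if (s <= 0)
    stop("dN/dS is undefined with zero observed synonymous mutations")
  if (expected_ratio <= 0)
    stop("expected ratio must be positive")
  (n / s) / expected_ratio
}

#' Fraction of nonsynonymous mutations attributable to positive selection
#'
#' Under a dN/dS of d > 1, a fraction (d - 1)/d of the observed nonsynonymous
#' mutations exceeds the neutral expectation; values at or below 1 give 0.
#'
#' @param dnds A dN/dS value (> 0).
#' @return Fraction in \[0, 1).
#' @export
selection_excess_fraction <- function(dnds) {
  if (dnds <= 0)
    stop("dN/dS must be positive")
  max(0, (dnds - 1) / dnds)
}

#' One-sided binomial test for dN/dS above 1
#'
#' Under neutrality each observed mutation is nonsynonymous with probability
#' `pi = sum(N_i P_i) / (sum(N_i P_i) + sum(S_i P_i))`. The test computes
#' `P[X >= n]` for `X ~ Binomial(n + s, pi)`. For the missense or nonsense
#' variants, N is replaced by the corresponding site counts and n by the
#' submetric mutation count (s unchanged).
#'
#' @param n Observed numerator mutation count.
#' @param s Observed synonymous count.
#' @param sites `site_counts` for the tested scope.
#' @param prior A [spectrum_prior].
#' @param metric `"all"`, `"missense"` or `"nonsense"`.
#' @return One-sided p-value.
#' @export
binomial_selection_test <- function(n, s, sites, prior, metric = "all") {
  if (n + s <= 0)
    stop("binomial selection test needs at least one observed mutation")
  p <- as.numeric(prior)
  num <- sum(site_counts_n(sites, metric) * p)
  den <- num + sum(sites[, "syn"] * p)
  if (den <= 0)
    stop("neutral nonsynonymous probability is undefined")
  pbinom(n - 1L, size = n + s, prob = num / den, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with selection calls
#'
#' @param pvalues Vector of p-values in (0, 1\].
#' @param threshold FDR threshold for calls (default 0.1).
#' @return Data frame with `p`, `q` and logical `called`.
#' @export
bh_fdr <- function(pvalues, threshold = 0.1) {
  if (any(is.na(pvalues)) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  q <- p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, called = q < threshold)
}

scope_selection <- function(scope, muts, sites, prior, metrics) {
  s <- sum(muts$consequence == "synonymous")
  do.call(rbind, lapply(metrics, function(metric) {
    n <- switch(metric,
                all = sum(muts$consequence != "synonymous"),
                missense = sum(muts$consequence == "missense"),
                nonsense = sum(muts$consequence == "nonsense"))
    er <- tryCatch(expected_ns_ratio(sites, prior, metric), error = function(e) NA_real_)
    stat <- if (s > 0 && !is.na(er) && er > 0) (n / s) / er else NA_real_
    p <- if (n + s > 0 && !is.na(er))
      tryCatch(binomial_selection_test(n, s, sites, prior, metric),
               error = function(e) NA_real_) else NA_real_
    data.frame(scope = scope, metric = c(all = "dN/dS", missense = "dMiss/dS",
                                         nonsense = "dNons/dS")[[metric]],
               n = n, s = s, expected_ratio = er, statistic = stat, p = p,
               stringsAsFactors = FALSE)
  }))
}

#' Run the dN/dS selection analysis over a mutation table
#'
#' Pools annotated SNVs (DNV/MNV records are excluded), counts observed
#' synonymous and nonsynonymous mutations per scope, normalizes by the
#' prior-weighted site ratio, and applies the one-sided binomial test with
#' Benjamini-Hochberg correction. FDR adjustment is performed per metric
#' within each grouping family.
#'
#' @param mutations Annotated mutation table.
#' @param panel A `gene_panel`.
#' @param prior A [spectrum_prior].
#' @param grouping `"global"`, `"gene_set"` or `"gene"`.
#' @param metrics Subset of `c("all", "missense", "nonsense")`.
#' @param fdr FDR threshold for calls (default 0.1).
#' @return Data frame with one row per scope x metric: `scope`, `metric`,
#'   `n`, `s`, `expected_ratio`, `statistic`, `p`, `q`, `called`.
#' @export
run_selection <- function(mutations, panel, prior,
                          grouping = c("global", "gene_set", "gene"),
                          metrics = c("all", "missense", "nonsense"),
                          fdr = 0.1) {
  grouping <- match.arg(grouping)
  metrics <- match.arg(metrics, several.ok = TRUE)
  snv <- mutations[!is.na(mutations$consequence) & mutations$var_class == "SNV", ,
                   drop = FALSE]
  gene_sites <- lapply(panel, enumerate_sites)
  pool_sites <- function(ids) {
    m <- Reduce(`+`, lapply(gene_sites[ids], unclass))
    structure(m, class = c("site_counts", "matrix"))
  }
  scopes <- switch(grouping,
    global = list(global = names(panel)),
    gene_set = {
      sets <- vapply(panel, `[[`, "", "gene_set")
      split(names(panel), sets)
    },
    gene = setNames(as.list(names(panel)), names(panel)))
  res <- do.call(rbind, lapply(names(scopes), function(sc) {
    ids <- scopes[[sc]]
    scope_selection(sc, snv[snv$gene_id %in% ids, , drop = FALSE],
                    pool_sites(ids), prior, metrics)
  }))
  res$q <- NA_real_
  res$called <- NA
  for (m in unique(res$metric)) {
    i <- which(res$metric == m & !is.na(res$p))
    if (length(i)) {
      adj <- bh_fdr(res$p[i], threshold = fdr)
      res$q[i] <- adj$q
      res$called[i] <- adj$called
    }
  }
  rownames(res) <- NULL
  res
}
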
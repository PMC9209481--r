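# Independent oracles used to validate the package's own implementations.
# They deliberately take different code paths: translation via seqinr, class
# normalization via Biostrings reverse complement, tail probabilities via
# explicit log-binomial sums, and rank-sum p-values via exhaustive
# enumeration.

oracle_translate <- function(seq) {
  paste(seqinr::translate(seqinr::s2c(seq)), collapse = "")
}

# consequence of a substitution by translating the whole mutated CDS
oracle_consequence <- function(cds, pos, alt) {
  mut <- cds
  substr(mut, pos, pos) <- alt
  aa_old <- oracle_translate(cds)
  aa_new <- oracle_translate(mut)
  ci <- (pos - 1) %/% 3 + 1
  o <- substr(aa_old, ci, ci)
  n <- substr(aa_new, ci, ci)
  if (o == n) "synonymous"
  else if (o != "*" && n == "*") "nonsense"
  else if (o == "*" && n != "*") "stoploss"
  else "missense"
}

oracle_class96 <- function(context, ref, alt) {
  if (ref %in% c("A", "G")) {
    context <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(context)))
    ref <- as.character(Biostrings::complement(Biostrings::DNAString(ref)))
    alt <- as.character(Biostrings::complement(Biostrings::DNAString(alt)))
  }
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
}

# brute-force site counts: loop over every position and alternate base
oracle_site_counts <- function(gene) {
  labels <- sbs96_labels()
  m <- matrix(0L, 96, 4, dimnames = list(labels, c("syn", "missense",
                                                   "nonsense", "stoploss")))
  cds <- gene$cds
  L <- nchar(cds)
  for (pos in seq_len(L)) {
    ref <- substr(cds, pos, pos)
    prev <- if (pos == 1) gene$flank5 else substr(cds, pos - 1, pos - 1)
    nxt <- if (pos == L) gene$flank3 else substr(cds, pos + 1, pos + 1)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      cls <- oracle_class96(paste0(prev, ref, nxt), ref, alt)
      cons <- oracle_consequence(cds, pos, alt)
      col <- c(synonymous = "syn", missense = "missense",
               nonsense = "nonsense", stoploss = "stoploss")[[cons]]
      m[cls, col] <- m[cls, col] + 1L
    }
  }
  m
}

# upper-tail binomial probability P[X >= k] by explicit log-space summation
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# two-sided exact binomial p: sum of outcome probabilities not exceeding the
# observed outcome's probability (within a relative tolerance)
oracle_binom_two_sided <- function(k, n, p = 0.5) {
  d <- exp(lchoose(n, 0:n) + (0:n) * log(p) + (n - 0:n) * log1p(-p))
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

# one-sided rank-sum p by exhaustive enumeration of group assignments:
# probability that a random split gives a rank sum at least as large as the
# observed one for the first group
oracle_ranksum_greater <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  sets <- utils::combn(length(pooled), length(x))
  mean(apply(sets, 2, function(i) sum(r[i])) >= w_obs - 1e-9)
}

random_gene <- function(n_codons, gene_set = "driver",
                        id = paste0("g", n_codons)) {
  body <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE),
                               c("TAA", "TAG", "TGA")),
                       n_codons - 2, replace = TRUE), collapse = "")
  gene_model(id, paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1)),
             flank5 = sample(c("A", "C", "G", "T"), 1),
             flank3 = sample(c("A", "C", "G", "T"), 1),
             gene_set = gene_set)
}

uniform_prior <- function() {
  spectrum_prior(rep(1 / 96, 96), "uniform")
}

# minimal three-codon gene used across examples
toy_gene <- function() gene_model("g1", "ATGGAATAA", flank5 = "A", flank3 = "A")
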
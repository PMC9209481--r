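#' Substitution-class prior
#'
#' Wraps a probability vector over the 96 trinucleotide substitution classes,
#' used to weight site counts in the dN/dS expectation and to drive the
#' impact-score null sampler.
#'
#' @param p Numeric vector of length 96, non-negative, summing to 1 (within
#'   1e-9). Named vectors are reordered to [sbs96_labels()]; unnamed vectors
#'   are assumed to already be in that order.
#' @param source_label Free-text provenance label (e.g. `"SKCM-like"`).
#' @return Named numeric vector of class `spectrum_prior`.
#' @export
spectrum_prior <- function(p, source_label = "unspecified") {
  labels <- sbs96_labels()
  if (length(p) != 96L)
    stop("a spectrum prior must have 96 entries")
  if (!is.null(names(p))) {
    if (!setequal(names(p), labels))
      stop("prior names must be the 96 class labels")
    p <- p[labels]
  } else names(p) <- labels
  if (any(p < 0))
    stop("prior probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("prior probabilities must sum to 1")
  structure(p, class = c("spectrum_prior", "numeric"),
            source_label = source_label)
}

#' Tabulate the 96-class mutation spectrum of a mutation table
#'
#' Counts annotated SNVs per substitution class; DNV/MNV records are excluded.
#'
#' @param mutations Annotated mutation table (see [annotate_mutations()]).
#' @return Named integer vector of length 96 with attribute `n_snv`.
#' @export
compute_spectrum <- function(mutations) {
  labels <- sbs96_labels()
  snv <- mutations[!is.na(mutations$class96) & mutations$var_class == "SNV", ,
                   drop = FALSE]
  counts <- table(factor(snv$class96, levels = labels))
  out <- setNames(as.integer(counts), labels)
  attr(out, "n_snv") <- sum(out)
  out
}

#' Estimate substitution-class prior probabilities from a mutation catalogue
#'
#' Computes the empirical frequency of each of the 96 classes in a reference
#' catalogue (e.g. a cutaneous-melanoma-like or head-and-neck-like mutation
#' set), to serve as the background substitution probabilities P_i. Classes
#' absent from the catalogue get probability 0; no pseudo-count is added.
#'
#' @param catalogue Data frame with columns `context`, `ref`, `alt` (SNVs).
#' @param source_label Provenance label stored on the result.
#' @return A [spectrum_prior].
#' @export
estimate_prior <- function(catalogue, source_label = "catalogue") {
  if (!nrow(catalogue))
    stop("cannot estimate a prior from an empty catalogue")
  cls <- classify_96(catalogue$context, catalogue$ref, catalogue$alt)
  counts <- table(factor(cls, levels = sbs96_labels()))
  spectrum_prior(as.numeric(counts) / sum(counts), source_label)
}

is_pyrimidine <- function(b) b %in% c("C", "T")

#' Fraction of C>T substitutions in a dipyrimidine context
#'
#' A C>T substitution (or G>A, which is C>T on the opposite strand) counts as
#' dipyrimidine if, on the strand carrying the mutated pyrimidine, the 5' or
#' 3' neighboring base is also a pyrimidine. Dipyrimidine sites are the
#' substrate of UV-induced pyrimidine dimers, so a high fraction is a UV
#' hallmark.
#'
#' @param mutations Annotated mutation table; only C>T-class SNVs are used.
#' @return Fraction in \[0, 1\].
#' @export
dipyrimidine_fraction <- function(mutations) {
  snv <- mutations[!is.na(mutations$class96) & mutations$var_class == "SNV", ,
                   drop = FALSE]
  ct <- snv[grepl("\\[C>T\\]", snv$class96), , drop = FALSE]
  if (!nrow(ct))
    stop("no C>T substitutions: dipyrimidine fraction is undefined")
  f5 <- substr(ct$class96, 1, 1)
  f3 <- substr(ct$class96, 7, 7)
  mean(is_pyrimidine(f5) | is_pyrimidine(f3))
}

#' Count pyrimidine strand placement of substitutions
#'
#' For each SNV of the requested substitution type, records whether the
#' mutated pyrimidine lies on the coding (untranscribed) or template
#' (transcribed) strand: a pyrimidine reference base on the coding strand
#' counts as coding, a purine reference (pyrimidine on the opposite strand)
#' as template.
#'
#' @param mutations Annotated mutation table.
#' @param type Pyrimidine substitution type, e.g. `"C>T"`; `NULL` for all
#'   SNVs.
#' @return List with integer `coding` and `template` counts.
#' @export
strand_counts <- function(mutations, type = "C>T") {
  snv <- mutations[!is.na(mutations$class96) & mutations$var_class == "SNV", ,
                   drop = FALSE]
  if (!is.null(type))
    snv <- snv[grepl(paste0("\\[", type, "\\]"), snv$class96), , drop = FALSE]
  coding <- sum(is_pyrimidine(snv$ref))
  list(coding = coding, template = nrow(snv) - coding)
}

#' Exact test for transcriptional strand bias
#'
#' Compares the number of substitutions with the pyrimidine on the coding
#' strand against the template strand. Treating the two counts as independent
#' Poisson counts, the exact conditional test of equal rates is the exact
#' binomial test on coding successes out of (coding + template) trials with
#' success probability 0.5.
#'
#' @param coding,template Non-negative strand counts, not both zero. `coding`
#'   may also be the list returned by [strand_counts()].
#' @param alternative Sidedness of the test (default two-sided).
#' @return List with `ratio` (coding/template), `excess_percent`
#'   (100 x (ratio - 1)) and `p`.
#' @export
strand_bias_test <- function(coding, template = NULL,
                             alternative = c("two.sided", "greater", "less")) {
  if (is.list(coding)) { template <- coding$template; coding <- coding$coding }
  alternative <- match.arg(alternative)
  if (coding < 0 || template < 0)
    stop("strand counts must be non-negative")
  if (coding + template == 0)
    stop("strand bias is undefined when both counts are zero")
  ratio <- coding / template
  list(coding = coding, template = template, ratio = ratio,
       excess_percent = 100 * (ratio - 1),
       p = binom.test(coding, coding + template, p = 0.5,
                      alternative = alternative)$p.value)
}

#' Strand analysis of CC>TT dinucleotide variants
#'
#' CC>TT dinucleotide variants are a UV hallmark arising from pyrimidine
#' dimers; their strand placement reveals transcription-coupled repair. A DNV
#' with reference `CC` (alternate `TT`) carries its pyrimidines on the coding
#' strand; `GG>AA` is the template-strand equivalent. Tests the fraction on
#' the coding strand against 0.5 with a one-sided exact binomial test.
#'
#' @param mutations Mutation table containing DNV records (after
#'   [merge_phased()] and [annotate_mutations()]).
#' @return List with `n_coding`, `n_template`, `fraction_coding` and `p`.
#' @export
dnv_strand_analysis <- function(mutations) {
  dnv <- mutations[mutations$var_class == "DNV", , drop = FALSE]
  n_coding <- sum(dnv$ref == "CC" & dnv$alt == "TT")
  n_template <- sum(dnv$ref == "GG" & dnv$alt == "AA")
  n <- n_coding + n_template
  if (n == 0)
    stop("no CC>TT dinucleotide variants found")
  list(n_coding = n_coding, n_template = n_template,
       fraction_coding = n_coding / n,
       p = binom.test(n_coding, n, p = 0.5, alternative = "greater")$p.value)
}

#' Refit known mutational signatures to an observed spectrum
#'
#' Estimates the contribution (exposure) of each known signature to an
#' observed 96-class spectrum by non-negative least squares on the frequency
#' vector, with exposures renormalized to proportions summing to 1. This is
#' refitting against a fixed signature matrix, not de novo extraction.
#'
#' @param spectrum Named 96-vector of counts or frequencies (e.g. from
#'   [compute_spectrum()]); must be non-zero.
#' @param signatures Numeric matrix with 96 rows (class labels as rownames)
#'   and one column per signature, each column a probability vector summing
#'   to 1 (within 1e-6).
#' @return Named numeric vector of exposure proportions with attribute
#'   `residual` (Euclidean norm of the frequency-space residual).
#' @export
refit_signatures <- function(spectrum, signatures) {
  labels <- sbs96_labels()
  if (sum(spectrum) <= 0)
    stop("cannot refit signatures to an empty spectrum")
  if (!is.null(names(spectrum))) spectrum <- spectrum[labels]
  signatures <- as.matrix(signatures)
  if (nrow(signatures) != 96L)
    stop("signature matrix must have 96 rows")
  if (!is.null(rownames(signatures))) signatures <- signatures[labels, , drop = FALSE]
  csums <- colSums(signatures)
  if (any(csums == 0))
    stop("signature matrix contains a zero column")
  if (any(abs(csums - 1) > 1e-6))
    stop("signature columns must each sum to 1")
  freq <- as.numeric(spectrum) / sum(spectrum)
  fit <- pracma::lsqnonneg(signatures, freq)
  x <- fit$x
  if (sum(x) == 0)
    stop("non-negative least squares returned an all-zero exposure vector")
  exposures <- setNames(x / sum(x), colnames(signatures))
  attr(exposures, "residual") <- sqrt(sum((freq - signatures %*% x)^2))
  exposures
}

#' Read / write a signature matrix as TSV
#'
#' The TSV has the 96 class labels in the first column (`class`) in the
#' conventional class order and one named column per signature.
#'
#' @param path File path.
#' @return `read_signature_matrix`: numeric matrix 96 x signatures.
#' @export
read_signature_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!setequal(rownames(m), sbs96_labels()))
    stop("signature matrix rows must be the 96 class labels")
  m[sbs96_labels(), , drop = FALSE]
}

#' @rdname read_signature_matrix
#' @param signatures Matrix as returned by [read_signature_matrix()].
#' @export
write_signature_matrix <- function(signatures, path) {
  df <- data.frame(class = rownames(signatures), signatures,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
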
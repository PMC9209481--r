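#' @importFrom stats median p.adjust pbinom rbeta rbinom runif rpois setNames
#'   wilcox.test binom.test rmultinom
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")
SBS_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(strsplit(comp_base(x), ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' The 96 trinucleotide substitution class labels
#'
#' Labels of the pyrimidine-centered trinucleotide substitution classes in the
#' conventional order: the six pyrimidine substitution types (C>A, C>G, C>T,
#' T>A, T>C, T>G) each expanded over the 16 flanking-base combinations, 5'
#' flank varying before 3' flank. Labels have the form `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
sbs96_labels <- function() {
  grid <- expand.grid(f3 = DNA_BASES, f5 = DNA_BASES, type = SBS_TYPES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$type, SBS_TYPES), grid$f5, grid$f3), ]
  paste0(grid$f5, "[", grid$type, "]", grid$f3)
}

#' Map a substitution in trinucleotide context to its 96-class label
#'
#' Purine-centered substitutions are mapped by reverse complement onto the
#' pyrimidine-centered strand, so that every possible single-base substitution
#' lands in exactly one of the 96 classes. The map is strand-involutive:
#' classifying the reverse complement of a substitution gives the same class.
#'
#' @param context 3-mer context on the coding strand, centered on the mutated
#'   base.
#' @param ref,alt Reference and alternate base (single characters). `context`
#'   must have `ref` as its middle base.
#' @return Character vector of class labels, e.g. `"T[C>T]A"`.
#' @examples
#' classify_96("ACA", "C", "T")  # "A[C>T]A"
#' classify_96("TGT", "G", "A")  # same class via reverse complement
#' @export
classify_96 <- function(context, ref, alt) {
  n <- max(length(context), length(ref), length(alt))
  context <- rep_len(toupper(context), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(nchar(context) != 3L))
    stop("context must be a 3-mer")
  bad <- !grepl("^[ACGT]{3}$", context) | !(ref %in% DNA_BASES) |
    !(alt %in% DNA_BASES)
  if (any(bad))
    stop("context, ref and alt must contain only A/C/G/T")
  if (any(substr(context, 2, 2) != ref))
    stop("context center does not match ref")
  if (any(ref == alt))
    stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    context[flip] <- revcomp(context[flip])
    ref[flip] <- comp_base(ref[flip])
    alt[flip] <- comp_base(alt[flip])
  }
  labels <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
                   substr(context, 3, 3))
  stopifnot(all(labels %in% sbs96_labels()))
  labels
}

#' Cosine similarity between two non-negative spectra
#'
#' @param u,v Numeric vectors of equal length; at least one non-zero entry
#'   each. For non-negative inputs the value lies in \[0, 1\].
#' @return Scalar cosine similarity `u.v / (|u| |v|)`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("cosine similarity is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}
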
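#' Read barcoded amplicon reads from FASTQ
#'
#' The molecular barcode (UMI) is carried either as a fixed-length prefix of
#' the read sequence (`barcode_len` given; the prefix is stripped from the
#' returned read) or in the read header after a `UMI:` tag.
#'
#' @param path FASTQ file path.
#' @param barcode_len Length of the leading barcode, or `NULL` to parse
#'   `UMI:<barcode>` from headers.
#' @return Data frame with `read_id`, `barcode`, `seq`.
#' @export
read_barcoded_fastq <- function(path, barcode_len = NULL) {
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- names(reads)
  seqs <- as.character(reads)
  if (!is.null(barcode_len)) {
    if (any(nchar(seqs) <= barcode_len))
      stop("reads shorter than the barcode length")
    barcode <- substr(seqs, 1L, barcode_len)
    seqs <- substring(seqs, barcode_len + 1L)
  } else {
    m <- regmatches(ids, regexpr("UMI:[ACGTN]+", ids))
    if (length(m) != length(ids))
      stop("reads without a UMI: tag in the header")
    barcode <- sub("^UMI:", "", m)
  }
  data.frame(read_id = sub("\\s.*$", "", ids), barcode = barcode, seq = seqs,
             stringsAsFactors = FALSE)
}

#' Group reads into barcode families
#'
#' One family per distinct barcode; input read order is preserved within each
#' family, and every read belongs to exactly one family.
#'
#' @param reads Data frame with columns `barcode` and `seq` (e.g. from
#'   [read_barcoded_fastq()]).
#' @return Named list of character vectors (read sequences) keyed by barcode.
#' @export
group_families <- function(reads) {
  if (!all(c("barcode", "seq") %in% names(reads)))
    stop("reads must have columns barcode and seq")
  if (!nrow(reads)) return(structure(list(), names = character(0)))
  if (any(is.na(reads$barcode) | reads$barcode == ""))
    stop("reads with a missing barcode")
  split(reads$seq, factor(reads$barcode, levels = unique(reads$barcode)))
}

#' Call a consensus sequence for one barcode family
#'
#' Applies the family-consensus acceptance rules: families with fewer than 10
#' reads are rejected; families of 10-20 reads are accepted only if all reads
#' are identical; families with more than 20 reads are accepted if the most
#' frequent read sequence accounts for at least 90% of reads (ties for the
#' most frequent sequence are rejected). The consensus is the (plurality)
#' read sequence.
#'
#' @param reads Character vector of equal-length read sequences.
#' @return List with `accepted` (logical), `consensus` (sequence or `NA`),
#'   `size`, and `reason` for rejections.
#' @export
call_consensus <- function(reads) {
  n <- length(reads)
  if (!n) stop("empty barcode family")
  if (length(unique(nchar(reads))) != 1L)
    stop("reads in a family must have equal length")
  if (n < 10L)
    return(list(accepted = FALSE, consensus = NA_character_, size = n,
                reason = "fewer than 10 reads"))
  tab <- sort(table(reads), decreasing = TRUE)
  if (n <= 20L) {
    if (length(tab) == 1L)
      return(list(accepted = TRUE, consensus = names(tab), size = n,
                  reason = NA_character_))
    return(list(accepted = FALSE, consensus = NA_character_, size = n,
                reason = "discordant reads in a family of <= 20"))
  }
  if (length(tab) > 1L && tab[1] == tab[2])
    return(list(accepted = FALSE, consensus = NA_character_, size = n,
                reason = "tie for the plurality read"))
  if (tab[1] / n >= 0.9)
    return(list(accepted = TRUE, consensus = names(tab)[1], size = n,
                reason = NA_character_))
  list(accepted = FALSE, consensus = NA_character_, size = n,
       reason = "plurality read below 90%")
}

#' Call consensus over all families
#'
#' @param families Named list from [group_families()].
#' @return Data frame with `barcode`, `size`, `accepted`, `consensus`,
#'   `reason`.
#' @export
consensus_families <- function(families) {
  rows <- lapply(names(families), function(b) {
    cc <- call_consensus(families[[b]])
    data.frame(barcode = b, size = cc$size, accepted = cc$accepted,
               consensus = cc$consensus, reason = cc$reason,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(barcode = character(), size = integer(),
                  accepted = logical(), consensus = character(),
                  reason = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Define an amplicon hotspot
#'
#' Describes a hotspot window within a (synthetic) reference amplicon: the
#' reference sequence, the UV-susceptible motif it must contain, and the
#' positions expected to mutate (C>T at ETS-motif hotspots).
#'
#' @param amplicon_id Identifier (free text, e.g. including the genomic
#'   coordinates the amplicon emulates).
#' @param ref Reference amplicon sequence.
#' @param mut_pos Integer vector of 1-based mutant positions within `ref`.
#' @param alt Alternate base expected at the mutant positions (default "T").
#' @param motif Motif that must occur in `ref` (default the ETS site
#'   "CTTCCGG").
#' @return List of class `hotspot_def`.
#' @export
hotspot_def <- function(amplicon_id, ref, mut_pos, alt = "T",
                        motif = "CTTCCGG") {
  ref <- toupper(ref)
  if (!grepl(motif, ref, fixed = TRUE))
    stop("reference amplicon does not contain the motif ", motif)
  if (any(mut_pos < 1L | mut_pos > nchar(ref)))
    stop("mutant positions outside the amplicon")
  structure(list(amplicon_id = amplicon_id, ref = ref,
                 mut_pos = as.integer(mut_pos), alt = alt, motif = motif),
            class = "hotspot_def")
}

#' Quantify hotspot VAF from consensus reads
#'
#' The VAF at each hotspot position is the fraction of accepted consensus
#' reads carrying the alternate base, i.e. the fraction of original molecules
#' estimated to be mutant after barcode-family error suppression.
#'
#' @param consensus Data frame from [consensus_families()] (or a character
#'   vector of consensus sequences).
#' @param hotspot A [hotspot_def].
#' @return Data frame with `amplicon`, `position`, `ref`, `alt`,
#'   `n_mut_families`, `n_families`, `vaf`.
#' @export
hotspot_vaf <- function(consensus, hotspot) {
  seqs <- if (is.data.frame(consensus))
    consensus$consensus[consensus$accepted] else consensus
  if (!length(seqs))
    stop("no accepted consensus reads")
  if (any(nchar(seqs) != nchar(hotspot$ref)))
    stop("consensus length does not match the reference amplicon")
  rows <- lapply(hotspot$mut_pos, function(p) {
    obs <- substr(seqs, p, p)
    data.frame(amplicon = hotspot$amplicon_id, position = p,
               ref = substr(hotspot$ref, p, p), alt = hotspot$alt,
               n_mut_families = sum(obs == hotspot$alt),
               n_families = length(seqs),
               vaf = mean(obs == hotspot$alt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Built-in synthetic promoter hotspot fixtures
#'
#' Synthetic amplicon windows emulating the RPL13A and DPH3 promoter UV
#' hotspots (named after the genomic windows they stand in for,
#' chr19:49,487,384-49,487,466 and chr3:16,264,961-16,265,030). The sequences
#' are synthetic constructs containing the ETS CTTCCGG motif at which C>T
#' hotspot mutations occur; they are not genomic sequence.
#'
#' @return A [hotspot_def].
#' @export
rpl13a_hotspot <- function() {
  # CTTCCGG motif at offset 21; hotspot C positions 21 and 24 (the motif Cs)
  ref <- paste0("ACGGATTAGCAGGTGAACTA", "CTTCCGG", "TAGGCATTAACGGATCCATG",
                "AGGTTACAGCTAGGAT")
  hotspot_def("RPL13A_promoter_synthetic(chr19:49487384-49487466)",
              ref, mut_pos = c(21L, 24L))
}

#' @rdname rpl13a_hotspot
#' @export
dph3_hotspot <- function() {
  ref <- paste0("TTGACCAGGATCAAG", "CTTCCGG", "ATCCGAAGGTTTACCAGGTCAAGGTCA")
  hotspot_def("DPH3_promoter_synthetic(chr3:16264961-16265030)",
              ref, mut_pos = c(16L, 19L))
}
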
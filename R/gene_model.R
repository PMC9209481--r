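STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (any(is.na(aa)))
    stop("invalid codon: ", paste(codon[is.na(aa)], collapse = ", "))
  unname(aa)
}

#' Construct a gene model
#'
#' A gene model holds one coding sequence (CDS, including the terminal stop
#' codon) together with single-base flanking context at both CDS edges, its
#' strand relative to the reference used for context, and the gene-set label
#' used by the selection analyses.
#'
#' @param gene_id Gene identifier.
#' @param cds Coding sequence (A/C/G/T), length at least 6 and divisible by 3,
#'   ending in a stop codon.
#' @param flank5,flank3 Single bases giving the coding-strand context just
#'   outside the CDS.
#' @param strand `"+"` or `"-"`.
#' @param gene_set One of `"driver"`, `"immune"`, `"housekeeping"`.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, cds, flank5 = "A", flank3 = "A",
                       strand = "+", gene_set = "driver") {
  cds <- toupper(cds)
  if (!grepl("^[ACGT]+$", cds))
    stop("gene ", gene_id, ": CDS contains non-ACGT characters")
  if (nchar(cds) < 6L || nchar(cds) %% 3L != 0L)
    stop("gene ", gene_id, ": CDS length must be >= 6 and divisible by 3, got ",
         nchar(cds))
  if (!all(c(flank5, flank3) %in% DNA_BASES))
    stop("gene ", gene_id, ": flanks must be single A/C/G/T bases")
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": strand must be '+' or '-'")
  gene_set <- match.arg(gene_set, c("driver", "immune", "housekeeping"))
  structure(list(gene_id = gene_id, cds = cds, flank5 = flank5,
                 flank3 = flank3, strand = strand, gene_set = gene_set),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s, %s strand): %d bp CDS\n",
              x$gene_id, x$gene_set, x$strand, nchar(x$cds)))
  invisible(x)
}

#' Read a gene panel from FASTA plus a metadata table
#'
#' The FASTA holds one record per gene (record id = gene id) containing the
#' CDS. The tab-separated metadata table must have columns `gene_id` and
#' `gene_set`, and may carry optional `strand`, `flank5` and `flank3` columns
#' (defaults `"+"`, `"A"`, `"A"`). Every FASTA record must have a metadata row
#' and vice versa.
#'
#' @param fasta_path Path to the CDS FASTA.
#' @param metadata_path Path to the metadata TSV.
#' @return A named list of [gene_model] objects (class `gene_panel`).
#' @export
read_panel <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "gene_set") %in% names(meta)))
    stop("metadata must have columns gene_id and gene_set")
  if (anyDuplicated(ids))
    stop("duplicate FASTA record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing_meta <- setdiff(ids, meta$gene_id)
  if (length(missing_meta))
    stop("no metadata row for gene(s): ", paste(missing_meta, collapse = ", "))
  missing_seq <- setdiff(meta$gene_id, ids)
  if (length(missing_seq))
    stop("no FASTA record for gene(s): ", paste(missing_seq, collapse = ", "))
  meta <- meta[match(ids, meta$gene_id), ]
  panel <- lapply(seq_along(ids), function(i) {
    gene_model(gene_id = ids[i],
               cds = as.character(seqs[[i]]),
               flank5 = if ("flank5" %in% names(meta)) meta$flank5[i] else "A",
               flank3 = if ("flank3" %in% names(meta)) meta$flank3[i] else "A",
               strand = if ("strand" %in% names(meta)) meta$strand[i] else "+",
               gene_set = meta$gene_set[i])
  })
  names(panel) <- ids
  structure(panel, class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  sets <- table(vapply(x, `[[`, "", "gene_set"))
  cat(sprintf("<gene_panel> %d genes (%s)\n", length(x),
              paste(names(sets), sets, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Annotate the coding consequence of a single-base substitution
#'
#' Classifies a substitution at a 1-based CDS position as synonymous (amino
#' acid, including stop, unchanged), nonsense (non-stop codon gains a stop),
#' stoploss (stop codon lost), or missense (any other amino-acid change).
#'
#' @param gene A [gene_model].
#' @param pos 1-based position within the CDS.
#' @param ref,alt Reference and alternate base; `ref` must match the CDS.
#' @return One of `"synonymous"`, `"missense"`, `"nonsense"`, `"stoploss"`.
#' @examples
#' g <- gene_model("g1", "ATGGAATAA")
#' annotate_consequence(g, 4, "G", "A")  # missense (Glu -> Lys)
#' annotate_consequence(g, 6, "A", "G")  # synonymous
#' annotate_consequence(g, 4, "G", "T")  # nonsense (GAA -> TAA)
#' @export
annotate_consequence <- function(gene, pos, ref, alt) {
  L <- nchar(gene$cds)
  if (any(pos < 1L | pos > L))
    stop("position out of CDS range for gene ", gene$gene_id)
  cds_ref <- substring(gene$cds, pos, pos)
  if (any(cds_ref != toupper(ref)))
    stop("ref does not match CDS of gene ", gene$gene_id, " at position ",
         paste(pos[cds_ref != toupper(ref)], collapse = ", "))
  consequence_of(gene$cds, pos, toupper(alt))
}

consequence_of <- function(cds, pos, alt) {
  ci <- (pos - 1L) %/% 3L
  offset <- (pos - 1L) %% 3L + 1L
  old_codon <- substring(cds, ci * 3L + 1L, ci * 3L + 3L)
  new_codon <- old_codon
  substr(new_codon, offset, offset) <- alt
  aa_old <- translate_codon(old_codon)
  aa_new <- translate_codon(new_codon)
  ifelse(aa_old == aa_new, "synonymous",
    ifelse(aa_old != "*" & aa_new == "*", "nonsense",
      ifelse(aa_old == "*" & aa_new != "*", "stoploss", "missense")))
}

#' Enumerate every possible single-base substitution of a gene
#'
#' Lists the 3L possible substitutions of an L-base CDS, each with its
#' coding-strand trinucleotide context (edge contexts use the flanking bases),
#' 96-class label, and coding consequence. This table underlies site counting,
#' the impact-score null, and the synthetic mutation generator.
#'
#' @param gene A [gene_model].
#' @return Data frame with columns `gene_id`, `gene_set`, `pos`, `ref`, `alt`,
#'   `context`, `class96`, `consequence`.
#' @export
gene_site_table <- function(gene) {
  cds <- strsplit(gene$cds, "")[[1]]
  L <- length(cds)
  prev <- c(gene$flank5, cds[-L])
  nxt <- c(cds[-1], gene$flank3)
  context1 <- paste0(prev, cds, nxt)
  pos <- rep(seq_len(L), each = 3L)
  ref <- rep(cds, each = 3L)
  alt <- unlist(lapply(cds, function(b) DNA_BASES[DNA_BASES != b]),
                use.names = FALSE)
  context <- rep(context1, each = 3L)
  data.frame(gene_id = gene$gene_id, gene_set = gene$gene_set,
             pos = pos, ref = ref, alt = alt, context = context,
             class96 = classify_96(context, ref, alt),
             consequence = consequence_of(gene$cds, pos, alt),
             stringsAsFactors = FALSE)
}

panel_site_table <- function(panel) {
  do.call(rbind, lapply(unname(panel), gene_site_table))
}

#' Annotate a mutation table against a gene panel
#'
#' Adds coding-strand trinucleotide context, 96-class label, consequence, and
#' variant class (SNV/DNV/MNV) to a mutation table. Context, class and
#' consequence are assigned to SNVs; multi-base records keep `NA` there and are
#' excluded from substitution-class analyses downstream.
#'
#' @param mutations Data frame with columns `sample_id`, `gene_id`, `pos`,
#'   `ref`, `alt`, `vaf` and optionally `phase_tag`.
#' @param panel A `gene_panel`.
#' @return The mutation table with columns `var_class`, `context`, `class96`,
#'   `consequence` added.
#' @export
annotate_mutations <- function(mutations, panel) {
  req <- c("sample_id", "gene_id", "pos", "ref", "alt", "vaf")
  if (!all(req %in% names(mutations)))
    stop("mutation table must have columns: ", paste(req, collapse = ", "))
  if (!all(mutations$gene_id %in% names(panel)))
    stop("mutations reference genes absent from the panel: ",
         paste(setdiff(mutations$gene_id, names(panel)), collapse = ", "))
  if (any(mutations$vaf <= 0 | mutations$vaf > 1))
    stop("VAF must lie in (0, 1]")
  if (any(mutations$ref == mutations$alt))
    stop("ref and alt must differ")
  if (any(nchar(mutations$ref) != nchar(mutations$alt)))
    stop("ref and alt must have equal length (substitutions only)")
  n <- nchar(mutations$ref)
  mutations$var_class <- ifelse(n == 1L, "SNV", ifelse(n == 2L, "DNV", "MNV"))
  mutations$context <- NA_character_
  mutations$class96 <- NA_character_
  mutations$consequence <- NA_character_
  is_snv <- mutations$var_class == "SNV"
  if (any(is_snv)) {
    idx <- which(is_snv)
    for (g in unique(mutations$gene_id[idx])) {
      gi <- idx[mutations$gene_id[idx] == g]
      gene <- panel[[g]]
      pos <- mutations$pos[gi]
      L <- nchar(gene$cds)
      if (any(pos < 1L | pos > L))
        stop("position out of CDS range for gene ", g)
      cds_ref <- substring(gene$cds, pos, pos)
      if (any(cds_ref != mutations$ref[gi]))
        stop("ref does not match CDS of gene ", g)
      prev <- ifelse(pos == 1L, gene$flank5, substring(gene$cds, pos - 1L, pos - 1L))
      nxt <- ifelse(pos == L, gene$flank3, substring(gene$cds, pos + 1L, pos + 1L))
      mutations$context[gi] <- paste0(prev, mutations$ref[gi], nxt)
      mutations$class96[gi] <- classify_96(mutations$context[gi],
                                           mutations$ref[gi], mutations$alt[gi])
      mutations$consequence[gi] <- consequence_of(gene$cds, pos,
                                                  mutations$alt[gi])
    }
  }
  mutations
}

#' Flag pairs of mutations lying close together in the same sample and gene
#'
#' Mutation pairs from the same sample and gene whose positions differ by at
#' most `window` base pairs are flagged; such pairs are candidates for being
#' two reads of one multi-nucleotide event and are resolved by
#' [merge_phased()] using the phase tag.
#'
#' @param mutations Mutation table with `sample_id`, `gene_id`, `pos`.
#' @param window Maximum distance in base pairs (inclusive; default 10).
#' @return Data frame with one row per flagged pair: `sample_id`, `gene_id`,
#'   `pos1`, `pos2`, `distance`.
#' @export
flag_proximal <- function(mutations, window = 10L) {
  out <- list()
  if (nrow(mutations)) {
    key <- paste(mutations$sample_id, mutations$gene_id, sep = "\r")
    for (k in unique(key)) {
      rows <- mutations[key == k, ]
      pos <- sort(rows$pos)
      if (length(pos) < 2L) next
      pr <- which(outer(pos, pos, function(a, b) b - a) <= window &
                  upper.tri(diag(length(pos))), arr.ind = TRUE)
      if (nrow(pr))
        out[[k]] <- data.frame(sample_id = rows$sample_id[1],
                               gene_id = rows$gene_id[1],
                               pos1 = pos[pr[, 1]], pos2 = pos[pr[, 2]],
                               distance = pos[pr[, 2]] - pos[pr[, 1]],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), gene_id = character(),
                      pos1 = integer(), pos2 = integer(),
                      distance = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Merge phased adjacent SNVs into DNV/MNV records
#'
#' SNVs sharing a phase tag (observed on the same read) at consecutive CDS
#' positions in the same sample and gene are replaced by a single DNV (two
#' bases) or MNV (three or more) record. The merged record's VAF is the
#' arithmetic mean of the member VAFs. Untagged mutations and tagged mutations
#' without an adjacent same-tag partner pass through unchanged.
#'
#' @param mutations Mutation table with optional `phase_tag` column; `NA` or
#'   empty tags mean "not co-read".
#' @return Mutation table in which merged runs appear as one record anchored
#'   at the run's first position.
#' @export
merge_phased <- function(mutations) {
  if (!"phase_tag" %in% names(mutations))
    mutations$phase_tag <- NA_character_
  tagged <- !is.na(mutations$phase_tag) & mutations$phase_tag != ""
  keep <- mutations[!tagged, , drop = FALSE]
  tg <- mutations[tagged, , drop = FALSE]
  if (!nrow(tg)) {
    rownames(mutations) <- NULL
    return(mutations)
  }
  if (any(nchar(tg$ref) != 1L))
    stop("phase-tagged records must be SNVs")
  gkey <- paste(tg$sample_id, tg$gene_id, tg$phase_tag, sep = "\r")
  pkey <- paste(tg$sample_id, tg$gene_id, tg$pos, sep = "\r")
  if (anyDuplicated(pkey))
    stop("inconsistent overlap: the same position appears in two merge groups")
  merged <- lapply(split(tg, gkey), function(grp) {
    grp <- grp[order(grp$pos), , drop = FALSE]
    run <- cumsum(c(1L, diff(grp$pos) != 1L))
    do.call(rbind, lapply(split(grp, run), function(r) {
      if (nrow(r) == 1L) return(r)
      out <- r[1L, , drop = FALSE]
      out$ref <- paste(r$ref, collapse = "")
      out$alt <- paste(r$alt, collapse = "")
      out$vaf <- mean(r$vaf)
      out$phase_tag <- NA_character_
      out
    }))
  })
  out <- rbind(keep, do.call(rbind, merged))
  out <- out[order(out$sample_id, out$gene_id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
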
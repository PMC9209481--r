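#' Surface area of a circular punch biopsy
#'
#' @param diameter_mm Biopsy diameter in mm (> 0).
#' @return Area in mm^2, `pi * (d/2)^2`. A 5 mm punch gives 19.63 mm^2.
#' @export
biopsy_area <- function(diameter_mm) {
  if (any(diameter_mm <= 0))
    stop("biopsy diameter must be positive")
  pi * (diameter_mm / 2)^2
}

#' Clone surface area inferred from VAF
#'
#' Under the assumption that mutant cells are diploid and heterozygous for the
#' mutation, a variant allele frequency v in a biopsy of area A implies a
#' clone occupying `2 * v * A` mm^2 of the sampled surface.
#'
#' @param vaf Variant allele frequency in (0, 1\].
#' @param area_mm2 Biopsy surface area in mm^2.
#' @param ploidy_factor Multiplier converting VAF to cell fraction (default 2,
#'   diploid heterozygous).
#' @return Clone size in mm^2.
#' @export
clone_size <- function(vaf, area_mm2, ploidy_factor = 2) {
  if (any(vaf <= 0 | vaf > 1))
    stop("VAF must lie in (0, 1]")
  ploidy_factor * vaf * area_mm2
}

#' Read a biopsy sample sheet
#'
#' Tab-separated with columns `sample_id`, `tissue` and either `diameter_mm`
#' or an explicit `area_mm2`. Samples with neither are retained with unknown
#' area and excluded from clone-size inference.
#'
#' @param path File path.
#' @return Data frame with `sample_id`, `tissue`, `area_mm2`, `area_known`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% names(df)))
    stop("sample sheet must have columns sample_id and tissue")
  area <- if ("area_mm2" %in% names(df)) df$area_mm2 else rep(NA_real_, nrow(df))
  if ("diameter_mm" %in% names(df)) {
    use_d <- is.na(area) & !is.na(df$diameter_mm)
    area[use_d] <- biopsy_area(df$diameter_mm[use_d])
  }
  data.frame(sample_id = df$sample_id, tissue = df$tissue,
             area_mm2 = area, area_known = !is.na(area),
             stringsAsFactors = FALSE)
}

clone_scope <- function(mutations, samples, genes = NULL) {
  known <- samples[samples$area_known, , drop = FALSE]
  cl <- mutations[mutations$sample_id %in% known$sample_id, , drop = FALSE]
  if (!is.null(genes))
    cl <- cl[cl$gene_id %in% genes, , drop = FALSE]
  cl$area_mm2 <- known$area_mm2[match(cl$sample_id, known$sample_id)]
  cl$size_mm2 <- clone_size(cl$vaf, cl$area_mm2)
  list(clones = cl, total_area = sum(known$area_mm2),
       excluded_samples = samples$sample_id[!samples$area_known])
}

#' Clone frequency per square centimeter of sampled tissue
#'
#' Each mutation in scope counts as one clone. Only samples with known area
#' contribute; the frequency is the clone count divided by the total sampled
#' area, scaled to clones per cm^2.
#'
#' @param mutations Mutation table (each row one clone-defining mutation).
#' @param samples Sample sheet from [read_sample_sheet()].
#' @param genes Optional gene filter.
#' @return Clones per cm^2.
#' @export
clones_per_cm2 <- function(mutations, samples, genes = NULL) {
  sc <- clone_scope(mutations, samples, genes)
  if (sc$total_area <= 0)
    stop("total sampled area is zero")
  nrow(sc$clones) / sc$total_area * 100
}

#' Percentage of sampled tissue occupied by clones of a gene
#'
#' `100 * sum(clone sizes) / total sampled area`, equivalently the
#' area-weighted mean of 2 x VAF. Overlapping clones are not modelled, so
#' pathological inputs can exceed 100%; such values are reported unclamped
#' with a warning.
#'
#' @inheritParams clones_per_cm2
#' @param gene Gene whose clones are measured.
#' @return Percent of sampled surface.
#' @export
occupancy_percent <- function(mutations, samples, gene) {
  sc <- clone_scope(mutations, samples, gene)
  if (sc$total_area <= 0)
    stop("total sampled area is zero")
  pct <- 100 * sum(sc$clones$size_mm2) / sc$total_area
  if (pct > 100)
    warning("occupancy exceeds 100% (overlapping clones are not modelled)")
  pct
}

#' Per-gene clone summary table
#'
#' For each positively selected gene, summarizes its clones across samples
#' with known area: number of clones, clone frequency per cm^2, median clone
#' size and percent of tissue occupied. Genes outside `selected_genes` are
#' excluded.
#'
#' @param mutations Mutation table.
#' @param samples Sample sheet.
#' @param selected_genes Genes called under positive selection (e.g. at 10%
#'   FDR from [run_selection()]).
#' @return Data frame with `gene_id`, `n_clones`, `clones_per_cm2`,
#'   `median_size_mm2`, `occupancy_percent`; attribute `excluded_samples`
#'   lists samples lacking a known area.
#' @export
clone_table <- function(mutations, samples, selected_genes) {
  sc <- clone_scope(mutations, samples, selected_genes)
  if (sc$total_area <= 0)
    stop("total sampled area is zero")
  rows <- lapply(selected_genes, function(g) {
    cl <- sc$clones[sc$clones$gene_id == g, , drop = FALSE]
    data.frame(gene_id = g, n_clones = nrow(cl),
               clones_per_cm2 = nrow(cl) / sc$total_area * 100,
               median_size_mm2 = if (nrow(cl)) median(cl$size_mm2) else NA_real_,
               occupancy_percent = 100 * sum(cl$size_mm2) / sc$total_area,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_clones), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_samples") <- sc$excluded_samples
  out
}
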
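test_that("read_panel joins FASTA records with metadata and validates genes", {
  d <- withr::local_tempdir()
  fa <- file.path(d, "p.fasta")
  meta <- file.path(d, "m.tsv")
  writeLines(c(">g1", "ATGGAATAA"), fa)
  writeLines(c("gene_id\tgene_set", "g1\tdriver"), meta)
  panel <- read_panel(fa, meta)
  expect_s3_class(panel, "gene_panel")
  expect_length(panel, 1)
  expect_equal(panel$g1$gene_set, "driver")
  expect_equal(panel$g1$cds, "ATGGAATAA")

  writeLines(c(">g1", "ATGGAATA"), fa)  # length 8
  expect_error(read_panel(fa, meta), "g1")

  writeLines(c(">g1", "ATGGAATAA"), fa)
  writeLines(c("gene_id\tgene_set", "g1\tdriver", "g2\timmune"), meta)
  expect_error(read_panel(fa, meta), "g2")
})

test_that("gene_model enforces its invariants", {
  expect_error(gene_model("x", "ATGNNNTAA"), "non-ACGT")
  expect_error(gene_model("x", "ATGTAA", gene_set = "other"))
  expect_error(gene_model("x", "ATG"), "divisible")
  expect_silent(gene_model("x", "ATGTAA"))
})

test_that("annotate_consequence follows the codon table", {
  g <- toy_gene()
  expect_equal(annotate_consequence(g, 4, "G", "A"), "missense")
  expect_equal(annotate_consequence(g, 6, "A", "G"), "synonymous")
  expect_equal(annotate_consequence(g, 4, "G", "T"), "nonsense")
})

test_that("stop codon edits distinguish synonymous stop from stoploss", {
  g <- toy_gene()  # ends TAA
  expect_equal(annotate_consequence(g, 9, "A", "G"), "synonymous")  # TAA -> TAG
  expect_equal(annotate_consequence(g, 8, "A", "C"), "stoploss")    # TAA -> TCA
  expect_error(annotate_consequence(g, 10, "A", "G"), "range")
  expect_error(annotate_consequence(g, 4, "C", "A"), "ref")
})

test_that("classify_96 maps purine-centered substitutions by reverse complement", {
  expect_equal(classify_96("ACA", "C", "T"), "A[C>T]A")
  expect_equal(classify_96("TGT", "G", "A"), "A[C>T]A")
  expect_error(classify_96("ACA", "C", "C"), "differ")
  expect_error(classify_96("ANA", "N", "T"))
  expect_error(classify_96("ACA", "G", "T"), "center")
})

test_that("full enumeration of contexts collapses to exactly 96 classes", {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(f5 = bases, ref = bases, f3 = bases, alt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$ref != grid$alt, ]
  expect_equal(nrow(grid), 192)
  cls <- classify_96(paste0(grid$f5, grid$ref, grid$f3), grid$ref, grid$alt)
  expect_equal(sort(unique(cls)), sort(sbs96_labels()))
  expect_length(unique(cls), 96)
  # for one flanking pair, the 12 pyrimidine+purine substitutions collapse
  # onto 6 classes
  one <- grid[grid$f5 == "A" & grid$f3 == "A" & grid$ref %in% c("C", "G"), ]
  expect_length(unique(classify_96(paste0("A", one$ref, "A"),
                                   one$ref, one$alt)), 6)
})

test_that("classify_96 is strand-involutive on random substitutions", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
    rc_ctx <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(ctx)))
    expect_equal(
      classify_96(rc_ctx, chartr("ACGT", "TGCA", ref), chartr("ACGT", "TGCA", alt)),
      classify_96(ctx, ref, alt))
  }
})

test_that("consequences over all substitutions partition 3L sites (oracle check)", {
  set.seed(21)
  for (rep in 1:5) {
    g <- random_gene(sample(4:12, 1), id = paste0("r", rep))
    st <- gene_site_table(g)
    expect_equal(nrow(st), 3 * nchar(g$cds))
    oracle <- vapply(seq_len(nrow(st)), function(i)
      oracle_consequence(g$cds, st$pos[i], st$alt[i]), character(1))
    expect_equal(st$consequence, oracle)
  }
})

test_that("flag_proximal flags pairs within 10 bp in the same sample and gene", {
  muts <- data.frame(sample_id = c("s1", "s1", "s1", "s2"),
                     gene_id = "g1", pos = c(100L, 105L, 111L, 105L),
                     ref = "C", alt = "T", vaf = 0.01)
  fl <- flag_proximal(muts)
  expect_equal(nrow(fl), 2)  # (100,105) and (105,111); not (100,111)
  expect_true(any(fl$pos1 == 100 & fl$pos2 == 105))
  expect_true(any(fl$pos1 == 105 & fl$pos2 == 111))
  expect_false(any(fl$pos1 == 100 & fl$pos2 == 111))
  # distance exactly 10 is included; different samples are never paired
  muts2 <- data.frame(sample_id = c("s1", "s1"), gene_id = "g1",
                      pos = c(100L, 110L), ref = "C", alt = "T", vaf = 0.01)
  expect_equal(nrow(flag_proximal(muts2)), 1)
  expect_equal(nrow(flag_proximal(muts2[0, ])), 0)
})

test_that("merge_phased merges same-tag adjacent SNVs into DNV/MNV records", {
  muts <- data.frame(
    sample_id = "s1", gene_id = "g1",
    pos = c(10L, 11L, 30L, 31L, 50L, 51L, 52L, 70L),
    ref = c("C", "C", "C", "C", "C", "C", "C", "C"),
    alt = c("T", "T", "T", "T", "T", "A", "G", "T"),
    vaf = c(0.02, 0.04, 0.01, 0.01, 0.1, 0.1, 0.1, 0.05),
    phase_tag = c("a", "a", "x", "y", "m", "m", "m", NA),
    stringsAsFactors = FALSE)
  out <- merge_phased(muts)
  dnv <- out[out$pos == 10, ]
  expect_equal(dnv$ref, "CC")
  expect_equal(dnv$alt, "TT")
  expect_equal(dnv$vaf, 0.03)  # mean of members
  # different tags at adjacent positions stay separate SNVs
  expect_equal(nchar(out$ref[out$pos %in% c(30, 31)]), c(1L, 1L))
  # three consecutive same-tag SNVs become one MNV of length 3
  mnv <- out[out$pos == 50, ]
  expect_equal(mnv$ref, "CCC")
  expect_equal(mnv$alt, "TAG")
  # mutation mass is conserved: consumed SNVs = emitted record lengths
  expect_equal(sum(nchar(out$ref)), nrow(muts))
  # untagged mutations pass through
  expect_true(70 %in% out$pos)
})

test_that("merge_phased rejects a position claimed by two merge groups", {
  muts <- data.frame(sample_id = "s1", gene_id = "g1",
                     pos = c(10L, 11L, 11L), ref = "C", alt = "T",
                     vaf = 0.01, phase_tag = c("a", "a", "b"),
                     stringsAsFactors = FALSE)
  expect_error(merge_phased(muts), "merge groups")
})
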
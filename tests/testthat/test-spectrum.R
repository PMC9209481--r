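annotated <- function(class96, ref = substr(class96, 3, 3),
                      var_class = "SNV") {
  data.frame(sample_id = "s1", gene_id = "g1", pos = seq_along(class96),
             ref = ref, alt = substr(class96, 5, 5), vaf = 0.01,
             var_class = var_class, class96 = class96,
             stringsAsFactors = FALSE)
}

test_that("compute_spectrum counts SNVs per class and excludes DNVs", {
  m <- annotated("A[C>T]A")
  sp <- compute_spectrum(m)
  expect_equal(sum(sp), 1)
  expect_equal(unname(sp["A[C>T]A"]), 1L)

  empty <- compute_spectrum(m[0, ])
  expect_equal(sum(empty), 0)
  expect_equal(attr(empty, "n_snv"), 0L)

  set.seed(3)
  m10 <- annotated(sample(sbs96_labels(), 10, replace = TRUE))
  expect_equal(sum(compute_spectrum(m10)), 10)

  mixed <- rbind(m, transform(m, var_class = "DNV"))
  expect_equal(sum(compute_spectrum(mixed)), 1)
})

test_that("estimate_prior returns empirical class frequencies", {
  # uniform catalogue: every class once
  labels <- sbs96_labels()
  cat_u <- data.frame(context = paste0(substr(labels, 1, 1),
                                       substr(labels, 3, 3),
                                       substr(labels, 7, 7)),
                      ref = substr(labels, 3, 3), alt = substr(labels, 5, 5))
  p <- estimate_prior(cat_u)
  expect_equal(as.numeric(p), rep(1 / 96, 96))

  cat_d <- data.frame(context = "TCT", ref = "C", alt = "T")
  p2 <- estimate_prior(cat_d)
  expect_equal(unname(p2["T[C>T]T"]), 1)
  expect_equal(sum(p2), 1)
  expect_error(estimate_prior(cat_d[0, ]), "empty")
})

test_that("prior estimation is consistent under resampling from the prior", {
  set.seed(17)
  labels <- sbs96_labels()
  w <- rgamma(96, 1); w <- w / sum(w)
  truth <- spectrum_prior(setNames(w, labels))
  n <- 1e5
  cls <- sample(labels, n, replace = TRUE, prob = w)
  cat_df <- data.frame(context = paste0(substr(cls, 1, 1), substr(cls, 3, 3),
                                        substr(cls, 7, 7)),
                       ref = substr(cls, 3, 3), alt = substr(cls, 5, 5))
  est <- estimate_prior(cat_df)
  se <- sqrt(w * (1 - w) / n)
  dev <- abs(as.numeric(est) - w)
  # per-class 3-SE agreement, allowing for multiplicity across the 96 classes
  expect_gte(mean(dev <= 3 * se + 1e-12), 0.95)
  expect_true(all(dev <= 5 * se + 1e-12))
})

test_that("dipyrimidine classification follows the neighboring-base rule", {
  expect_equal(dipyrimidine_fraction(annotated("T[C>T]A")), 1)  # 5' pyrimidine
  expect_equal(dipyrimidine_fraction(annotated("A[C>T]A")), 0)  # purine flanks
  # contexts TCA, ACT, ACA, GCG, all C>T: two dipyrimidine of four
  m4 <- annotated(c("T[C>T]A", "A[C>T]T", "A[C>T]A", "G[C>T]G"))
  expect_equal(dipyrimidine_fraction(m4), 0.5)
  expect_error(dipyrimidine_fraction(m4[0, ]), "undefined")
  # G>A substitutions are counted via their pyrimidine-strand class
  ga <- annotate_mutations(
    data.frame(sample_id = "s", gene_id = "g1", pos = 5L, ref = "G",
               alt = "A", vaf = 0.01),
    structure(list(g1 = gene_model("g1", "ATGGGATAA")), class = "gene_panel"))
  expect_equal(ga$class96, "T[C>T]C")  # revcomp of GGA context
  expect_equal(dipyrimidine_fraction(ga), 1)
})

test_that("strand_bias_test matches exact binomial oracles", {
  sym <- strand_bias_test(10, 10)
  expect_equal(sym$ratio, 1)
  expect_equal(sym$excess_percent, 0)
  expect_equal(sym$p, 1)

  sb <- strand_bias_test(62, 50)
  expect_equal(sb$ratio, 1.24)
  expect_equal(sb$excess_percent, 24)
  expect_equal(sb$p, oracle_binom_two_sided(62, 112), tolerance = 1e-12)

  one_sided <- strand_bias_test(34, 0)
  expect_equal(one_sided$p, min(1, 2 * 0.5^34), tolerance = 1e-12)
  expect_true(is.infinite(one_sided$ratio))
  expect_error(strand_bias_test(0, 0), "zero")
})

test_that("strand bias p-value is exchange-symmetric", {
  set.seed(5)
  for (i in 1:20) {
    a <- sample(0:80, 1); b <- sample(0:80, 1)
    if (a + b == 0) next
    expect_equal(strand_bias_test(a, b)$p, strand_bias_test(b, a)$p)
  }
})

test_that("strand_counts splits pyrimidine placement by reference base", {
  m <- annotated(c("A[C>T]A", "A[C>T]A", "T[C>T]T"), ref = c("C", "G", "C"))
  sc <- strand_counts(m, "C>T")
  expect_equal(sc$coding, 2)
  expect_equal(sc$template, 1)
})

test_that("dnv_strand_analysis tests the CC>TT coding-strand fraction", {
  dnv <- function(n_cc, n_gg) {
    data.frame(sample_id = "s", gene_id = "g", pos = seq_len(n_cc + n_gg),
               ref = rep(c("CC", "GG"), c(n_cc, n_gg)),
               alt = rep(c("TT", "AA"), c(n_cc, n_gg)), vaf = 0.01,
               var_class = "DNV", stringsAsFactors = FALSE)
  }
  res <- dnv_strand_analysis(dnv(28, 6))
  expect_equal(res$fraction_coding, 28 / 34, tolerance = 1e-12)
  expect_equal(round(res$fraction_coding, 4), 0.8235)
  expect_equal(res$p, oracle_binom_upper(28, 34, 0.5), tolerance = 1e-12)
  expect_equal(dnv_strand_analysis(dnv(5, 0))$fraction_coding, 1)
  eq <- dnv_strand_analysis(dnv(4, 4))
  expect_equal(eq$fraction_coding, 0.5)
  expect_gte(eq$p, 0.5)
  expect_error(dnv_strand_analysis(dnv(1, 0)[0, ]), "CC>TT")
})

test_that("cosine_similarity has the expected closed-form values", {
  u <- rep(1, 96)
  expect_equal(cosine_similarity(u, u), 1)
  a <- c(1, 0, rep(0, 94)); b <- c(0, 1, rep(0, 94))
  expect_equal(cosine_similarity(a, b), 0)
  expect_equal(cosine_similarity(c(1, 1, rep(0, 94)), a), 1 / sqrt(2))
  expect_error(cosine_similarity(a, rep(0, 96)), "zero")
})

test_that("refit_signatures recovers pure and mixed spectra", {
  sigs <- reference_signatures()
  # pure signature: spectrum proportional to one column
  pure <- setNames(round(sigs[, "UVlike"] * 1000), rownames(sigs))
  e <- refit_signatures(pure, sigs)
  expect_equal(unname(e["UVlike"]), 1, tolerance = 1e-6)
  expect_equal(sum(e), 1)

  # constructed 0.6/0.4 mixture of disjoint-support signatures
  mix <- 0.6 * sigs[, "SmokingLike"] + 0.4 * sigs[, "TtoC"]
  spec <- setNames(round(mix * 1e5), rownames(sigs))
  e2 <- refit_signatures(spec, sigs)
  expect_equal(unname(e2["SmokingLike"]), 0.6, tolerance = 0.01)
  expect_equal(unname(e2["TtoC"]), 0.4, tolerance = 0.01)

  expect_error(refit_signatures(setNames(rep(0, 96), rownames(sigs)), sigs),
               "empty")
  bad <- sigs; bad[, 1] <- 0
  expect_error(refit_signatures(pure, bad), "zero column")
})

test_that("mixture refit residual is no larger than any single-signature fit", {
  set.seed(29)
  sigs <- reference_signatures()
  counts <- as.numeric(rmultinom(1, 2000, 0.5 * sigs[, "UVlike"] +
                                   0.3 * sigs[, "Flat"] + 0.2 * sigs[, "TtoC"]))
  spec <- setNames(counts, rownames(sigs))
  freq <- counts / sum(counts)
  fit <- refit_signatures(spec, sigs)
  single <- vapply(colnames(sigs), function(s) {
    # best non-negative scale of a single signature
    beta <- max(0, sum(freq * sigs[, s]) / sum(sigs[, s]^2))
    sqrt(sum((freq - beta * sigs[, s])^2))
  }, numeric(1))
  expect_true(all(attr(fit, "residual") <= single + 1e-12))
})

test_that("signature matrix round-trips through TSV", {
  d <- withr::local_tempdir()
  p <- file.path(d, "sigs.tsv")
  sigs <- reference_signatures()
  write_signature_matrix(sigs, p)
  expect_equal(read_signature_matrix(p), sigs)
})

test_that("UV-like exposure rises with the generator's UV weight", {
  sigs <- reference_signatures()
  uv_exposure <- vapply(c(0.2, 0.5, 0.8), function(u) {
    cfg <- sim_config(seed = 77, uv_weight = u, selection_weight = 1,
                      dnv_rate = 0, impact_bias = 1)
    panel <- generate_panel(cfg)
    muts <- annotate_mutations(simulate_mutations(panel, cfg), panel)
    unname(refit_signatures(compute_spectrum(muts), sigs)["UVlike"])
  }, numeric(1))
  expect_true(all(diff(uv_exposure) > 0))
})
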
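test_that("enumerate_sites matches the brute-force oracle on the toy gene", {
  g <- toy_gene()
  sites <- enumerate_sites(g)
  expect_equal(sum(sites), 27)  # 3L possible substitutions
  expect_equal(unclass(sites), oracle_site_counts(g))
})

test_that("enumerate_sites matches the oracle on random short genes", {
  set.seed(31)
  for (rep in 1:6) {
    g <- random_gene(sample(3:10, 1), id = paste0("e", rep))
    sites <- enumerate_sites(g)
    expect_equal(sum(sites), 3 * nchar(g$cds))
    expect_equal(unclass(sites), oracle_site_counts(g))
  }
})

test_that("codon-synonymous recodings shift site counts as the oracle dictates", {
  # CTG and TTG both encode Leu but offer different synonymous opportunities
  g1 <- gene_model("a", "ATGCTGTAA")
  g2 <- gene_model("a", "ATGTTGTAA")
  s1 <- enumerate_sites(g1); s2 <- enumerate_sites(g2)
  expect_equal(unclass(s1), oracle_site_counts(g1))
  expect_equal(unclass(s2), oracle_site_counts(g2))
  expect_false(identical(colSums(s1), colSums(s2)))
})

test_that("expected_ns_ratio reduces to closed forms on degenerate inputs", {
  g <- toy_gene()
  sites <- enumerate_sites(g)
  u <- uniform_prior()
  # direct summation oracle with the uniform prior
  N <- rowSums(sites[, c("missense", "nonsense", "stoploss")])
  expect_equal(expected_ns_ratio(sites, u), sum(N / 96) / sum(sites[, "syn"] / 96))

  # symmetric synthetic counts give exactly 1
  eq <- matrix(0L, 96, 4, dimnames = dimnames(unclass(sites)))
  eq[, "syn"] <- 2L; eq[, "missense"] <- 2L
  eq <- structure(eq, class = c("site_counts", "matrix"))
  expect_equal(expected_ns_ratio(eq, u), 1)

  # prior mass on one class -> N_j / S_j for that class
  j <- which(sites[, "syn"] > 0)[1]
  p1 <- spectrum_prior(setNames(replace(rep(0, 96), j, 1), sbs96_labels()))
  expect_equal(expected_ns_ratio(sites, p1), unname(N[j] / sites[j, "syn"]))

  # zero synonymous mass is signalled
  k <- which(sites[, "syn"] == 0 & N > 0)[1]
  p0 <- spectrum_prior(setNames(replace(rep(0, 96), k, 1), sbs96_labels()))
  expect_error(expected_ns_ratio(sites, p0), "synonymous")
})

test_that("global dN/dS reproduces the observed/expected worked example", {
  # observed nonsynonymous/synonymous ratio 3.68 against expectation 2.12
  expect_equal(round(global_dnds(3.68, 1, 2.12), 2), 1.74)
  expect_equal(global_dnds(3.68, 1, 2.12), 3.68 / 2.12, tolerance = 1e-12)
  expect_equal(global_dnds(5, 2, 2.5), 1)
  expect_equal(global_dnds(0, 10, 2), 0)
  expect_error(global_dnds(5, 0, 2), "undefined")
})

test_that("selection excess fraction clamps at neutrality", {
  expect_equal(round(selection_excess_fraction(1.73), 2), 0.42)
  expect_equal(selection_excess_fraction(1.73), 0.73 / 1.73, tolerance = 1e-12)
  expect_equal(selection_excess_fraction(1), 0)
  expect_equal(selection_excess_fraction(0.5), 0)
})

test_that("binomial selection test matches exhaustive tail sums", {
  labels <- sbs96_labels()
  mk_sites <- function(syn, mis) {
    m <- matrix(0L, 96, 4, dimnames = list(labels, c("syn", "missense",
                                                     "nonsense", "stoploss")))
    m[1, "syn"] <- syn; m[1, "missense"] <- mis
    structure(m, class = c("site_counts", "matrix"))
  }
  p1 <- spectrum_prior(setNames(replace(rep(0, 96), 1, 1), labels))
  # pi = 0.5
  expect_equal(binomial_selection_test(10, 0, mk_sites(5, 5), p1), 0.5^10,
               tolerance = 1e-12)
  expect_equal(binomial_selection_test(0, 4, mk_sites(5, 5), p1), 1)
  # pi = 0.7, n = 7, s = 3
  expect_equal(binomial_selection_test(7, 3, mk_sites(3, 7), p1),
               oracle_binom_upper(7, 10, 0.7), tolerance = 1e-12)
  expect_error(binomial_selection_test(0, 0, mk_sites(3, 7), p1), "at least one")
})

test_that("bh_fdr applies the step-up adjustment", {
  one <- bh_fdr(0.03)
  expect_equal(one$q, 0.03)
  expect_true(one$called)
  four <- bh_fdr(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(four$q, rep(0.04, 4))
  set.seed(41)
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)$q) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
})

test_that("run_selection reports zero dN/dS when all mutations are synonymous", {
  set.seed(47)
  panel <- structure(list(gA = random_gene(40, id = "gA"),
                          gB = random_gene(40, gene_set = "housekeeping", id = "gB")),
                     class = "gene_panel")
  st <- panel_syn <- do.call(rbind, lapply(panel, gene_site_table))
  syn <- st[st$consequence == "synonymous", ][1:20, ]
  muts <- data.frame(sample_id = "s1", gene_id = syn$gene_id, pos = syn$pos,
                     ref = syn$ref, alt = syn$alt, vaf = 0.01)
  res <- run_selection(annotate_mutations(muts, panel), panel, uniform_prior(),
                       grouping = "global", metrics = "all")
  expect_equal(res$statistic, 0)
  expect_false(res$called)
})

test_that("driver enrichment is detected and destroyed by label permutation", {
  cfg <- sim_config(seed = 53, n_driver = 2, n_immune = 10, n_housekeeping = 8,
                    cds_codons = c(100L, 160L), selection_weight = 3,
                    strand_excess = 1, dnv_rate = 0, impact_bias = 1,
                    n_samples = 6L, muts_per_sample = 50L)
  panel <- generate_panel(cfg)
  prior <- mixture_prior(cfg)
  muts <- annotate_mutations(simulate_mutations(panel, cfg), panel)
  res <- run_selection(muts, panel, prior, grouping = "gene_set",
                       metrics = "all")
  expect_true(res$called[res$scope == "driver"])
  expect_false(res$called[res$scope == "housekeeping"])

  # permuting the gene-set labels destroys the driver signal
  set.seed(59)
  destroyed <- vapply(1:10, function(i) {
    sets <- unname(sample(vapply(panel, `[[`, "", "gene_set")))
    perm <- panel
    for (j in seq_along(perm)) perm[[j]]$gene_set <- sets[j]
    r <- run_selection(muts, perm, prior, grouping = "gene_set",
                       metrics = "all")
    !isTRUE(r$called[r$scope == "driver"])
  }, logical(1))
  expect_gte(sum(destroyed), 9)
})

test_that("nonsense-only selection lifts dNons/dS above dN/dS", {
  cfg <- sim_config(seed = 61, selection_weight = 4, nonsense_only = TRUE,
                    strand_excess = 1, dnv_rate = 0, impact_bias = 1,
                    n_samples = 8L, muts_per_sample = 60L)
  panel <- generate_panel(cfg)
  muts <- annotate_mutations(simulate_mutations(panel, cfg), panel)
  res <- run_selection(muts, panel, mixture_prior(cfg), grouping = "gene_set")
  drv <- res[res$scope == "driver", ]
  expect_gt(drv$statistic[drv$metric == "dNons/dS"],
            drv$statistic[drv$metric == "dN/dS"])
})
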
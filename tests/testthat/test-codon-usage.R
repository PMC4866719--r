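test_that("count_codons counts in-frame triplets and tallies stops apart", {
  m <- build_toy_genome(list(trna_block("trnG"),
                             list(label = "nad3", seq = "ATGGACGATTAA"),
                             trna_block("trnW")))
  cc <- count_codons(m)
  ct <- cc$counts
  expect_equal(ct$count[ct$codon == "ATG"], 1L)
  expect_equal(ct$count[ct$codon == "GAC"], 1L)
  expect_equal(ct$count[ct$codon == "GAT"], 1L)
  expect_equal(ct$count[ct$codon == "TAA"], 1L)
  expect_equal(ct$aa[ct$codon == "TAA"], "*")
  expect_equal(sum(ct$count), 4L)
  fr <- aa_frequencies(cc)
  expect_equal(unname(fr["M"]), 1 / 3)
  expect_equal(unname(fr["D"]), 2 / 3)
  expect_equal(sum(fr), 1)
})

test_that("an incomplete terminal T is not counted as a codon", {
  m <- build_toy_genome(list(trna_block("trnG"),
                             list(label = "nad3", seq = "ATGGACGATT"),
                             trna_block("trnW")))
  cc <- count_codons(m)
  expect_equal(sum(cc$counts$count), 3L)  # ATG GAC GAT, trailing T dropped
  expect_equal(sum(cc$counts$count[cc$counts$aa == "*"]), 0L)
})

test_that("synthetic genomes recover the configured Asp codon bias", {
  aas <- setdiff(unique(Biostrings::getGeneticCode("5")), "*")
  wts <- stats::setNames(rep(1, length(aas)), aas)
  wts["D"] <- 6  # enough Asp draws for a tight binomial check
  m <- generate_genome(simulation_config(77, theta_gat = 0.8,
                                         aa_weights = wts))
  cc <- count_codons(m)
  gac <- cc$counts$count[cc$counts$codon == "GAC"]
  gat <- cc$counts$count[cc$counts$codon == "GAT"]
  n <- gac + gat
  expect_gt(n, 800)
  ci <- 2.576 * sqrt(0.8 * 0.2 / n)  # 99% binomial band
  expect_lt(abs(gat / n - 0.8), ci + 0.01)
})

test_that("the packaged clitellate table has the documented margins", {
  tab <- asp_table_clitellata()
  expect_s3_class(tab, "asp_table")
  expect_equal(nrow(tab), 9L)
  expect_equal(sum(tab$GAC) + sum(tab$GAT), 658L)
  expect_equal(sum(tab$GAC), 253L)
})

test_that("asp_table from codon counts gives one row per genome", {
  m1 <- generate_genome(simulation_config(5))
  m2 <- generate_genome(simulation_config(5))
  tab <- asp_table(list(count_codons(m1), count_codons(m2)))
  expect_equal(tab$GAC[1], tab$GAC[2])  # identical genomes, identical rows
  expect_equal(tab$GAT[1], tab$GAT[2])
  expect_error(asp_table(list(count_codons(m1))), "at least 2")
})

test_that("gac_gat_ratio rounds half-up to two decimals", {
  expect_equal(gac_gat_ratio(12, 78), 0.15)
  expect_equal(gac_gat_ratio(34, 40), 0.85)
  expect_equal(gac_gat_ratio(0, 10), 0)
  expect_equal(gac_gat_ratio(1, 8), 0.13)  # 0.125 rounds up, not to even
  expect_true(is.na(gac_gat_ratio(5, 0)))
})

test_that("exact test equals full enumeration on small tables", {
  p <- fisher_exact_rx2(matrix(c(3, 1, 1, 3), 2))
  expect_equal(as.numeric(p), naive_fisher_rx2(c(3, 1), c(1, 3)),
               tolerance = 1e-12)
  # cross-check against the independent FEXACT implementation
  expect_equal(as.numeric(p),
               stats::fisher.test(matrix(c(3, 1, 1, 3), 2))$p.value,
               tolerance = 1e-7)
  m3 <- cbind(c(12, 8, 14), c(78, 58, 56))
  expect_equal(as.numeric(fisher_exact_rx2(m3)),
               stats::fisher.test(m3)$p.value, tolerance = 1e-6)
})

test_that("degenerate and invalid tables are handled", {
  expect_equal(as.numeric(fisher_exact_rx2(cbind(c(0, 0), c(5, 7)))), 1)
  expect_equal(as.numeric(fisher_exact_rx2(cbind(c(5, 7), c(0, 0)))), 1)
  expect_error(fisher_exact_rx2(cbind(c(-1, 2), c(1, 1))), "negative")
  expect_error(fisher_exact_rx2(matrix(c(1, 2), 1)), "2 rows")
})

test_that("p is in (0,1] and invariant to row permutation and column swap", {
  set.seed(42)
  for (i in 1:25) {
    R <- sample(2:4, 1)
    a <- rpois(R, 6); b <- rpois(R, 6) + 1
    p <- as.numeric(fisher_exact_rx2(cbind(a, b)))
    expect_gt(p, 0); expect_lte(p, 1)
    perm <- sample(R)
    expect_equal(as.numeric(fisher_exact_rx2(cbind(a[perm], b[perm]))), p,
                 tolerance = 1e-12)
    expect_equal(as.numeric(fisher_exact_rx2(cbind(b, a))), p,
                 tolerance = 1e-12)
  }
})

test_that("the exact test is conservative under the null", {
  set.seed(2024)
  nrej <- 0L
  nsim <- 2000L
  for (i in 1:nsim) {
    a <- rbinom(4, 20, 0.35)
    p <- fisher_exact_rx2(cbind(a, 20 - a), alpha = 0.05)
    if (attr(p, "p_upper") <= 0.05) nrej <- nrej + 1L
  }
  rate <- nrej / nsim
  se <- sqrt(0.05 * 0.95 / nsim)
  expect_lte(rate, 0.05 + 2 * se)
})

test_that("kruskal_wallis matches hand-ranked arithmetic", {
  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2, 2), c(2, 2)))$p, 1)
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-10)  # ranks 1:6, no ties
  expect_equal(kw$df, 1L)
  kw2 <- kruskal_wallis(list(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(kw2$H, kw$H)  # group order irrelevant
  expect_error(kruskal_wallis(list(1:3)), "2 nonempty")
})

test_that("three identical rows form one homogeneous group with p = 1", {
  t3 <- asp_table(data.frame(organism = c("a", "b", "c"),
                             GAC = c(5, 5, 5), GAT = c(9, 9, 9)))
  sg <- homogeneous_subgroups(t3, alpha = 0.05)
  expect_equal(nrow(sg$groups), 1L)
  expect_equal(sg$groups$size, 3L)
  expect_equal(sg$groups$p, 1)
})

test_that("reported subgroups are maximal by direct superset checking", {
  tab <- asp_table(data.frame(
    organism = letters[1:5],
    GAC = c(10, 11, 9, 40, 42), GAT = c(40, 38, 42, 10, 9)))
  sg <- homogeneous_subgroups(tab, alpha = 0.05)
  for (g in sg$member_indices) {
    others <- setdiff(seq_len(nrow(tab)), g)
    for (o in others) {
      p_sup <- as.numeric(fisher_exact_rx2(tab[c(g, o), , drop = FALSE]))
      expect_lte(p_sup, 0.05)
    }
  }
})
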
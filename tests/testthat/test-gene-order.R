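test_that("normalize_order anchors, reverses minus-strand anchors, idempotent", {
  o <- gene_order(c("trnD", "atp8", "cox1"))
  n <- normalize_order(o)
  expect_equal(n$labels, c("cox1", "trnD", "atp8"))
  expect_equal(normalize_order(n), n)  # idempotent
  # anchored on minus: whole order reversed and complemented
  o2 <- gene_order(c("atp8", "cox1", "trnD"), strands = c("+", "-", "+"))
  n2 <- normalize_order(o2)
  expect_equal(n2$labels, c("cox1", "atp8", "trnD"))
  expect_equal(n2$strands, c("+", "-", "-"))
  expect_equal(normalize_order(n2), n2)
  expect_error(normalize_order(gene_order(c("a", "a"), circular = TRUE),
                               anchor = "a"), "exactly once")
  expect_error(normalize_order(o, anchor = "nad5"), "exactly once")
})

test_that("pcg_order_identical ignores tRNA placement but sees PCG swaps", {
  a <- clitellate_template()
  b <- apply_events(a, list(list(kind = "translocation", gene = "trnA",
                                 to_index = 20L)))
  expect_true(pcg_order_identical(a, b))
  # nad2/nad3 exchanged positions: PCG orders differ
  ij <- match(c("nad2", "nad3"), a$labels)
  lab <- a$labels; lab[ij] <- lab[rev(ij)]
  expect_false(pcg_order_identical(a, gene_order(lab)))
  expect_true(pcg_order_identical(a, a))
})

test_that("breakpoint_distance matches brute-force adjacency comparison", {
  expect_equal(breakpoint_distance(clitellate_template(),
                                   clitellate_template()), 0L)
  # one adjacent swap on a 5-gene circular order
  a <- gene_order(c("cox1", "cox2", "cox3", "atp6", "atp8"))
  b <- gene_order(c("cox1", "cox3", "cox2", "atp6", "atp8"))
  expect_equal(breakpoint_distance(a, b), naive_breakpoints(a, b))
  # one translocation on n = 10 breaks three adjacencies
  a10 <- gene_order(c("cox1", "cox2", "cox3", "cob", "atp6", "atp8",
                      "nad1", "nad2", "nad3", "nad4"))
  b10 <- apply_events(a10, list(list(kind = "translocation", gene = "cob",
                                     to_index = 8L)))
  expect_equal(breakpoint_distance(a10, b10), 3L)
  expect_equal(naive_breakpoints(a10, b10), 3L)
  # randomized signed circular permutations, n <= 5, against the oracle,
  # plus symmetry
  labs <- c("cox1", "cox2", "cox3", "atp6", "atp8")
  set.seed(1)
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    x <- gene_order(sample(labs[1:n]),
                    strands = sample(c("+", "-"), n, replace = TRUE))
    y <- gene_order(sample(labs[1:n]),
                    strands = sample(c("+", "-"), n, replace = TRUE))
    d <- breakpoint_distance(x, y)
    expect_equal(d, naive_breakpoints(x, y))
    expect_equal(d, breakpoint_distance(y, x))
  }
  expect_error(breakpoint_distance(gene_order(c("cox1", "cox1", "cox2")),
                                   gene_order(c("cox1", "cox1", "cox2"))),
               "detect_duplications")
  expect_error(breakpoint_distance(a, a10), "different label sets")
})

test_that("detect_duplications reports copies with positions", {
  o <- apply_events(clitellate_template(),
                    list(list(kind = "duplication", gene = "trnD")))
  d <- detect_duplications(o)
  expect_equal(d$label, "trnD")
  expect_equal(d$count, 2L)
  expect_equal(nrow(detect_duplications(clitellate_template())), 0L)
  o3 <- apply_events(o, list(list(kind = "duplication", gene = "trnD")))
  expect_equal(detect_duplications(o3)$count, 3L)
})

test_that("detect_events returns nothing for identical orders", {
  ref <- normalize_order(clitellate_template())
  expect_equal(nrow(detect_events(ref, ref)), 0L)
})

test_that("an exchanged tRNA pair is reported as one adjacent swap", {
  ref <- normalize_order(clitellate_template())
  q <- apply_events(ref, list(list(kind = "adjacent_swap",
                                   genes = c("trnA", "trnS2"))))
  ev <- detect_events(q, ref)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "adjacent_swap")
  expect_equal(ev$genes, "trnA;trnS2")
})

test_that("each single event kind is recovered by detect_events", {
  ref <- normalize_order(clitellate_template())
  kinds <- c("translocation", "adjacent_swap", "inversion", "duplication",
             "loss")
  set.seed(99)
  for (kind in kinds) {
    for (i in 1:25) {
      ev <- sample_event(ref, kind)
      q <- apply_events(ref, list(ev))
      det <- detect_events(q, ref)
      expect_equal(nrow(det), 1L)
      expect_equal(det$kind, kind)
      genes <- strsplit(det$genes, ";")[[1]]
      expect_true(all((if (kind == "adjacent_swap") ev$genes
                       else if (kind == "inversion") ev$genes
                       else ev$gene) %in% genes))
    }
  }
})

test_that("a duplicated tRNA plus a translocation are both recovered", {
  ref <- normalize_order(clitellate_template())
  q <- apply_events(ref, list(
    list(kind = "duplication", gene = "trnD"),
    list(kind = "translocation", gene = "trnW", to_index = 3L)))
  det <- detect_events(q, ref)
  expect_setequal(det$kind, c("duplication", "translocation"))
  expect_true(any(grepl("trnD", det$genes[det$kind == "duplication"])))
  expect_true(any(grepl("trnW", det$genes[det$kind == "translocation"])))
})

test_that("syntenic blocks cover shared labels and respect rearrangement", {
  a <- clitellate_template()
  expect_equal(syntenic_blocks(a, a), list(a$labels))
  # two blocks exchange locations as units: both reported intact
  lin <- gene_order(c("cox1", "nad2", "cob", "trnG", "nad4L", "nad4"),
                    circular = FALSE)
  swp <- gene_order(c("cox1", "nad4L", "nad4", "trnG", "nad2", "cob"),
                    circular = FALSE)
  blocks <- syntenic_blocks(lin, swp)
  expect_true(any(vapply(blocks, identical, TRUE, c("nad2", "cob"))))
  expect_true(any(vapply(blocks, identical, TRUE, c("nad4L", "nad4"))))
  # disjoint label sets share nothing
  expect_equal(syntenic_blocks(gene_order(c("cox1", "cox2")),
                               gene_order(c("nad1", "nad2"))), list())
})
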
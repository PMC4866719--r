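test_that("GenBank coordinates convert to 0-based half-open", {
  f <- tempfile(fileext = ".gb")
  writeLines(toy_genbank_text(), f)
  m <- read_genbank(f)
  expect_equal(m$length, 1900L)
  expect_equal(m$topology, "circular")
  expect_equal(m$features$label, c("cox1", "trnD", "atp8", "pCR"))
  expect_equal(m$features$start, c(0L, 1536L, 1600L, 1759L))
  expect_equal(m$features$end, c(1536L, 1600L, 1759L, 1900L))
  expect_equal(m$features$kind,
               c("CDS", "tRNA", "CDS", "control_region"))
})

test_that("origin-wrapping join() locations become one wrapped feature", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       WRAP 15190 bp    DNA     circular INV",
               "FEATURES             Location/Qualifiers",
               "     CDS             join(14000..15190,1..200)",
               "                     /gene=\"cox1\"",
               "//"), f)
  m <- read_genbank(f)
  expect_true(m$features$wraps_origin[1])
  expect_equal(m$features$start[1], 13999L)
  expect_equal(m$features$end[1], 200L)
  expect_equal(feature_lengths(m), 15190L - 13999L + 200L)
  # and it survives a round trip through write_genbank
  f2 <- tempfile(fileext = ".gb")
  write_genbank(m, f2)
  m2 <- read_genbank(f2)
  expect_equal(m2$features, m$features)
})

test_that("unknown labels are retained as noncoding with a warning", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       UNK 500 bp    DNA     circular INV",
               "FEATURES             Location/Qualifiers",
               "     CDS             1..300",
               "                     /gene=\"mysterygene\"",
               "//"), f)
  expect_warning(m <- read_genbank(f), "unknown gene label")
  expect_equal(m$features$kind, "noncoding")
  expect_equal(nrow(m$features), 1L)
})

test_that("malformed LOCUS headers raise a parse error naming the line", {
  f <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS horribly wrong", "//"), f)
  expect_error(read_genbank(f), "malformed LOCUS")
})

test_that("label normalization maps synonyms and resolves paralogs", {
  expect_equal(normalize_gene_label(c("COX1", "COI", "cox1")),
               rep("cox1", 3))
  expect_equal(normalize_gene_label(c("CYTB", "cob")), rep("cob", 2))
  expect_equal(normalize_gene_label("tRNA-Asp"), "trnD")
  expect_equal(normalize_gene_label("trnD2"), "trnD")  # copy suffix stripped
  expect_equal(normalize_gene_label("trnL", anticodon = "TAG"), "trnL1")
  expect_equal(normalize_gene_label("trnL", anticodon = "TAA"), "trnL2")
  expect_equal(normalize_gene_label("trnS", anticodon = "TCT"), "trnS1")
  expect_equal(normalize_gene_label("nonsense"), NA_character_)
  expect_equal(normalize_gene_label("weird", extra = c(weird = "nad3")),
               "nad3")
})

test_that("read/write round trip is lossless on random feature sets", {
  labs <- mito_gene_labels()
  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(3:12, 1)
    pick <- sample(labs[labs != "pCR"], n)
    len <- 200L
    rows <- lapply(pick, function(l) {
      kind <- if (l %in% mito_trna_labels()) "tRNA" else NULL
      w <- if (is.null(kind)) sample(90:300, 1) else sample(55:85, 1)
      ac <- if (identical(kind, "tRNA"))
        paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
              collapse = "") else NA_character_
      f <- gene_feature(l, len, len + w, anticodon = ac)
      len <<- len + w + sample(0:20, 1)
      f
    })
    m <- mitogenome(sprintf("RT%03d", seed), len + 100L, do.call(rbind, rows))
    f <- tempfile(fileext = ".gb")
    write_genbank(m, f)
    m2 <- read_genbank(f)
    expect_equal(m2$features, m$features)
    expect_equal(m2$length, m$length)
    unlink(f)
  }
})

test_that("mitogenome invariants are enforced", {
  expect_error(mitogenome("X", 100, gene_feature("cox1", 50, 150)),
               "out of bounds")
  expect_error(mitogenome("X", 500, gene_feature("trnD", 0, 200)),
               "50-90")
  expect_error(mitogenome("X", 500, gene_feature("blah", 0, 90, kind = "CDS")),
               "controlled vocabulary")
  expect_error(
    mitogenome("X", 500, rbind(gene_feature("pCR", 0, 100),
                               gene_feature("pCR", 200, 300))),
    "more than one control_region")
  m <- generate_genome(simulation_config(11))
  expect_silent(validate_mitogenome(m, clitellate = TRUE))
})

test_that("gene_order_of lists genes from position 0 and can drop RNAs", {
  f <- tempfile(fileext = ".gb")
  writeLines(toy_genbank_text(), f)
  m <- read_genbank(f)
  expect_equal(gene_order_of(m)$labels, c("cox1", "trnD", "atp8", "pCR"))
  expect_equal(gene_order_of(m, include_rna = FALSE)$labels,
               c("cox1", "atp8"))
  # wrap-origin gene is listed once, first
  mw <- rotate_mitogenome(m, 1800L)  # origin now falls inside the pCR
  expect_true(mw$features$wraps_origin[mw$features$label == "pCR"])
  expect_equal(gene_order_of(mw)$labels[1], "pCR")
  expect_equal(length(gene_order_of(mw)$labels), 4L)
})

test_that("gene order is rotation invariant up to cyclic rotation", {
  m <- generate_genome(simulation_config(12))
  o1 <- normalize_order(gene_order_of(m))
  for (off in c(1L, 137L, 7001L, m$length - 3L)) {
    o2 <- normalize_order(gene_order_of(rotate_mitogenome(m, off)))
    expect_equal(o2$labels, o1$labels)
    expect_equal(o2$strands, o1$strands)
  }
})

test_that("feature_table exports uid-suffixed duplicate copies", {
  m <- generate_genome(simulation_config(
    21, dup_spec = list(isotype = "trnD", spacer_len = 0L)))
  tab <- feature_table(m)
  expect_equal(sum(tab$uid == "trnD"), 1L)
  expect_equal(sum(tab$uid == "trnD2"), 1L)
  expect_equal(sum(tab$label == "trnD"), 2L)
})
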
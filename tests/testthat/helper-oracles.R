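# Naive full-enumeration oracle for the exact R x 2 homogeneity test:
# enumerates every margin-consistent table directly and sums the
# probabilities of those no more probable than the observed table.
# Independent of the package's pruned engine; feasible for R <= 4, N <= 40.
naive_fisher_rx2 <- function(a, b, tie_eps = 1e-7) {
  r <- a + b
  R <- length(r)
  c1 <- sum(a)
  N <- sum(r)
  if (c1 == 0 || c1 == N) return(1)
  g <- do.call(expand.grid, lapply(r[-R], function(ri) 0:min(ri, c1)))
  last <- c1 - rowSums(g)
  g <- cbind(g, last)[last >= 0 & last <= r[R], , drop = FALSE]
  lp <- -lchoose(N, c1)
  for (i in seq_len(R)) lp <- lp + lchoose(r[i], g[, i])
  lp_obs <- sum(lchoose(r, a)) - lchoose(N, c1)
  sum(exp(lp[lp <= lp_obs + log1p(tie_eps)]))
}

# brute-force breakpoint count: for each consecutive (cyclic) signed pair in
# `a`, scan `b` for the same pair read in either direction
naive_breakpoints <- function(a, b) {
  pairs_of <- function(o) {
    n <- length(o$labels)
    idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
    if (!o$circular) idx <- idx[-n, , drop = FALSE]
    idx
  }
  has_pair <- function(o, x, sx, y, sy) {
    idx <- pairs_of(o)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      if (o$labels[i] == x && o$strands[i] == sx &&
          o$labels[j] == y && o$strands[j] == sy) return(TRUE)
      # same adjacency read on the opposite strand
      fx <- if (sx == "+") "-" else "+"
      fy <- if (sy == "+") "-" else "+"
      if (o$labels[i] == y && o$strands[i] == fy &&
          o$labels[j] == x && o$strands[j] == fx) return(TRUE)
    }
    FALSE
  }
  idx <- pairs_of(a)
  miss <- 0L
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (!has_pair(b, a$labels[i], a$strands[i], a$labels[j], a$strands[j]))
      miss <- miss + 1L
  }
  miss
}

# hand-built 4-feature toy record used across the I/O and curation tests
toy_genbank_text <- function() {
  c("LOCUS       TOY1 1900 bp    DNA     circular INV",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..1536",
    "                     /gene=\"COX1\"",
    "     tRNA            1537..1600",
    "                     /gene=\"tRNA-Asp\"",
    "     CDS             1601..1759",
    "                     /gene=\"ATP8\"",
    "     D-loop          1760..1900",
    "                     /gene=\"pCR\"",
    "//")
}

# a 65 nt pseudo-tRNA block for junction fixtures
trna_block <- function(label = "trnG") {
  list(label = label, seq = paste(rep("ACGGT", 13), collapse = ""))
}

# a small circular genome built from explicit sequence blocks; returns the
# mitogenome plus the block coordinates
build_toy_genome <- function(blocks, topology = "circular") {
  seqs <- vapply(blocks, `[[`, "", "seq")
  ends <- cumsum(nchar(seqs))
  starts <- c(0L, ends[-length(ends)])
  rows <- mapply(function(b, s, e) {
    if (is.null(b$label)) return(NULL)
    ac <- if (is.null(b$anticodon)) NA_character_ else b$anticodon
    if (is.null(b$kind)) gene_feature(b$label, s, e, anticodon = ac)
    else gene_feature(b$label, s, e, kind = b$kind, anticodon = ac)
  }, blocks, starts, ends, SIMPLIFY = FALSE)
  rows <- Filter(Negate(is.null), rows)
  feats <- if (length(rows)) do.call(rbind, rows) else
    gene_feature(character(0), integer(0), integer(0))
  mitogenome("TOY", sum(nchar(seqs)), feats,
             sequence = paste(seqs, collapse = ""), topology = topology,
             validate = FALSE)
}
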
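#' Count codons of a mitogenome under the invertebrate mitochondrial code
#'
#' In-frame triplets are counted per CDS from the curated start position;
#' an incomplete terminal T/TA (see [classify_stop()]) is excluded
#' automatically and stop codons are tallied separately under `aa = "*"`.
#'
#' @param m A `mitogenome` with sequence and CDS annotations.
#' @param curation Curation table from [curate_genome()]; computed when
#'   missing.
#' @param code_table NCBI genetic code id (default `"5"`, invertebrate
#'   mitochondrial).
#' @return An object of class `codon_counts`: list with `id`, `code_table`
#'   and `counts` (`data.frame` codon / aa / count over all 64 codons).
#' @export
count_codons <- function(m, curation = curate_genome(m), code_table = "5") {
  if (is.null(m$sequence)) stop("mitogenome has no sequence")
  code <- Biostrings::getGeneticCode(code_table)
  counts <- stats::setNames(integer(length(code)), names(code))
  idx <- which(m$features$kind == "CDS")
  lens <- feature_lengths(m)
  L <- m$length
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (lens[i] < 3L) stop("CDS '", m$features$label[i], "' shorter than one codon")
    dec <- curation[curation$gene == m$features$label[i], , drop = FALSE][1, ]
    from <- if (!is.na(dec$start_pos)) dec$start_pos else m$features$start[i]
    span <- .circ_dist(from, (m$features$start[i] + lens[i]) %% L, L)
    ncod <- span %/% 3L
    if (ncod < 1L) next
    sq <- .circ_substr(m$sequence, from, 3L * ncod, L)
    cods <- substring(sq, seq(1L, 3L * ncod - 2L, 3L), seq(3L, 3L * ncod, 3L))
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(id = m$id, code_table = code_table,
                 counts = data.frame(codon = names(code), aa = unname(code),
                                     count = unname(counts),
                                     stringsAsFactors = FALSE)),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  used <- x$counts[x$counts$count > 0, ]
  cat("<codon_counts> ", x$id, ": ", sum(used$count), " codons (",
      sum(used$count[used$aa == "*"]), " stops), code table ", x$code_table,
      "\n", sep = "")
  invisible(x)
}

#' Amino-acid frequency vector of a genome's proteome
#'
#' @param cc A [count_codons()] result.
#' @return Named numeric vector over amino acids (stops excluded),
#'   summing to 1.
#' @export
aa_frequencies <- function(cc) {
  ct <- cc$counts[cc$counts$aa != "*", ]
  tot <- tapply(ct$count, ct$aa, sum)
  v <- as.numeric(tot) / sum(tot)
  stats::setNames(v, names(tot))
}

#' Aspartic-acid codon-usage table (GAC vs GAT) across genomes
#'
#' Builds the R x 2 contingency table of synonymous Asp codon counts that
#' the homogeneity analysis operates on: one row per genome, columns GAC
#' and GAT.
#'
#' @param x A list of [count_codons()] results, or a `data.frame` with
#'   columns `organism`, `GAC`, `GAT`.
#' @return An object of class `asp_table` (a `data.frame` with columns
#'   organism, GAC, GAT).
#' @export
asp_table <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("organism", "GAC", "GAT") %in% names(x)))
    tab <- data.frame(organism = as.character(x$organism),
                      GAC = as.integer(x$GAC), GAT = as.integer(x$GAT),
                      stringsAsFactors = FALSE)
  } else {
    if (length(x) < 2L) stop("need at least 2 genomes")
    rows <- lapply(x, function(cc) {
      ct <- cc$counts
      data.frame(organism = cc$id,
                 GAC = ct$count[ct$codon == "GAC"],
                 GAT = ct$count[ct$codon == "GAT"],
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  if (any(tab$GAC < 0 | tab$GAT < 0)) stop("negative counts")
  rownames(tab) <- NULL
  class(tab) <- c("asp_table", "data.frame")
  tab
}

#' The packaged clitellate Asp codon-usage table
#'
#' GAC/GAT counts for nine clitellate mitochondrial proteomes (five
#' oligochaetes and four hirudineans, including the two *Placobdella*
#' species), shipped as a plain-text fixture.
#'
#' @return An [asp_table()] with nine rows (column totals 253 GAC, 405 GAT).
#' @export
asp_table_clitellata <- function() {
  path <- system.file("extdata", "asp_codon_usage_clitellata.tsv",
                      package = "mitocomp", mustWork = TRUE)
  asp_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' GAC/GAT usage ratio, rounded half-up to two decimals
#'
#' @param a GAC count(s).
#' @param b GAT count(s); a zero denominator yields `NA` (undefined).
#' @return Numeric vector of ratios.
#' @export
gac_gat_ratio <- function(a, b) {
  ifelse(b > 0, floor(a / b * 100 + 0.5) / 100, NA_real_)
}

#' Exact conditional test of codon-usage homogeneity (R x 2)
#'
#' Two-sided exact test on an R x 2 table under the probability-ordering
#' criterion: conditioning on all margins, the p-value is the total
#' probability of margin-consistent tables no more probable than the
#' observed one, P(table) = prod_i C(r_i, a_i) / C(N, c1), with relative
#' tie tolerance `tie_eps`. The enumeration is a pruned stage-wise scan
#' (feasibility pruning, O(1) whole-subtree inclusion/exclusion via
#' precomputed suffix bounds and mass sums, and clustering of partial paths
#' with near-identical log-probability), which keeps tables with R up to 9
#' and several hundred observations exact and tractable -- no Monte Carlo.
#'
#' @param x An [asp_table()], or an R x 2 matrix/data.frame of counts.
#' @param tie_eps Relative tie tolerance on the probability ordering.
#' @param delta Path-clustering quantum; `NULL` selects automatically from
#'   the enumeration size (effectively exact below 1e7 tables, then 1e-4 /
#'   1e-3 with ~5e-5 / ~5e-4 documented relative accuracy).
#' @param alpha When supplied, the scan stops as soon as the comparison
#'   `p > alpha` is decided and returns bounded values (used by
#'   [homogeneous_subgroups()]).
#' @return Numeric p-value in (0, 1], with attributes `p_lower`, `p_upper`,
#'   `resolved`, `nodes`, `n_tables`.
#' @examples
#' fisher_exact_rx2(matrix(c(3, 1, 1, 3), 2))
#' @export
fisher_exact_rx2 <- function(x, tie_eps = 1e-7, delta = NULL, alpha = NULL) {
  ab <- .as_rx2(x)
  if (nrow(ab) < 2L) stop("need at least 2 rows")
  res <- .fisher_rx2_engine(ab[, 1L], ab[, 2L], tie_eps,
                            if (is.null(delta)) -1 else delta,
                            if (is.null(alpha)) NA_real_ else alpha)
  structure(res$p, p_lower = res$p_lower, p_upper = res$p_upper,
            resolved = res$resolved, nodes = res$nodes,
            n_tables = res$n_tables)
}

.as_rx2 <- function(x) {
  if (inherits(x, "asp_table")) return(cbind(x$GAC, x$GAT))
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("expected an R x 2 table")
  storage.mode(x) <- "integer"
  x
}

#' Kruskal-Wallis rank test across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H statistic,
#' chi-squared upper-tail p on k - 1 degrees of freedom), in the shape used
#' by the amino-acid frequency comparisons.
#'
#' @param groups List of numeric vectors (>= 2 groups, each nonempty).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need >= 2 nonempty groups")
  vals <- unlist(groups, use.names = FALSE)
  if (length(unique(vals)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(vals, factor(rep(seq_along(groups), lengths(groups))))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Progressive search for maximal codon-usage-homogeneous subgroups
#'
#' Enumerates row subsets of size >= 2 in decreasing size; a subset is
#' homogeneous iff its exact test p-value exceeds `alpha`. Subsets of an
#' already-accepted group are skipped, so the reported groups are maximal
#' (no homogeneous strict superset exists). The homogeneity decision uses
#' the early-terminating mode of [fisher_exact_rx2()]; exact p-values are
#' recomputed in full for the reported groups.
#'
#' @param t An [asp_table()].
#' @param alpha Significance threshold in (0, 1).
#' @return Object of class `subgroup_result`: list with `groups` (a
#'   `data.frame`: members, size, p), `alpha`, `n_tested`.
#' @export
homogeneous_subgroups <- function(t, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  R <- nrow(t)
  if (R < 3L) stop("need at least 3 rows")
  accepted <- list()
  n_tested <- 0L
  # The homogeneity decision runs the exact scan with coarse path
  # clustering (relative accuracy a few 1e-3) plus running-bound early
  # exit; only subsets whose p lands within 1.5x of alpha are re-scanned
  # at full accuracy before deciding.
  decide_homogeneous <- function(sub) {
    p <- fisher_exact_rx2(sub, delta = 0.1, alpha = alpha)
    if (attr(p, "p_lower") > alpha * 1.5) return(TRUE)
    if (attr(p, "p_upper") <= alpha / 1.5) return(FALSE)
    as.numeric(fisher_exact_rx2(sub)) > alpha
  }
  for (sz in R:2) {
    for (cs in utils::combn(R, sz, simplify = FALSE)) {
      if (any(vapply(accepted, function(g) all(cs %in% g), logical(1))))
        next  # strict subset of a homogeneous group: not maximal
      n_tested <- n_tested + 1L
      if (decide_homogeneous(t[cs, , drop = FALSE]))
        accepted[[length(accepted) + 1L]] <- cs
    }
  }
  groups <- do.call(rbind, lapply(accepted, function(g) {
    data.frame(members = paste(t$organism[g], collapse = ";"),
               size = length(g),
               p = as.numeric(fisher_exact_rx2(t[g, , drop = FALSE])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(groups))
    groups <- data.frame(members = character(0), size = integer(0),
                         p = numeric(0), stringsAsFactors = FALSE)
  structure(list(groups = groups, alpha = alpha, n_tested = n_tested,
                 member_indices = accepted, table = t),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat("<subgroup_result> alpha =", x$alpha, "--", nrow(x$groups),
      "maximal homogeneous group(s) from", x$n_tested, "tested subsets\n")
  if (nrow(x$groups)) print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Effect of adding one genome to a candidate group
#'
#' @param t An [asp_table()].
#' @param group Row indices or organism names of the candidate group.
#' @param add Row index or organism name to add.
#' @return p-value of the augmented group's exact test.
#' @export
subgroup_with <- function(t, group, add) {
  ix <- function(v) if (is.character(v)) match(v, t$organism) else as.integer(v)
  rows <- c(ix(group), ix(add))
  if (anyNA(rows)) stop("unknown organism")
  fisher_exact_rx2(t[rows, , drop = FALSE])
}
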
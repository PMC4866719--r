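#' A+T fraction of a DNA string
#'
#' @param x Character DNA string.
#' @return Fraction of A/T bases in (0, 1); `NaN` for an empty string.
#' @export
at_content <- function(x) {
  n <- nchar(x)
  if (!n) return(NaN)
  (n - nchar(gsub("[AT]", "", toupper(x)))) / n
}

#' Find intergenic (unannotated) spans of a mitogenome
#'
#' Positions not covered by any gene feature (CDS, tRNA, rRNA). Annotated
#' control-region and noncoding features do not count as coverage -- the
#' putative control region is itself the largest such span. The circular
#' wrap is included; spans are sorted by decreasing length.
#'
#' @param m A `mitogenome`.
#' @param min_len Minimum span length to report.
#' @return `data.frame`: start, end (0-based half-open, end may wrap),
#'   length, upstream, downstream (flanking gene labels), at_content
#'   (`NA` without sequence).
#' @export
find_intergenic <- function(m, min_len = 1L) {
  L <- m$length
  f <- m$features[m$features$kind %in% c("CDS", "tRNA", "rRNA"), , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      upstream = character(0), downstream = character(0),
                      at_content = numeric(0), stringsAsFactors = FALSE)
  if (!nrow(f)) return(empty)
  covered <- logical(L)
  lens <- ifelse(f$wraps_origin, L - f$start + f$end, f$end - f$start)
  for (i in seq_len(nrow(f))) {
    pos <- (f$start[i] + seq_len(lens[i]) - 1L) %% L
    covered[pos + 1L] <- TRUE
  }
  if (all(covered)) return(empty)
  if (!any(covered)) stop("no gene coverage")
  # runs of uncovered positions, treated circularly
  gapstart <- which(!covered & covered[c(L, seq_len(L - 1L))]) - 1L
  rows <- lapply(gapstart, function(s) {
    len <- 0L
    while (!covered[(s + len) %% L + 1L]) len <- len + 1L
    e <- (s + len) %% L
    up <- f$label[which((f$end %% L) == s)]
    if (!length(up)) { # nearest feature end, circularly before the gap
      d <- .circ_dist(f$end %% L, s, L)
      up <- f$label[which.min(d)]
    }
    dn <- f$label[which(f$start == e)]
    if (!length(dn)) {
      d <- .circ_dist(e, f$start, L)
      dn <- f$label[which.min(d)]
    }
    atc <- if (is.null(m$sequence)) NA_real_ else
      at_content(.circ_substr(m$sequence, s, len, L))
    data.frame(start = s, end = e, length = len, upstream = up[1],
               downstream = dn[1], at_content = atc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$length >= min_len, , drop = FALSE]
  out <- out[order(-out$length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify the putative control region (pCR)
#'
#' Operationally, the pCR candidate is the longest intergenic span; the
#' positional signature of clitellate mitogenomes is then checked: the span
#' conforms when flanked by `trnR` upstream and `trnH` downstream. The flag
#' is invariant under genome rotation.
#'
#' @param m A `mitogenome` with at least one intergenic span.
#' @return List: `span` (one-row `data.frame` as in [find_intergenic()]),
#'   `conforms` (logical).
#' @export
identify_pcr <- function(m) {
  ig <- find_intergenic(m)
  if (!nrow(ig)) stop("no intergenic span found")
  span <- ig[1L, , drop = FALSE]
  list(span = span,
       conforms = span$upstream == "trnR" && span$downstream == "trnH")
}

#' Compare the copies of a duplicated tRNA gene
#'
#' Reports each copy's anticodon, flanking genes, the spacer length between
#' consecutive copies, and pairwise percent identity from a global
#' alignment (match +1, mismatch -1, gap -2; identity = matching columns /
#' alignment columns).
#'
#' @param m A `mitogenome` with sequence.
#' @param isotype tRNA label occurring at least twice (e.g. `"trnD"`).
#' @return List: `isotype`, `n_copies`, `copies` (`data.frame`: start, end,
#'   length, anticodon, upstream, downstream), `spacer` (length(s) between
#'   consecutive copies), `identity` (`data.frame`: copy_i, copy_j,
#'   matches, columns, identity).
#' @export
compare_trna_copies <- function(m, isotype) {
  idx <- which(m$features$label == isotype)
  if (length(idx) < 2L)
    stop("isotype '", isotype, "' has ", length(idx),
         " copies; need at least 2")
  if (is.null(m$sequence)) stop("mitogenome has no sequence")
  f <- m$features
  lens <- feature_lengths(m)
  copies <- data.frame(
    start = f$start[idx], end = f$end[idx], length = lens[idx],
    anticodon = f$anticodon[idx],
    upstream = f$label[vapply(idx, .neighbor_index, 0L, m = m, side = "up")],
    downstream = f$label[vapply(idx, .neighbor_index, 0L, m = m, side = "down")],
    stringsAsFactors = FALSE)
  spacer <- if (length(idx) > 1L)
    vapply(seq_len(length(idx) - 1L), function(k)
      .circ_dist(f$end[idx[k]] %% m$length, f$start[idx[k + 1L]], m$length),
      0) else numeric(0)
  seqs <- vapply(idx, function(i) feature_seq(m, i), "")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pairs <- utils::combn(seq_along(idx), 2L)
  id <- apply(pairs, 2L, function(pr) {
    al <- Biostrings::pairwiseAlignment(seqs[pr[1]], seqs[pr[2]],
                                        substitutionMatrix = mat,
                                        gapOpening = 0, gapExtension = 2,
                                        type = "global")
    p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    c(matches = sum(p == s), columns = length(p))
  })
  identity <- data.frame(copy_i = pairs[1, ], copy_j = pairs[2, ],
                         matches = id["matches", ], columns = id["columns", ],
                         identity = id["matches", ] / id["columns", ])
  list(isotype = isotype, n_copies = length(idx), copies = copies,
       spacer = as.integer(spacer), identity = identity)
}
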
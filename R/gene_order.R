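#' Construct a gene order
#'
#' The circular (or linear) ordered list of gene labels and strands used for
#' rearrangement analysis. Duplicate labels are allowed (gene duplications).
#'
#' @param labels Character vector of gene labels (length >= 1).
#' @param strands `"+"`/`"-"` vector, recycled to `length(labels)`.
#' @param circular Is the order circular?
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(labels, strands = "+", circular = TRUE) {
  labels <- as.character(labels)
  if (!length(labels)) stop("gene order must have at least one element")
  strands <- rep_len(as.character(strands), length(labels))
  if (!all(strands %in% c("+", "-"))) stop("strands must be '+' or '-'")
  structure(list(labels = labels, strands = strands,
                 circular = isTRUE(circular)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  sym <- ifelse(x$strands == "-", paste0("-", x$labels), x$labels)
  cat("<gene_order> ", if (x$circular) "circular" else "linear",
      ", ", length(x$labels), " genes\n  ", paste(sym, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$labels)

#' Normalize a gene order onto a fixed anchor
#'
#' Rotates a circular order so `anchor` comes first; if the anchor lies on
#' the minus strand the whole order is reversed and strands are flipped so
#' that the anchor reads `+`. Idempotent. Every genome in scope encodes
#' `cox1`, hence the default anchor.
#'
#' @param o A [gene_order()].
#' @param anchor Anchor label; must occur exactly once.
#' @return The normalized `gene_order`.
#' @export
normalize_order <- function(o, anchor = "cox1") {
  hit <- which(o$labels == anchor)
  if (length(hit) != 1L)
    stop("anchor '", anchor, "' must occur exactly once (found ",
         length(hit), ")")
  lab <- o$labels; str <- o$strands
  if (str[hit] == "-") {
    lab <- rev(lab)
    str <- rev(ifelse(str == "+", "-", "+"))
    hit <- length(lab) - hit + 1L
  }
  if (hit != 1L) {
    if (!o$circular)
      stop("cannot rotate a linear order to anchor '", anchor, "'")
    idx <- c(hit:length(lab), seq_len(hit - 1L))
    lab <- lab[idx]; str <- str[idx]
  }
  gene_order(lab, str, o$circular)
}

# restrict an order to a subset of labels, keeping order and strands
.restrict_order <- function(o, keep) {
  sel <- o$labels %in% keep
  if (!any(sel)) return(NULL)
  gene_order(o$labels[sel], o$strands[sel], o$circular)
}

#' Are two gene orders identical on the protein-coding genes?
#'
#' Compares the PCG-only subsequences (labels and strands) after
#' normalization, cyclically for circular orders.
#'
#' @param a,b [gene_order()] objects.
#' @param anchor Anchor passed to [normalize_order()].
#' @return Logical scalar.
#' @export
pcg_order_identical <- function(a, b, anchor = "cox1") {
  pa <- .restrict_order(normalize_order(a, anchor), mito_pcg_labels())
  pb <- .restrict_order(normalize_order(b, anchor), mito_pcg_labels())
  if (is.null(pa) || is.null(pb)) return(is.null(pa) && is.null(pb))
  identical(pa$labels, pb$labels) && identical(pa$strands, pb$strands)
}

# canonical signed adjacency strings of an order (cyclic if circular):
# the adjacency (x>, y>) equals its reading on the other strand (<y, <x)
.adjacencies <- function(o) {
  n <- length(o$labels)
  i <- seq_len(if (o$circular) n else n - 1L)
  j <- if (o$circular) c(seq_len(n)[-1], 1L) else i + 1L
  x <- paste0(o$strands[i], o$labels[i]); y <- paste0(o$strands[j], o$labels[j])
  flip <- function(s) ifelse(substr(s, 1, 1) == "+",
                             paste0("-", substring(s, 2)),
                             paste0("+", substring(s, 2)))
  fwd <- paste(x, y, sep = "|")
  rev <- paste(flip(y), flip(x), sep = "|")
  ifelse(fwd < rev, fwd, rev)
}

#' Breakpoint distance between two gene orders
#'
#' The number of signed (cyclic) gene adjacencies present in one order but
#' not the other -- a standard, symmetric rearrangement dissimilarity.
#' Duplicated labels are rejected; detect and resolve duplications first
#' (see [detect_duplications()]).
#'
#' @param a,b [gene_order()] objects over the same label multiset.
#' @return Non-negative integer.
#' @export
breakpoint_distance <- function(a, b) {
  if (anyDuplicated(a$labels) || anyDuplicated(b$labels))
    stop("duplicated labels; run detect_duplications() and resolve copies first")
  if (!setequal(a$labels, b$labels))
    stop("gene orders are over different label sets")
  length(setdiff(.adjacencies(a), .adjacencies(b)))
}

#' Detect duplicated genes in an order
#'
#' @param o A [gene_order()].
#' @return `data.frame` with columns label, count, positions
#'   (comma-separated 1-based indices); zero rows when no label repeats.
#' @export
detect_duplications <- function(o) {
  tab <- table(o$labels)
  dup <- names(tab)[tab >= 2L]
  if (!length(dup))
    return(data.frame(label = character(0), count = integer(0),
                      positions = character(0), stringsAsFactors = FALSE))
  data.frame(label = dup,
             count = as.integer(tab[dup]),
             positions = vapply(dup, function(l)
               paste(which(o$labels == l), collapse = ","), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

# longest common subsequence of two label vectors; returns index pairs
.lcs_indices <- function(x, y) {
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1L, j + 1L] <- if (x[i] == y[j]) D[i, j] + 1L
                         else max(D[i, j + 1L], D[i + 1L, j])
  ii <- integer(0); jj <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (x[i] == y[j] && D[i + 1L, j + 1L] == D[i, j] + 1L) {
      ii <- c(i, ii); jj <- c(j, jj); i <- i - 1L; j <- j - 1L
    } else if (D[i, j + 1L] >= D[i + 1L, j]) i <- i - 1L else j <- j - 1L
  }
  cbind(ref = ii, query = jj)
}

.event_row <- function(kind, genes, from_index = NA_integer_,
                       to_index = NA_integer_) {
  data.frame(kind = kind, genes = paste(genes, collapse = ";"),
             from_index = as.integer(from_index),
             to_index = as.integer(to_index), stringsAsFactors = FALSE)
}

#' Detect rearrangement events between a query and a reference order
#'
#' A deterministic greedy pipeline with fixed priority: (1) label multiset
#' differences become duplication / loss events; (2) maximal runs whose
#' strand is flipped relative to the reference and whose reversed labels are
#' contiguous in the reference become inversions (and are flipped back);
#' (3) labels off the longest common subsequence of the remaining orders
#' become translocations, with two adjacently exchanged genes reported as a
#' single `adjacent_swap`. Events are sorted by reference position. The
#' inference is parsimony-of-description, not an optimization; composite
#' event sets are recovered best-effort.
#'
#' @param query,ref [gene_order()] objects (normalized; see
#'   [normalize_order()]).
#' @return `data.frame` with columns kind, genes (`;`-separated),
#'   from_index (reference position), to_index (query position).
#' @export
detect_events <- function(query, ref) {
  if (!length(query$labels) || !length(ref$labels)) stop("empty gene order")
  ev <- list()
  tq <- table(query$labels); tr <- table(ref$labels)
  all_lab <- union(names(tq), names(tr))
  nq <- ifelse(is.na(tq[all_lab]), 0L, tq[all_lab])
  nr <- ifelse(is.na(tr[all_lab]), 0L, tr[all_lab])
  names(nq) <- names(nr) <- all_lab
  for (l in all_lab[nq > nr])
    ev[[length(ev) + 1L]] <- .event_row("duplication", rep(l, nq[[l]]),
                                        from_index = match(l, ref$labels),
                                        to_index = match(l, query$labels))
  for (l in all_lab[nq < nr])
    ev[[length(ev) + 1L]] <- .event_row("loss", l,
                                        from_index = match(l, ref$labels))
  shared <- all_lab[nq >= 1L & nr >= 1L & pmax(nq, nr) >= 1L]
  shared <- shared[nq[shared] >= 1L & nr[shared] >= 1L]
  # reduce to single copies: keep first occurrence of each shared label
  first_of <- function(o) {
    keep <- !duplicated(o$labels) & o$labels %in% shared
    gene_order(o$labels[keep], o$strands[keep], o$circular)
  }
  q <- first_of(query); r <- first_of(ref)
  rpos <- match(q$labels, r$labels)
  rstr <- r$strands[rpos]
  # (2) inversions: maximal runs with flipped strand, reversed-contiguous in ref
  flipped <- q$strands != rstr
  if (any(flipped)) {
    runs <- rle(flipped)
    endi <- cumsum(runs$lengths); starti <- endi - runs$lengths + 1L
    qlab <- q$labels
    for (k in which(runs$values)) {
      idx <- starti[k]:endi[k]
      rp <- rpos[idx]
      ev[[length(ev) + 1L]] <- .event_row("inversion",
                                          r$labels[sort(rp)],
                                          from_index = min(rp),
                                          to_index = idx[1])
      if (length(idx) == 1L || all(diff(rev(rp)) == 1L))
        qlab[idx] <- rev(qlab[idx]) # undo so step (3) sees pre-inversion order
    }
    # restore strands from the reference by label
    qstr <- r$strands[match(qlab, r$labels)]
    q <- gene_order(qlab, qstr, q$circular)
    rpos <- match(q$labels, r$labels)
  }
  # (3) translocations / adjacent swaps off the LCS
  lcs <- .lcs_indices(r$labels, q$labels)
  off <- setdiff(seq_along(q$labels), lcs[, "query"])
  used <- logical(length(q$labels))
  for (j in off) {
    if (used[j]) next
    g <- q$labels[j]
    fi <- match(g, r$labels)
    swapped <- FALSE
    for (nb in c(j - 1L, j + 1L)) {
      if (nb < 1L || nb > length(q$labels) || used[nb]) next
      h <- q$labels[nb]
      fh <- match(h, r$labels)
      # g,h adjacent in both orders but in opposite relative order,
      # and swapping them back reproduces the reference order
      if (!is.na(fh) && abs(fh - fi) == 1L && sign(fh - fi) != sign(nb - j)) {
        test <- q$labels
        test[c(j, nb)] <- test[c(nb, j)]
        if (identical(test, r$labels)) {
          pair <- if (fi < fh) c(g, h) else c(h, g)
          ev[[length(ev) + 1L]] <- .event_row("adjacent_swap", pair,
                                              from_index = min(fi, fh),
                                              to_index = min(j, nb))
          used[c(j, nb)] <- TRUE
          swapped <- TRUE
          break
        }
      }
    }
    if (!swapped) {
      ev[[length(ev) + 1L]] <- .event_row("translocation", g,
                                          from_index = fi, to_index = j)
      used[j] <- TRUE
    }
  }
  if (!length(ev))
    return(data.frame(kind = character(0), genes = character(0),
                      from_index = integer(0), to_index = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, ev)
  out <- out[order(out$from_index, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Syntenic blocks shared by two gene orders
#'
#' Maximal runs of genes that are contiguous and co-oriented in both orders
#' (cyclic-aware); together the blocks cover all labels occurring exactly
#' once in each order.
#'
#' @param a,b [gene_order()] objects.
#' @return List of character vectors (runs in the orientation of `a`).
#' @export
syntenic_blocks <- function(a, b) {
  shared <- intersect(a$labels[!(duplicated(a$labels) |
                                 duplicated(a$labels, fromLast = TRUE))],
                      b$labels[!(duplicated(b$labels) |
                                 duplicated(b$labels, fromLast = TRUE))])
  if (!length(shared)) return(list())
  ra <- .restrict_order(a, shared); rb <- .restrict_order(b, shared)
  n <- length(ra$labels)
  if (n == 1L) return(list(ra$labels))
  posb <- match(ra$labels, rb$labels)
  relstr <- (ra$strands == rb$strands[posb])
  cyc <- ra$circular && rb$circular
  m <- length(rb$labels)
  nexti <- if (cyc) c(seq_len(n)[-1], 1L) else c(seq_len(n)[-1], NA)
  linked <- logical(n) # linked[i]: edge i -> next(i) preserved in b
  for (i in seq_len(n)) {
    j <- nexti[i]
    if (is.na(j)) next
    succ <- if (cyc) posb[i] %% m + 1L else posb[i] + 1L
    linked[i] <- relstr[i] && relstr[j] && posb[j] == succ
  }
  if (all(linked)) return(list(ra$labels))
  # blocks are maximal chains of linked edges; start after each unlinked edge
  starts <- which(!linked) %% n + 1L
  blocks <- list()
  for (s in sort(unique(starts))) {
    run <- s
    i <- s
    while (linked[i]) {
      i <- nexti[i]
      run <- c(run, i)
    }
    blocks[[length(blocks) + 1L]] <- ra$labels[run]
  }
  blocks
}
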
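#' @useDynLib mitocomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# index of the feature immediately upstream / downstream of feature i:
# the previous / next non-noncoding feature in cyclic start order (robust
# to overlapping annotations such as nad4L running into nad4)
.neighbor_index <- function(m, i, side = c("up", "down")) {
  side <- match.arg(side)
  f <- m$features
  cand <- which(f$kind != "noncoding")
  if (length(cand) < 2L || !(i %in% cand)) stop("no neighboring feature")
  ord <- cand[order(!f$wraps_origin[cand], f$start[cand], f$end[cand])]
  k <- match(i, ord)
  n <- length(ord)
  if (side == "up") ord[(k - 2L) %% n + 1L] else ord[k %% n + 1L]
}

#' Assign a start codon to a CDS by the junction-scan rule
#'
#' Putative start codons are identified on the basis of immediately
#' following the 3' end of the upstream coding sequence, tRNA or rRNA:
#' in-frame triplets are scanned from the first base after the upstream
#' feature's 3' end over a window of `window` codons, and the first
#' candidate from `candidates` is chosen -- except that ATG anywhere in the
#' window is preferred over a nearer alternative codon. When the upstream
#' feature overlaps the annotated CDS start, the scan starts at the
#' annotated start instead.
#'
#' @param m A `mitogenome` with sequence.
#' @param cds Row index of a CDS feature in `m$features`.
#' @param window Scan window, in codons.
#' @param candidates Allowed start triplets, most- to least-preferred.
#' @return One-row `data.frame`: gene, start_codon (`NA` if none found),
#'   start_pos (0-based), start_note.
#' @export
assign_start <- function(m, cds, window = 10L,
                         candidates = c("ATG", "GTG", "TTG")) {
  if (is.null(m$sequence)) stop("mitogenome has no sequence")
  f <- m$features[cds, ]
  if (f$kind != "CDS") stop("feature ", cds, " is not a CDS")
  L <- m$length
  up <- .neighbor_index(m, cds, "up")
  upend <- m$features$end[up] %% L
  gap <- .circ_dist(upend, f$start, L)
  junction <- if (gap > L / 2) f$start else upend  # upstream overlaps the CDS
  win <- .circ_substr(m$sequence, junction, 3L * window, L)
  cods <- substring(win, seq(1, 3L * window - 2L, 3L), seq(3, 3L * window, 3L))
  hits <- which(cods %in% candidates)
  note <- ""
  if (!length(hits)) {
    return(data.frame(gene = f$label, start_codon = NA_character_,
                      start_pos = NA_integer_,
                      start_note = sprintf("no candidate start in %d codons after %s",
                                           window, m$features$label[up]),
                      stringsAsFactors = FALSE))
  }
  atg <- which(cods == "ATG")
  k <- if (length(atg)) atg[1] else hits[1]
  if (length(atg) && hits[1] != atg[1])
    note <- sprintf("ATG at codon %d preferred over %s at codon %d",
                    atg[1], cods[hits[1]], hits[1])
  data.frame(gene = f$label, start_codon = cods[k],
             start_pos = as.integer((junction + 3L * (k - 1L)) %% L),
             start_note = note, stringsAsFactors = FALSE)
}

#' Classify the stop codon of a CDS
#'
#' Three-way classification: (1) `canonical` -- an in-frame TAA/TAG ends at
#' or before the downstream feature's start (no overlap with a tRNA);
#' (2) `partial_TA` / `partial_T` -- the CDS's final in-frame bases are TA
#' or T and a tRNA abuts directly (gap 0), the stop being completed to TAA
#' by post-transcriptional 3' adenylation of the mRNA; (3) `overlap` -- the
#' CDS runs into the downstream feature, with the overlap length recorded.
#'
#' @inheritParams assign_start
#' @return One-row `data.frame`: gene, stop_class, stop_codon,
#'   overlap_len, stop_note.
#' @export
classify_stop <- function(m, cds) {
  if (is.null(m$sequence)) stop("mitogenome has no sequence")
  f <- m$features[cds, ]
  if (f$kind != "CDS") stop("feature ", cds, " is not a CDS")
  L <- m$length
  len <- feature_lengths(m)[cds]
  if (len < 3L) stop("CDS shorter than one codon")
  dn <- .neighbor_index(m, cds, "down")
  dnf <- m$features[dn, ]
  endpos <- (f$start + len) %% L
  gap <- .circ_dist(endpos, dnf$start, L)
  overlap <- if (gap > L / 2) L - gap else 0L  # downstream starts inside CDS
  rem <- len %% 3L
  res <- function(class, codon, note = "", olen = 0L) {
    data.frame(gene = f$label, stop_class = class, stop_codon = codon,
               overlap_len = as.integer(olen), stop_note = note,
               stringsAsFactors = FALSE)
  }
  if (rem == 0L) {
    last <- .circ_substr(m$sequence, (f$start + len - 3L) %% L, 3L, L)
    if (last %in% c("TAA", "TAG") && overlap == 0L)
      return(res("canonical", last))
  } else {
    tail <- .circ_substr(m$sequence, (f$start + len - rem) %% L, rem, L)
    if (overlap == 0L && gap == 0L && dnf$kind == "tRNA" &&
        tail %in% c("T", "TA")) {
      return(res(paste0("partial_", tail), tail,
                 note = "completed to TAA by post-transcriptional 3' adenylation"))
    }
  }
  res("overlap", "",
      note = sprintf("3' end overlaps %s by %d bp", dnf$label, overlap),
      olen = overlap)
}

#' Curate all protein-coding genes of a mitogenome
#'
#' Applies [assign_start()] and [classify_stop()] to every CDS; the result
#' is deterministic given the genome and invariant under rotation.
#'
#' @inheritParams assign_start
#' @return `data.frame` with one row per CDS: gene, start_codon, start_pos,
#'   stop_class, stop_codon, overlap_len, start_note, stop_note.
#' @export
curate_genome <- function(m, window = 10L,
                          candidates = c("ATG", "GTG", "TTG")) {
  idx <- which(m$features$kind == "CDS")
  if (!length(idx))
    return(data.frame(gene = character(0), start_codon = character(0),
                      start_pos = integer(0), stop_class = character(0),
                      stop_codon = character(0), overlap_len = integer(0),
                      start_note = character(0), stop_note = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(idx, function(i) {
    s <- assign_start(m, i, window = window, candidates = candidates)
    e <- classify_stop(m, i)
    cbind(s[, c("gene", "start_codon", "start_pos")],
          e[, c("stop_class", "stop_codon", "overlap_len")],
          s[, "start_note", drop = FALSE], e[, "stop_note", drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
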
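#' Controlled mitochondrial gene vocabulary
#'
#' Gene labels used throughout the package: the 13 protein-coding genes
#' (PCGs), 22 tRNAs (with the Leu/Ser paralogs disambiguated as
#' `trnL1`/`trnL2` and `trnS1`/`trnS2`), the two rRNAs, the putative control
#' region (`pCR`) and a catch-all `noncoding` kind for unrecognized features.
#'
#' @return Character vector of valid labels.
#' @export
mito_gene_labels <- function() {
  c(mito_pcg_labels(), mito_trna_labels(), c("rrnS", "rrnL"), "pCR")
}

#' @rdname mito_gene_labels
#' @export
mito_pcg_labels <- function() {
  c("cox1", "cox2", "cox3", "cob", "atp6", "atp8",
    "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
}

#' @rdname mito_gene_labels
#' @export
mito_trna_labels <- function() {
  paste0("trn", c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                  "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y"))
}

.kind_for_label <- function(label) {
  ifelse(label %in% mito_pcg_labels(), "CDS",
    ifelse(label %in% mito_trna_labels(), "tRNA",
      ifelse(label %in% c("rrnS", "rrnL"), "rRNA",
        ifelse(label == "pCR", "control_region", "noncoding"))))
}

#' Construct a gene feature table
#'
#' Features use 0-based half-open coordinates internally; GenBank I/O
#' converts to/from 1-based inclusive. A feature crossing the origin of a
#' circular genome is stored contiguously with `wraps_origin = TRUE`
#' (its `end` is then less than or equal to its `start`).
#'
#' @param label Gene label (see [mito_gene_labels()]); arbitrary labels are
#'   allowed for `kind = "noncoding"`.
#' @param kind One of `"CDS"`, `"tRNA"`, `"rRNA"`, `"control_region"`,
#'   `"noncoding"`. Defaults to the kind implied by the label.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @param anticodon Optional 3-letter DNA triplet (tRNA features only).
#' @param wraps_origin Does the feature span the origin?
#' @return A `data.frame` with one row per feature.
#' @export
gene_feature <- function(label, start, end, kind = .kind_for_label(label),
                         strand = "+", anticodon = NA_character_,
                         wraps_origin = FALSE) {
  data.frame(label = as.character(label), kind = as.character(kind),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand),
             anticodon = as.character(anticodon),
             wraps_origin = as.logical(wraps_origin),
             stringsAsFactors = FALSE)
}

.empty_features <- function() {
  gene_feature(character(0), integer(0), integer(0), kind = character(0),
               strand = character(0), anticodon = character(0),
               wraps_origin = logical(0))
}

#' Construct an annotated mitogenome
#'
#' @param id Accession-like identifier.
#' @param length Genome length in bases.
#' @param features Feature table as built by [gene_feature()] (rows are
#'   re-sorted by start, ties broken by end).
#' @param sequence Optional uppercase DNA string of length `length`.
#' @param taxon Free-text organism name.
#' @param topology `"circular"` or `"linear"`.
#' @param validate Run [validate_mitogenome()]?
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, length, features = .empty_features(),
                       sequence = NULL, taxon = "", topology = "circular",
                       validate = TRUE) {
  if (nrow(features)) {
    ord <- order(features$start, features$end)
    features <- features[ord, , drop = FALSE]
    rownames(features) <- NULL
  }
  m <- structure(list(id = as.character(id), taxon = as.character(taxon),
                      topology = match.arg(topology, c("circular", "linear")),
                      length = as.integer(length),
                      sequence = if (is.null(sequence)) NULL else toupper(sequence),
                      features = features),
                 class = "mitogenome")
  if (validate) validate_mitogenome(m)
  m
}

#' Validate a mitogenome against the package's structural invariants
#'
#' Checks coordinate bounds, label vocabulary, tRNA lengths (50-90 nt),
#' anticodon syntax, the at-most-one control region rule and, optionally,
#' the clitellate 37-gene single-strand organization.
#'
#' @param m A `mitogenome`.
#' @param clitellate Additionally require 13 PCGs, at least 22 tRNA features,
#'   2 rRNAs and a single coding strand.
#' @return `m`, invisibly; errors describe the first violated invariant.
#' @export
validate_mitogenome <- function(m, clitellate = FALSE) {
  stopifnot(inherits(m, "mitogenome"))
  f <- m$features
  L <- m$length
  if (!is.null(m$sequence) && nchar(m$sequence) != L)
    stop("sequence length (", nchar(m$sequence), ") != declared length (", L, ")")
  if (nrow(f)) {
    bad <- !f$wraps_origin & !(f$start >= 0 & f$start < f$end & f$end <= L)
    if (any(bad))
      stop("feature coordinates out of bounds: ", paste(f$label[bad], collapse = ", "))
    if (any(f$wraps_origin & m$topology != "circular"))
      stop("wraps_origin feature in a linear genome")
    badlab <- !(f$label %in% mito_gene_labels()) & f$kind != "noncoding"
    if (any(badlab))
      stop("labels outside controlled vocabulary: ",
           paste(unique(f$label[badlab]), collapse = ", "))
    ac <- f$anticodon[!is.na(f$anticodon)]
    if (length(ac) && !all(grepl("^[ACGT]{3}$", ac)))
      stop("malformed anticodon triplet")
    if (any(!is.na(f$anticodon) & f$kind != "tRNA"))
      stop("anticodon on a non-tRNA feature")
    tl <- feature_lengths(m)[f$kind == "tRNA"]
    if (length(tl) && any(tl < 50 | tl > 90))
      stop("tRNA feature length outside 50-90 nt")
    if (sum(f$kind == "control_region") > 1)
      stop("more than one control_region feature")
  }
  if (clitellate) {
    if (sum(f$kind == "CDS") != 13) stop("expected 13 protein-coding genes")
    if (sum(f$kind == "tRNA") < 22) stop("expected at least 22 tRNA genes")
    if (sum(f$kind == "rRNA") != 2) stop("expected 2 rRNA genes")
    gs <- f$strand[f$kind %in% c("CDS", "tRNA", "rRNA")]
    if (length(unique(gs)) != 1)
      stop("clitellate organization requires all genes on one strand")
  }
  invisible(m)
}

#' Feature lengths, modulo the genome length for origin-wrapping features
#'
#' @param m A `mitogenome`.
#' @return Integer vector parallel to `m$features`.
#' @export
feature_lengths <- function(m) {
  f <- m$features
  as.integer(ifelse(f$wraps_origin, m$length - f$start + f$end,
                    f$end - f$start))
}

#' Extract the DNA sequence of one feature
#'
#' @param m A `mitogenome` with `sequence` present.
#' @param i Feature row index.
#' @return Character scalar (plus strand only; no reverse complement).
#' @export
feature_seq <- function(m, i) {
  if (is.null(m$sequence)) stop("mitogenome has no sequence")
  f <- m$features[i, ]
  if (f$wraps_origin) {
    paste0(substr(m$sequence, f$start + 1L, m$length),
           substr(m$sequence, 1L, f$end))
  } else {
    substr(m$sequence, f$start + 1L, f$end)
  }
}

# circular span from 0-based position `from` of length `len`
.circ_substr <- function(seq, from, len, L) {
  from <- from %% L
  if (from + len <= L) return(substr(seq, from + 1L, from + len))
  paste0(substr(seq, from + 1L, L), substr(seq, 1L, from + len - L))
}

# circular distance from position a to position b (0-based), in [0, L)
.circ_dist <- function(a, b, L) (b - a) %% L

#' Rotate a circular mitogenome so that `offset` becomes position 0
#'
#' Coordinates and sequence shift together; features that come to span the
#' origin get `wraps_origin = TRUE`. Used mainly to test rotation invariance
#' of downstream analyses.
#'
#' @param m A circular `mitogenome`.
#' @param offset New origin, 0-based.
#' @return The rotated `mitogenome`.
#' @export
rotate_mitogenome <- function(m, offset) {
  stopifnot(m$topology == "circular")
  L <- m$length
  offset <- offset %% L
  f <- m$features
  if (nrow(f)) {
    ln <- feature_lengths(m)
    f$start <- (f$start - offset) %% L
    f$end <- f$start + ln
    f$wraps_origin <- f$end > L
    f$end <- f$end %% L
    f$end[f$end == 0L] <- L
    f$end[f$wraps_origin] <- (f$start[f$wraps_origin] + ln[f$wraps_origin]) %% L
  }
  sq <- m$sequence
  if (!is.null(sq) && offset > 0)
    sq <- paste0(substr(sq, offset + 1L, L), substr(sq, 1L, offset))
  mitogenome(m$id, L, f, sequence = sq, taxon = m$taxon,
             topology = m$topology)
}

#' Extract the gene order of a mitogenome
#'
#' Labels are listed in genomic order starting from position 0; a feature
#' wrapping the origin is listed once, first. `noncoding` features are
#' excluded; the control region is kept (it is a landmark in clitellate
#' arrangements).
#'
#' @param m A `mitogenome` with at least one gene feature.
#' @param include_rna Keep tRNA/rRNA/control-region features; `FALSE`
#'   restricts to the 13 protein-coding genes.
#' @return A [gene_order()] object.
#' @export
gene_order_of <- function(m, include_rna = TRUE) {
  f <- m$features[m$features$kind != "noncoding", , drop = FALSE]
  if (!include_rna) f <- f[f$kind == "CDS", , drop = FALSE]
  if (!nrow(f)) stop("no gene features")
  ord <- order(!f$wraps_origin, f$start, f$end)
  f <- f[ord, , drop = FALSE]
  gene_order(f$label, f$strand, circular = m$topology == "circular")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat("<mitogenome> ", x$id,
      if (nzchar(x$taxon)) paste0(" (", x$taxon, ")"), "\n", sep = "")
  cat("  ", x$length, " bp, ", x$topology, ", ",
      nrow(x$features), " features",
      if (is.null(x$sequence)) ", no sequence", "\n", sep = "")
  invisible(x)
}
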
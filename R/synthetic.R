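# run expr under a local RNG seed without disturbing the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' The clitellate reference gene arrangement
#'
#' A 37-gene single-strand circular order (plus the pCR landmark) satisfying
#' the organization shared by clitellate mitogenomes: the pCR lies between
#' `trnR` and `trnH` with `atp6` immediately upstream of `trnR`; `trnD` sits
#' between `cox2` and `atp8`; the two rRNAs lie between `trnM` and `trnL1`,
#' separated by the mid-rRNA placement of `trnV`; and `nad4L` is immediately
#' upstream of `nad4` (their annotated overlap is a conserved clitellate
#' feature). The remaining tRNA placements are fixed, documented, editable
#' data, not an inference.
#'
#' @return A [gene_order()] of 38 labels, all on `+`.
#' @export
clitellate_template <- function() {
  gene_order(c("cox1", "trnN", "trnA", "trnS2", "cox2", "trnD", "atp8",
               "atp6", "trnR", "pCR", "trnH", "nad5", "trnF", "trnE",
               "cob", "trnW", "nad1", "trnI", "trnK", "cox3", "trnQ",
               "nad6", "trnC", "nad3", "trnT", "nad4L", "nad4", "trnL2",
               "trnG", "nad2", "trnM", "rrnS", "trnV", "rrnL", "trnL1",
               "trnY", "trnP", "trnS1"),
             strands = "+", circular = TRUE)
}

#' Standard anticodons of the mitochondrial tRNA isotypes
#'
#' DNA-alphabet anticodon triplets placed into synthetic tRNAs; `trnD`
#' carries GTC (reading GAC/GAT). The Leu/Ser paralogs follow the decoding
#' convention trnL1 = TAG, trnL2 = TAA, trnS1 = TCT, trnS2 = TGA.
#'
#' @return Named character vector over the 22 tRNA labels.
#' @export
mito_anticodons <- function() {
  c(trnA = "TGC", trnC = "GCA", trnD = "GTC", trnE = "TTC", trnF = "GAA",
    trnG = "TCC", trnH = "GTG", trnI = "GAT", trnK = "TTT", trnL1 = "TAG",
    trnL2 = "TAA", trnM = "CAT", trnN = "GTT", trnP = "TGG", trnQ = "TTG",
    trnR = "TCG", trnS1 = "TCT", trnS2 = "TGA", trnT = "TGT", trnV = "TAC",
    trnW = "TCA", trnY = "GTA")
}

# realistic coding-body lengths (bp, multiples of 3, stop excluded)
.default_cds_lengths <- c(
  cox1 = 1536, cox2 = 684, cox3 = 780, cob = 1137, atp6 = 684, atp8 = 156,
  nad1 = 927, nad2 = 996, nad3 = 351, nad4 = 1338, nad4L = 288,
  nad5 = 1719, nad6 = 453)

.default_stop_plan <- c(
  cox1 = "canonical", cox2 = "partial_TA", atp8 = "canonical",
  atp6 = "partial_T", nad5 = "partial_T", cob = "partial_T",
  nad1 = "partial_T", cox3 = "partial_T", nad6 = "partial_T",
  nad3 = "partial_TA", nad4L = "overlap", nad4 = "partial_T",
  nad2 = "partial_T")

.default_start_plan <- stats::setNames(
  ifelse(names(.default_cds_lengths) == "cox3", "TTG", "ATG"),
  names(.default_cds_lengths))

#' Simulation configuration for synthetic clitellate mitogenomes
#'
#' All draws are fixed by `seed`. Defaults emulate the organization and
#' codon-usage conditions of hirudinean mitogenomes: every CDS starts with
#' ATG except the glossiphoniid TTG shift in `cox3`; most stops are
#' incomplete (T, less often TA) at tRNA junctions; `nad4L` overlaps
#' `nad4`; and the aspartic-acid codon bias is GAT-heavy
#' (`theta_gat = 0.85`).
#'
#' @param seed Integer seed fixing every draw.
#' @param template Gene arrangement (with the pCR landmark).
#' @param codon_bias Named list: per amino-acid (one-letter code) named
#'   probability vectors over its synonymous codons; unspecified amino
#'   acids use a uniform vector. `Asp` defaults to
#'   `c(GAC = 1 - theta_gat, GAT = theta_gat)`.
#' @param theta_gat Default GAT fraction among Asp codons.
#' @param aa_weights Optional named sampling weights over amino acids for
#'   CDS body composition (uniform when `NULL`).
#' @param cds_lengths Named coding-body lengths (multiples of 3).
#' @param trna_len Length range tRNAs are drawn from.
#' @param rrn_lens Lengths of `rrnS` / `rrnL`.
#' @param pcr_len,pcr_at Length and A+T fraction of the control region.
#' @param stop_class_plan,start_codon_plan Per-CDS stop class / start codon.
#' @param overlap_len Annotated 3' overlap for `overlap`-class CDSs.
#' @param start_window Codon window within which non-ATG planned starts are
#'   guaranteed unambiguous (matches the curation default).
#' @param spacers Named integer vector: intergenic spacer inserted after
#'   the named gene (e.g. `c(atp6 = 20)`).
#' @param events List of rearrangement events applied to the template by
#'   [apply_events()] before sequence generation.
#' @param dup_spec Optional tRNA duplication:
#'   `list(isotype =, after =, spacer_len =, anticodon =)` -- a second copy
#'   inserted after the existing copy (`after` defaults to the isotype),
#'   separated by `spacer_len` unannotated bases, optionally carrying a
#'   shifted anticodon.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed, template = clitellate_template(),
                              codon_bias = list(), theta_gat = 0.85,
                              aa_weights = NULL,
                              cds_lengths = .default_cds_lengths,
                              trna_len = c(60L, 72L),
                              rrn_lens = c(rrnS = 744L, rrnL = 1212L),
                              pcr_len = 600L, pcr_at = 0.78,
                              stop_class_plan = .default_stop_plan,
                              start_codon_plan = .default_start_plan,
                              overlap_len = 7L, start_window = 10L,
                              spacers = integer(0),
                              events = list(), dup_spec = NULL) {
  if (!("D" %in% names(codon_bias)))
    codon_bias$D <- c(GAC = 1 - theta_gat, GAT = theta_gat)
  for (aa in names(codon_bias)) {
    pb <- codon_bias[[aa]]
    if (abs(sum(pb) - 1) > 1e-8) stop("codon bias for ", aa, " must sum to 1")
  }
  structure(list(seed = as.integer(seed), template = template,
                 codon_bias = codon_bias, aa_weights = aa_weights,
                 cds_lengths = cds_lengths, trna_len = as.integer(trna_len),
                 rrn_lens = rrn_lens, pcr_len = as.integer(pcr_len),
                 pcr_at = pcr_at, stop_class_plan = stop_class_plan,
                 start_codon_plan = start_codon_plan,
                 overlap_len = as.integer(overlap_len),
                 start_window = as.integer(start_window),
                 spacers = spacers, events = events, dup_spec = dup_spec),
            class = "sim_config")
}

# codon tables under transl_table 5, stops excluded, grouped by amino acid
# (memoized: getGeneticCode's S4 dispatch dominates generation time otherwise)
.codon_cache <- new.env(parent = emptyenv())
.codons_by_aa <- function() {
  if (is.null(.codon_cache$byaa)) {
    code <- Biostrings::getGeneticCode("5")
    code <- code[code != "*"]
    .codon_cache$byaa <- split(names(code), unname(code))
  }
  .codon_cache$byaa
}

.random_dna <- function(n, at = 0.7) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

# draw n codons from the configured bias; optionally forbid ATG
.draw_codons <- function(n, byaa, bias, aa_weights, no_atg = FALSE) {
  if (n == 0L) return(character(0))
  aas <- names(byaa)
  wt <- if (is.null(aa_weights)) rep(1, length(aas)) else {
    w <- aa_weights[aas]; w[is.na(w)] <- 0; as.numeric(w)
  }
  draw_aa <- sample(aas, n, replace = TRUE, prob = wt)
  out <- character(n)
  for (aa in unique(draw_aa)) {
    sel <- draw_aa == aa
    cods <- byaa[[aa]]
    pb <- bias[[aa]]
    prob <- if (is.null(pb)) rep(1 / length(cods), length(cods)) else {
      p <- pb[cods]; p[is.na(p)] <- 0; as.numeric(p)
    }
    out[sel] <- sample(cods, sum(sel), replace = TRUE, prob = prob)
  }
  if (no_atg && any(out == "ATG")) out[out == "ATG"] <- "ATA"  # Met stays Met
  out
}

#' Generate an annotated synthetic clitellate mitogenome
#'
#' Builds a full DNA sequence plus annotations from a [simulation_config()]:
#' CDS bodies are drawn codon-wise from the configured bias with the
#' planned start codons and stop realizations (canonical TAA, incomplete
#' T/TA before an abutting tRNA, or an annotated 3' overlap into the next
#' gene); tRNAs carry isotype-correct anticodons at a fixed internal
#' offset; the control region is AT-rich unannotated-style sequence carried
#' as a `control_region` feature. The result is deterministic per seed and
#' carries its ground truth in `attr(, "ground_truth")`.
#'
#' @param cfg A [simulation_config()].
#' @return A validated [mitogenome()].
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .generate_genome_impl(cfg))
}

.generate_genome_impl <- function(cfg) {
  o <- apply_events(cfg$template, cfg$events)
  if (!is.null(cfg$dup_spec)) {
    ds <- cfg$dup_spec
    after <- if (is.null(ds$after)) ds$isotype else ds$after
    k <- match(after, o$labels)
    if (is.na(k)) stop("dup_spec: gene '", after, "' not in order")
    o <- gene_order(append(o$labels, ds$isotype, k),
                    append(o$strands, "+", k), o$circular)
  }
  byaa <- .codons_by_aa()
  anticod <- mito_anticodons()
  ac_offset <- 28L  # fixed internal anticodon placement (0-based)
  segs <- character(0)
  rows <- list()
  pos <- 0L
  pending_overlap <- 0L  # previous CDS annotated into this feature
  dup_seen <- character(0)
  first_copy_seq <- list()
  n <- length(o$labels)
  for (j in seq_len(n)) {
    lab <- o$labels[j]
    kind <- .kind_for_label(lab)
    nxt <- o$labels[j %% n + 1L]
    if (kind == "CDS") {
      body_len <- cfg$cds_lengths[[lab]]
      if (is.null(body_len)) stop("no length configured for CDS ", lab)
      start_codon <- cfg$start_codon_plan[[lab]]
      stop_class <- cfg$stop_class_plan[[lab]]
      ncod <- body_len %/% 3L - 1L
      guard <- min(cfg$start_window - 1L, ncod)
      body <- c(start_codon,
                .draw_codons(guard, byaa, cfg$codon_bias, cfg$aa_weights,
                             no_atg = TRUE),
                .draw_codons(ncod - guard, byaa, cfg$codon_bias,
                             cfg$aa_weights))
      sq <- paste(body, collapse = "")
      tail <- switch(stop_class, canonical = "TAA", partial_T = "T",
                     partial_TA = "TA", overlap = "",
                     stop("unknown stop class ", stop_class))
      if (stop_class %in% c("partial_T", "partial_TA") &&
          .kind_for_label(nxt) != "tRNA")
        stop("partial stop planned for ", lab,
             " but downstream feature ", nxt, " is not a tRNA")
      if (stop_class == "overlap" && !.kind_for_label(nxt) %in% c("CDS", "tRNA"))
        stop("overlap stop planned for ", lab,
             " before non-gene feature ", nxt)
      sq <- paste0(sq, tail)
      end <- pos + nchar(sq)
      ann_end <- if (stop_class == "overlap") end + cfg$overlap_len else end
      rows[[length(rows) + 1L]] <- gene_feature(lab, pos, ann_end)
    } else if (kind == "tRNA") {
      if (lab %in% dup_seen && !is.null(first_copy_seq[[lab]])) {
        sq <- first_copy_seq[[lab]]  # duplicate copy: same sequence ...
        ds <- cfg$dup_spec
        ac <- anticod[[lab]]
        if (!is.null(ds) && identical(ds$isotype, lab) &&
            !is.null(ds$anticodon)) {  # ... optionally with shifted anticodon
          substr(sq, ac_offset + 1L, ac_offset + 3L) <- ds$anticodon
          ac <- ds$anticodon
        }
        if (!is.null(ds) && identical(ds$isotype, lab) &&
            !is.null(ds$spacer_len) && ds$spacer_len > 0L) {
          segs <- c(segs, .random_dna(ds$spacer_len))
          pos <- pos + ds$spacer_len
        }
      } else {
        len <- sample(seq(cfg$trna_len[1], cfg$trna_len[2]), 1L)
        sq <- .random_dna(len)
        substr(sq, ac_offset + 1L, ac_offset + 3L) <- anticod[[lab]]
        ac <- anticod[[lab]]
        first_copy_seq[[lab]] <- sq
        dup_seen <- c(dup_seen, lab)
      }
      rows[[length(rows) + 1L]] <-
        gene_feature(lab, pos, pos + nchar(sq), anticodon = ac)
    } else if (kind == "rRNA") {
      sq <- .random_dna(cfg$rrn_lens[[lab]])
      rows[[length(rows) + 1L]] <- gene_feature(lab, pos, pos + nchar(sq))
    } else if (kind == "control_region") {
      sq <- .random_dna(cfg$pcr_len, at = cfg$pcr_at)
      rows[[length(rows) + 1L]] <- gene_feature(lab, pos, pos + nchar(sq))
    } else stop("cannot generate feature of kind ", kind)
    segs <- c(segs, sq)
    pos <- pos + nchar(sq)
    sp <- cfg$spacers[lab]
    if (!is.na(sp) && sp > 0L) {
      segs <- c(segs, .random_dna(sp))
      pos <- pos + as.integer(sp)
    }
  }
  feat <- do.call(rbind, rows)
  m <- mitogenome(sprintf("SIM%08d", cfg$seed %% 1e8), pos, feat,
                  sequence = paste(segs, collapse = ""),
                  taxon = "synthetic clitellate", topology = "circular")
  attr(m, "ground_truth") <- list(
    seed = cfg$seed, order = o,
    start_codon_plan = cfg$start_codon_plan,
    stop_class_plan = cfg$stop_class_plan,
    overlap_len = cfg$overlap_len,
    codon_bias = cfg$codon_bias, events = cfg$events,
    dup_spec = cfg$dup_spec)
  m
}

#' Apply rearrangement events to a gene order
#'
#' Events (lists with a `kind` field) are applied in sequence:
#' `translocation` (`gene`, `to_index`), `adjacent_swap` (`genes`),
#' `inversion` (`genes`: a contiguous run, reversed and strand-flipped),
#' `duplication` (`gene`, optional `to_index`; default inserts the copy
#' next to the original), `loss` (`gene`).
#'
#' @param o A [gene_order()].
#' @param events List of event lists.
#' @return The rearranged `gene_order`.
#' @export
apply_events <- function(o, events) {
  for (ev in events) {
    lab <- o$labels; str <- o$strands
    kind <- ev$kind
    if (kind == "translocation") {
      i <- match(ev$gene, lab)
      if (is.na(i)) stop("translocation: gene not found: ", ev$gene)
      g <- lab[i]; s <- str[i]
      lab <- lab[-i]; str <- str[-i]
      k <- min(ev$to_index, length(lab) + 1L)
      lab <- append(lab, g, k - 1L); str <- append(str, s, k - 1L)
    } else if (kind == "adjacent_swap") {
      i <- match(ev$genes[1], lab); j <- match(ev$genes[2], lab)
      if (anyNA(c(i, j)) || abs(i - j) != 1L)
        stop("adjacent_swap: genes not adjacent: ",
             paste(ev$genes, collapse = ","))
      lab[c(i, j)] <- lab[c(j, i)]; str[c(i, j)] <- str[c(j, i)]
    } else if (kind == "inversion") {
      idx <- match(ev$genes, lab)
      if (anyNA(idx) || !all(diff(idx) == 1L))
        stop("inversion: genes not a contiguous run")
      lab[idx] <- rev(lab[idx])
      str[idx] <- rev(ifelse(str[idx] == "+", "-", "+"))
    } else if (kind == "duplication") {
      i <- match(ev$gene, lab)
      if (is.na(i)) stop("duplication: gene not found: ", ev$gene)
      k <- if (is.null(ev$to_index)) i else ev$to_index
      lab <- append(lab, ev$gene, k); str <- append(str, str[i], k)
    } else if (kind == "loss") {
      i <- match(ev$gene, lab)
      if (is.na(i)) stop("loss: gene not found: ", ev$gene)
      lab <- lab[-i]; str <- str[-i]
    } else stop("unknown event kind: ", kind)
    o <- gene_order(lab, str, o$circular)
  }
  o
}

#' Draw a random single rearrangement event applicable to an order
#'
#' Used by the event-recovery simulations. The anchor gene (`cox1`) and the
#' control region are never moved (the anchor defines the rotational frame
#' of comparison); sampled translocations displace a gene by at least two
#' positions so the event class is unambiguous (a one-position move is an
#' adjacent swap).
#'
#' @param o A [gene_order()] without duplicate labels.
#' @param kind Event kind.
#' @param max_span Maximum inversion run length.
#' @return An event list consumable by [apply_events()].
#' @export
sample_event <- function(o, kind = c("translocation", "adjacent_swap",
                                     "inversion", "duplication", "loss"),
                         max_span = 4L) {
  kind <- match.arg(kind)
  n <- length(o$labels)
  movable <- setdiff(seq_len(n), c(match("cox1", o$labels),
                                   which(o$labels == "pCR")))
  if (kind == "translocation") {
    i <- sample(movable, 1L)
    repeat {
      k <- sample(setdiff(2L:n, i), 1L)
      if (abs(k - i) >= 2L && !(k == i - 1L)) break
    }
    list(kind = "translocation", gene = o$labels[i], to_index = k)
  } else if (kind == "adjacent_swap") {
    repeat {
      i <- sample(movable[movable < n], 1L)
      if ((i + 1L) %in% movable) break
    }
    list(kind = "adjacent_swap", genes = o$labels[c(i, i + 1L)])
  } else if (kind == "inversion") {
    span <- sample(seq_len(max_span), 1L)
    ok <- movable[movable + span - 1L <= n &
                  vapply(movable, function(i)
                    all(seq(i, min(i + span - 1L, n)) %in% movable),
                    logical(1))]
    i <- sample(ok, 1L)
    list(kind = "inversion", genes = o$labels[i:(i + span - 1L)])
  } else if (kind == "duplication") {
    trnas <- which(o$labels %in% mito_trna_labels())
    i <- sample(trnas, 1L)
    list(kind = "duplication", gene = o$labels[i])
  } else {
    trnas <- intersect(movable, which(o$labels %in% mito_trna_labels()))
    i <- sample(trnas, 1L)
    list(kind = "loss", gene = o$labels[i])
  }
}
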
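#' Gene-label synonym table
#'
#' GenBank annotations name the same mitochondrial genes in many ways
#' (COX1/COI/CO1, CYTB/cob, tRNA-Asp/trnD, 12S/rrnS, ...). This table maps
#' lower-cased aliases to the controlled vocabulary; users can extend it via
#' the `extra` argument of [normalize_gene_label()] / [read_genbank()].
#'
#' @return Named character vector (alias -> canonical label).
#' @export
gene_synonyms <- function() {
  aa3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
           Glu = "E", Gly = "G", His = "H", Ile = "I", Lys = "K", Met = "M",
           Phe = "F", Pro = "P", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  syn <- c(
    coi = "cox1", co1 = "cox1", cox1 = "cox1", coxi = "cox1",
    coii = "cox2", co2 = "cox2", cox2 = "cox2", coxii = "cox2",
    coiii = "cox3", co3 = "cox3", cox3 = "cox3", coxiii = "cox3",
    cytb = "cob", cob = "cob", cytochromeb = "cob",
    atp6 = "atp6", atpase6 = "atp6", atp8 = "atp8", atpase8 = "atp8",
    nd1 = "nad1", nad1 = "nad1", nd2 = "nad2", nad2 = "nad2",
    nd3 = "nad3", nad3 = "nad3", nd4 = "nad4", nad4 = "nad4",
    nd4l = "nad4L", nad4l = "nad4L", nd5 = "nad5", nad5 = "nad5",
    nd6 = "nad6", nad6 = "nad6",
    rrns = "rrnS", "12s" = "rrnS", srrna = "rrnS", "12srrna" = "rrnS",
    rrnl = "rrnL", "16s" = "rrnL", lrrna = "rrnL", "16srrna" = "rrnL",
    pcr = "pCR", dloop = "pCR", controlregion = "pCR")
  for (nm in names(aa3)) {
    syn[[tolower(paste0("trna-", nm))]] <- paste0("trn", aa3[[nm]])
    syn[[tolower(paste0("trn", aa3[[nm]]))]] <- paste0("trn", aa3[[nm]])
  }
  # Leu/Ser paralogs: explicit names win; plain trnL/trnS resolved by anticodon
  syn[["trnl1"]] <- "trnL1"; syn[["trnl2"]] <- "trnL2"
  syn[["trns1"]] <- "trnS1"; syn[["trns2"]] <- "trnS2"
  syn[["trna-leu1"]] <- "trnL1"; syn[["trna-leu2"]] <- "trnL2"
  syn[["trna-ser1"]] <- "trnS1"; syn[["trna-ser2"]] <- "trnS2"
  syn
}

# anticodon-based disambiguation of Leu/Ser paralogs:
# L1 decodes CUN via anticodon TAG, L2 decodes UUR via TAA,
# S1 via TCT, S2 via TGA (DNA alphabet)
.paralog_by_anticodon <- c(TAG = "trnL1", TAA = "trnL2",
                           TCT = "trnS1", TGA = "trnS2")

#' Normalize a GenBank gene label to the controlled vocabulary
#'
#' @param x Character vector of raw labels.
#' @param anticodon Optional parallel vector of anticodon triplets, used to
#'   disambiguate trnL/trnS paralogs.
#' @param extra Named character vector of additional alias -> label entries.
#' @return Character vector; `NA` where no synonym matches.
#' @export
normalize_gene_label <- function(x, anticodon = NULL, extra = NULL) {
  syn <- c(gene_synonyms(), extra)
  key <- gsub("[ _]", "", tolower(trimws(x)))
  # strip duplicate-copy suffixes (trnD2 -> trnD), but leave the Leu/Ser
  # paralog names intact
  paralog <- key %in% c("trnl1", "trnl2", "trns1", "trns2")
  key2 <- ifelse(paralog, key, sub("^(trn[a-z])[-_]?([0-9])$", "\\1", key))
  out <- unname(syn[key2])
  amb <- which(key2 %in% c("trnl", "trna-leu", "trns", "trna-ser"))
  if (length(amb) && !is.null(anticodon)) {
    hit <- .paralog_by_anticodon[toupper(anticodon[amb])]
    out[amb] <- unname(hit)
  }
  out
}

.parse_gb_location <- function(loc, L) {
  # returns list(start, end, strand, wraps) in 0-based half-open coords
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L)
      stop("unsupported join() location with ", length(parts), " segments: ", loc)
    seg <- lapply(parts, function(p) as.integer(strsplit(p, "\\.\\.")[[1]]))
    if (seg[[2]][1] != 1L)
      stop("join() location does not wrap the origin: ", loc)
    return(list(start = seg[[1]][1] - 1L, end = seg[[2]][2],
                strand = strand, wraps = TRUE))
  }
  if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
    ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
    return(list(start = ab[1] - 1L, end = ab[2], strand = strand, wraps = FALSE))
  }
  if (grepl("^[0-9]+$", loc)) {
    p <- as.integer(loc)
    return(list(start = p - 1L, end = p, strand = strand, wraps = FALSE))
  }
  stop("cannot parse location: ", loc)
}

.gb_feature_keys <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                      `D-loop` = "control_region",
                      misc_feature = "noncoding")

#' Read a GenBank flat file into a mitogenome
#'
#' A minimal offline parser for the LOCUS/FEATURES/ORIGIN dialect this
#' package writes and that standard mitogenome records use. Coordinates are
#' converted from 1-based inclusive to the internal 0-based half-open
#' convention; a two-segment `join()` ending at base 1 is interpreted as an
#' origin-wrapping feature. Gene labels are normalized through
#' [gene_synonyms()]; features whose label cannot be normalized are retained
#' with `kind = "noncoding"` and a warning.
#'
#' @param path Path to a GenBank flat file.
#' @param extra_synonyms Named character vector extending [gene_synonyms()].
#' @return A [mitogenome()].
#' @export
read_genbank <- function(path, extra_synonyms = NULL) {
  lines <- readLines(path, warn = FALSE)
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc)) stop("malformed GenBank file: no LOCUS line")
  tok <- strsplit(trimws(lines[iloc[1]]), "[[:space:]]+")[[1]]
  if (length(tok) < 3 || is.na(suppressWarnings(as.integer(tok[3]))))
    stop("malformed LOCUS header at line ", iloc[1], ": ", lines[iloc[1]])
  id <- tok[2]
  L <- as.integer(tok[3])
  topology <- if (any(tolower(tok) == "circular")) "circular" else "linear"
  taxon <- ""
  iorg <- grep("^ {2}ORGANISM", lines)
  if (length(iorg)) taxon <- trimws(sub("^ {2}ORGANISM", "", lines[iorg[1]]))

  ifea <- grep("^FEATURES", lines)
  iori <- grep("^ORIGIN", lines)
  iend <- grep("^//", lines)
  feat <- .empty_features()
  if (length(ifea)) {
    to <- min(c(iori, iend, length(lines) + 1L)) - 1L
    block <- lines[(ifea[1] + 1L):to]
    starts <- grep("^ {5}\\S", block)
    raw <- list()
    for (j in seq_along(starts)) {
      from <- starts[j]
      upto <- if (j < length(starts)) starts[j + 1] - 1L else length(block)
      chunk <- block[from:upto]
      head <- strsplit(trimws(chunk[1]), "[[:space:]]+")[[1]]
      key <- head[1]
      loc <- paste0(head[-1], collapse = "")
      quals <- paste(trimws(chunk[-1]), collapse = " ")
      raw[[j]] <- list(key = key, loc = loc, quals = quals)
    }
    qual <- function(q, name) {
      mm <- regmatches(q, regexec(paste0("/", name, "=\"([^\"]*)\""), q))[[1]]
      if (length(mm) == 2) mm[2] else NA_character_
    }
    rows <- list()
    for (ft in raw) {
      if (!ft$key %in% names(.gb_feature_keys)) next
      lc <- .parse_gb_location(ft$loc, L)
      gene <- qual(ft$quals, "gene")
      if (is.na(gene)) gene <- qual(ft$quals, "product")
      ac <- qual(ft$quals, "anticodon")
      if (!is.na(ac)) {
        mm <- regmatches(ac, regexec("seq:([acgtACGT]{3})", ac))[[1]]
        ac <- toupper(if (length(mm) == 2) mm[2] else ac)
        if (!grepl("^[ACGT]{3}$", ac)) ac <- NA_character_
      }
      kind <- .gb_feature_keys[[ft$key]]
      lab <- normalize_gene_label(gene, anticodon = ac, extra = extra_synonyms)
      if (is.na(lab)) {
        if (kind %in% c("CDS", "tRNA", "rRNA")) {
          warning("unknown gene label '", gene, "' retained as noncoding")
          kind <- "noncoding"
        } else if (kind == "control_region") {
          lab <- "pCR"
        }
        if (is.na(lab)) lab <- if (is.na(gene)) ft$key else gene
      } else if (lab == "pCR") {
        kind <- "control_region"
      }
      rows[[length(rows) + 1L]] <-
        gene_feature(lab, lc$start, lc$end, kind = kind, strand = lc$strand,
                     anticodon = ac, wraps_origin = lc$wraps)
    }
    if (length(rows)) feat <- do.call(rbind, rows)
  }
  sequence <- NULL
  if (length(iori)) {
    to <- if (length(iend)) iend[1] - 1L else length(lines)
    if (to > iori[1]) {
      sq <- gsub("[^A-Za-z]", "", paste(lines[(iori[1] + 1L):to], collapse = ""))
      if (nzchar(sq)) sequence <- toupper(sq)
    }
  }
  mitogenome(id, L, feat, sequence = sequence, taxon = taxon,
             topology = topology)
}

.fmt_gb_location <- function(f, L) {
  loc <- if (f$wraps_origin) {
    sprintf("join(%d..%d,1..%d)", f$start + 1L, L, f$end)
  } else {
    sprintf("%d..%d", f$start + 1L, f$end)
  }
  if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a file re-readable by [read_genbank()]; origin-wrapping features are
#' written as two-segment `join()` locations. The ORIGIN section is included
#' when the genome carries a sequence.
#'
#' @param m A [mitogenome()].
#' @param path Output path.
#' @param write_sequence Include the ORIGIN section (errors if no sequence).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(m, path, write_sequence = !is.null(m$sequence)) {
  if (write_sequence && is.null(m$sequence))
    stop("ORIGIN requested but mitogenome has no sequence")
  out <- character(0)
  out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV",
                        m$id, m$length, m$topology))
  if (nzchar(m$taxon))
    out <- c(out, sprintf("DEFINITION  %s mitochondrion.", m$taxon),
             "SOURCE      mitochondrion", sprintf("  ORGANISM  %s", m$taxon))
  out <- c(out, "FEATURES             Location/Qualifiers")
  key_of <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
              control_region = "D-loop", noncoding = "misc_feature")
  f <- m$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      fi <- f[i, ]
      out <- c(out, sprintf("     %-16s%s", key_of[[fi$kind]],
                            .fmt_gb_location(fi, m$length)))
      out <- c(out, sprintf("                     /gene=\"%s\"", fi$label))
      if (!is.na(fi$anticodon))
        out <- c(out, sprintf("                     /anticodon=\"%s\"",
                              fi$anticodon))
    }
  }
  if (write_sequence) {
    out <- c(out, "ORIGIN")
    sq <- tolower(m$sequence)
    pos <- seq(1L, nchar(sq), by = 60L)
    for (p in pos) {
      chunk <- substr(sq, p, min(p + 59L, nchar(sq)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      out <- c(out, sprintf("%9d %s", p, paste(tens, collapse = " ")))
    }
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read / write the genome sequence as FASTA
#'
#' Thin wrappers over Biostrings. `read_fasta()` returns a sequence-only
#' [mitogenome()] (no features); `write_fasta()` exports the sequence.
#'
#' @param path FASTA path.
#' @param topology Topology to assume on read.
#' @return `read_fasta()`: a `mitogenome`; `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) stop("expected a single-record FASTA")
  id <- strsplit(names(ss)[1], "[[:space:]]+")[[1]][1]
  mitogenome(id, Biostrings::width(ss)[1], sequence = as.character(ss[[1]]),
             topology = topology)
}

#' @rdname read_fasta
#' @param m A `mitogenome` with sequence.
#' @export
write_fasta <- function(m, path) {
  if (is.null(m$sequence)) stop("mitogenome has no sequence")
  ss <- Biostrings::DNAStringSet(m$sequence)
  names(ss) <- m$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Export the feature annotation as a TSV table
#'
#' Columns: id, uid (label with a numeric suffix on second and later copies
#' of a duplicated gene, e.g. `trnD`, `trnD2`), label, kind, start, end
#' (0-based half-open), strand, anticodon, wraps_origin.
#'
#' @param m A `mitogenome`.
#' @param path Optional output path; when `NULL` the table is returned only.
#' @return The table, invisibly when written.
#' @export
feature_table <- function(m, path = NULL) {
  f <- m$features
  copy <- stats::ave(seq_len(nrow(f)), f$label, FUN = seq_along)
  uid <- ifelse(copy > 1L, paste0(f$label, copy), f$label)
  tab <- cbind(data.frame(id = rep(m$id, nrow(f)), uid = uid,
                          stringsAsFactors = FALSE), f)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
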
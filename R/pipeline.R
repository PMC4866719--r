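#' Run the end-to-end comparative-mitogenomics pipeline
#'
#' Curates every genome, compares gene orders against a reference
#' arrangement, runs the aspartic-acid codon-usage homogeneity analysis
#' (exact R x 2 test plus progressive subgroup search), and characterizes
#' intergenic spans, the putative control region and any duplicated tRNAs.
#' All outputs are plain text / TSV; re-running with the same inputs and
#' seed is byte-identical (no timestamps are written).
#'
#' @param genomes Character vector of GenBank file paths, or a list of
#'   [mitogenome()] objects. Ignored when `simulate > 0`.
#' @param simulate Number of synthetic genomes to generate instead of
#'   reading inputs.
#' @param seed Seed for simulation.
#' @param reference Reference [gene_order()] for event detection.
#' @param asp_counts Optional [asp_table()] (or TSV path with columns
#'   organism/GAC/GAT) to use for the codon-usage analysis instead of
#'   counts derived from the genomes; the packaged clitellate table can be
#'   selected with `asp_counts = "clitellata"`.
#' @param alpha Significance threshold of the subgroup search.
#' @param out_dir Output directory (created); `NULL` skips file output.
#' @return List with elements `curation`, `orders`, `events`, `asp`,
#'   `fisher_p`, `subgroups`, `intergenic`, `pcr`, `duplications`,
#'   invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(genomes = NULL, simulate = 0L, seed = 1L,
                         reference = clitellate_template(),
                         asp_counts = NULL, alpha = 0.05, out_dir = NULL) {
  if (simulate > 0L) {
    genomes <- lapply(seq_len(simulate), function(k)
      generate_genome(simulation_config(seed + k - 1L)))
  } else if (is.character(genomes)) {
    genomes <- lapply(genomes, read_genbank)
  }
  if (!length(genomes) && is.null(asp_counts))
    stop("no input genomes; supply `genomes`, `simulate` or `asp_counts`")

  curation <- lapply(genomes, function(m)
    cbind(data.frame(id = m$id, stringsAsFactors = FALSE), curate_genome(m)))
  names(curation) <- vapply(genomes, `[[`, "", "id")

  orders <- lapply(genomes, gene_order_of)
  events <- lapply(orders, function(o)
    detect_events(normalize_order(o), normalize_order(reference)))
  duplications <- lapply(orders, detect_duplications)

  asp <- NULL
  if (identical(asp_counts, "clitellata")) {
    asp <- asp_table_clitellata()
  } else if (is.character(asp_counts)) {
    asp <- asp_table(utils::read.delim(asp_counts, stringsAsFactors = FALSE))
  } else if (!is.null(asp_counts)) {
    asp <- asp_table(asp_counts)
  } else if (length(genomes) >= 2L) {
    counts <- mapply(function(m, cu) count_codons(m, cu), genomes, curation,
                     SIMPLIFY = FALSE)
    asp <- asp_table(counts)
  }
  fisher_p <- if (!is.null(asp)) as.numeric(fisher_exact_rx2(asp)) else NA_real_
  subgroups <- if (!is.null(asp) && nrow(asp) >= 3L)
    homogeneous_subgroups(asp, alpha = alpha) else NULL

  intergenic <- lapply(genomes, find_intergenic)
  pcr <- lapply(genomes, function(m)
    tryCatch(identify_pcr(m), error = function(e) NULL))

  res <- list(curation = curation, orders = orders, events = events,
              duplications = duplications, asp = asp, fisher_p = fisher_p,
              subgroups = subgroups, intergenic = intergenic, pcr = pcr)
  if (is.null(out_dir)) return(res)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                          sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  if (length(curation)) wt(do.call(rbind, curation), "curation.tsv")
  if (length(events)) {
    ev <- do.call(rbind, mapply(function(id, e)
      if (nrow(e)) cbind(data.frame(id = id, stringsAsFactors = FALSE), e)
      else NULL,
      names(curation), events, SIMPLIFY = FALSE))
    if (!is.null(ev)) wt(ev, "events.tsv") else
      writeLines("id\tkind\tgenes\tfrom_index\tto_index",
                 file.path(out_dir, "events.tsv"))
  }
  if (!is.null(asp)) {
    tab <- cbind(asp, ratio = gac_gat_ratio(asp$GAC, asp$GAT))
    wt(tab, "asp_table.tsv")
  }
  if (!is.null(subgroups)) wt(subgroups$groups, "subgroups.tsv")

  summary_lines <- c(
    "mitocomp pipeline summary",
    sprintf("genomes: %d", length(genomes)),
    if (length(genomes))
      sprintf("  %s: %d bp, %d features",
              vapply(genomes, `[[`, "", "id"),
              vapply(genomes, `[[`, 0L, "length"),
              vapply(genomes, function(m) nrow(m$features), 0L)),
    sprintf("gene-order events vs reference: %s",
            paste(vapply(events, nrow, 0L), collapse = ", ")),
    if (!is.null(asp))
      sprintf("asp codon usage: %d genomes, GAC %d, GAT %d, exact test p = %.4g",
              nrow(asp), sum(asp$GAC), sum(asp$GAT), fisher_p),
    if (!is.null(subgroups))
      sprintf("maximal homogeneous subgroups (alpha = %g): %d",
              alpha, nrow(subgroups$groups)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(res)
}
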
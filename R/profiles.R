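## Dominant-biological-process profiling of DEG sets by majority vote.

#' Dominant biological processes of one DE comparison
#'
#' Maps the differentially expressed genes (FDR below `fdr_cut`) of one
#' (species, tissue, comparison) table to reference ids and counts their
#' process annotations: each DEG contributes one vote to every label it
#' carries; DEGs without any annotation are counted under `"unannotated"`.
#' The dominant set contains every label attaining the maximum count (ties
#' are retained, never broken). Profiles built from fewer than `min_degs`
#' DEGs are flagged `low_support`, since very small DEG sets may poorly
#' reflect the underlying age-related processes.
#'
#' @param de_table A `de_result` table (FDR-adjusted).
#' @param annotations An [annotation_table()] keyed by reference id.
#' @param orthologs An [ortholog_map()].
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param min_degs Support floor below which the profile is flagged
#'   (default 5).
#' @return A list of class `process_profile`: `species`, `tissue`,
#'   `comparison`, `n_degs`, `label_counts` (named integer vector),
#'   `dominant` (character vector), `low_support`.
#' @export
profile_comparison <- function(de_table, annotations, orthologs,
                               fdr_cut = 0.05, min_degs = 5L) {
  stopifnot(inherits(de_table, "de_result"), inherits(annotations, "annotation_table"))
  species <- attr(de_table, "species")
  degs <- de_table$gene_id[!is.na(de_table$fdr) & de_table$fdr < fdr_cut]
  refs <- to_reference_ids(orthologs, species, degs)
  counts <- integer(0)
  for (r in refs) {
    labels <- if (is.na(r)) character(0) else annotations$label[annotations$ref_id == r]
    if (length(labels) == 0L) labels <- "unannotated"
    for (lb in labels) counts[lb] <- (if (lb %in% names(counts)) counts[[lb]] else 0L) + 1L
  }
  if (length(counts) > 0L) counts <- counts[order(names(counts))]
  dominant <- if (length(counts) > 0L) names(counts)[counts == max(counts)] else character(0)
  structure(list(species = species, tissue = attr(de_table, "tissue"),
                 comparison = attr(de_table, "comparison"),
                 n_degs = length(degs), label_counts = counts,
                 dominant = sort(dominant),
                 low_support = length(degs) < min_degs),
            class = "process_profile")
}

#' @export
print.process_profile <- function(x, ...) {
  cat(sprintf("process_profile %s|%s|%s: %d DEGs%s; dominant: %s\n",
              x$species, x$tissue, x$comparison, x$n_degs,
              if (x$low_support) " (low support)" else "",
              if (length(x$dominant)) paste(x$dominant, collapse = ", ") else "none"))
  invisible(x)
}

#' Profile every DE table and tabulate the results
#'
#' @param de_tables List of `de_result` tables.
#' @inheritParams profile_comparison
#' @return data.frame: `species`, `tissue`, `comparison`, `n_degs`,
#'   `dominant` (semicolon-separated ties), `low_support`.
#' @export
profile_all <- function(de_tables, annotations, orthologs,
                        fdr_cut = 0.05, min_degs = 5L) {
  rows <- lapply(de_tables, function(tab) {
    p <- profile_comparison(tab, annotations, orthologs, fdr_cut, min_degs)
    data.frame(species = p$species, tissue = p$tissue, comparison = p$comparison,
               n_degs = p$n_degs,
               dominant = paste(p$dominant, collapse = ";"),
               low_support = p$low_support, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
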
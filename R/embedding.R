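## Cross-sample expression matrix over the selected genes and quantitative
## cluster-separation scores (the testable form of the qualitative claim
## that tissues and species separate while ages largely do not).

#' Assemble the pooled cross-species embedding input
#'
#' Builds a samples x selected-genes matrix of log2(TPM + 1) values pooled
#' over all species, anchored on the ortholog map: each sample's value for
#' a selected reference gene is taken from its species' own orthologue.
#' A species lacking a selected gene in its TPM matrix contributes a 0
#' fill for that gene (with a warning).
#'
#' @param tpm_set Named list of `tpm_matrix` objects, one per species.
#' @param selection A [preselect_genes()] result (must be non-empty).
#' @param orthologs An [ortholog_map()].
#' @return A list of class `embedding_input`: `matrix` (samples x genes,
#'   log2 scale), `labels` (data.frame `sample_id`, `species`, `tissue`,
#'   `age_group`).
#' @export
build_embedding_input <- function(tpm_set, selection, orthologs) {
  genes <- selection$selected
  if (length(genes) == 0L) stop("gene selection is empty; nothing to embed")
  blocks <- list(); labels <- list()
  for (sp in names(tpm_set)) {
    tpm <- tpm_set[[sp]]
    stopifnot(inherits(tpm, "tpm_matrix"))
    sp_ids <- from_reference_ids(orthologs, sp, genes)
    block <- matrix(0, nrow = ncol(tpm$tpm), ncol = length(genes),
                    dimnames = list(colnames(tpm$tpm), genes))
    found <- !is.na(sp_ids) & sp_ids %in% rownames(tpm$tpm)
    if (any(!found)) {
      warning(sprintf("species '%s': %d selected gene(s) missing from TPM; 0-filled",
                      sp, sum(!found)))
    }
    if (any(found)) {
      block[, found] <- t(log2(tpm$tpm[sp_ids[found], , drop = FALSE] + 1))
    }
    blocks[[sp]] <- block
    labels[[sp]] <- tpm$samples[, c("sample_id", "species", "tissue", "age_group")]
  }
  mat <- do.call(rbind, blocks)
  lab <- do.call(rbind, labels)
  rownames(mat) <- lab$sample_id
  rownames(lab) <- NULL
  structure(list(matrix = mat, labels = lab), class = "embedding_input")
}

#' Two-dimensional coordinates for visualisation
#'
#' The dimensionality-reduction optimizer is delegated behind this narrow
#' interface: any function mapping a samples x features matrix to 2-D
#' coordinates can be supplied (e.g. a t-SNE implementation, with the
#' given seed and perplexity). The built-in default is a seeded 2-D
#' principal-component projection. The separation scores do not require
#' coordinates at all and are the tested contract.
#'
#' @param inp An `embedding_input`.
#' @param fn Optional embedder `function(matrix, seed, perplexity)`
#'   returning a samples x 2 matrix.
#' @param seed Integer seed recorded (and forwarded to `fn`).
#' @param perplexity Neighbourhood-size parameter forwarded to `fn`
#'   (default 10); unused by the PCA default.
#' @return Matrix (samples x 2) with attributes `seed`, `perplexity`,
#'   `method` and `scale` ("log2(TPM+1)").
#' @export
embed_coordinates <- function(inp, fn = NULL, seed = 1L, perplexity = 10) {
  stopifnot(inherits(inp, "embedding_input"))
  if (is.null(fn)) {
    set.seed(seed)
    pc <- stats::prcomp(inp$matrix, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pc$x))
    coords <- pc$x[, seq_len(k), drop = FALSE]
    if (k < 2L) coords <- cbind(coords, 0)
    method <- "pca"
  } else {
    coords <- fn(inp$matrix, seed, perplexity)
    method <- "user"
  }
  coords <- as.matrix(coords)
  dimnames(coords) <- list(rownames(inp$matrix), c("x", "y"))
  structure(coords, seed = seed, perplexity = perplexity, method = method,
            scale = "log2(TPM+1)")
}

mean_silhouette <- function(d, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)), dist = d)
  mean(sil[, "sil_width"])
}

#' Cluster-separation scores under tissue, species-tissue and age labelings
#'
#' Mean silhouette coefficients (Euclidean distance) of the samples under
#' three labelings: tissue; species x tissue; and age group evaluated
#' within each species x tissue cluster, averaged over clusters. Scores
#' are computed on the 2-D embedding when provided, else directly on the
#' log-expression feature space. A labeling with a single class yields NA
#' for that score rather than an error.
#'
#' @param inp An `embedding_input`.
#' @param embedded Optional samples x 2 coordinate matrix (row order
#'   matching `inp`).
#' @return A list of class `separation_report`: `silhouette_by_tissue`,
#'   `silhouette_by_species_tissue`, `silhouette_by_age_within_cluster`,
#'   `computed_on` (`"embedding_2d"` or `"feature_space"`).
#' @export
separation_scores <- function(inp, embedded = NULL) {
  stopifnot(inherits(inp, "embedding_input"))
  lab <- inp$labels
  space <- if (is.null(embedded)) inp$matrix else as.matrix(embedded)
  if (nrow(space) != nrow(lab)) stop("coordinate rows do not match sample labels")
  d <- stats::dist(space)
  st <- paste(lab$species, lab$tissue, sep = ":")
  within <- vapply(unique(st), function(cl) {
    idx <- which(st == cl)
    if (length(idx) < 3L || length(unique(lab$age_group[idx])) < 2L) return(NA_real_)
    mean_silhouette(stats::dist(space[idx, , drop = FALSE]), lab$age_group[idx])
  }, numeric(1L))
  structure(list(
    silhouette_by_tissue = mean_silhouette(d, lab$tissue),
    silhouette_by_species_tissue = mean_silhouette(d, st),
    silhouette_by_age_within_cluster =
      if (all(is.na(within))) NA_real_ else mean(within, na.rm = TRUE),
    computed_on = if (is.null(embedded)) "feature_space" else "embedding_2d"
  ), class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf(
    "separation (%s): tissue %.3f | species x tissue %.3f | age within cluster %.3f\n",
    x$computed_on, x$silhouette_by_tissue, x$silhouette_by_species_tissue,
    x$silhouette_by_age_within_cluster))
  invisible(x)
}
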
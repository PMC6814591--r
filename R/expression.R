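## TPM normalization, expression filtering, and a simplified
## negative-binomial Wald test with Benjamini-Hochberg adjustment.

new_de_result <- function(df, species, tissue, comparison) {
  structure(df, class = c("de_result", "data.frame"),
            species = species, tissue = tissue, comparison = comparison)
}

#' TPM-normalize a count matrix
#'
#' Transcripts per million: counts are divided by gene length (length-rate),
#' then each sample is rescaled so its length-rates sum to one million:
#' \deqn{TPM_{gs} = 10^6 (c_{gs}/l_g) / \sum_j (c_{js}/l_j).}
#' Every column with at least one nonzero count sums to 1e6; an all-zero
#' sample yields an all-zero TPM column.
#'
#' @param cm A `count_matrix`.
#' @param lengths A `gene_lengths` vector covering every gene of `cm`.
#' @return A `tpm_matrix` (list with `tpm` matrix and `samples` metadata).
#' @export
tpm_normalize <- function(cm, lengths) {
  stopifnot(inherits(cm, "count_matrix"))
  genes <- rownames(cm$counts)
  missing <- setdiff(genes, names(lengths))
  if (length(missing) > 0L) {
    stop("missing gene length for: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  len <- as.numeric(lengths[genes])
  rate <- cm$counts / len
  denom <- colSums(rate)
  tpm <- sweep(rate, 2L, ifelse(denom > 0, denom, 1), "/") * 1e6
  dimnames(tpm) <- dimnames(cm$counts)
  new_tpm_matrix(tpm, cm$samples)
}

#' Expressed-gene filter
#'
#' Keeps genes with a TPM value strictly greater than 1 in at least one
#' sample; all others are discarded from downstream expression analysis.
#'
#' @param tpm A `tpm_matrix`.
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(tpm) {
  stopifnot(inherits(tpm, "tpm_matrix"))
  if (nrow(tpm$tpm) == 0L) return(character(0))
  rownames(tpm$tpm)[apply(tpm$tpm > 1, 1L, any)]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants: each sample's counts are divided by the
#' per-gene geometric mean across samples and the median of those ratios is
#' taken; genes with a zero geometric mean are excluded. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Integer matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA
  geo <- exp(rowMeans(lg))
  ok <- is.finite(geo) & geo > 0
  if (!any(ok)) stop("no gene with all-positive counts; size factors undefined")
  sf <- apply(counts[ok, , drop = FALSE], 2L, function(col) stats::median(col / geo[ok]))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-positive size factor estimated")
  sf / exp(mean(log(sf)))
}

#' Simplified negative-binomial Wald test for one age contrast
#'
#' A self-contained approximation of the standard negative-binomial
#' differential-expression test, calibrated by simulation rather than by
#' matching any published implementation: counts are scaled by
#' median-of-ratios size factors; per-group means are compared through
#' \eqn{log2FC = \log_2((m_c + 0.5)/(m_b + 0.5))} (contrast over baseline);
#' a gene-wise dispersion \eqn{\alpha} is estimated by method of moments
#' (variance = \eqn{\mu + \alpha\mu^2}) pooled across the two groups and
#' floored at 1e-8; the delta-method standard error of the log2 fold change
#' gives a Wald statistic, referred to a Student-t distribution with
#' \eqn{n_b + n_c - 2} degrees of freedom (two-sided). The t reference
#' absorbs the sampling noise of the gene-wise dispersion at small n and
#' keeps the test's type-I error at its nominal level.
#'
#' Swapping baseline and contrast negates every log2 fold change and leaves
#' p-values unchanged.
#'
#' @param cm A `count_matrix`; size factors are computed across all of its
#'   samples.
#' @param baseline,contrast Age groups (`"M"`, `"A"`, `"OA"`) to compare;
#'   each must have at least 2 replicates in `cm`.
#' @param kept_genes Genes to test (default: all genes of `cm`).
#' @return A `de_result` data.frame with columns `gene_id`, `base_mean`,
#'   `log2fc`, `p_value` and `fdr` (NA until [bh_fdr()] is applied).
#' @export
nb_wald_test <- function(cm, baseline, contrast, kept_genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- cm$samples
  idx_b <- which(meta$age_group == baseline)
  idx_c <- which(meta$age_group == contrast)
  cell <- sprintf("(%s, %s, %%s)", paste(unique(meta$species), collapse = "/"),
                  paste(unique(meta$tissue), collapse = "/"))
  if (length(idx_b) < 2L) stop(sprintf(paste0("fewer than 2 replicates in ", cell), baseline))
  if (length(idx_c) < 2L) stop(sprintf(paste0("fewer than 2 replicates in ", cell), contrast))
  if (is.null(kept_genes)) kept_genes <- rownames(cm$counts)
  missing <- setdiff(kept_genes, rownames(cm$counts))
  if (length(missing) > 0L) stop("kept_genes not in matrix: ", paste(utils::head(missing, 5L), collapse = ", "))

  sf <- size_factors(cm$counts)
  q <- sweep(cm$counts[kept_genes, , drop = FALSE], 2L, sf, "/")
  qb <- q[, idx_b, drop = FALSE]
  qc <- q[, idx_c, drop = FALSE]
  nb <- length(idx_b); nc <- length(idx_c)
  mb <- rowMeans(qb); mc <- rowMeans(qc)
  vb <- apply(qb, 1L, stats::var); vc <- apply(qc, 1L, stats::var)

  # method-of-moments dispersion per group, pooled with df weights
  ab <- ifelse(mb > 0, (vb - mb) / mb^2, NA_real_)
  ac <- ifelse(mc > 0, (vc - mc) / mc^2, NA_real_)
  wb <- ifelse(is.na(ab), 0, nb - 1L)
  wc <- ifelse(is.na(ac), 0, nc - 1L)
  alpha <- (ifelse(is.na(ab), 0, ab) * wb + ifelse(is.na(ac), 0, ac) * wc) /
    pmax(wb + wc, 1)
  alpha <- pmax(alpha, 1e-8)

  eps <- 0.5
  lfc <- log2((mc + eps) / (mb + eps))
  var_mb <- (mb + alpha * mb^2) / nb
  var_mc <- (mc + alpha * mc^2) / nc
  se <- sqrt(var_mb / (mb + eps)^2 + var_mc / (mc + eps)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pt(-abs(z), df = nb + nc - 2L)

  df <- data.frame(gene_id = kept_genes,
                   base_mean = (mb * nb + mc * nc) / (nb + nc),
                   log2fc = lfc, p_value = p, fdr = NA_real_,
                   stringsAsFactors = FALSE, row.names = NULL)
  cmp <- comparisons()
  hit <- cmp$baseline == baseline & cmp$contrast == contrast
  new_de_result(df,
                species = unique(meta$species)[1L],
                tissue = unique(meta$tissue)[1L],
                comparison = if (any(hit)) cmp$comparison[hit][1L] else
                  paste0(baseline, "_vs_", contrast))
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} m \, p_{(j)} / j}, capped at 1; results are
#' returned in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1] and contain no NA")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run the full differential-expression stage for one species
#'
#' Per (species, tissue): TPM normalization and the expressed-gene filter
#' are applied jointly over all three age groups of that tissue, then the
#' negative-binomial Wald test is run for each of the three age comparisons
#' and Benjamini-Hochberg adjustment is applied within each
#' (species, tissue, comparison) table separately.
#'
#' @param cm A `count_matrix` holding one species' samples (any number of
#'   tissues; each tissue must carry all three age groups).
#' @param lengths A `gene_lengths` vector.
#' @param fdr_cut Significance cutoff recorded for downstream use
#'   (default 0.05); the tables themselves keep all tested genes.
#' @return Named list of `de_result` tables, one per (tissue, comparison),
#'   names `"species|tissue|comparison"`.
#' @export
run_de <- function(cm, lengths, fdr_cut = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  meta <- cm$samples
  species <- unique(meta$species)
  if (length(species) != 1L) stop("run_de expects a single-species count matrix")
  out <- list()
  for (tis in unique(meta$tissue)) {
    sub <- subset_count_matrix(cm, samples = meta$sample_id[meta$tissue == tis])
    ages <- unique(sub$samples$age_group)
    if (!setequal(ages, AGE_GROUPS)) {
      stop(sprintf("(%s, %s) lacks age group(s): %s", species, tis,
                   paste(setdiff(AGE_GROUPS, ages), collapse = ", ")))
    }
    kept <- expression_filter(tpm_normalize(sub, lengths))
    cmp <- comparisons()
    for (i in seq_len(nrow(cmp))) {
      res <- nb_wald_test(sub, cmp$baseline[i], cmp$contrast[i], kept_genes = kept)
      res$fdr <- bh_fdr(res$p_value)
      out[[paste(species, tis, cmp$comparison[i], sep = "|")]] <- res
    }
  }
  out
}
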
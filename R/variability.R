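## Coefficient-of-variation analysis of expression across age groups.

#' Per-gene coefficient of variation within each age group
#'
#' For every gene and age group of each (species, tissue) in the TPM
#' matrix, computes CV = sample standard deviation (n-1 denominator)
#' divided by mean, across the replicates of that group. A gene enters a
#' group's table only when it is expressed there (group mean TPM > 1);
#' groups need at least 2 replicates.
#'
#' @param tpm A `tpm_matrix` (one or more tissues of one species, or any
#'   sample collection with metadata).
#' @param gene_subset Optional character vector restricting the analysis
#'   (e.g. the preselected panel, in the namespace of the TPM rownames);
#'   default all genes.
#' @return data.frame of class `cv_table`: `species`, `tissue`, `gene_id`,
#'   `age_group`, `cv`, `n_samples`.
#' @export
compute_cv <- function(tpm, gene_subset = NULL) {
  stopifnot(inherits(tpm, "tpm_matrix"))
  mat <- tpm$tpm
  if (!is.null(gene_subset)) {
    keep <- intersect(rownames(mat), gene_subset)
    mat <- mat[keep, , drop = FALSE]
  }
  meta <- tpm$samples
  out <- list()
  cells <- unique(meta[, c("species", "tissue")])
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; tis <- cells$tissue[i]
    for (age in AGE_GROUPS) {
      cols <- meta$sample_id[meta$species == sp & meta$tissue == tis &
                               meta$age_group == age]
      if (length(cols) == 0L) next
      if (length(cols) < 2L) {
        stop(sprintf("(%s, %s, %s) has fewer than 2 replicates; CV undefined",
                     sp, tis, age))
      }
      sub <- mat[, cols, drop = FALSE]
      mu <- rowMeans(sub)
      expressed <- mu > 1
      if (!any(expressed)) next
      sdev <- apply(sub[expressed, , drop = FALSE], 1L, stats::sd)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, tissue = tis,
        gene_id = rownames(sub)[expressed], age_group = age,
        cv = sdev / mu[expressed], n_samples = length(cols),
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(species = character(0), tissue = character(0),
                      gene_id = character(0), age_group = character(0),
                      cv = numeric(0), n_samples = integer(0),
                      stringsAsFactors = FALSE)
  res <- if (length(out) == 0L) empty else do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cv_table", "data.frame"))
}

#' Compare per-gene CV distributions between two age groups
#'
#' Per (species, tissue), a two-sided Welch t-test on the per-gene CV
#' values of the two age groups. The direction label (`decrease` when the
#' second group's mean CV is lower, `increase` when higher) is assigned
#' when p falls at or below `sig_level`; otherwise `none`. The
#' significance tier (0.01, 0.001, 0.0001, or NA) is reported alongside.
#'
#' @param cv A `cv_table` from [compute_cv()].
#' @param pair Character vector of two age groups, e.g. `c("A", "OA")`;
#'   the first is the reference.
#' @param sig_level Significance level for the direction label
#'   (default 0.01, the outermost tier).
#' @return data.frame of class `cv_comparison`: `species`, `tissue`,
#'   `group1`, `group2`, `n1`, `n2`, `mean_cv_1`, `mean_cv_2`,
#'   `t_statistic`, `p_value`, `tier`, `direction`.
#' @export
compare_cv <- function(cv, pair = c("A", "OA"), sig_level = 0.01) {
  stopifnot(inherits(cv, "cv_table"), length(pair) == 2L)
  if (!all(pair %in% AGE_GROUPS)) stop("pair must name two age groups")
  cells <- unique(as.data.frame(cv)[, c("species", "tissue")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; tis <- cells$tissue[i]
    v1 <- cv$cv[cv$species == sp & cv$tissue == tis & cv$age_group == pair[1L]]
    v2 <- cv$cv[cv$species == sp & cv$tissue == tis & cv$age_group == pair[2L]]
    if (length(v1) < 2L || length(v2) < 2L) {
      stop(sprintf("(%s, %s): both age groups need >= 2 expressed genes", sp, tis))
    }
    if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(v2, v1, alternative = "two.sided", var.equal = FALSE)
    }
    p <- tt$p.value
    tier <- if (p <= 1e-4) 1e-4 else if (p <= 1e-3) 1e-3 else
      if (p <= 1e-2) 1e-2 else NA_real_
    dir <- if (p <= sig_level) {
      if (mean(v2) < mean(v1)) "decrease" else "increase"
    } else "none"
    out[[length(out) + 1L]] <- data.frame(
      species = sp, tissue = tis, group1 = pair[1L], group2 = pair[2L],
      n1 = length(v1), n2 = length(v2),
      mean_cv_1 = mean(v1), mean_cv_2 = mean(v2),
      t_statistic = unname(tt$statistic), p_value = p, tier = tier,
      direction = dir, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("cv_comparison", "data.frame"))
}

#' Percentile summary of the CV distribution per age group
#'
#' Empirical 2.5%, 50% and 97.5% percentiles (linear interpolation) of the
#' per-gene CV distribution, per (species, tissue, age group).
#'
#' @param cv A `cv_table`.
#' @return data.frame: `species`, `tissue`, `age_group`, `n_genes`,
#'   `p2.5`, `median`, `p97.5`.
#' @export
cv_percentile_summary <- function(cv) {
  stopifnot(inherits(cv, "cv_table"))
  key <- paste(cv$species, cv$tissue, cv$age_group, sep = "\r")
  grp <- split(as.data.frame(cv), key)
  out <- do.call(rbind, lapply(grp, function(g) {
    if (nrow(g) < 2L) stop("percentile summary needs >= 2 genes per group")
    q <- stats::quantile(g$cv, probs = c(0.025, 0.5, 0.975), type = 7, names = FALSE)
    data.frame(species = g$species[1L], tissue = g$tissue[1L],
               age_group = g$age_group[1L], n_genes = nrow(g),
               `p2.5` = q[1L], median = q[2L], `p97.5` = q[3L],
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$species, out$tissue, match(out$age_group, AGE_GROUPS)), ]
  rownames(out) <- NULL
  out
}
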
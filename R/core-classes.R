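#' @keywords internal
"_PACKAGE"

#' Age-group levels of the cross-sectional design
#'
#' Every sample belongs to exactly one of three age groups: mature (`"M"`),
#' aged (`"A"`) and old-aged (`"OA"`).
#'
#' @export
AGE_GROUPS <- c("M", "A", "OA")

#' The three age comparisons
#'
#' Each (species, tissue) is analysed with three pairwise contrasts of its
#' age groups: early aging (M vs A), late aging (M vs OA) and longevity
#' (A vs OA). The baseline group is listed first; a positive log2 fold
#' change always means higher expression in the older (contrast) group.
#'
#' @return A data.frame with columns `comparison`, `baseline`, `contrast`.
#' @export
comparisons <- function() {
  data.frame(
    comparison = c("early", "late", "longevity"),
    baseline   = c("M", "M", "A"),
    contrast   = c("A", "OA", "OA"),
    stringsAsFactors = FALSE
  )
}

## ---- sample metadata -------------------------------------------------------

validate_sample_meta <- function(meta) {
  required <- c("sample_id", "species", "tissue", "age_group", "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("sample metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
    stop("duplicate sample_id in metadata: ", paste(dup, collapse = ", "))
  }
  bad <- !meta$age_group %in% AGE_GROUPS
  if (any(bad)) {
    stop("invalid age_group value(s): ", paste(unique(meta$age_group[bad]), collapse = ", "),
         " (must be one of ", paste(AGE_GROUPS, collapse = "/"), ")")
  }
  rep_num <- suppressWarnings(as.numeric(meta$replicate))
  if (any(is.na(rep_num)) || any(rep_num < 1) || any(rep_num != round(rep_num))) {
    stop("replicate must be a positive integer for every sample")
  }
  meta$replicate <- as.integer(rep_num)
  meta$sample_id <- as.character(meta$sample_id)
  meta$species <- as.character(meta$species)
  meta$tissue <- as.character(meta$tissue)
  meta$age_group <- as.character(meta$age_group)
  meta[, required]
}

## ---- count matrix ----------------------------------------------------------

#' Construct a validated count matrix
#'
#' Bundles an integer genes x samples read-count matrix with its sample
#' metadata. Counts must be non-negative integers; gene and sample
#' identifiers must be unique; the columns of `counts` must match
#' `meta$sample_id` one-to-one and are reordered to follow the metadata.
#'
#' @param counts Numeric matrix of read counts with rownames (gene ids) and
#'   colnames (sample ids).
#' @param meta data.frame with columns `sample_id`, `species`, `tissue`,
#'   `age_group` (one of `"M"`, `"A"`, `"OA"`) and `replicate`.
#' @return An object of class `count_matrix` with elements `counts`
#'   (integer matrix) and `samples` (metadata data.frame).
#' @export
count_matrix <- function(counts, meta) {
  meta <- validate_sample_meta(meta)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- unique(rownames(counts)[duplicated(rownames(counts))])
    stop("duplicate gene id(s) in count matrix: ", paste(dup, collapse = ", "))
  }
  extra_meta <- setdiff(meta$sample_id, colnames(counts))
  if (length(extra_meta) > 0L) {
    stop("metadata lists sample(s) absent from the count matrix: ",
         paste(extra_meta, collapse = ", "))
  }
  extra_counts <- setdiff(colnames(counts), meta$sample_id)
  if (length(extra_counts) > 0L) {
    stop("count matrix contains sample(s) absent from the metadata: ",
         paste(extra_counts, collapse = ", "))
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-integer or negative count for gene '%s', sample '%s'",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]]
    ))
  }
  counts <- counts[, meta$sample_id, drop = FALSE]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d genes x %d samples (%s)\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$samples$species), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by samples and/or genes
#'
#' @param cm A `count_matrix`.
#' @param samples Character vector of sample ids to keep (default all).
#' @param genes Character vector of gene ids to keep (default all).
#' @return A `count_matrix` restricted to the requested rows/columns.
#' @export
subset_count_matrix <- function(cm, samples = NULL, genes = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  meta <- cm$samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, meta$sample_id)
    if (length(missing) > 0L) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "))
    }
    meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
    counts <- counts[, samples, drop = FALSE]
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing) > 0L) {
      stop("unknown gene id(s): ", paste(missing, collapse = ", "))
    }
    counts <- counts[genes, , drop = FALSE]
  }
  count_matrix(counts, meta)
}

## ---- gene lengths ----------------------------------------------------------

#' Construct a validated gene-length table
#'
#' @param lengths Named numeric vector of gene lengths in nucleotides.
#' @return Named integer vector of class `gene_lengths`.
#' @export
gene_lengths <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths)))) {
    stop("gene lengths must be named by gene id")
  }
  if (anyDuplicated(names(lengths))) {
    stop("duplicate gene id(s) in gene lengths")
  }
  if (any(is.na(lengths)) || any(lengths <= 0) || any(lengths != round(lengths))) {
    bad <- names(lengths)[is.na(lengths) | lengths <= 0 | lengths != round(lengths)][1L]
    stop("gene length must be a positive integer; offending gene: ", bad)
  }
  structure(as.integer(stats::setNames(lengths, names(lengths))),
            names = names(lengths), class = "gene_lengths")
}

## ---- TPM matrix ------------------------------------------------------------

new_tpm_matrix <- function(tpm, meta) {
  structure(list(tpm = tpm, samples = meta), class = "tpm_matrix")
}

#' @export
print.tpm_matrix <- function(x, ...) {
  cat(sprintf("tpm_matrix: %d genes x %d samples\n", nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

## ---- ortholog map ----------------------------------------------------------

#' Construct a validated one-to-one ortholog map
#'
#' Links per-species gene identifiers to a reference gene identifier (by
#' convention the mouse orthologue id). Mapping must be one-to-one in both
#' directions within each species; rows with a missing species entry are
#' retained but flagged incomplete.
#'
#' @param df data.frame whose first column `ref_id` holds reference gene ids
#'   and remaining columns (one per species) the species gene ids; empty
#'   strings or NA mark a missing orthologue.
#' @param species Character vector naming the species columns to use.
#' @return data.frame of class `ortholog_map` with an added logical
#'   `complete` column and attribute `species`.
#' @export
ortholog_map <- function(df, species) {
  if (!"ref_id" %in% names(df)) stop("ortholog table must have a 'ref_id' column")
  missing <- setdiff(species, names(df))
  if (length(missing) > 0L) {
    stop("ortholog table is missing species column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, c("ref_id", species), drop = FALSE]
  df[] <- lapply(df, as.character)
  if (anyDuplicated(df$ref_id)) {
    dup <- unique(df$ref_id[duplicated(df$ref_id)])
    stop("duplicate reference gene id(s) in ortholog map: ", paste(dup, collapse = ", "))
  }
  for (sp in species) {
    v <- df[[sp]]
    v[is.na(v)] <- ""
    df[[sp]] <- v
    present <- v[nzchar(v)]
    if (anyDuplicated(present)) {
      dup <- unique(present[duplicated(present)])
      stop(sprintf(
        "gene id(s) mapped to more than one reference gene for species '%s': %s (one-to-one required)",
        sp, paste(dup, collapse = ", ")
      ))
    }
  }
  df$complete <- apply(df[, species, drop = FALSE], 1L, function(r) all(nzchar(r)))
  structure(df, class = c("ortholog_map", "data.frame"), species = species)
}

#' Map species gene ids to reference ids
#'
#' @param orthologs An `ortholog_map`.
#' @param species Species whose namespace `gene_ids` live in.
#' @param gene_ids Character vector of species gene ids.
#' @return Character vector of reference ids, NA where unmapped.
#' @export
to_reference_ids <- function(orthologs, species, gene_ids) {
  stopifnot(inherits(orthologs, "ortholog_map"))
  if (!species %in% attr(orthologs, "species")) {
    stop("species '", species, "' not present in ortholog map")
  }
  idx <- match(gene_ids, orthologs[[species]])
  orthologs$ref_id[idx]
}

#' Map reference ids to species gene ids
#'
#' @inheritParams to_reference_ids
#' @param ref_ids Character vector of reference gene ids.
#' @return Character vector of species gene ids, NA where unmapped.
#' @export
from_reference_ids <- function(orthologs, species, ref_ids) {
  stopifnot(inherits(orthologs, "ortholog_map"))
  if (!species %in% attr(orthologs, "species")) {
    stop("species '", species, "' not present in ortholog map")
  }
  out <- orthologs[[species]][match(ref_ids, orthologs$ref_id)]
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

## ---- annotation table ------------------------------------------------------

#' Default controlled vocabulary of biological-process labels
#'
#' The six process categories used to annotate the senescence/inflammation
#' gene panel: immune/inflammatory response, senescence, apoptosis,
#' oxidative stress response, cell cycle, and other.
#'
#' @return Character vector of labels.
#' @export
process_vocabulary <- function() {
  c("immune/inflammatory response", "senescence", "apoptosis",
    "oxidative stress response", "cell cycle", "other")
}

#' Construct a validated gene-to-process annotation table
#'
#' @param df data.frame with columns `ref_id` and `label`, one row per
#'   (gene, label) pair; a gene may carry several labels.
#' @param vocabulary Character vector of admissible labels.
#' @return data.frame of class `annotation_table` with attribute `vocabulary`.
#' @export
annotation_table <- function(df, vocabulary = process_vocabulary()) {
  if (!all(c("ref_id", "label") %in% names(df))) {
    stop("annotation table must have columns 'ref_id' and 'label'")
  }
  df <- data.frame(ref_id = as.character(df$ref_id),
                   label = as.character(df$label),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$label), vocabulary)
  if (length(bad) > 0L) {
    stop("annotation label(s) outside the controlled vocabulary: ",
         paste(bad, collapse = ", "))
  }
  df <- unique(df)
  structure(df, class = c("annotation_table", "data.frame"), vocabulary = vocabulary)
}

## ---- study design ----------------------------------------------------------

#' Construct a study design (availability and replication structure)
#'
#' Records which (species, tissue) combinations exist and how many
#' replicates each (species, tissue, age group) cell has. Not all species
#' need carry all tissues.
#'
#' @param cells data.frame with columns `species`, `tissue`, `age_group`,
#'   `n_reps`; or NULL to build a complete design from `species`, `tissues`,
#'   `n_reps`.
#' @param species,tissues,n_reps Used when `cells` is NULL: every species
#'   gets every tissue with `n_reps` replicates in each of the three age
#'   groups.
#' @return data.frame of class `study_design`.
#' @export
study_design <- function(cells = NULL, species = NULL, tissues = NULL, n_reps = 5L) {
  if (is.null(cells)) {
    if (is.null(species) || is.null(tissues)) {
      stop("either 'cells' or both 'species' and 'tissues' must be given")
    }
    cells <- expand.grid(species = species, tissue = tissues,
                         age_group = AGE_GROUPS,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells$n_reps <- as.integer(n_reps)
  }
  required <- c("species", "tissue", "age_group", "n_reps")
  if (!all(required %in% names(cells))) {
    stop("study design needs columns: ", paste(required, collapse = ", "))
  }
  cells <- cells[, required]
  cells$species <- as.character(cells$species)
  cells$tissue <- as.character(cells$tissue)
  cells$age_group <- as.character(cells$age_group)
  cells$n_reps <- as.integer(cells$n_reps)
  if (any(!cells$age_group %in% AGE_GROUPS)) {
    stop("age_group values must be among ", paste(AGE_GROUPS, collapse = "/"))
  }
  if (any(cells$n_reps < 1L)) stop("every design cell must have at least 1 replicate")
  key <- paste(cells$species, cells$tissue, cells$age_group)
  if (anyDuplicated(key)) stop("duplicate (species, tissue, age_group) cell in design")
  # a (species, tissue) present must carry all three age groups
  st <- unique(cells[, c("species", "tissue")])
  for (i in seq_len(nrow(st))) {
    ages <- cells$age_group[cells$species == st$species[i] & cells$tissue == st$tissue[i]]
    if (!setequal(ages, AGE_GROUPS)) {
      stop(sprintf("(%s, %s) lacks age group(s): %s", st$species[i], st$tissue[i],
                   paste(setdiff(AGE_GROUPS, ages), collapse = ", ")))
    }
  }
  structure(cells, class = c("study_design", "data.frame"))
}

#' Available (species, tissue) combinations of a design
#'
#' @param design A `study_design`.
#' @return data.frame with columns `species`, `tissue`.
#' @export
design_cells <- function(design) {
  stopifnot(inherits(design, "study_design"))
  unique(as.data.frame(design)[, c("species", "tissue")])
}
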
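## Tabular I/O. One dialect throughout: tab-separated, UTF-8, '#' comment
## lines ignored, gene ids case-sensitive, floats at 6 significant digits.

read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 6L, format = "g")
  out[is.na(x)] <- "NA"
  trimws(out)
}

write_tsv_file <- function(df, path, comment = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  cols <- vapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
  if (nrow(df) == 0L) cols <- matrix(character(0), nrow = 0L, ncol = ncol(df))
  body <- if (nrow(df) > 0L) apply(cols, 1L, paste, collapse = "\t") else character(0)
  lines <- c(lines, paste(names(df), collapse = "\t"), body)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## ---- count matrices --------------------------------------------------------

#' Read a count matrix and its sample metadata from TSV files
#'
#' The count file has gene ids in its first column and one column of
#' integer read counts per sample; the metadata file has columns
#' `sample_id`, `species`, `tissue`, `age_group`, `replicate`. Samples
#' present in only one of the two files are an error. Samples are ordered
#' as in the metadata.
#'
#' @param path Path to the count TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, meta_path) {
  tab <- read_tsv_file(path)
  if (ncol(tab) < 2L) stop("count matrix must have a gene id column plus sample columns")
  genes <- tab[[1L]]
  mat_chr <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(mat <- matrix(as.numeric(mat_chr), nrow = nrow(mat_chr),
                                 dimnames = list(genes, colnames(mat_chr))))
  bad <- which(is.na(mat) | mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count for gene '%s', sample '%s' in %s",
                 genes[bad[1L, 1L]], colnames(mat)[bad[1L, 2L]], path))
  }
  meta <- read_tsv_file(meta_path)
  count_matrix(mat, meta)
}

#' Write a count matrix (and optionally its metadata) to TSV
#'
#' @param cm A `count_matrix`.
#' @param path Output path for the counts.
#' @param meta_path Optional output path for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, meta_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_file(df, path)
  if (!is.null(meta_path)) write_tsv_file(cm$samples, meta_path)
  invisible(path)
}

## ---- gene lengths ----------------------------------------------------------

#' Read a gene-length table (gene_id, length_nt) from TSV
#'
#' @param path Path to the TSV.
#' @return A [gene_lengths()] vector.
#' @export
read_gene_lengths <- function(path) {
  tab <- read_tsv_file(path)
  if (!all(c("gene_id", "length_nt") %in% names(tab))) {
    stop("gene-length table must have columns 'gene_id' and 'length_nt'")
  }
  gene_lengths(stats::setNames(suppressWarnings(as.numeric(tab$length_nt)), tab$gene_id))
}

#' Write a gene-length table to TSV
#'
#' @param lengths A `gene_lengths` vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_lengths <- function(lengths, path) {
  write_tsv_file(data.frame(gene_id = names(lengths),
                            length_nt = as.integer(lengths)), path)
}

## ---- ortholog map ----------------------------------------------------------

#' Read a one-to-one ortholog map from TSV
#'
#' @param path Path to a TSV with a `ref_id` column plus one column per
#'   species; empty cells mark a missing orthologue.
#' @param species Character vector of species column names.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path, species) {
  ortholog_map(read_tsv_file(path), species)
}

#' Write an ortholog map to TSV
#'
#' @param orthologs An `ortholog_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_map <- function(orthologs, path) {
  df <- as.data.frame(orthologs)[, c("ref_id", attr(orthologs, "species"))]
  write_tsv_file(df, path)
}

## ---- annotations -----------------------------------------------------------

#' Read a gene-to-process annotation table from TSV
#'
#' @param path Path to a TSV with columns `ref_id` and `label`.
#' @param vocabulary Admissible process labels.
#' @return An [annotation_table()].
#' @export
read_annotations <- function(path, vocabulary = process_vocabulary()) {
  annotation_table(read_tsv_file(path), vocabulary)
}

## ---- generic result writer -------------------------------------------------

#' Write a tabular result to TSV
#'
#' Floats are written at 6 significant digits; the column order is stable,
#' so writing, re-reading and writing again is byte-identical.
#'
#' @param obj A result object (`de_result`, `count_matrix`, or any
#'   data.frame such as signature calls, CV tables or profiles).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) UseMethod("write_table")

#' @export
write_table.data.frame <- function(obj, path) write_tsv_file(obj, path)

#' @export
write_table.count_matrix <- function(obj, path) write_count_matrix(obj, path)

#' @export
write_table.de_result <- function(obj, path) {
  hdr <- sprintf("species=%s tissue=%s comparison=%s",
                 attr(obj, "species"), attr(obj, "tissue"), attr(obj, "comparison"))
  write_tsv_file(as.data.frame(obj), path, comment = hdr)
}

#' Read a differential-expression result table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A `de_result` data.frame with attributes `species`, `tissue`,
#'   `comparison`.
#' @export
read_de_table <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(species = NA_character_, tissue = NA_character_, comparison = NA_character_)
  if (startsWith(first, "#")) {
    kv <- regmatches(first, gregexpr("[a-z]+=[^ ]+", first))[[1L]]
    for (pair in kv) {
      parts <- strsplit(pair, "=", fixed = TRUE)[[1L]]
      if (parts[1L] %in% names(meta)) meta[[parts[1L]]] <- parts[2L]
    }
  }
  tab <- read_tsv_file(path)
  for (col in c("base_mean", "log2fc", "p_value", "fdr")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  new_de_result(tab, meta$species, meta$tissue, meta$comparison)
}
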
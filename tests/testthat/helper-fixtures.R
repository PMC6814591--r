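# Fixture builders: everything is generated in code at test time.

make_meta <- function(species = "mmu", tissue = "brain",
                      ages = rep(c("M", "A", "OA"), each = 2)) {
  n <- length(ages)
  reps <- stats::ave(seq_len(n), ages, FUN = seq_along)
  data.frame(sample_id = sprintf("%s_%s_%s_r%d", species, tissue, ages, reps),
             species = species, tissue = tissue, age_group = ages,
             replicate = reps, stringsAsFactors = FALSE)
}

make_cm <- function(counts, species = "mmu", tissue = "brain",
                    ages = rep(c("M", "A", "OA"), each = 2)) {
  meta <- make_meta(species, tissue, ages)
  colnames(counts) <- meta$sample_id
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  count_matrix(counts, meta)
}

make_lengths <- function(gene_ids, len = 1000L) {
  gene_lengths(stats::setNames(rep(len, length(gene_ids)), gene_ids))
}

make_de_table <- function(species, tissue, comparison, gene_ids, lfc, fdr) {
  df <- data.frame(gene_id = gene_ids, base_mean = 100, log2fc = lfc,
                   p_value = fdr, fdr = fdr, stringsAsFactors = FALSE)
  agesig:::new_de_result(df, species, tissue, comparison)
}

# identity-style ortholog map: ref gene g -> "<sp>_<g>" for each species
make_orthologs <- function(genes, species) {
  df <- data.frame(ref_id = genes, stringsAsFactors = FALSE)
  for (sp in species) df[[sp]] <- paste0(sp, "_", genes)
  ortholog_map(df, species)
}

make_selection <- function(genes) {
  structure(list(initial = genes, selected = genes,
                 exclusions = data.frame(ref_id = character(0),
                                         reason = character(0))),
            class = "gene_selection")
}

# random small DE-table collections for oracle-equivalence checks
random_de_tables <- function(n_genes, species, tissues, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  orthologs <- make_orthologs(genes, species)
  tabs <- list()
  for (sp in species) for (tis in tissues) for (cmp in c("early", "late", "longevity")) {
    tabs[[paste(sp, tis, cmp, sep = "|")]] <- make_de_table(
      sp, tis, cmp, paste0(sp, "_", genes),
      lfc = round(stats::rnorm(n_genes, 0, 0.4), 3),
      fdr = round(stats::runif(n_genes, 0, 0.4), 3))
  }
  list(tables = tabs, genes = genes, orthologs = orthologs)
}
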
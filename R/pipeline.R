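## End-to-end orchestration: simulate/load -> DE -> preselection ->
## conserved signatures -> tissue markers -> CV analysis -> process
## profiles -> separation scores, with one resolved configuration.

#' Pipeline configuration
#'
#' Gathers every tunable threshold with its default: FDR cutoff 0.05,
#' minimum same-direction change 10% for conserved signatures, 25% for
#' tissue markers, conservation span of at least 3 species and 3 tissues,
#' DEG-support floor of 5 for process profiles.
#'
#' @param fdr_cut FDR significance cutoff.
#' @param min_change Conserved-signature minimum change (fraction).
#' @param marker_min_change Tissue-marker minimum change (fraction); must
#'   be >= `min_change`.
#' @param min_species,min_tissues Conservation span thresholds.
#' @param min_degs Profile support floor.
#' @param cv_pair Age-group pair for the variability comparison.
#' @param cv_genes `"selected"` (the preselected panel) or `"all"`
#'   (every expressed gene).
#' @param tissue_groups Named list of species groups for the marker
#'   screen; NULL for [default_tissue_groups()].
#' @param seed Seed forwarded to the simulator when no data is supplied.
#' @param sim A [sim_config()]; NULL for the default configuration with
#'   `seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fdr_cut = 0.05, min_change = 0.10,
                       marker_min_change = 0.25,
                       min_species = 3L, min_tissues = 3L, min_degs = 5L,
                       cv_pair = c("A", "OA"), cv_genes = c("selected", "all"),
                       tissue_groups = NULL, seed = 1L, sim = NULL) {
  cv_genes <- match.arg(cv_genes)
  if (marker_min_change < min_change) {
    stop("marker_min_change (", marker_min_change,
         ") must be >= min_change (", min_change, ")")
  }
  if (fdr_cut <= 0 || fdr_cut >= 1) stop("fdr_cut must lie in (0, 1)")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(fdr_cut = fdr_cut, min_change = min_change,
                 marker_min_change = marker_min_change,
                 min_species = as.integer(min_species),
                 min_tissues = as.integer(min_tissues),
                 min_degs = as.integer(min_degs),
                 cv_pair = cv_pair, cv_genes = cv_genes,
                 tissue_groups = tissue_groups,
                 seed = as.integer(seed), sim = sim),
            class = "run_config")
}

resolved_config_lines <- function(cfg) {
  c(sprintf("fdr_cut=%g", cfg$fdr_cut),
    sprintf("min_change=%g", cfg$min_change),
    sprintf("marker_min_change=%g", cfg$marker_min_change),
    sprintf("min_species=%d", cfg$min_species),
    sprintf("min_tissues=%d", cfg$min_tissues),
    sprintf("min_degs=%d", cfg$min_degs),
    sprintf("cv_pair=%s", paste(cfg$cv_pair, collapse = ":")),
    sprintf("cv_genes=%s", cfg$cv_genes),
    sprintf("seed=%d", cfg$seed),
    sprintf("sim.n_genes=%d", cfg$sim$n_genes),
    sprintf("sim.nb_dispersion=%g", cfg$sim$nb_dispersion),
    sprintf("sim.conserved=%d+%d@%g", cfg$sim$n_conserved_up,
            cfg$sim$n_conserved_down, cfg$sim$conserved_fold),
    sprintf("sim.markers=%d@%g(%s)", cfg$sim$n_tissue_markers,
            cfg$sim$marker_fold, cfg$sim$marker_tissue),
    sprintf("sim.oa_cv_scale=%g", cfg$sim$oa_cv_scale),
    sprintf("sim.seed=%d", cfg$sim$seed))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on the supplied study data (or
#' on a freshly simulated study when `data` is NULL): per-species
#' differential expression, ortholog-anchored preselection, the conserved
#' signature filter, the tissue-marker screen, the CV variability
#' comparison, process profiling and the separation scores. Identical
#' inputs, configuration and seed give identical results.
#'
#' @param cfg A [run_config()].
#' @param data Study data as returned by [simulate_study()] (elements
#'   `counts`, `lengths`, `orthologs`, `annotations`, optionally `truth`);
#'   NULL to simulate from `cfg$sim`.
#' @param out_dir Optional directory; when given, all result tables, the
#'   resolved configuration and a summary are written there.
#' @return A list of class `run_summary` holding the stage results
#'   (`selection`, `conserved`, `markers`, `cv_tests`, `profiles`,
#'   `separation`, `overlaps`), per-stage counts (`counts`), elapsed
#'   seconds per stage (`elapsed`) and, for simulated data, `truth`.
#' @export
run_pipeline <- function(cfg, data = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  elapsed <- c()
  tick <- function() proc.time()[["elapsed"]]
  t0 <- tick()
  if (is.null(data)) data <- simulate_study(cfg$sim)
  elapsed["simulate"] <- tick() - t0

  species <- names(data$counts)
  t0 <- tick()
  de_tables <- list()
  for (sp in species) {
    de_tables <- c(de_tables, run_de(data$counts[[sp]], data$lengths, cfg$fdr_cut))
  }
  elapsed["de"] <- tick() - t0

  t0 <- tick()
  selection <- preselect_genes(data$orthologs$ref_id, data$orthologs,
                               de_tables, cfg$fdr_cut)
  conserved <- conserved_signatures(de_tables, selection, data$orthologs,
                                    cfg$min_change, cfg$fdr_cut,
                                    cfg$min_species, cfg$min_tissues)
  markers <- tissue_specific_markers(de_tables, selection, data$orthologs,
                                     cfg$tissue_groups,
                                     cfg$marker_min_change, cfg$fdr_cut)
  index <- de_table_index(de_tables)
  shared <- names(which(table(unique(index[, c("species", "tissue")])$tissue) >= 2L))
  overlaps <- lapply(stats::setNames(shared, shared), function(tis) {
    common_deg_overlap(de_tables, tis, data$orthologs, cfg$fdr_cut)
  })
  elapsed["signatures"] <- tick() - t0

  t0 <- tick()
  tpm_set <- lapply(data$counts, tpm_normalize, lengths = data$lengths)
  cv_tables <- list(); cv_tests <- list()
  for (sp in species) {
    subset <- if (cfg$cv_genes == "selected") {
      ids <- from_reference_ids(data$orthologs, sp, selection$selected)
      ids[!is.na(ids)]
    } else NULL
    cvt <- compute_cv(tpm_set[[sp]], gene_subset = subset)
    cv_tables[[sp]] <- cvt
    cv_tests[[sp]] <- compare_cv(cvt, pair = cfg$cv_pair)
  }
  cv_table <- structure(do.call(rbind, c(cv_tables, list(make.row.names = FALSE))),
                        class = c("cv_table", "data.frame"))
  cv_tests <- do.call(rbind, c(cv_tests, list(make.row.names = FALSE)))
  elapsed["cv"] <- tick() - t0

  t0 <- tick()
  profiles <- profile_all(de_tables, data$annotations, data$orthologs,
                          cfg$fdr_cut, cfg$min_degs)
  elapsed["profiles"] <- tick() - t0

  t0 <- tick()
  emb <- build_embedding_input(tpm_set, selection, data$orthologs)
  separation <- separation_scores(emb)
  elapsed["embedding"] <- tick() - t0

  summary <- structure(list(
    selection = selection, conserved = conserved, markers = markers,
    overlaps = overlaps, cv_table = cv_table, cv_tests = cv_tests,
    profiles = profiles, separation = separation,
    de_tables = de_tables, truth = data$truth, config = cfg,
    counts = list(
      n_genes_initial = length(selection$initial),
      n_genes_selected = length(selection$selected),
      n_conserved_up = sum(conserved$conserved & conserved$direction == "up"),
      n_conserved_down = sum(conserved$conserved & conserved$direction == "down"),
      n_exclusive_markers = length(unique(markers$ref_id[markers$exclusive])),
      n_de_tables = length(de_tables)),
    elapsed = elapsed), class = "run_summary")

  if (!is.null(out_dir)) write_run_outputs(summary, out_dir)
  summary
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "run_summary: %d/%d genes selected; conserved up %d / down %d; ",
    "%d exclusive marker gene(s); %d DE tables\n"),
    x$counts$n_genes_selected, x$counts$n_genes_initial,
    x$counts$n_conserved_up, x$counts$n_conserved_down,
    x$counts$n_exclusive_markers, x$counts$n_de_tables))
  invisible(x)
}

write_run_outputs <- function(summary, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  writeLines(resolved_config_lines(summary$config), p("config.txt"))
  sel <- data.frame(ref_id = summary$selection$initial, stringsAsFactors = FALSE)
  sel$selected <- sel$ref_id %in% summary$selection$selected
  sel$reason <- summary$selection$exclusions$reason[
    match(sel$ref_id, summary$selection$exclusions$ref_id)]
  write_table(sel, p("selection.tsv"))
  write_table(as.data.frame(summary$conserved), p("conserved.tsv"))
  write_table(as.data.frame(summary$markers), p("markers.tsv"))
  write_table(as.data.frame(summary$cv_tests), p("cv_tests.tsv"))
  write_table(cv_percentile_summary(summary$cv_table), p("cv_summary.tsv"))
  write_table(summary$profiles, p("profiles.tsv"))
  if (length(summary$overlaps) > 0L) {
    ov <- do.call(rbind, lapply(names(summary$overlaps), function(tis) {
      cbind(tissue = tis, summary$overlaps[[tis]]$intersections)
    }))
    write_table(ov, p("overlap.tsv"))
  }
  sep <- summary$separation
  write_table(data.frame(metric = c("silhouette_by_tissue",
                                    "silhouette_by_species_tissue",
                                    "silhouette_by_age_within_cluster"),
                         value = c(sep$silhouette_by_tissue,
                                   sep$silhouette_by_species_tissue,
                                   sep$silhouette_by_age_within_cluster),
                         computed_on = sep$computed_on), p("separation.tsv"))
  if (!is.null(summary$truth)) write_table(summary$truth, p("truth.tsv"))
  cnt <- summary$counts
  write_table(data.frame(key = names(cnt), value = unlist(cnt, use.names = FALSE)),
              p("summary.tsv"))
  invisible(out_dir)
}

#' Recovery of planted truth by a pipeline run
#'
#' Compares the run's conserved-signature and exclusive-marker calls with
#' the simulator's planted truth. A planted conserved gene is recovered
#' when a conserved call with the planted direction exists; a planted
#' marker when an exclusive call in the planted tissue exists (any species
#' group). False calls are calls whose gene is not planted with that role.
#'
#' @param summary A `run_summary` from a simulated run.
#' @param truth The simulator truth table (default: the one recorded in
#'   `summary`).
#' @return data.frame: `class` (`conserved`, `tissue_marker`),
#'   `n_planted`, `n_recovered`, `sensitivity` (NA when nothing was
#'   planted), `false_calls`.
#' @export
recovery_report <- function(summary, truth = summary$truth) {
  stopifnot(inherits(summary, "run_summary"))
  if (is.null(truth)) stop("no planted truth available for this run")
  if (!all(truth$ref_id %in% summary$selection$initial)) {
    stop("truth and run gene universes do not match")
  }
  cons_truth <- truth[truth$role %in% c("conserved_up", "conserved_down"), ]
  cons_calls <- summary$conserved[summary$conserved$conserved, , drop = FALSE]
  call_key <- paste(cons_calls$ref_id, cons_calls$direction)
  truth_key <- paste(cons_truth$ref_id, cons_truth$direction)
  cons_rec <- sum(truth_key %in% call_key)
  cons_false <- sum(!call_key %in% truth_key)

  mk_truth <- truth[truth$role == "tissue_marker", ]
  mk_calls <- summary$markers[summary$markers$exclusive, , drop = FALSE]
  mk_call_key <- unique(paste(mk_calls$ref_id, mk_calls$tissue))
  mk_truth_key <- paste(mk_truth$ref_id, mk_truth$tissue)
  mk_rec <- sum(mk_truth_key %in% mk_call_key)
  mk_false <- sum(!mk_call_key %in% mk_truth_key)

  data.frame(
    class = c("conserved", "tissue_marker"),
    n_planted = c(nrow(cons_truth), nrow(mk_truth)),
    n_recovered = c(cons_rec, mk_rec),
    sensitivity = c(if (nrow(cons_truth) > 0L) cons_rec / nrow(cons_truth) else NA_real_,
                    if (nrow(mk_truth) > 0L) mk_rec / nrow(mk_truth) else NA_real_),
    false_calls = c(cons_false, mk_false),
    stringsAsFactors = FALSE)
}
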
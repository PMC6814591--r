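## Synthetic multi-species study generator: negative-binomial counts with
## planted conserved signatures, tissue-exclusive markers and an
## age-dependent change of expression variability, plus matching ortholog
## and annotation tables and a ground-truth record.

#' Default study design of the simulator
#'
#' Four evolutionarily distinct species (two mammals, two fish) by three
#' tissues, five replicates in each of the three age groups.
#'
#' @return A [study_design()].
#' @export
default_design <- function() {
  study_design(species = c("hsa", "mmu", "dre", "nfu"),
               tissues = c("brain", "liver", "skin"), n_reps = 5L)
}

#' Simulation configuration
#'
#' Defines the generative model: per-gene baseline means drawn log10-uniform
#' over `baseline_mean_log_range` (expected counts at library scale 1);
#' species- and tissue-specific multiplicative baseline offsets (log2-normal
#' with the given standard deviations) so that tissue structure dominates
#' age structure, as in real bulk transcriptomes; a per-sample library scale
#' drawn log10-uniform over `library_scale_log_range`; gamma-Poisson counts
#' with variance \eqn{\mu + \alpha\mu^2}; planted conserved genes whose mean
#' is multiplied by `conserved_fold` per age step (M to A, A to OA) in every
#' species and tissue (reciprocal for down-regulated genes); planted markers
#' regulated the same way but only in `marker_tissue`; and an old-age
#' dispersion multiplier `oa_cv_scale` (< 1 plants the tighter expression
#' control observed in long-lived individuals, > 1 the opposite pattern
#' seen in fish skin).
#'
#' @param n_genes Number of genes (the simulated curated panel).
#' @param design A [study_design()].
#' @param baseline_mean_log_range log10 range of baseline expected counts.
#' @param nb_dispersion Negative-binomial dispersion \eqn{\alpha > 0}.
#' @param n_conserved_up,n_conserved_down Planted conserved gene counts.
#' @param conserved_fold Fold change per age step for conserved genes (> 1).
#' @param n_tissue_markers Planted exclusive markers for `marker_tissue`.
#' @param marker_tissue Tissue carrying the planted markers.
#' @param marker_fold Fold change per age step for markers (> 1).
#' @param oa_cv_scale Dispersion multiplier applied to the OA age group.
#' @param species_effect_sd,tissue_effect_sd log2 SD of per-(gene, species)
#'   and per-(gene, species, tissue) baseline offsets.
#' @param library_scale_log_range log10 range of per-sample library scale.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       design = default_design(),
                       baseline_mean_log_range = c(1, 3),
                       nb_dispersion = 0.1,
                       n_conserved_up = 30L,
                       n_conserved_down = 30L,
                       conserved_fold = 2,
                       n_tissue_markers = 10L,
                       marker_tissue = "liver",
                       marker_fold = 2,
                       oa_cv_scale = 0.5,
                       species_effect_sd = 1.5,
                       tissue_effect_sd = 1.5,
                       library_scale_log_range = c(-0.15, 0.15),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), design = design,
              baseline_mean_log_range = as.numeric(baseline_mean_log_range),
              nb_dispersion = nb_dispersion,
              n_conserved_up = as.integer(n_conserved_up),
              n_conserved_down = as.integer(n_conserved_down),
              conserved_fold = conserved_fold,
              n_tissue_markers = as.integer(n_tissue_markers),
              marker_tissue = marker_tissue, marker_fold = marker_fold,
              oa_cv_scale = oa_cv_scale,
              species_effect_sd = species_effect_sd,
              tissue_effect_sd = tissue_effect_sd,
              library_scale_log_range = as.numeric(library_scale_log_range),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg$design, "study_design"))
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0 (Poisson limit excluded)")
  n_planted <- cfg$n_conserved_up + cfg$n_conserved_down + cfg$n_tissue_markers
  if (any(c(cfg$n_conserved_up, cfg$n_conserved_down, cfg$n_tissue_markers) < 0L)) {
    stop("planted gene counts must be non-negative")
  }
  if (n_planted >= cfg$n_genes) stop("planted gene counts must sum to < n_genes")
  if (cfg$conserved_fold <= 1 || cfg$marker_fold <= 1) stop("fold changes must be > 1")
  if (cfg$oa_cv_scale <= 0) stop("oa_cv_scale must be positive")
  if (cfg$n_tissue_markers > 0L &&
      !cfg$marker_tissue %in% design_cells(cfg$design)$tissue) {
    stop("marker_tissue '", cfg$marker_tissue, "' is not in the design")
  }
  invisible(cfg)
}

age_step <- function(age) match(age, AGE_GROUPS) - 1L

#' Simulate a full multi-species aging study
#'
#' Draws negative-binomial counts for every (species, tissue, age group,
#' replicate) cell of the design, along with shared gene lengths (uniform
#' in 500-5000 nt, identical across orthologues), a complete one-to-one
#' ortholog map, a process-annotation table in which planted gene classes
#' carry recoverable labels (conserved up: immune/inflammatory response;
#' conserved down: oxidative stress response; markers: senescence; null
#' genes: a random label), and the planted-truth record.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts` (named list of per-species
#'   [count_matrix()]), `lengths` ([gene_lengths()] over all species gene
#'   ids), `orthologs` ([ortholog_map()]), `annotations`
#'   ([annotation_table()]), `truth` (data.frame: `ref_id`, `role`,
#'   `direction`, `tissue`, `fold`) and `config`.
#' @export
simulate_study <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  species <- unique(cfg$design$species)
  ref_ids <- sprintf("g%05d", seq_len(n))

  lengths_ref <- round(stats::runif(n, 500, 5000))
  baseline <- 10^stats::runif(n, cfg$baseline_mean_log_range[1L],
                              cfg$baseline_mean_log_range[2L])

  n_up <- cfg$n_conserved_up; n_dn <- cfg$n_conserved_down; n_mk <- cfg$n_tissue_markers
  planted <- sample.int(n, n_up + n_dn + n_mk)
  role <- rep("null", n)
  direction <- rep(NA_character_, n)
  idx_up <- planted[seq_len(n_up)]
  idx_dn <- planted[n_up + seq_len(n_dn)]
  idx_mk <- planted[n_up + n_dn + seq_len(n_mk)]
  role[idx_up] <- "conserved_up"; direction[idx_up] <- "up"
  role[idx_dn] <- "conserved_down"; direction[idx_dn] <- "down"
  role[idx_mk] <- "tissue_marker"; direction[idx_mk] <- "up"

  # log2 fold-change per age step, per gene (0 for null; tissue-restricted
  # for markers, handled below)
  step_l2fc <- rep(0, n)
  step_l2fc[idx_up] <- log2(cfg$conserved_fold)
  step_l2fc[idx_dn] <- -log2(cfg$conserved_fold)
  marker_l2fc <- rep(0, n)
  marker_l2fc[idx_mk] <- log2(cfg$marker_fold)

  counts <- list()
  for (sp in species) {
    sp_offset <- 2^stats::rnorm(n, 0, cfg$species_effect_sd)
    tissues <- unique(cfg$design$tissue[cfg$design$species == sp])
    cols <- list(); meta <- list()
    for (tis in tissues) {
      tis_offset <- 2^stats::rnorm(n, 0, cfg$tissue_effect_sd)
      l2fc <- step_l2fc + if (tis == cfg$marker_tissue) marker_l2fc else 0
      for (age in AGE_GROUPS) {
        n_reps <- cfg$design$n_reps[cfg$design$species == sp &
                                      cfg$design$tissue == tis &
                                      cfg$design$age_group == age]
        alpha <- cfg$nb_dispersion * if (age == "OA") cfg$oa_cv_scale else 1
        mu_gene <- baseline * sp_offset * tis_offset * 2^(l2fc * age_step(age))
        for (r in seq_len(n_reps)) {
          lib <- 10^stats::runif(1L, cfg$library_scale_log_range[1L],
                                 cfg$library_scale_log_range[2L])
          sid <- sprintf("%s_%s_%s_r%d", sp, tis, age, r)
          cols[[sid]] <- stats::rnbinom(n, mu = mu_gene * lib, size = 1 / alpha)
          meta[[sid]] <- data.frame(sample_id = sid, species = sp, tissue = tis,
                                    age_group = age, replicate = r,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    mat <- do.call(cbind, cols)
    rownames(mat) <- paste0(sp, "_", ref_ids)
    counts[[sp]] <- count_matrix(mat, do.call(rbind, meta))
  }

  # shared lengths: identical across orthologues of a reference gene
  len_all <- unlist(lapply(species, function(sp) {
    stats::setNames(lengths_ref, paste0(sp, "_", ref_ids))
  }))
  lengths <- gene_lengths(len_all)

  ortho_df <- data.frame(ref_id = ref_ids, stringsAsFactors = FALSE)
  for (sp in species) ortho_df[[sp]] <- paste0(sp, "_", ref_ids)
  orthologs <- ortholog_map(ortho_df, species)

  vocab <- process_vocabulary()
  label <- rep(NA_character_, n)
  label[idx_up] <- "immune/inflammatory response"
  label[idx_dn] <- "oxidative stress response"
  label[idx_mk] <- "senescence"
  null_idx <- which(role == "null")
  label[null_idx] <- sample(vocab, length(null_idx), replace = TRUE)
  ann <- data.frame(ref_id = ref_ids, label = label, stringsAsFactors = FALSE)
  # a minority of null genes carries a second label (multi-label support)
  second <- null_idx[stats::runif(length(null_idx)) < 0.15]
  if (length(second) > 0L) {
    extra <- vapply(second, function(i) {
      sample(setdiff(vocab, label[i]), 1L)
    }, character(1L))
    ann <- rbind(ann, data.frame(ref_id = ref_ids[second], label = extra,
                                 stringsAsFactors = FALSE))
  }
  annotations <- annotation_table(ann, vocab)

  truth <- data.frame(
    ref_id = ref_ids, role = role, direction = direction,
    tissue = ifelse(role == "tissue_marker", cfg$marker_tissue, NA_character_),
    fold = ifelse(role == "tissue_marker", cfg$marker_fold,
                  ifelse(role == "null", NA_real_, cfg$conserved_fold)),
    stringsAsFactors = FALSE
  )

  list(counts = counts, lengths = lengths, orthologs = orthologs,
       annotations = annotations, truth = truth, config = cfg)
}

#' Simulate a two-group null count matrix
#'
#' Both groups (labelled as age groups M and A of a single synthetic
#' species/tissue) are drawn from the identical negative-binomial law;
#' intended as the calibration input for the differential-expression test.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Replicates per group (>= 2).
#' @param mean Common negative-binomial mean.
#' @param dispersion Dispersion \eqn{\alpha > 0} (variance
#'   \eqn{\mu + \alpha\mu^2}); 0 is rejected.
#' @param seed Integer seed.
#' @return A [count_matrix()] with `2 * n_per_group` samples.
#' @export
simulate_null_pair <- function(n_genes, n_per_group, mean, dispersion, seed = 1L) {
  if (n_genes < 1L || n_per_group < 2L || mean <= 0) {
    stop("n_genes, n_per_group (>= 2) and mean must be positive")
  }
  if (dispersion <= 0) stop("dispersion must be > 0 (Poisson limit excluded)")
  set.seed(seed)
  n_samp <- 2L * n_per_group
  mat <- matrix(stats::rnbinom(n_genes * n_samp, mu = mean, size = 1 / dispersion),
                nrow = n_genes)
  rownames(mat) <- sprintf("g%05d", seq_len(n_genes))
  grp <- rep(c("M", "A"), each = n_per_group)
  ids <- sprintf("null_%s_r%d", grp, rep(seq_len(n_per_group), times = 2L))
  colnames(mat) <- ids
  meta <- data.frame(sample_id = ids, species = "sim", tissue = "null",
                     age_group = grp,
                     replicate = rep(seq_len(n_per_group), times = 2L),
                     stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}
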
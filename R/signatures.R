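## Gene preselection, the conserved-signature filter, the tissue-exclusive
## marker filter, and common-DEG overlap counting.

de_table_index <- function(de_tables) {
  data.frame(
    species = vapply(de_tables, function(t) attr(t, "species"), character(1L)),
    tissue = vapply(de_tables, function(t) attr(t, "tissue"), character(1L)),
    comparison = vapply(de_tables, function(t) attr(t, "comparison"), character(1L)),
    idx = seq_along(de_tables),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

## lfc and fdr matrices (genes x comparisons) of one (species, tissue) cell,
## restricted to `gene_ids` (species namespace); NA where untested
cell_matrices <- function(de_tables, index, species, tissue, gene_ids) {
  cmp <- comparisons()$comparison
  lfc <- matrix(NA_real_, length(gene_ids), length(cmp),
                dimnames = list(gene_ids, cmp))
  fdr <- lfc
  rows <- index[index$species == species & index$tissue == tissue, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    tab <- de_tables[[rows$idx[i]]]
    m <- match(gene_ids, tab$gene_id)
    lfc[, rows$comparison[i]] <- tab$log2fc[m]
    fdr[, rows$comparison[i]] <- tab$fdr[m]
  }
  list(lfc = lfc, fdr = fdr)
}

## vectorized qualification over the rows of cell matrices;
## returns "up"/"down"/NA per gene; genes with any missing comparison get NA
qualify_matrix <- function(lfc, fdr, min_change, fdr_cut) {
  thr <- log2(1 + min_change)
  complete <- rowSums(is.na(lfc) | is.na(fdr)) == 0L
  k <- ncol(lfc)
  up <- rep(FALSE, nrow(lfc)); dn <- rep(FALSE, nrow(lfc))
  for (c_star in seq_len(k)) {
    others <- setdiff(seq_len(k), c_star)
    sig_up <- fdr[, c_star] < fdr_cut & lfc[, c_star] > 0
    sig_dn <- fdr[, c_star] < fdr_cut & lfc[, c_star] < 0
    oth_up <- rowSums(lfc[, others, drop = FALSE] >= thr) == length(others)
    oth_dn <- rowSums(lfc[, others, drop = FALSE] <= -thr) == length(others)
    up <- up | (sig_up & oth_up)
    dn <- dn | (sig_dn & oth_dn)
  }
  out <- rep(NA_character_, nrow(lfc))
  out[complete & up] <- "up"
  out[complete & dn] <- "down"
  out
}

#' Direction qualification of one gene in one (species, tissue) cell
#'
#' A gene qualifies as up-regulated with aging in a cell if it is
#' significantly up-regulated (FDR below `fdr_cut`, positive log2 fold
#' change) in at least one of the three age comparisons and every other
#' comparison shows the same direction by at least the minimum expression
#' change, i.e. log2FC >= log2(1 + min_change) (about 0.1375 for the 10%
#' default). Down-regulation is the mirror image. A gene can never qualify
#' in both directions in the same cell.
#'
#' @param de_rows data.frame with columns `comparison`, `log2fc`, `fdr`
#'   holding the gene's three comparison rows for one (species, tissue).
#' @param min_change Minimum same-direction expression change as a fraction
#'   (default 0.10).
#' @param fdr_cut FDR significance cutoff (default 0.05).
#' @return `"up"`, `"down"`, or `NA` (no qualification). A missing
#'   comparison row yields `NA` with a warning.
#' @export
qualifies_in_cell <- function(de_rows, min_change = 0.10, fdr_cut = 0.05) {
  if (min_change <= 0 || min_change >= 1) stop("min_change must lie in (0, 1)")
  cmp <- comparisons()$comparison
  m <- match(cmp, de_rows$comparison)
  if (any(is.na(m))) {
    warning("missing comparison row(s): ", paste(cmp[is.na(m)], collapse = ", "),
            "; cell skipped")
    return(NA_character_)
  }
  lfc <- matrix(de_rows$log2fc[m], nrow = 1L, dimnames = list(NULL, cmp))
  fdr <- matrix(de_rows$fdr[m], nrow = 1L, dimnames = list(NULL, cmp))
  qualify_matrix(lfc, fdr, min_change, fdr_cut)[1L]
}

#' Preselect genes by ortholog completeness and differential expression
#'
#' A gene survives the preselection if and only if its ortholog-map entry is
#' complete for all species and it is differentially expressed (FDR below
#' `fdr_cut`) in at least one (species, tissue, comparison) table. Missing
#' orthology is checked first and recorded as the exclusion reason.
#'
#' @param initial Character vector of reference gene ids (the curated
#'   panel).
#' @param orthologs An [ortholog_map()].
#' @param de_tables List of `de_result` tables covering all available
#'   (species, tissue, comparison) cells.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return A list of class `gene_selection`: `initial`, `selected`
#'   (character vector) and `exclusions` (data.frame `ref_id`, `reason`
#'   with reason `missing_ortholog` or `never_de`).
#' @export
preselect_genes <- function(initial, orthologs, de_tables, fdr_cut = 0.05) {
  stopifnot(inherits(orthologs, "ortholog_map"))
  initial <- unique(as.character(initial))
  m <- match(initial, orthologs$ref_id)
  complete <- !is.na(m) & orthologs$complete[m]

  # ever significant, per reference id
  index <- de_table_index(de_tables)
  ever_de <- rep(FALSE, length(initial))
  for (i in seq_along(de_tables)) {
    tab <- de_tables[[i]]
    sig <- tab$gene_id[!is.na(tab$fdr) & tab$fdr < fdr_cut]
    if (length(sig) == 0L) next
    refs <- to_reference_ids(orthologs, index$species[i], sig)
    ever_de <- ever_de | initial %in% refs[!is.na(refs)]
  }

  reason <- ifelse(!complete, "missing_ortholog",
                   ifelse(!ever_de, "never_de", NA_character_))
  selected <- initial[is.na(reason)]
  excl <- data.frame(ref_id = initial[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(initial = initial, selected = selected, exclusions = excl),
            class = "gene_selection")
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf("gene_selection: %d of %d genes selected (%d missing_ortholog, %d never_de)\n",
              length(x$selected), length(x$initial),
              sum(x$exclusions$reason == "missing_ortholog"),
              sum(x$exclusions$reason == "never_de")))
  invisible(x)
}

## per-(species,tissue) qualification of all selected genes;
## returns data.frame gene (ref), species, tissue, direction
qualify_all_cells <- function(de_tables, selection, orthologs, min_change, fdr_cut) {
  index <- de_table_index(de_tables)
  cells <- unique(index[, c("species", "tissue")])
  genes <- selection$selected
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; tis <- cells$tissue[i]
    sp_ids <- from_reference_ids(orthologs, sp, genes)
    ok <- !is.na(sp_ids)
    if (!any(ok)) next
    mats <- cell_matrices(de_tables, index, sp, tis, sp_ids[ok])
    q <- qualify_matrix(mats$lfc, mats$fdr, min_change, fdr_cut)
    hit <- !is.na(q)
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        ref_id = genes[ok][hit], species = sp, tissue = tis,
        direction = q[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref_id = character(0), species = character(0),
                      tissue = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Conserved aging-signature filter
#'
#' Evaluates [qualifies_in_cell()] for every selected gene in every
#' available (species, tissue) cell and collects the supporting cells per
#' direction. A direction is conserved when its supporting cells span at
#' least `min_species` distinct species and at least `min_tissues` distinct
#' tissues. Both directions are evaluated independently; a gene qualifying
#' up in some cells and down in others yields two calls, each judged on its
#' own cell set.
#'
#' @param de_tables List of `de_result` tables (FDR-adjusted).
#' @param selection A [preselect_genes()] result.
#' @param orthologs An [ortholog_map()].
#' @param min_change Minimum same-direction change (default 0.10).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @param min_species,min_tissues Span thresholds (default 3 and 3).
#' @return data.frame of class `signature_calls`: `ref_id`, `direction`,
#'   `cells` (semicolon-separated `species:tissue`), `species_count`,
#'   `tissue_count`, `conserved`.
#' @export
conserved_signatures <- function(de_tables, selection, orthologs,
                                 min_change = 0.10, fdr_cut = 0.05,
                                 min_species = 3L, min_tissues = 3L) {
  qual <- qualify_all_cells(de_tables, selection, orthologs, min_change, fdr_cut)
  empty <- data.frame(ref_id = character(0), direction = character(0),
                      cells = character(0), species_count = integer(0),
                      tissue_count = integer(0), conserved = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(qual) == 0L) return(structure(empty, class = c("signature_calls", "data.frame")))
  key <- paste(qual$ref_id, qual$direction, sep = "\r")
  grp <- split(qual, key)
  calls <- do.call(rbind, lapply(grp, function(g) {
    g <- g[order(g$species, g$tissue), , drop = FALSE]
    data.frame(
      ref_id = g$ref_id[1L], direction = g$direction[1L],
      cells = paste(paste0(g$species, ":", g$tissue), collapse = ";"),
      species_count = length(unique(g$species)),
      tissue_count = length(unique(g$tissue)),
      stringsAsFactors = FALSE)
  }))
  calls$conserved <- calls$species_count >= min_species &
    calls$tissue_count >= min_tissues
  calls <- calls[order(calls$ref_id, calls$direction), , drop = FALSE]
  rownames(calls) <- NULL
  structure(calls, class = c("signature_calls", "data.frame"))
}

#' Default species comparison groups for tissue-marker screening
#'
#' Tissue-exclusive markers are screened within species groups: all species
#' together and, when the mammalian ("hsa", "mmu") and fish ("dre", "nfu")
#' clades are both represented, each clade separately — skin in particular
#' behaves differently between fur-bearing mammals and scaled fish.
#'
#' @param species Character vector of species identifiers.
#' @return Named list of species vectors.
#' @export
default_tissue_groups <- function(species) {
  groups <- list(all = species)
  mam <- intersect(c("hsa", "mmu"), species)
  fish <- intersect(c("dre", "nfu"), species)
  if (length(mam) >= 2L) groups$mammals <- mam
  if (length(fish) >= 2L) groups$fishes <- fish
  groups
}

## direction-consistency pattern: all comparisons >= thr in one direction,
## irrespective of significance; used for the exclusivity judgement
pattern_matrix <- function(lfc, min_change) {
  thr <- log2(1 + min_change)
  complete <- rowSums(is.na(lfc)) == 0L
  up <- rowSums(lfc >= thr) == ncol(lfc)
  dn <- rowSums(lfc <= -thr) == ncol(lfc)
  out <- rep(NA_character_, nrow(lfc))
  out[complete & up] <- "up"
  out[complete & dn] <- "down"
  out
}

## per-(species,tissue) direction-consistency of all selected genes
pattern_all_cells <- function(de_tables, selection, orthologs, min_change) {
  index <- de_table_index(de_tables)
  cells <- unique(index[, c("species", "tissue")])
  genes <- selection$selected
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sp <- cells$species[i]; tis <- cells$tissue[i]
    sp_ids <- from_reference_ids(orthologs, sp, genes)
    ok <- !is.na(sp_ids)
    if (!any(ok)) next
    mats <- cell_matrices(de_tables, index, sp, tis, sp_ids[ok])
    q <- pattern_matrix(mats$lfc, min_change)
    hit <- !is.na(q)
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        ref_id = genes[ok][hit], species = sp, tissue = tis,
        direction = q[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(ref_id = character(0), species = character(0),
                      tissue = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Tissue-exclusive marker filter
#'
#' Applies the qualification rule at a stricter minimum change (default
#' 25%): a gene is a marker call for tissue t within species group G when
#' it qualifies with one common direction in t for every species of G. The
#' call is exclusive when no other tissue of any species of G shows the
#' consistent same-direction change (every comparison at or beyond the
#' threshold, either direction, irrespective of significance) — a change
#' that is present elsewhere, significant or not, disqualifies tissue
#' exclusivity. Groups in which a species lacks the tissue are skipped for
#' that tissue.
#'
#' @param de_tables List of `de_result` tables.
#' @param selection A [preselect_genes()] result.
#' @param orthologs An [ortholog_map()].
#' @param tissue_groups Named list assigning species to comparison groups;
#'   default [default_tissue_groups()] over the species present.
#' @param min_change Minimum change for marker qualification (default 0.25).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return data.frame of class `marker_calls`: `ref_id`, `tissue`, `group`,
#'   `direction`, `species` (semicolon-separated), `exclusive`.
#' @export
tissue_specific_markers <- function(de_tables, selection, orthologs,
                                    tissue_groups = NULL,
                                    min_change = 0.25, fdr_cut = 0.05) {
  index <- de_table_index(de_tables)
  if (is.null(tissue_groups)) {
    tissue_groups <- default_tissue_groups(unique(index$species))
  }
  qual <- qualify_all_cells(de_tables, selection, orthologs, min_change, fdr_cut)
  pat <- pattern_all_cells(de_tables, selection, orthologs, min_change)
  out <- list()
  for (gname in names(tissue_groups)) {
    gsp <- tissue_groups[[gname]]
    tissues <- unique(index$tissue[index$species %in% gsp])
    for (tis in tissues) {
      have <- unique(index$species[index$tissue == tis & index$species %in% gsp])
      if (!setequal(have, gsp)) {
        message(sprintf("marker screen: tissue '%s' skipped for group '%s' (missing in: %s)",
                        tis, gname, paste(setdiff(gsp, have), collapse = ", ")))
        next
      }
      qt <- qual[qual$tissue == tis & qual$species %in% gsp, , drop = FALSE]
      if (nrow(qt) == 0L) next
      for (gene in unique(qt$ref_id)) {
        rows <- qt[qt$ref_id == gene, , drop = FALSE]
        if (length(unique(rows$species)) < length(gsp)) next
        if (length(unique(rows$direction)) != 1L) next
        other <- pat[pat$ref_id == gene & pat$tissue != tis &
                       pat$species %in% gsp, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          ref_id = gene, tissue = tis, group = gname,
          direction = rows$direction[1L],
          species = paste(sort(unique(rows$species)), collapse = ";"),
          exclusive = nrow(other) == 0L, stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(ref_id = character(0), tissue = character(0),
                      group = character(0), direction = character(0),
                      species = character(0), exclusive = logical(0),
                      stringsAsFactors = FALSE)
  res <- if (length(out) == 0L) empty else do.call(rbind, out)
  res <- res[order(res$tissue, res$group, res$ref_id), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("marker_calls", "data.frame"))
}

#' Per-species DEG sets of one tissue and their overlaps
#'
#' For every species carrying the tissue, takes the union over the three
#' age comparisons of genes with FDR below `fdr_cut`, maps them to
#' reference ids, and reports the intersection cardinality of every
#' non-empty species subset.
#'
#' @param de_tables List of `de_result` tables.
#' @param tissue Tissue to analyse (at least 2 species must carry it).
#' @param orthologs An [ortholog_map()].
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return List with `sets` (named list of reference-id character vectors,
#'   one per species) and `intersections` (data.frame `species_set`,
#'   `n_species`, `size`).
#' @export
common_deg_overlap <- function(de_tables, tissue, orthologs, fdr_cut = 0.05) {
  index <- de_table_index(de_tables)
  sp_have <- unique(index$species[index$tissue == tissue])
  if (length(sp_have) < 2L) {
    stop("tissue '", tissue, "' is present in fewer than 2 species")
  }
  sets <- lapply(sp_have, function(sp) {
    rows <- index[index$species == sp & index$tissue == tissue, , drop = FALSE]
    ids <- unlist(lapply(rows$idx, function(i) {
      tab <- de_tables[[i]]
      tab$gene_id[!is.na(tab$fdr) & tab$fdr < fdr_cut]
    }))
    refs <- to_reference_ids(orthologs, sp, unique(ids))
    sort(unique(refs[!is.na(refs)]))
  })
  names(sets) <- sp_have
  combos <- list()
  for (k in seq_along(sp_have)) {
    cmb <- utils::combn(sp_have, k, simplify = FALSE)
    combos <- c(combos, cmb)
  }
  inter <- do.call(rbind, lapply(combos, function(s) {
    common <- Reduce(intersect, sets[s])
    data.frame(species_set = paste(s, collapse = "&"), n_species = length(s),
               size = length(common), stringsAsFactors = FALSE)
  }))
  list(sets = sets, intersections = inter)
}
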
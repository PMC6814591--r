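# Independent brute-force oracles, deliberately written as literal loop
# translations of the filtering rules; they share no code with the package.

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# rule: significant (fdr < cut, matching sign) in at least one comparison,
# and every OTHER comparison in the same direction by >= min_change
oracle_qualify <- function(lfc, fdr, min_change = 0.10, fdr_cut = 0.05) {
  thr <- log2(1 + min_change)
  k <- length(lfc)
  up <- FALSE; dn <- FALSE
  for (c_star in seq_len(k)) {
    if (fdr[c_star] < fdr_cut && lfc[c_star] > 0) {
      if (all(lfc[-c_star] >= thr)) up <- TRUE
    }
    if (fdr[c_star] < fdr_cut && lfc[c_star] < 0) {
      if (all(lfc[-c_star] <= -thr)) dn <- TRUE
    }
  }
  if (up && dn) stop("oracle: both directions qualified; rule violated")
  if (up) "up" else if (dn) "down" else NA_character_
}

# exhaustive evaluation of the conservation rule over a set of DE tables
oracle_conserved <- function(de_tables, genes, orthologs,
                             min_change = 0.10, fdr_cut = 0.05,
                             min_species = 3L, min_tissues = 3L) {
  meta <- data.frame(
    species = vapply(de_tables, function(t) attr(t, "species"), character(1)),
    tissue = vapply(de_tables, function(t) attr(t, "tissue"), character(1)),
    comparison = vapply(de_tables, function(t) attr(t, "comparison"), character(1)),
    stringsAsFactors = FALSE)
  cells <- unique(meta[, c("species", "tissue")])
  out <- list()
  for (g in genes) {
    support <- list(up = character(0), down = character(0))
    for (i in seq_len(nrow(cells))) {
      sp <- cells$species[i]; tis <- cells$tissue[i]
      gid <- from_reference_ids(orthologs, sp, g)
      if (is.na(gid)) next
      lfc <- numeric(0); fdr <- numeric(0); found <- TRUE
      for (cmp in c("early", "late", "longevity")) {
        j <- which(meta$species == sp & meta$tissue == tis & meta$comparison == cmp)
        if (length(j) != 1) { found <- FALSE; break }
        tab <- de_tables[[j]]
        r <- which(tab$gene_id == gid)
        if (length(r) != 1) { found <- FALSE; break }
        lfc <- c(lfc, tab$log2fc[r]); fdr <- c(fdr, tab$fdr[r])
      }
      if (!found) next
      d <- oracle_qualify(lfc, fdr, min_change, fdr_cut)
      if (!is.na(d)) support[[d]] <- c(support[[d]], paste(sp, tis))
    }
    for (d in c("up", "down")) {
      if (length(support[[d]]) == 0) next
      sps <- unique(sub(" .*", "", support[[d]]))
      tis <- unique(sub(".* ", "", support[[d]]))
      out[[length(out) + 1]] <- data.frame(
        ref_id = g, direction = d,
        species_count = length(sps), tissue_count = length(tis),
        conserved = length(sps) >= min_species && length(tis) >= min_tissues,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(ref_id = character(0), direction = character(0),
                      species_count = integer(0), tissue_count = integer(0),
                      conserved = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$ref_id, res$direction), , drop = FALSE]
}
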
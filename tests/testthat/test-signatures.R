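de_rows <- function(lfc, fdr = c(0.5, 0.5, 0.5)) {
  data.frame(comparison = c("early", "late", "longevity"),
             log2fc = lfc, fdr = fdr, stringsAsFactors = FALSE)
}

test_that("cell qualification applies the 10% threshold at log2(1.1)", {
  expect_equal(qualifies_in_cell(de_rows(c(0.8, 0.5, 0.14), c(0.01, 0.5, 0.5))), "up")
  expect_true(is.na(qualifies_in_cell(de_rows(c(0.8, 0.5, 0.10), c(0.01, 0.5, 0.5)))))
  # boundary: log2(1.1) itself passes (>=)
  expect_equal(qualifies_in_cell(de_rows(c(0.8, log2(1.1), 0.5), c(0.01, 0.5, 0.5))), "up")
  expect_equal(qualifies_in_cell(de_rows(-c(0.8, 0.5, 0.14), c(0.01, 0.5, 0.5))), "down")
  # the significant comparison itself needs no magnitude threshold
  expect_equal(qualifies_in_cell(de_rows(c(0.01, 0.5, 0.5), c(0.01, 0.5, 0.5))), "up")
  # no significant comparison -> none
  expect_true(is.na(qualifies_in_cell(de_rows(c(0.8, 0.5, 0.5), c(0.06, 0.5, 0.5)))))
  # missing comparison row -> NA with a warning
  expect_warning(r <- qualifies_in_cell(de_rows(c(1, 1, 1))[1:2, ]), "missing comparison")
  expect_true(is.na(r))
})

test_that("qualification agrees with brute force on the exhaustive grid", {
  lfc_grid <- c(-0.5, -0.2, -0.1, 0, 0.1, 0.2, 0.5)
  fdr_grid <- c(0.01, 0.2)
  lfcs <- expand.grid(lfc_grid, lfc_grid, lfc_grid)
  fdrs <- expand.grid(fdr_grid, fdr_grid, fdr_grid)
  for (i in seq_len(nrow(lfcs))) {
    for (j in seq_len(nrow(fdrs))) {
      l <- as.numeric(lfcs[i, ]); f <- as.numeric(fdrs[j, ])
      got <- qualifies_in_cell(de_rows(l, f))
      want <- oracle_qualify(l, f)
      expect_identical(got, want)
    }
  }
})

test_that("a cell never qualifies in both directions", {
  set.seed(31)
  for (i in 1:300) {
    l <- rnorm(3, 0, 0.5); f <- runif(3, 0, 0.3)
    expect_identical(qualifies_in_cell(de_rows(l, f)), oracle_qualify(l, f))
  }
})

test_that("preselection records exclusion reasons, orthology first", {
  genes <- c("g1", "g2", "g3")
  om <- ortholog_map(data.frame(ref_id = genes,
                                s1 = c("s1_g1", "s1_g2", ""),
                                s2 = c("s2_g1", "s2_g2", "s2_g3"),
                                s3 = c("s3_g1", "s3_g2", "s3_g3"),
                                stringsAsFactors = FALSE), c("s1", "s2", "s3"))
  tabs <- list(make_de_table("s1", "t1", "early", c("s1_g1", "s1_g2", "s1_g3"),
                             lfc = c(1, 1, 1), fdr = c(0.04, 0.06, 0.01)))
  sel <- preselect_genes(genes, om, tabs)
  expect_equal(sel$selected, "g1")
  expect_equal(sel$exclusions$reason[sel$exclusions$ref_id == "g2"], "never_de")
  # g3 is significant but lacks an s1 orthologue: orthology wins
  expect_equal(sel$exclusions$reason[sel$exclusions$ref_id == "g3"], "missing_ortholog")
  # a gene absent from the map entirely counts as missing_ortholog
  sel2 <- preselect_genes(c("g1", "g9"), om, tabs)
  expect_equal(sel2$exclusions$reason[sel2$exclusions$ref_id == "g9"], "missing_ortholog")
})

make_cell_tables <- function(patterns, species, tissues, genes) {
  # patterns: list of (gene, species, tissue, direction) rows that should
  # qualify strongly; everything else stays null
  tabs <- list()
  for (sp in species) for (tis in tissues) {
    lfc <- matrix(0, length(genes), 3, dimnames = list(genes, NULL))
    fdr <- matrix(0.9, length(genes), 3, dimnames = list(genes, NULL))
    for (p in patterns) {
      if (p$species == sp && p$tissue == tis) {
        s <- if (p$direction == "up") 1 else -1
        lfc[p$gene, ] <- s * c(0.8, 0.5, 0.4)
        fdr[p$gene, 1] <- 0.001
      }
    }
    for (k in 1:3) {
      cmp <- c("early", "late", "longevity")[k]
      tabs[[paste(sp, tis, cmp, sep = "|")]] <- make_de_table(
        sp, tis, cmp, paste0(sp, "_", genes), lfc[, k], fdr[, k])
    }
  }
  tabs
}

test_that("conservation asks for spans of 3 species and 3 tissues", {
  species <- c("s1", "s2", "s3", "s4"); tissues <- c("blood", "liver", "skin")
  genes <- c("gA", "gB")
  patterns <- c(
    lapply(list(c("s1", "blood"), c("s2", "liver"), c("s3", "skin"), c("s1", "liver")),
           function(x) list(gene = "gA", species = x[1], tissue = x[2], direction = "up")),
    lapply(c("s1", "s2", "s3"),
           function(s) list(gene = "gB", species = s, tissue = "blood", direction = "up")))
  tabs <- make_cell_tables(patterns, species, tissues, genes)
  om <- make_orthologs(genes, species)
  calls <- conserved_signatures(tabs, make_selection(genes), om)
  a <- calls[calls$ref_id == "gA", ]
  expect_equal(a$species_count, 3L)
  expect_equal(a$tissue_count, 3L)
  expect_true(a$conserved)
  b <- calls[calls$ref_id == "gB", ]
  expect_equal(b$tissue_count, 1L)
  expect_false(b$conserved)
})

test_that("conserved calls match the brute-force rule on random instances", {
  for (seed in 1:100) {
    inst <- random_de_tables(n_genes = 12L, species = c("s1", "s2", "s3"),
                             tissues = c("t1", "t2", "t3"), seed = 400 + seed)
    got <- conserved_signatures(inst$tables, make_selection(inst$genes),
                                inst$orthologs)
    want <- oracle_conserved(inst$tables, inst$genes, inst$orthologs)
    got_df <- as.data.frame(got)[, c("ref_id", "direction", "species_count",
                                     "tissue_count", "conserved")]
    rownames(got_df) <- NULL; rownames(want) <- NULL
    expect_equal(got_df, want)
  }
})

test_that("raising the minimum change never adds a call", {
  for (seed in 1:25) {
    inst <- random_de_tables(n_genes = 15L, species = c("s1", "s2", "s3"),
                             tissues = c("t1", "t2", "t3"), seed = 700 + seed)
    sel <- make_selection(inst$genes)
    c10 <- conserved_signatures(inst$tables, sel, inst$orthologs, min_change = 0.10)
    c25 <- conserved_signatures(inst$tables, sel, inst$orthologs, min_change = 0.25)
    key10 <- paste(c10$ref_id, c10$direction)[c10$conserved]
    key25 <- paste(c25$ref_id, c25$direction)[c25$conserved]
    expect_true(all(key25 %in% key10))
    # and every 25% supporting cell set is contained in the 10% one
    m <- match(paste(c25$ref_id, c25$direction), paste(c10$ref_id, c10$direction))
    expect_false(anyNA(m))
    for (i in seq_len(nrow(c25))) {
      cells25 <- strsplit(c25$cells[i], ";")[[1]]
      cells10 <- strsplit(c10$cells[m[i]], ";")[[1]]
      expect_true(all(cells25 %in% cells10))
    }
  }
})

test_that("tissue markers require the whole group and exclusivity", {
  species <- c("s1", "s2", "s3"); tissues <- c("liver", "skin", "brain")
  genes <- c("gA", "gB")
  pat <- function(g, sp, tis) list(gene = g, species = sp, tissue = tis, direction = "up")
  patterns <- c(lapply(species, function(s) pat("gA", s, "liver")),
                lapply(species, function(s) pat("gB", s, "liver")),
                list(pat("gB", "s2", "skin")))
  tabs <- make_cell_tables(patterns, species, tissues, genes)
  om <- make_orthologs(genes, species)
  mk <- tissue_specific_markers(tabs, make_selection(genes), om,
                                tissue_groups = list(all = species))
  a <- mk[mk$ref_id == "gA", ]
  expect_equal(a$tissue, "liver")
  expect_true(a$exclusive)
  b <- mk[mk$ref_id == "gB" & mk$tissue == "liver", ]
  expect_false(b$exclusive)
})

test_that("a species lacking the tissue skips that group with a message", {
  species <- c("s1", "s2"); genes <- "gA"
  patterns <- lapply(species, function(s)
    list(gene = "gA", species = s, tissue = "liver", direction = "up"))
  tabs <- make_cell_tables(patterns, species, "liver", genes)
  # s3 is in the group but has no tables at all
  om <- make_orthologs(genes, c(species, "s3"))
  expect_message(
    mk <- tissue_specific_markers(tabs, make_selection(genes), om,
                                  tissue_groups = list(all = c(species, "s3"))),
    "skipped")
  expect_equal(nrow(mk), 0L)
})

test_that("common DEG overlaps equal direct set algebra", {
  genes <- sprintf("g%02d", 1:10)
  om <- make_orthologs(genes, c("s1", "s2"))
  sig1 <- c("g01", "g02", "g03"); sig2 <- c("g02", "g03", "g04")
  tabs <- list(
    make_de_table("s1", "liver", "early", paste0("s1_", genes),
                  lfc = rep(1, 10), fdr = ifelse(genes %in% sig1, 0.01, 0.9)),
    make_de_table("s2", "liver", "early", paste0("s2_", genes),
                  lfc = rep(1, 10), fdr = ifelse(genes %in% sig2, 0.01, 0.9)))
  ov <- common_deg_overlap(tabs, "liver", om)
  expect_setequal(ov$sets$s1, sig1)
  expect_equal(ov$intersections$size[ov$intersections$species_set == "s1&s2"], 2L)

  # union across comparisons, and a brute-force recount on random tables
  set.seed(55)
  inst <- random_de_tables(20L, c("s1", "s2", "s3"), "liver", seed = 56)
  ov2 <- common_deg_overlap(inst$tables, "liver", inst$orthologs, fdr_cut = 0.2)
  brute <- lapply(c("s1", "s2", "s3"), function(sp) {
    ids <- character(0)
    for (tab in inst$tables) {
      if (attr(tab, "species") == sp) ids <- c(ids, tab$gene_id[tab$fdr < 0.2])
    }
    sort(unique(sub("^s[0-9]_", "", ids)))
  })
  names(brute) <- c("s1", "s2", "s3")
  expect_equal(ov2$sets, brute)
  for (i in seq_len(nrow(ov2$intersections))) {
    sps <- strsplit(ov2$intersections$species_set[i], "&", fixed = TRUE)[[1]]
    expect_equal(ov2$intersections$size[i], length(Reduce(intersect, brute[sps])))
  }
  expect_error(common_deg_overlap(tabs, "skin", om), "fewer than 2")
})
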
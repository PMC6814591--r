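embed_fixture <- function(n_genes = 50L, seed = 81L) {
  set.seed(seed)
  species <- c("s1", "s2"); tissues <- c("t1", "t2")
  genes <- sprintf("g%03d", seq_len(n_genes))
  om <- make_orthologs(genes, species)
  tpm_set <- lapply(setNames(species, species), function(sp) {
    ages <- rep(c("M", "A", "OA"), each = 2)
    meta <- do.call(rbind, lapply(tissues, function(tis) {
      m <- make_meta(sp, tis, ages)
      m
    }))
    mat <- matrix(runif(n_genes * nrow(meta), 0, 50), n_genes, nrow(meta),
                  dimnames = list(paste0(sp, "_", genes), meta$sample_id))
    agesig:::new_tpm_matrix(mat, meta)
  })
  list(tpm_set = tpm_set, selection = make_selection(genes), om = om)
}

test_that("embedding input has pooled samples by selected genes on log2 scale", {
  fx <- embed_fixture()
  inp <- build_embedding_input(fx$tpm_set, fx$selection, fx$om)
  expect_equal(dim(inp$matrix), c(24L, 50L))  # 2 sp x 2 ti x 3 ages x 2 reps
  expect_equal(nrow(inp$labels), 24L)
  # value check: log2(TPM + 1), species' own orthologue
  sid <- inp$labels$sample_id[1]
  expect_equal(unname(inp$matrix[sid, "g001"]),
               log2(fx$tpm_set$s1$tpm["s1_g001", sid] + 1))
  # TPM 0 maps to 0
  fx$tpm_set$s1$tpm["s1_g001", sid] <- 0
  inp0 <- build_embedding_input(fx$tpm_set, fx$selection, fx$om)
  expect_equal(unname(inp0$matrix[sid, "g001"]), 0)
  expect_error(build_embedding_input(fx$tpm_set, make_selection(character(0)), fx$om),
               "empty")
})

test_that("a species lacking a selected gene is 0-filled with a warning", {
  fx <- embed_fixture()
  fx$tpm_set$s2$tpm <- fx$tpm_set$s2$tpm[-1, , drop = FALSE]  # drop s2_g001
  expect_warning(inp <- build_embedding_input(fx$tpm_set, fx$selection, fx$om),
                 "0-filled")
  s2_samples <- inp$labels$sample_id[inp$labels$species == "s2"]
  expect_true(all(inp$matrix[s2_samples, "g001"] == 0))
})

test_that("well-separated clouds score high; random labels score near zero", {
  set.seed(83)
  n <- 30L
  coords <- rbind(matrix(rnorm(n * 2, 0, 0.1), n, 2),
                  matrix(rnorm(n * 2, 10, 0.1), n, 2))
  lab <- data.frame(sample_id = sprintf("s%02d", 1:(2 * n)),
                    species = "s1",
                    tissue = rep(c("t1", "t2"), each = n),
                    age_group = "M", stringsAsFactors = FALSE)
  inp <- structure(list(matrix = coords, labels = lab), class = "embedding_input")
  rep1 <- separation_scores(inp)
  expect_gt(rep1$silhouette_by_tissue, 0.9)
  # single age class within each cluster: age score undefined, not an error
  expect_true(is.na(rep1$silhouette_by_age_within_cluster))

  sils <- vapply(1:20, function(i) {
    lab2 <- lab
    lab2$tissue <- sample(lab$tissue)
    separation_scores(structure(list(matrix = coords, labels = lab2),
                                class = "embedding_input"))$silhouette_by_tissue
  }, numeric(1))
  expect_lt(abs(mean(sils)), 0.05)
})

test_that("separation scores are invariant under rotation and sample order", {
  fx <- embed_fixture(n_genes = 10L, seed = 84L)
  inp <- build_embedding_input(fx$tpm_set, fx$selection, fx$om)
  coords <- embed_coordinates(inp, seed = 1L)
  expect_equal(attr(coords, "method"), "pca")
  r1 <- separation_scores(inp, coords)
  expect_equal(r1$computed_on, "embedding_2d")
  theta <- 0.7
  rot <- coords %*% matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2)
  rot <- sweep(rot, 2, c(3, -5), "+")
  r2 <- separation_scores(inp, rot)
  expect_equal(r2$silhouette_by_tissue, r1$silhouette_by_tissue, tolerance = 1e-9)

  perm <- sample(nrow(inp$matrix))
  inp_p <- structure(list(matrix = inp$matrix[perm, ], labels = inp$labels[perm, ]),
                     class = "embedding_input")
  r3 <- separation_scores(inp_p)
  r0 <- separation_scores(inp)
  expect_equal(r3$silhouette_by_tissue, r0$silhouette_by_tissue, tolerance = 1e-9)
  expect_equal(r3$silhouette_by_species_tissue, r0$silhouette_by_species_tissue,
               tolerance = 1e-9)
})

test_that("permuting sample order permutes embedding-input rows identically", {
  fx <- embed_fixture(n_genes = 8L, seed = 85L)
  inp <- build_embedding_input(fx$tpm_set, fx$selection, fx$om)
  # reorder one species' TPM columns; rows must follow the samples
  perm <- rev(seq_len(ncol(fx$tpm_set$s1$tpm)))
  fx$tpm_set$s1$tpm <- fx$tpm_set$s1$tpm[, perm]
  fx$tpm_set$s1$samples <- fx$tpm_set$s1$samples[perm, ]
  inp2 <- build_embedding_input(fx$tpm_set, fx$selection, fx$om)
  expect_equal(inp2$matrix[rownames(inp$matrix), ], inp$matrix)
})
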
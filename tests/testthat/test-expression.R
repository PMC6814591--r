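test_that("TPM matches the closed form and normalizes every column to 1e6", {
  cm <- make_cm(matrix(c(10L, 40L), 2, 1), ages = "M")
  tpm <- tpm_normalize(cm, gene_lengths(c(g001 = 1000L, g002 = 2000L)))
  expect_equal(unname(tpm$tpm[, 1]), c(1e6 * 0.01 / 0.03, 1e6 * 0.02 / 0.03))

  one <- make_cm(matrix(7L, 1, 1), ages = "M")
  expect_equal(unname(tpm_normalize(one, make_lengths("g001"))$tpm[1, 1]), 1e6)

  set.seed(1)
  cm <- make_cm(matrix(rpois(300, 40), 50, 6))
  lens <- gene_lengths(setNames(sample(500:5000, 50), rownames(cm$counts)))
  tpm <- tpm_normalize(cm, lens)
  expect_true(all(abs(colSums(tpm$tpm) - 1e6) <= 1e-9 * 1e6))

  # scale invariance: multiplying one sample's counts leaves its TPM unchanged
  cm2 <- cm; cm2$counts[, 3] <- cm$counts[, 3] * 7L
  tpm2 <- tpm_normalize(count_matrix(cm2$counts, cm2$samples), lens)
  expect_equal(tpm2$tpm[, 3], tpm$tpm[, 3])

  # all-zero sample stays all-zero; missing length errors with the gene name
  cmz <- make_cm(matrix(c(0L, 0L, 3L, 9L), 2, 2), ages = c("M", "A"))
  tpz <- tpm_normalize(cmz, make_lengths(rownames(cmz$counts)))
  expect_equal(unname(tpz$tpm[, 1]), c(0, 0))
  expect_error(tpm_normalize(cm, gene_lengths(c(gX = 100L))), "missing gene length")
})

test_that("expression filter keeps genes exceeding 1 TPM in any sample", {
  tpm <- agesig:::new_tpm_matrix(
    matrix(c(0.5, 0.9, 1.0,
             0.0, 1.01, 0.2), 2, 3, byrow = TRUE,
           dimnames = list(c("gA", "gB"), c("s1", "s2", "s3"))),
    make_meta(ages = c("M", "A", "OA")))
  expect_equal(expression_filter(tpm), "gB")
  empty <- agesig:::new_tpm_matrix(matrix(numeric(0), 0, 0), make_meta()[0, ])
  expect_equal(expression_filter(empty), character(0))
})

test_that("identical groups give log2fc 0 and p 1; swapping groups negates log2fc", {
  set.seed(5)
  block <- matrix(rnbinom(200 * 3, mu = 80, size = 10), 200, 3)
  cm <- make_cm(cbind(block, block)[, c(1, 4, 2, 5, 3, 6)],
                ages = c("M", "M", "M", "A", "A", "A"))
  # columns 1:3 == columns 4:6 by construction
  cm <- make_cm(cbind(block, block), ages = rep(c("M", "A"), each = 3))
  res <- nb_wald_test(cm, "M", "A")
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$p_value == 1))

  set.seed(6)
  cm2 <- make_cm(matrix(rnbinom(200 * 6, mu = 80, size = 10), 200, 6),
                 ages = rep(c("M", "A"), each = 3))
  fwd <- nb_wald_test(cm2, "M", "A")
  rev <- nb_wald_test(cm2, "A", "M")
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p_value, fwd$p_value)
})

test_that("a group below 2 replicates is an error naming the cell", {
  cm <- make_cm(matrix(1L, 4, 3), ages = c("M", "M", "A"))
  expect_error(nb_wald_test(cm, "M", "A"), "fewer than 2 replicates.*A")
})

test_that("BH adjustment matches the hand-computed and brute-force step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:200) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("size factors have geometric mean 1 and track library scale", {
  set.seed(11)
  base <- matrix(rnbinom(300 * 4, mu = 100, size = 10) + 1L, 300, 4)
  scaled <- base
  scaled[, 2] <- base[, 2] * 2L
  colnames(scaled) <- paste0("s", 1:4); rownames(scaled) <- paste0("g", 1:300)
  sf <- size_factors(scaled)
  expect_lt(abs(exp(mean(log(sf))) - 1), 1e-6)
  expect_gt(sf[2] / mean(sf[-2]), 1.8)
})

test_that("run_de produces one FDR-adjusted table per tissue and comparison", {
  cfg <- sim_config(n_genes = 150L,
                    design = study_design(species = "s1",
                                          tissues = c("t1", "t2", "t3"),
                                          n_reps = 3L),
                    n_conserved_up = 3L, n_conserved_down = 0L,
                    n_tissue_markers = 0L, seed = 12L)
  out <- simulate_study(cfg)
  tabs <- run_de(out$counts$s1, out$lengths)
  expect_length(tabs, 9L)
  expect_setequal(
    unique(vapply(tabs, function(t) attr(t, "comparison"), character(1))),
    c("early", "late", "longevity"))
  for (t in tabs) {
    expect_true(all(t$fdr >= t$p_value - 1e-12))
    expect_true(all(t$fdr <= 1))
  }
})

test_that("the DE test is roughly calibrated under the null", {
  rates <- vapply(1:5, function(s) {
    cm <- simulate_null_pair(1000L, 5L, mean = 100, dispersion = 0.1, seed = 100L + s)
    res <- nb_wald_test(cm, "M", "A")
    mean(res$p_value < 0.05)
  }, numeric(1))
  expect_gt(mean(rates), 0.02)
  expect_lt(mean(rates), 0.09)
})
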
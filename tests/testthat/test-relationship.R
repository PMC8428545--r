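test_that("GRM matches analytic two-individual case and brute-force oracle", {
  # one variant, dosages (0, 2): p = 0.5, standardized scores -/+ sqrt(2)
  g <- genotype_matrix(matrix(c(0, 2), 2, 1))
  G <- compute_grm(g)
  expect_equal(bare(G), matrix(c(2, -2, -2, 2), 2, 2), tolerance = 1e-12)
  # identical dosage rows give identical diagonal/off-diagonal entries
  d <- rbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 1, 0, 0))
  G2 <- compute_grm(genotype_matrix(d))
  expect_equal(G2[1, 2], G2[1, 1], tolerance = 1e-12)
  expect_equal(G2[1, 2], G2[2, 2], tolerance = 1e-12)
  # brute-force double-loop equality on a 10 x 50 fixture with missing calls
  g3 <- make_genotypes(10, 50, seed = 3)
  d3 <- g3$dosages
  set.seed(4)
  d3[sample(length(d3), 20)] <- NA
  g3 <- genotype_matrix(d3, g3$sample_ids, g3$variant_ids)
  expect_lt(max(abs(bare(compute_grm(g3)) - oracle_grm(d3))), 1e-10)
})

test_that("GRM errors on monomorphic variants and has ~unit mean diagonal", {
  g <- genotype_matrix(cbind(c(0, 2, 1), c(0, 0, 0)))
  expect_error(compute_grm(g), "monomorphic")
  gg <- make_genotypes(500, 600, seed = 11)
  G <- compute_grm(gg)
  expect_lt(max(abs(unclass(G) - t(unclass(G)))), 1e-10)
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("kinship thresholding zeroes entries below the cutoff and is idempotent", {
  v <- matrix(c(0.50, 0.024, -0.01,
                0.024, 0.90, 0.026,
                -0.01, 0.026, 1.10), 3, 3)
  G <- relationship_matrix(v, kind = "G")
  K <- threshold_kinship(G)
  expect_equal(unname(K[1, 2]), 0)
  expect_equal(unname(K[1, 3]), 0)   # negative entries also zeroed
  expect_equal(unname(K[2, 3]), 0.026)
  expect_equal(unname(diag(K)), c(0.50, 0.90, 1.10))
  # idempotence (on a fresh G-kind wrapper of K's values)
  K2 <- threshold_kinship(relationship_matrix(unclass(K), kind = "G"))
  expect_equal(bare(K2), bare(K), tolerance = 1e-15)
  # identity in, identity out
  I3 <- relationship_matrix(diag(3), kind = "G")
  expect_equal(bare(threshold_kinship(I3)), diag(3))
})

test_that("categorical similarity builds the block indicator and is PSD", {
  S <- categorical_similarity(c("never", "never", "current"))
  expect_equal(bare(S), matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  expect_equal(bare(categorical_similarity(rep("a", 4))), matrix(1, 4, 4))
  expect_equal(bare(categorical_similarity(letters[1:4])), diag(4))
  expect_error(categorical_similarity(c("a", NA)), "missing")
  set.seed(1)
  for (i in 1:5) {
    S <- categorical_similarity(sample(letters[1:4], 30, replace = TRUE))
    expect_gte(min(eigen(unclass(S), symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
  }
})

test_that("hadamard products annihilate, mask, commute and associate", {
  set.seed(2)
  g <- make_genotypes(12, 60, seed = 2)
  G <- compute_grm(g)
  smk <- categorical_similarity(
    setNames(sample(c("n", "e", "c"), 12, replace = TRUE), g$sample_ids))
  sex <- categorical_similarity(
    setNames(sample(c("F", "M"), 12, replace = TRUE), g$sample_ids),
    kind = "SEX")
  GS <- hadamard(G, smk)
  expect_equal(bare(GS), bare(G) * bare(smk), tolerance = 1e-15)
  expect_true(all(GS[unclass(smk) == 0] == 0))
  # identity mask keeps only the diagonal
  I12 <- relationship_matrix(diag(12), sample_ids = g$sample_ids, kind = "ENV")
  AI <- hadamard(G, I12)
  expect_equal(bare(AI), diag(diag(bare(G))))
  # commutativity and associativity (three-way product)
  expect_lt(max(abs(unclass(hadamard(smk, G)) - unclass(GS))), 1e-12)
  expect_lt(max(abs(unclass(hadamard(GS, sex)) -
                      unclass(hadamard(G, hadamard(smk, sex))))), 1e-12)
  expect_lt(max(abs(unclass(hadamard(G, smk, sex)) -
                      unclass(hadamard(GS, sex)))), 1e-12)
  # dimension / id mismatch
  expect_error(hadamard(G, categorical_similarity(letters[1:5])), "dimension")
})

test_that("ORM iteration reaches a doubly standardized matrix", {
  set.seed(9)
  W0 <- matrix(rnorm(20 * 10), 20, 10)
  M <- compute_orm(W0)
  W <- attr(M, "W")
  expect_lt(max(abs(colMeans(W))), 1e-8)
  expect_lt(max(abs(colMeans(W^2) - 1)), 1e-6)
  expect_lt(max(abs(rowMeans(W))), 1e-8)
  expect_lt(max(abs(rowMeans(W^2) - 1)), 1e-6)
  expect_equal(bare(M), unname(tcrossprod(W) / ncol(W)), tolerance = 1e-12)
  expect_lt(abs(mean(diag(M)) - 1), 0.05)
  # already-standardized input is a fixed point: one sweep, no change
  M2 <- compute_orm(W)
  expect_identical(attr(M2, "iterations"), 1L)
  expect_lt(max(abs(attr(M2, "W") - W)), 1e-7)
})

test_that("ORM drops zero-variance probes and mean-imputes missing cells", {
  set.seed(10)
  W <- matrix(rnorm(60), 15, 4)
  W[, 2] <- 5
  expect_warning(M <- compute_orm(W), "zero-variance")
  expect_match(attr(M, "provenance"), "3 probes")
  W2 <- matrix(rnorm(150), 15, 10)
  W2[3, 5] <- NA
  expect_silent(compute_orm(W2))
})

test_that("CpG selection applies both-study p and strict h2 rules", {
  tbl <- data.frame(
    cpg_id = paste0("cg", 1:4),
    p_study1 = c(1e-8, 1e-8, 1e-8, 0.5),
    p_study2 = c(1e-9, 1e-6, 1e-8, 1e-9),
    h2 = c(0.30, 0.30, 0.40, 0.10))
  out <- suppressMessages(select_smoking_cpgs(tbl))
  expect_equal(out$selected, c(TRUE, FALSE, FALSE, FALSE))
  # permutation invariance of the selected set
  set.seed(3)
  big <- data.frame(cpg_id = paste0("cg", 1:300),
                    p_study1 = 10^-runif(300, 0, 12),
                    p_study2 = 10^-runif(300, 0, 12),
                    h2 = runif(300))
  sel1 <- suppressMessages(select_smoking_cpgs(big))
  perm <- sample(300)
  sel2 <- suppressMessages(select_smoking_cpgs(big[perm, ]))
  expect_setequal(sel1$cpg_id[sel1$selected], sel2$cpg_id[sel2$selected])
  # count equals the brute-force filter
  expect_equal(sum(sel1$selected),
               sum(big$p_study1 < 1e-7 & big$p_study2 < 1e-7 & big$h2 < 0.4))
})

test_that("relationship matrix constructor enforces symmetry", {
  m <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(relationship_matrix(m, kind = "G"), "not symmetric")
})
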
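test_that("simulation_spec validates its inputs", {
  expect_error(simulation_spec(variance_fractions = c(G = 0.7, K = 0.4)),
               "sum to more than 1")
  expect_error(simulation_spec(variance_fractions = c(G = -0.1)),
               "non-negative")
  expect_error(simulation_spec(cpg_h2 = 0.45), "below 0.40")
  expect_error(simulation_spec(n_individuals = 100, n_families = 60,
                               family_size = 2))
  spec <- simulation_spec()
  expect_equal(spec$residual, 0.40)
})

test_that("genotype simulation is reproducible and respects family structure", {
  spec <- simulation_spec(n_individuals = 220, n_families = 20,
                          family_size = 2, m_snps = 5000)
  g1 <- simulate_genotypes(spec, seed = 3)
  g2 <- simulate_genotypes(spec, seed = 3)
  expect_identical(g1$genotypes$dosages, g2$genotypes$dosages)
  expect_identical(g1$pedigree, g2$pedigree)
  G <- unclass(compute_grm(g1$genotypes))
  ped <- g1$pedigree$family_id
  sib <- outer(ped, ped, "==") & upper.tri(G) &
    outer(grepl("^fam", ped), grepl("^fam", ped), "&")
  unrel <- !outer(ped, ped, "==") & upper.tri(G)
  # full sibs share half their genome on average; unrelateds carry only the
  # small negative offset (~ -1/(n-1)) induced by in-sample centring
  expect_gt(mean(G[sib]), 0.45)
  expect_lt(mean(G[sib]), 0.55)
  expect_lt(abs(mean(G[unrel])), 0.01)
})

test_that("an all-unrelated cohort has near-zero off-diagonal relatedness", {
  spec <- simulation_spec(n_individuals = 250, n_families = 0,
                          family_size = 2, m_snps = 5000)
  g <- simulate_genotypes(spec, seed = 4)
  expect_true(all(grepl("^solo", g$pedigree$family_id)))
  G <- unclass(compute_grm(g$genotypes))
  expect_lt(abs(mean(G[upper.tri(G)])), 0.01)
})

test_that("smoking category counts follow the configured probabilities", {
  spec <- simulation_spec(n_individuals = 2000, n_families = 0,
                          m_snps = 10, cpg_h2 = 0,
                          smoking_probs = c(never = 0.5, ex = 0.25,
                                            current = 0.25))
  g <- simulate_genotypes(spec, seed = 5)
  set.seed(5)
  sm <- simulate_smoking_and_methylation(spec, g$genotypes)
  cnt <- table(sm$smoking)
  # multinomial 99% bands
  for (cat in names(spec$smoking_probs)) {
    p <- spec$smoking_probs[[cat]]
    expect_lt(abs(cnt[[cat]] - 2000 * p), 2.58 * sqrt(2000 * p * (1 - p)) + 1)
  }
})

test_that("per-CpG smoking R2 matches its target (and its null)", {
  spec0 <- simulation_spec(n_individuals = 2000, n_families = 0,
                           m_snps = 10, n_cpgs = 30, cpg_smoking_r2 = 0,
                           cpg_h2 = 0)
  g <- simulate_genotypes(spec0, seed = 6)
  set.seed(6)
  sm0 <- simulate_smoking_and_methylation(spec0, g$genotypes)
  r2_null <- mean(vapply(seq_len(30), function(j)
    summary(lm(sm0$methylation[, j] ~ sm0$smoking))$r.squared, numeric(1)))
  expect_lt(r2_null, 0.01)
  spec3 <- simulation_spec(n_individuals = 5000, n_families = 0,
                           m_snps = 10, n_cpgs = 30, cpg_smoking_r2 = 0.3,
                           cpg_h2 = 0, smoking_between_r2 = 1)
  g3 <- simulate_genotypes(spec3, seed = 7)
  set.seed(7)
  sm3 <- simulate_smoking_and_methylation(spec3, g3$genotypes)
  r2 <- mean(vapply(seq_len(30), function(j)
    summary(lm(sm3$methylation[, j] ~ sm3$exposure))$r.squared, numeric(1)))
  expect_lt(abs(r2 - 0.3), 0.03)
})

test_that("null phenotypes are pure noise and seeds reproduce exactly", {
  spec <- simulation_spec(n_individuals = 400, n_families = 50,
                          m_snps = 300,
                          variance_fractions = c(G = 0, K = 0, GxSmk = 0))
  co1 <- simulate_cohort(spec, seed = 8)
  co2 <- simulate_cohort(spec, seed = 8)
  expect_identical(co1$phenotypes$trait, co2$phenotypes$trait)
  expect_identical(co1$genotypes$dosages, co2$genotypes$dosages)
  # all fractions zero: var(y) within a chi-square CI of the residual
  v <- var(co1$phenotypes$trait)
  expect_gt(v, 1 * qchisq(0.005, 399) / 399)
  expect_lt(v, 1 * qchisq(0.995, 399) / 399)
  co3 <- simulate_cohort(spec, seed = 9)
  expect_false(identical(co1$phenotypes$trait, co3$phenotypes$trait))
})

test_that("replicate covariance of covariance-exact draws reproduces G", {
  spec <- simulation_spec(n_individuals = 200, n_families = 20,
                          family_size = 10, m_snps = 400,
                          variance_fractions = c(G = 1.0))
  co <- simulate_cohort(spec, seed = 10, matrices = "G")
  G <- as.matrix(co$matrices$G)
  set.seed(11)
  eg <- eigen(G, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  Y <- L %*% matrix(rnorm(200 * 500), 200)   # 500 replicate draws
  Chat <- tcrossprod(Y) / 500
  lt <- lower.tri(G, diag = TRUE)
  expect_gt(cor(Chat[lt], G[lt]), 0.95)
})

test_that("realized variance fractions approach the spec with growing n", {
  spec_fun <- function(n) simulation_spec(
    n_individuals = n, n_families = round(n / 10), m_snps = 400,
    variance_fractions = c(G = 0.25, K = 0.25, GxSmk = 0.10))
  dev <- vapply(c(500, 2000), function(n) {
    co <- simulate_cohort(spec_fun(n), seed = 12,
                          matrices = c("G", "K", "GxSmk"))
    rf <- co$truth$realized_fractions
    max(abs(rf[c("G", "K", "GxSmk", "residual")] -
              c(0.25, 0.25, 0.10, 0.40)))
  }, numeric(1))
  expect_lt(dev[2], 0.12)
  expect_lt(dev[2], dev[1] + 0.02)   # shrinking with n up to noise
})

test_that("mechanistic phenotypes hit their target fractions by construction", {
  spec <- simulation_spec(n_individuals = 300, n_families = 50,
                          m_snps = 500, mode = "mechanistic",
                          variance_fractions = c(G = 0.3, K = 0.2,
                                                 Smk = 0.1, GxSmk = 0.1))
  co <- simulate_cohort(spec, seed = 13,
                        matrices = c("G", "K", "Smk", "GxSmk"))
  rf <- co$truth$realized_fractions
  expect_lt(max(abs(rf[c("G", "K", "Smk", "GxSmk")] -
                      c(0.3, 0.2, 0.1, 0.1))), 0.05)
})

test_that("recovery_experiment tabulates truth, estimates and LRT p-values", {
  spec <- simulation_spec(n_individuals = 150, n_families = 30,
                          m_snps = 300,
                          variance_fractions = c(G = 0.3, K = 0.2))
  r <- recovery_experiment(spec, n_replicates = 3, seed = 14)
  expect_s3_class(r, "recovery_result")
  s <- r$summary
  expect_true(all(c("truth", "mean_estimate", "empirical_sd",
                    "mean_reported_se", "bias") %in% names(s)))
  expect_equal(s$truth[s$model == "GKGxSmk" & s$component == "G"], 0.3)
  expect_equal(s$truth[s$model == "GKGxSmk" & s$component == "GxSmk"], 0)
  expect_length(r$lrt_p$GKGxSmk, 3)
  expect_true(all(r$lrt_p$GKGxSmk > 0 & r$lrt_p$GKGxSmk <= 1))
})
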
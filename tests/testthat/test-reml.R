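test_that("restricted log-likelihood equals the error-contrast oracle", {
  set.seed(11)
  n <- 6
  g <- make_genotypes(n, 30, seed = 11)
  G <- compute_grm(g)
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  m <- vc_model(y, list(G = G), X = X)
  for (s in list(c(0.5, 0.5), c(0.2, 1.3), c(1e-3, 0.9))) {
    expect_equal(restricted_loglik(m, s),
                 oracle_restricted_loglik(y, X, list(unclass(G)), s),
                 tolerance = 1e-8)
  }
})

test_that("restricted log-likelihood is scale-equivariant", {
  set.seed(12)
  n <- 40
  g <- make_genotypes(n, 100, seed = 12)
  G <- compute_grm(g)
  y <- rnorm(n)
  m1 <- vc_model(y, list(G = G))
  m2 <- vc_model(3 * y, list(G = G))
  s <- c(0.4, 0.6)
  expect_equal(restricted_loglik(m2, 9 * s),
               restricted_loglik(m1, s) - (n - 1) * log(3),
               tolerance = 1e-8)
})

test_that("identity component creates a likelihood ridge over the total variance", {
  set.seed(13)
  y <- rnorm(30)
  m <- vc_model(y, list(dup = relationship_matrix(diag(30), kind = "ENV")))
  expect_equal(restricted_loglik(m, c(0.3, 0.7)),
               restricted_loglik(m, c(0.9, 0.1)), tolerance = 1e-10)
})

test_that("non-positive-definite V is reported", {
  m <- vc_model(rnorm(10),
                list(E = relationship_matrix(matrix(1, 10, 10),
                                             kind = "ENV")))
  expect_error(restricted_loglik(m, c(1, -0.5)), "positive definite")
})

test_that("balanced one-way REML equals the closed-form ANOVA estimators", {
  set.seed(14)
  grp <- factor(rep(1:10, each = 10))
  y <- rep(rnorm(10, sd = sqrt(1.5)), each = 10) + rnorm(100)
  fit <- fit_reml(vc_model(y, list(grp = categorical_similarity(grp))))
  ms <- anova(lm(y ~ grp))
  msb <- ms["grp", "Mean Sq"]
  msw <- ms["Residuals", "Mean Sq"]
  expect_equal(unname(fit$sigma2["grp"]), (msb - msw) / 10, tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["residual"]), msw, tolerance = 1e-6)
})

test_that("null genetic data drives genetic components to the floor", {
  set.seed(15)
  g <- make_genotypes(80, 300, seed = 15)
  G <- compute_grm(g)
  K <- threshold_kinship(G)
  y <- rnorm(80)   # no genetic signal at all
  fit <- fit_reml(vc_model(y, list(G = G, K = K)))
  expect_lt(fit$proportions[["G"]] + fit$proportions[["K"]], 0.25)
  expect_gte(min(fit$sigma2), 0)
})

test_that("AI-REML optimum matches a derivative-free optimizer", {
  set.seed(16)
  n <- 60
  g <- make_genotypes(n, 200, seed = 16)
  G <- compute_grm(g)
  y <- draw_vc_pheno(c(G = 0.5), list(G = G), n)
  m <- vc_model(y, list(G = G))
  fit <- fit_reml(m)
  op <- optim(log(fit$sigma2 + 1e-8),
              function(ls) -restricted_loglik(m, exp(ls)),
              method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(abs(fit$logL - (-op$value)), 1e-4)
})

test_that("estimates are equivariant under consistent permutation", {
  set.seed(17)
  n <- 50
  g <- make_genotypes(n, 150, seed = 17)
  G <- compute_grm(g)
  smk <- categorical_similarity(
    setNames(sample(c("n", "e", "c"), n, TRUE), g$sample_ids))
  y <- draw_vc_pheno(c(G = 0.4, Smk = 0.2), list(G = G, Smk = smk), n)
  fit1 <- fit_reml(vc_model(y, list(G = G, Smk = smk)))
  pi <- sample(n)
  Gp <- relationship_matrix(unclass(G)[pi, pi], kind = "G")
  Sp <- relationship_matrix(unclass(smk)[pi, pi], kind = "ENV")
  fit2 <- fit_reml(vc_model(y[pi], list(G = Gp, Smk = Sp)))
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-6)
  expect_equal(fit1$logL, fit2$logL, tolerance = 1e-6)
})

test_that("variance proportions normalize, are scale-free, and SEs match a bootstrap", {
  fake <- structure(list(
    sigma2 = c(a = 0.25, b = 0.25, residual = 0.50),
    se_sigma2 = c(a = 0.1, b = 0.1, residual = 0.1),
    proportions = c(a = 0.25, b = 0.25, residual = 0.50),
    se_proportions = c(a = NA, b = NA, residual = NA),
    cov_sigma2 = diag(c(0.01, 0.01, 0.01))), class = "reml_fit")
  vp <- variance_proportions(fake)
  expect_equal(vp$proportion, c(0.25, 0.25, 0.50))
  # a real fit: delta-method SE within 20% of a parametric bootstrap from
  # the asymptotic distribution of sigma2-hat
  set.seed(18)
  n <- 80
  g <- make_genotypes(n, 250, seed = 18)
  G <- compute_grm(g)
  y <- draw_vc_pheno(c(G = 0.5), list(G = G), n)
  fit <- fit_reml(vc_model(y, list(G = G)))
  ch <- chol(fit$cov_sigma2 + diag(1e-12, 2))
  draws <- matrix(rep(fit$sigma2, each = 200), 200) +
    matrix(rnorm(400), 200) %*% ch
  fracs <- draws[, 1] / rowSums(draws)
  expect_lt(abs(fit$se_proportions[["G"]] - sd(fracs)),
            0.2 * sd(fracs) + 1e-8)
  # doubling all components leaves fractions unchanged
  fake2 <- fake
  fake2$sigma2 <- 2 * fake$sigma2
  fake2$proportions <- fake2$sigma2 / sum(fake2$sigma2)
  expect_equal(variance_proportions(fake2)$proportion, vp$proportion)
})

test_that("boundary LRT uses the half-chi-square mixture", {
  mk <- function(logL, comps) structure(
    list(logL = logL, component_names = comps, y = 1:10,
         X = matrix(1, 10, 1)), class = "reml_fit")
  # statistic 2.706 -> p = 0.5 * P(chisq_1 >= 2.706) ~ 0.05
  res <- lrt(mk(-99, c("G", "GxSmk")), mk(-99 - 2.706 / 2, "G"))
  expect_equal(res$statistic, 2.706)
  expect_equal(res$p_value, 0.5 * pchisq(2.706, 1, lower.tail = FALSE))
  expect_lt(abs(res$p_value - 0.05), 5e-4)
  # zero (or negative) statistic carries the boundary point mass
  expect_equal(lrt(mk(-99, c("G", "GxSmk")), mk(-99, "G"))$p_value, 1)
  expect_equal(lrt(mk(-99.5, c("G", "GxSmk")), mk(-99, "G"))$statistic, 0)
  # multiple dropped components: conservative chi-square with warning
  expect_warning(res2 <- lrt(mk(-95, c("G", "K", "S")), mk(-99, "G")),
                 "conservative")
  expect_equal(res2$p_value, pchisq(8, 2, lower.tail = FALSE))
  # guards: subset and identical data
  expect_error(lrt(mk(-99, "G"), mk(-99, c("G", "K"))), "subset")
  bad <- mk(-100, "G"); bad$y <- 2:11
  expect_error(lrt(mk(-99, c("G", "K")), bad), "responses differ")
})

test_that("nested fits never lose likelihood on the same data", {
  set.seed(19)
  n <- 60
  g <- make_genotypes(n, 150, seed = 19)
  G <- compute_grm(g)
  smk <- categorical_similarity(
    setNames(sample(c("n", "e", "c"), n, TRUE), g$sample_ids))
  gs <- hadamard(G, smk)
  y <- draw_vc_pheno(c(G = 0.4), list(G = G), n)
  full <- fit_reml(vc_model(y, list(G = G, GxSmk = gs)))
  red <- fit_reml(vc_model(y, list(G = G)))
  expect_gte(full$logL, red$logL - 1e-4)
  expect_gte(lrt(full, red)$statistic, 0)
})

test_that("fixed-effect variance tracks the simulated between-category share", {
  set.seed(20)
  n <- 2000
  smoking <- factor(sample(c("never", "ex", "current"), n, TRUE,
                           prob = c(0.5, 0.3, 0.2)))
  shift <- c(never = 0, ex = 0.3, current = 0.8)
  mu <- unname(shift[as.character(smoking)])
  y <- mu + rnorm(n)
  clin <- categorical_similarity(sample(c("a", "b", "c"), n, TRUE))
  X <- cbind("(Intercept)" = 1, model.matrix(~smoking)[, -1])
  fit <- fit_reml(vc_model(y, list(clin = clin), X = X))
  expect_lt(abs(fixed_effect_variance(fit) - var(mu) / var(y)), 0.02)
  # intercept-only design explains nothing
  fit0 <- fit_reml(vc_model(y, list(clin = clin)))
  expect_equal(fixed_effect_variance(fit0), 0)
})
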
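#' Specify a synthetic cohort
#'
#' Declares the study conditions of a simulated cohort: sample size and
#' sibship structure, marker panel, exposure (smoking) distribution,
#' exposure-driven CpG methylation, and the true variance fractions of the
#' phenotype.  The defaults describe the calibration scenario used
#' throughout the package: n = 1000 individuals of which 200 form 100 full
#' sib pairs, m = 5000 independent common SNPs, a three-category smoking
#' variable, 62 smoking-associated CpGs with modest heritability, and a
#' phenotype with genomic, kinship and genome-by-smoking variance
#' (G = 0.25, K = 0.25, GxSmk = 0.10, residual = 0.40).
#'
#' @param n_individuals total cohort size.
#' @param n_families number of full-sib families.
#' @param family_size siblings per family (families are sibships; parents
#'   are simulated but not included in the cohort).
#' @param m_snps number of independent biallelic SNPs.
#' @param maf_range founder allele-frequency range (uniform draw),
#'   within \[0.05, 0.5\].
#' @param smoking_probs named category probabilities, summing to 1.
#' @param smoking_dose named dose score per category, the exposure scale on
#'   which smoking drives methylation and (in dose mode) the phenotype.
#' @param smoking_between_r2 fraction of the latent individual exposure
#'   explained by the self-report category (default 0.5): actual tobacco
#'   exposure varies within categories, and methylation tracks the latent
#'   exposure while the category matrix can only model its
#'   between-category part.
#' @param n_cpgs number of exposure-associated CpG sites.
#' @param cpg_smoking_r2 fraction of each CpG's variance explained by the
#'   smoking dose.
#' @param cpg_h2 per-CpG heritability; must stay below 0.40, mirroring the
#'   selection rule for environment-proxy CpGs.
#' @param variance_fractions named true phenotype variance fractions over
#'   `G`, `K`, `Smk`, `GxSmk`, `M`; the residual fraction is
#'   `1 - sum`.
#' @param mode `"covariance-exact"` (default): random effects drawn with
#'   exactly the covariance the estimator assumes; `"mechanistic"`:
#'   per-SNP effect sizes with category-specific deviations, family-block
#'   shared environment and category shifts, rescaled to the target
#'   fractions.
#' @param smoking_effect how the `Smk` fraction is realized:
#'   `"dose"` (default) — an effect proportional to the latent individual
#'   exposure (the same signal the CpGs respond to), of which the
#'   self-report category explains only `smoking_between_r2`;
#'   `"categorical"` — independent common effects per category
#'   (covariance exactly the SMK indicator matrix).
#' @param missing_rate genotype missingness rate (default 0).
#' @param n_clinics number of assessment centres.
#' @param beta_sex,beta_age,beta_smoking fixed-effect sizes on the raw
#'   phenotype scale (defaults 0).
#' @return A validated list of class `sim_spec`.
#' @export
simulation_spec <- function(n_individuals = 1000,
                            n_families = 100,
                            family_size = 2,
                            m_snps = 5000,
                            maf_range = c(0.05, 0.5),
                            smoking_probs = c(never = 0.5, ex = 0.3,
                                              current = 0.2),
                            smoking_dose = c(never = 0, ex = 0.5,
                                             current = 1),
                            smoking_between_r2 = 0.5,
                            n_cpgs = 62,
                            cpg_smoking_r2 = 0.3,
                            cpg_h2 = 0.2,
                            variance_fractions = c(G = 0.25, K = 0.25,
                                                   Smk = 0, GxSmk = 0.10,
                                                   M = 0),
                            mode = c("covariance-exact", "mechanistic"),
                            smoking_effect = c("dose", "categorical"),
                            missing_rate = 0,
                            n_clinics = 3,
                            beta_sex = 0, beta_age = 0, beta_smoking = 0) {
  mode <- match.arg(mode)
  smoking_effect <- match.arg(smoking_effect)
  vf <- c(G = 0, K = 0, Smk = 0, GxSmk = 0, M = 0)
  vf[names(variance_fractions)] <- variance_fractions
  if (any(vf < 0)) stop("variance fractions must be non-negative")
  if (sum(vf) > 1) stop("variance fractions sum to more than 1")
  stopifnot(n_individuals >= 2, m_snps >= 1,
            n_families * family_size <= n_individuals,
            maf_range[1] >= 0.05, maf_range[2] <= 0.5,
            abs(sum(smoking_probs) - 1) < 1e-8,
            identical(sort(names(smoking_probs)),
                      sort(names(smoking_dose))),
            smoking_between_r2 >= 0, smoking_between_r2 <= 1,
            cpg_smoking_r2 >= 0, cpg_h2 >= 0,
            cpg_smoking_r2 + cpg_h2 <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (cpg_h2 >= 0.40)
    stop("cpg_h2 must be below 0.40 (environment-proxy CpG selection rule)")
  structure(list(n_individuals = n_individuals, n_families = n_families,
                 family_size = family_size, m_snps = m_snps,
                 maf_range = maf_range, smoking_probs = smoking_probs,
                 smoking_dose = smoking_dose,
                 smoking_between_r2 = smoking_between_r2, n_cpgs = n_cpgs,
                 cpg_smoking_r2 = cpg_smoking_r2, cpg_h2 = cpg_h2,
                 variance_fractions = vf, residual = 1 - sum(vf),
                 mode = mode, smoking_effect = smoking_effect,
                 missing_rate = missing_rate, n_clinics = n_clinics,
                 beta_sex = beta_sex, beta_age = beta_age,
                 beta_smoking = beta_smoking),
            class = "sim_spec")
}

#' Simulate family-structured genotypes
#'
#' Founders receive binomial(2, p) dosages with per-SNP allele frequencies
#' drawn uniformly from `maf_range`.  Siblings are generated by Mendelian
#' transmission from simulated (unobserved) parental genotypes: at every
#' locus each child receives an allele from each parent with probability
#' equal to half the parental dosage, so realized within-sibship
#' relatedness is centred on 0.5.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional seed (set it here only when calling this function
#'   standalone; [simulate_cohort()] seeds the whole generation once).
#' @return list with `genotypes` (a [genotype_matrix()]) and `pedigree`
#'   (data.frame `sample_id`, `family_id`).
#' @export
simulate_genotypes <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_individuals
  m <- spec$m_snps
  p <- runif(m, spec$maf_range[1], spec$maf_range[2])
  n_fam_ind <- spec$n_families * spec$family_size
  n_unrel <- n - n_fam_ind
  d <- matrix(NA_real_, n, m)
  fam_id <- character(n)
  if (spec$n_families > 0) {
    probs <- matrix(p, spec$n_families, m, byrow = TRUE)
    fathers <- matrix(rbinom(spec$n_families * m, 2, probs),
                      spec$n_families, m)
    mothers <- matrix(rbinom(spec$n_families * m, 2, probs),
                      spec$n_families, m)
    for (s in seq_len(spec$family_size)) {
      rows <- (s - 1) * spec$n_families + seq_len(spec$n_families)
      d[rows, ] <- rbinom(length(fathers), 1, fathers / 2) +
        rbinom(length(mothers), 1, mothers / 2)
    }
    # interleave so each family's sibs are adjacent in ids, not in memory
    fam_of_row <- rep(seq_len(spec$n_families), spec$family_size)
    fam_id[seq_len(n_fam_ind)] <- sprintf("fam%04d", fam_of_row)
  }
  if (n_unrel > 0) {
    rows <- n_fam_ind + seq_len(n_unrel)
    probs <- matrix(p, n_unrel, m, byrow = TRUE)
    d[rows, ] <- rbinom(n_unrel * m, 2, probs)
    fam_id[rows] <- sprintf("solo%04d", seq_len(n_unrel))
  }
  if (spec$missing_rate > 0)
    d[runif(length(d)) < spec$missing_rate] <- NA
  ids <- sprintf("ind%05d", seq_len(n))
  geno <- genotype_matrix(d, sample_ids = ids,
                          variant_ids = sprintf("snp%05d", seq_len(m)))
  list(genotypes = geno,
       pedigree = data.frame(sample_id = ids, family_id = fam_id))
}

#' Simulate smoking exposure and exposure-driven methylation
#'
#' Assigns each individual a smoking category, maps it to a dose score
#' (never = 0, ex = 0.5, current = 1 by default), and forms a latent
#' individual exposure: the standardized dose plus a within-category
#' deviation, mixed so the category explains `smoking_between_r2` of the
#' exposure variance (actual tobacco exposure varies within self-report
#' categories).  CpG methylation is then simulated on the residualized
#' scale: each CpG is a mixture of the latent exposure (variance fraction
#' `cpg_smoking_r2`), a small genetic term built from a random set of
#' causal SNPs (fraction `cpg_h2`), and independent noise.
#'
#' @param spec a [simulation_spec()].
#' @param geno the cohort's [genotype_matrix()].
#' @param seed optional seed (see [simulate_genotypes()]).
#' @param n_causal_per_cpg causal SNPs behind each CpG's genetic term.
#' @return list with `smoking` (factor), `dose` (numeric), `exposure`
#'   (standardized latent exposure), `methylation` (n x n_cpgs matrix).
#' @export
simulate_smoking_and_methylation <- function(spec, geno, seed = NULL,
                                             n_causal_per_cpg = 20) {
  stopifnot(inherits(spec, "sim_spec"), inherits(geno, "genotype_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(geno$sample_ids)
  cats <- names(spec$smoking_probs)
  smoking <- factor(sample(cats, n, replace = TRUE,
                           prob = spec$smoking_probs), levels = cats)
  dose <- unname(spec$smoking_dose[as.character(smoking)])
  dtilde <- if (sd(dose) > 0) as.numeric(scale(dose)) else rep(0, n)
  b <- spec$smoking_between_r2
  exposure <- sqrt(b) * dtilde + sqrt(1 - b) * rnorm(n)
  exposure <- as.numeric(scale(exposure))
  r2 <- spec$cpg_smoking_r2
  h2 <- spec$cpg_h2
  meth <- matrix(NA_real_, n, spec$n_cpgs,
                 dimnames = list(geno$sample_ids,
                                 sprintf("cg%07d", seq_len(spec$n_cpgs))))
  if (h2 > 0) {
    d <- geno$dosages
    d[is.na(d)] <- 0
    Zs <- scale(d)
    Zs[, attr(Zs, "scaled:scale") == 0] <- 0
  }
  k_causal <- min(n_causal_per_cpg, spec$m_snps)
  # smoking CpGs are both hyper- and hypo-methylated: random exposure
  # loading signs (a constant-sign loading would be removed by the ORM's
  # per-individual standardization)
  load_sign <- sample(c(-1, 1), spec$n_cpgs, replace = TRUE)
  for (j in seq_len(spec$n_cpgs)) {
    g <- if (h2 > 0) {
      raw <- Zs[, sample.int(ncol(Zs), k_causal), drop = FALSE] %*%
        rnorm(k_causal)
      as.numeric(scale(raw))
    } else 0
    meth[, j] <- load_sign[j] * sqrt(r2) * exposure + sqrt(h2) * g +
      sqrt(1 - r2 - h2) * rnorm(n)
  }
  list(smoking = smoking, dose = dose, exposure = exposure,
       methylation = meth)
}

# symmetric square-root sampler: returns function(k) drawing k columns
# with covariance A (negative eigenvalues, if any, clipped at zero)
make_mvn_sampler <- function(A) {
  eg <- eigen(A, symmetric = TRUE)
  lam <- sqrt(pmax(eg$values, 0))
  U <- eg$vectors
  n <- nrow(A)
  function(k = 1) U %*% (lam * matrix(rnorm(n * k), n, k))
}

#' Simulate phenotypes with known variance composition
#'
#' Draws phenotypes from the cohort's relationship matrices.  In
#' covariance-exact mode each random effect is `sqrt(f_i) L_i z` with
#' `L_i` a symmetric square root of the corresponding matrix — exactly the
#' generative model the REML estimator assumes — so recovery experiments
#' isolate estimator behaviour.  In mechanistic mode effects are built
#' from per-SNP effect sizes (with category-specific deviations for the
#' interaction), family-block environment and category shifts, each term
#' rescaled to its target fraction.  The smoking main effect follows
#' `spec$smoking_effect` (see [simulation_spec()]).
#'
#' @param spec a [simulation_spec()].
#' @param cohort list as assembled by [simulate_cohort()] (needs
#'   `phenotypes` covariates, `smoking`, `dose`, `pedigree`, `genotypes`).
#' @param matrices named list with the `relmat`s referenced by non-zero
#'   variance fractions (`G`, `K`, `GxSmk`, `Smk`, `M`).
#' @param seed optional seed.
#' @return numeric vector of phenotypes (named by sample id) with
#'   attribute `realized_fractions`, the sample variance fraction of every
#'   generated term.
#' @export
simulate_phenotype <- function(spec, cohort, matrices, seed = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_individuals
  vf <- spec$variance_fractions
  if (sum(vf) > 1) stop("variance fractions sum to more than 1")
  need <- names(vf)[vf > 0]
  need_mats <- setdiff(need, if (spec$smoking_effect == "dose") "Smk")
  miss <- setdiff(need_mats, names(matrices))
  if (length(miss))
    stop("matrices missing for components: ", paste(miss, collapse = ", "))
  terms <- list()
  if (spec$mode == "covariance-exact") {
    for (cm in need) {
      if (cm == "Smk" && spec$smoking_effect == "dose") {
        expo <- if (!is.null(cohort$exposure)) cohort$exposure
                else if (sd(cohort$dose) > 0) as.numeric(scale(cohort$dose))
                else rep(0, n)
        terms[[cm]] <- sqrt(vf[[cm]]) * expo
      } else {
        terms[[cm]] <- sqrt(vf[[cm]]) *
          drop(make_mvn_sampler(as.matrix(matrices[[cm]]))(1))
      }
    }
  } else {
    d <- cohort$genotypes$dosages
    d[is.na(d)] <- 0
    Zs <- scale(d)
    Zs[, attr(Zs, "scaled:scale") == 0] <- 0
    m <- ncol(Zs)
    rescale <- function(x, f) {
      if (sd(x) == 0) return(rep(0, n))
      sqrt(f) * (x - mean(x)) / sd(x)
    }
    if (vf[["G"]] > 0)
      terms[["G"]] <- rescale(drop(Zs %*% rnorm(m, sd = 1 / sqrt(m))),
                              vf[["G"]])
    if (vf[["K"]] > 0) {
      fam <- cohort$pedigree$family_id
      eff <- rnorm(length(unique(fam)))
      names(eff) <- unique(fam)
      terms[["K"]] <- rescale(eff[fam], vf[["K"]])
    }
    if (vf[["GxSmk"]] > 0) {
      cats <- levels(cohort$smoking)
      dev <- matrix(rnorm(m * length(cats), sd = 1 / sqrt(m)), m)
      GW <- Zs %*% dev    # each individual under every category's effects
      gw <- GW[cbind(seq_len(n), as.integer(cohort$smoking))]
      terms[["GxSmk"]] <- rescale(gw, vf[["GxSmk"]])
    }
    if (vf[["Smk"]] > 0) {
      if (spec$smoking_effect == "dose") {
        terms[["Smk"]] <- rescale(
          if (!is.null(cohort$exposure)) cohort$exposure else cohort$dose,
          vf[["Smk"]])
      } else {
        cats <- levels(cohort$smoking)
        eff <- setNames(rnorm(length(cats)), cats)
        terms[["Smk"]] <- rescale(eff[as.character(cohort$smoking)],
                                  vf[["Smk"]])
      }
    }
    if (vf[["M"]] > 0)
      terms[["M"]] <- rescale(
        drop(cohort$methylation %*% rnorm(ncol(cohort$methylation))),
        vf[["M"]])
  }
  e <- sqrt(spec$residual) * rnorm(n)
  cov <- cohort$phenotypes
  xb <- spec$beta_sex * (cov$sex == "M") +
    spec$beta_age * as.numeric(scale(cov$age)) +
    spec$beta_smoking * cohort$dose
  y <- xb + e
  for (u in terms) y <- y + u
  names(y) <- cohort$genotypes$sample_ids
  genetic_part <- c(terms, list(residual = e))
  total <- var(y - xb)
  attr(y, "realized_fractions") <-
    vapply(genetic_part, function(u) var(u) / total, numeric(1))
  y
}

#' Simulate a full cohort
#'
#' Runs the generation chain — genotypes and pedigree, covariates (sex,
#' age, clinic), smoking and methylation, relationship matrices, phenotype
#' — under a single seed, so the cohort is bit-reproducible from
#' `(spec, seed)`.
#'
#' @param spec a [simulation_spec()].
#' @param seed integer seed.
#' @param matrices which relationship matrices to build; default builds
#'   what the spec's variance fractions and the standard model grid need.
#' @return A list of class `synthetic_cohort`: `genotypes`, `pedigree`,
#'   `smoking`, `dose`, `sex`, `methylation`, `phenotypes` (data.frame
#'   with covariates and the trait), `matrices`, `truth` (the spec plus
#'   realized fractions).
#' @export
simulate_cohort <- function(spec, seed = 1,
                            matrices = c("G", "K", "Smk", "GxSmk", "M",
                                         "GxM")) {
  stopifnot(inherits(spec, "sim_spec"))
  # pull in construction dependencies
  if ("GxSmk" %in% matrices) matrices <- c(matrices, "G", "Smk")
  if ("GxM" %in% matrices) matrices <- c(matrices, "G", "M")
  if ("K" %in% matrices) matrices <- c(matrices, "G")
  matrices <- unique(matrices)
  set.seed(seed)
  gen <- simulate_genotypes(spec)
  n <- spec$n_individuals
  ids <- gen$genotypes$sample_ids
  sex <- factor(sample(c("F", "M"), n, replace = TRUE))
  age <- round(runif(n, 18, 75))
  clinic <- factor(sample(sprintf("clinic%d", seq_len(spec$n_clinics)),
                          n, replace = TRUE))
  sm <- simulate_smoking_and_methylation(spec, gen$genotypes)
  mats <- list()
  if ("G" %in% matrices) mats$G <- compute_grm(gen$genotypes)
  if ("K" %in% matrices && !is.null(mats$G))
    mats$K <- threshold_kinship(mats$G)
  if ("Smk" %in% matrices)
    mats$Smk <- categorical_similarity(
      setNames(as.character(sm$smoking), ids), kind = "ENV")
  if ("Sex" %in% matrices)
    mats$Sex <- categorical_similarity(
      setNames(as.character(sex), ids), kind = "SEX")
  if ("GxSmk" %in% matrices && !is.null(mats$G) && !is.null(mats$Smk))
    mats$GxSmk <- hadamard(mats$G, mats$Smk)
  if ("M" %in% matrices) mats$M <- compute_orm(sm$methylation)
  if ("GxM" %in% matrices && !is.null(mats$G) && !is.null(mats$M))
    mats$GxM <- hadamard(mats$G, mats$M)
  cohort <- list(genotypes = gen$genotypes, pedigree = gen$pedigree,
                 smoking = sm$smoking, dose = sm$dose,
                 exposure = sm$exposure, sex = sex,
                 methylation = sm$methylation,
                 phenotypes = data.frame(sample_id = ids, sex = sex,
                                         age = age, clinic = clinic,
                                         smoking = sm$smoking))
  y <- simulate_phenotype(spec, cohort, mats)
  cohort$phenotypes$trait <- as.numeric(y)
  cohort$matrices <- mats
  cohort$truth <- list(spec = spec,
                       realized_fractions = attr(y, "realized_fractions"),
                       seed = seed)
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort: n =", x$truth$spec$n_individuals,
      ", m =", x$truth$spec$m_snps, ", seed =", x$truth$seed, "\n")
  cat("  realized fractions:",
      paste(sprintf("%s=%.3f", names(x$truth$realized_fractions),
                    x$truth$realized_fractions), collapse = ", "), "\n")
  invisible(x)
}

#' Replicated parameter-recovery experiment
#'
#' Simulates one cohort (genotypes, exposure, matrices held fixed — the
#' REML estimator conditions on the realized relationship matrices), draws
#' `n_replicates` independent phenotypes, fits the configured models to
#' each, and tabulates per-component recovery: mean estimate, empirical
#' SD/SEM over replicates, mean reported SE and bias against the
#' generating truth.  When a model names a `reduced` counterpart the
#' boundary LRT p-value is collected per replicate.
#'
#' @param spec a [simulation_spec()].
#' @param n_replicates number of phenotype replicates.
#' @param models list of [model_spec()]s
#'   (default: the full generating model `G + K + GxSmk`).
#' @param seed seed for the whole experiment.
#' @param ... passed to [fit_reml()].
#' @return list of class `recovery_result`: `summary` (data.frame per
#'   model x component), `replicates` (long per-replicate estimates),
#'   `lrt_p` (per-model named list of p-value vectors), `truth`.
#' @export
recovery_experiment <- function(spec, n_replicates = 30,
                                models = list(
                                  model_spec("GKGxSmk",
                                             c("G", "K", "GxSmk"),
                                             reduced = "GK"),
                                  model_spec("GK", c("G", "K"))),
                                seed = 1, ...) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(seed)
  cohort <- simulate_cohort(spec, seed = seed,
                            matrices = unique(c("G", "K",
                              unlist(lapply(models, `[[`, "components")))))
  samplers <- list()
  vf <- spec$variance_fractions
  for (cm in names(vf)[vf > 0])
    if (!(cm == "Smk" && spec$smoking_effect == "dose"))
      samplers[[cm]] <- make_mvn_sampler(as.matrix(cohort$matrices[[cm]]))
  expo <- cohort$exposure
  draw_y <- function() {
    y <- sqrt(spec$residual) * rnorm(spec$n_individuals)
    for (cm in names(vf)[vf > 0]) {
      y <- y + if (cm == "Smk" && spec$smoking_effect == "dose")
        sqrt(vf[[cm]]) * expo
      else sqrt(vf[[cm]]) * drop(samplers[[cm]](1))
    }
    y
  }
  # fit reduced models before the models that test against them
  ord <- order(!vapply(models, function(m) is.null(m$reduced), logical(1)))
  models <- models[ord]
  reps <- list()
  lrt_p <- list()
  for (r in seq_len(n_replicates)) {
    y <- draw_y()
    fits <- list()
    for (ms in models) {
      fit <- tryCatch(
        fit_reml(vc_model(y, cohort$matrices[ms$components]), ...),
        error = function(e) NULL)
      fits[[ms$name]] <- fit
      if (is.null(fit)) {
        reps[[length(reps) + 1]] <-
          data.frame(replicate = r, model = ms$name,
                     component = NA_character_, estimate = NA_real_,
                     se = NA_real_, converged = FALSE)
        next
      }
      reps[[length(reps) + 1]] <-
        data.frame(replicate = r, model = ms$name,
                   component = names(fit$proportions),
                   estimate = unname(fit$proportions),
                   se = unname(fit$se_proportions),
                   converged = fit$converged, row.names = NULL)
      if (!is.null(ms$reduced) && !is.null(fits[[ms$reduced]])) {
        p <- tryCatch(lrt(fit, fits[[ms$reduced]])$p_value,
                      error = function(e) NA_real_)
        lrt_p[[ms$name]] <- c(lrt_p[[ms$name]], p)
      }
    }
  }
  reps <- do.call(rbind, reps)
  truth_all <- c(vf, residual = spec$residual)
  ok <- reps[!is.na(reps$component), ]
  agg <- do.call(rbind, lapply(
    split(ok, list(ok$model, ok$component), drop = TRUE),
    function(d) data.frame(
      model = d$model[1], component = d$component[1],
      truth = unname(truth_all[d$component[1]]),
      mean_estimate = mean(d$estimate, na.rm = TRUE),
      empirical_sd = sd(d$estimate, na.rm = TRUE),
      empirical_sem = sd(d$estimate, na.rm = TRUE) /
        sqrt(sum(!is.na(d$estimate))),
      mean_reported_se = mean(d$se, na.rm = TRUE),
      n_replicates = sum(!is.na(d$estimate)))))
  agg$bias <- agg$mean_estimate - agg$truth
  rownames(agg) <- NULL
  structure(list(summary = agg, replicates = reps, lrt_p = lrt_p,
                 truth = truth_all, spec = spec, seed = seed),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("recovery_result over", max(x$replicates$replicate), "replicates\n")
  print(x$summary, digits = 3)
  invisible(x)
}
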
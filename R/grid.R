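#' Define one model of a grid
#'
#' A model specification names the random-effect matrices it includes, says
#' whether the exposure category enters the fixed effects, and optionally
#' names the reduced model against which a likelihood-ratio test is run.
#'
#' @param name model label (e.g. `"GKGxSmk"`).
#' @param components character vector of matrix labels (must exist in the
#'   matrix list handed to [run_model_grid()]).
#' @param fixed_smoking add exposure-category indicator columns to the
#'   fixed-effect design (default `FALSE`).
#' @param reduced optional name of the reduced model for the LRT.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, components, fixed_smoking = FALSE,
                       reduced = NULL) {
  stopifnot(is.character(name), length(components) >= 1)
  structure(list(name = name, components = components,
                 fixed_smoking = fixed_smoking, reduced = reduced),
            class = "model_spec")
}

#' Standard model grid
#'
#' The default set of model configurations: a base genomic + kinship model,
#' exposure as fixed effect, exposure as a random (common-environment)
#' effect, genome-by-exposure interaction with and without the exposure
#' main random effect, and — when a methylation matrix is supplied —
#' models adding the methylation similarity matrix and the
#' genome-by-methylation interaction.  Interaction models carry an LRT
#' against their no-interaction reduction.
#'
#' @param with_methylation include the methylation-based models
#'   (requires matrices `M` and `GxM`).
#' @return A list of [model_spec()] objects.
#' @export
standard_model_grid <- function(with_methylation = FALSE) {
  g <- list(
    model_spec("GK", c("G", "K")),
    model_spec("GK+Smk_fixed", c("G", "K"), fixed_smoking = TRUE),
    model_spec("GKSmk", c("G", "K", "Smk")),
    model_spec("GKGxSmk", c("G", "K", "GxSmk"), reduced = "GK"),
    model_spec("GKSmkGxSmk", c("G", "K", "Smk", "GxSmk"), reduced = "GKSmk"))
  if (with_methylation) {
    g <- c(g, list(
      model_spec("GKEM", c("G", "K", "Smk", "M")),
      model_spec("GKM", c("G", "K", "M")),
      model_spec("GKMGxM", c("G", "K", "M", "GxM"), reduced = "GKM")))
  }
  g
}

smoking_design <- function(smoking, n) {
  sm <- factor(smoking)
  if (nlevels(sm) < 2)
    stop("smoking has fewer than two categories; cannot be a fixed effect")
  model.matrix(~sm)[, -1, drop = FALSE]
}

#' Fit a grid of variance-component models
#'
#' Fits every configured model for every prepared trait and assembles one
#' row per (trait, model, component), the machine-readable layout of a
#' variance-partition results table: the proportion of phenotypic variance
#' (`var`), its standard error (`se`), the restricted log-likelihood, and
#' the boundary LRT p-value against the configured reduced model (reported
#' on the rows of the components being tested, `NA` elsewhere).
#'
#' A model that fails to fit is recorded with `converged = FALSE` and `NA`
#' estimates; it never aborts the grid.
#'
#' @param traits named list of prepared trait vectors (or a single numeric
#'   vector, labelled `"trait"`).
#' @param matrices named list of `relmat` objects the grid can draw on.
#' @param grid list of [model_spec()]s (default [standard_model_grid()]).
#' @param smoking per-individual exposure category; required by models with
#'   `fixed_smoking = TRUE`.
#' @param ... passed to [fit_reml()].
#' @return data.frame with columns `trait`, `model`, `component`, `var`,
#'   `se`, `logL`, `lrt_p`, `n`, `converged`.  Attribute `fits` keeps the
#'   underlying `reml_fit` objects, keyed `<trait>:<model>`.
#' @export
run_model_grid <- function(traits, matrices, grid = standard_model_grid(),
                           smoking = NULL, ...) {
  if (is.numeric(traits)) traits <- list(trait = traits)
  stopifnot(is.list(traits), !is.null(names(traits)))
  if (length(grid) == 0)
    return(data.frame(trait = character(), model = character(),
                      component = character(), var = numeric(),
                      se = numeric(), logL = numeric(), lrt_p = numeric(),
                      n = integer(), converged = logical()))
  rows <- list()
  fits <- list()
  for (tr in names(traits)) {
    y <- traits[[tr]]
    for (ms in grid) {
      key <- paste(tr, ms$name, sep = ":")
      missing_mats <- setdiff(ms$components, names(matrices))
      if (length(missing_mats) > 0) {
        rows[[key]] <- data.frame(trait = tr, model = ms$name,
                                  component = NA_character_, var = NA_real_,
                                  se = NA_real_, logL = NA_real_,
                                  lrt_p = NA_real_, n = NA_integer_,
                                  converged = FALSE)
        warning("model ", ms$name, ": missing matrices ",
                paste(missing_mats, collapse = ", "))
        next
      }
      X <- NULL
      if (isTRUE(ms$fixed_smoking)) {
        if (is.null(smoking)) stop("model ", ms$name,
                                   " needs the smoking labels")
        X <- cbind("(Intercept)" = 1, smoking_design(smoking))
      }
      fit <- tryCatch(
        fit_reml(vc_model(y, matrices[ms$components], X = X), ...),
        error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[key]] <- data.frame(trait = tr, model = ms$name,
                                  component = NA_character_, var = NA_real_,
                                  se = NA_real_, logL = NA_real_,
                                  lrt_p = NA_real_, n = NA_integer_,
                                  converged = FALSE)
        next
      }
      fits[[key]] <- fit
      lrt_p <- setNames(rep(NA_real_, length(fit$sigma2)),
                        names(fit$sigma2))
      if (!is.null(ms$reduced)) {
        red_key <- paste(tr, ms$reduced, sep = ":")
        red <- fits[[red_key]]
        if (!is.null(red)) {
          tested <- setdiff(fit$component_names, red$component_names)
          res <- tryCatch(lrt(fit, red), error = function(e) NULL)
          if (!is.null(res)) lrt_p[tested] <- res$p_value
        }
      }
      rows[[key]] <- data.frame(trait = tr, model = ms$name,
                                component = names(fit$sigma2),
                                var = unname(fit$proportions),
                                se = unname(fit$se_proportions),
                                logL = fit$logL,
                                lrt_p = unname(lrt_p),
                                n = fit$n, converged = fit$converged,
                                row.names = NULL)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  out
}
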
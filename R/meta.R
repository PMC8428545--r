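#' Meta-analysis of per-sub-cohort variance-component estimates
#'
#' Pools one variance component's estimates across sub-cohorts by
#' inverse-variance weighting, as done when a large cohort is analysed in
#' geographically defined groups.  `meta_fixed()` uses fixed-effect weights
#' `w_i = 1/se_i^2`; `meta_random_dl()` adds a DerSimonian-Laird
#' between-group variance
#' \deqn{\hat\tau^2 = \max\!\left(0,
#'   \frac{Q - (k - 1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' and re-weights with `1 / (se_i^2 + tau2)`.  When the heterogeneity
#' statistic `Q` does not exceed `k - 1`, the random-effects result reduces
#' exactly to the fixed-effect one.  P-values are two-sided normal
#' (no small-k t correction).  Computation is delegated to
#' [metafor::rma.uni()].
#'
#' @param estimates per-group estimates (e.g. variance proportions).
#' @param ses per-group standard errors, all positive.
#' @param group_ids optional group labels.
#' @return An object of class `meta_result`: list with `pooled`, `se`,
#'   `p_value`, `tau2`, `Q`, `I2` (as a fraction), `k`, `method`.
#' @examples
#' meta_fixed(c(0.02, 0.04), c(0.01, 0.01))
#' @export
meta_fixed <- function(estimates, ses, group_ids = NULL) {
  meta_pool(estimates, ses, group_ids, method = "FE")
}

#' @rdname meta_fixed
#' @export
meta_random_dl <- function(estimates, ses, group_ids = NULL) {
  meta_pool(estimates, ses, group_ids, method = "DL")
}

meta_pool <- function(estimates, ses, group_ids, method) {
  if (length(estimates) < 2)
    stop("meta-analysis needs at least two groups")
  if (length(ses) != length(estimates))
    stop("estimates and ses must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0))
    stop("all standard errors must be positive")
  if (is.null(group_ids)) group_ids <- paste0("group", seq_along(estimates))
  res <- metafor::rma.uni(yi = estimates, sei = ses, method = method,
                          test = "z")
  structure(list(pooled = as.numeric(res$beta), se = res$se,
                 p_value = res$pval, tau2 = res$tau2, Q = res$QE,
                 I2 = res$I2 / 100, k = res$k, method = method,
                 group_ids = group_ids),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "meta_result [%s, k = %d]: pooled = %.4f (se %.4f), p = %.4g\n",
    x$method, x$k, x$pooled, x$se, x$p_value))
  cat(sprintf("  tau2 = %.4g, Q = %.4f, I2 = %.1f%%\n",
              x$tau2, x$Q, 100 * x$I2))
  invisible(x)
}

#' Meta-analyse one component across sub-cohort grid results
#'
#' Convenience wrapper extracting one (trait, model, component) row from
#' each group's [run_model_grid()] table and pooling the estimates.
#'
#' @param results named list of grid result tables, one per sub-cohort.
#' @param component component label to pool (e.g. `"GxSmk"`).
#' @param model model name the component is taken from.
#' @param trait trait name (default: first trait present).
#' @param method `"DL"` (random effects, default) or `"FE"`.
#' @return A `meta_result`.
#' @export
meta_component <- function(results, component, model, trait = NULL,
                           method = c("DL", "FE")) {
  method <- match.arg(method)
  pick <- function(df) {
    if (is.null(trait)) trait <- df$trait[1]
    row <- df[df$trait == trait & df$model == model &
                df$component == component & !is.na(df$component), ]
    if (nrow(row) != 1 || !row$converged)
      return(c(NA_real_, NA_real_))
    c(row$var, row$se)
  }
  vals <- vapply(results, pick, numeric(2))
  ok <- !is.na(vals[1, ]) & !is.na(vals[2, ])
  if (sum(ok) < 2)
    stop("fewer than two usable sub-cohort estimates for ", component)
  fn <- if (method == "DL") meta_random_dl else meta_fixed
  fn(vals[1, ok], vals[2, ok], group_ids = names(results)[ok])
}
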
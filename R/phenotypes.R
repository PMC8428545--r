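#' Add derived anthropometric traits
#'
#' Adds body mass index (`bmi = weight / height^2`, weight in kg and height
#' in metres) and waist-to-hip ratio (`whr = waist / hips`) to a phenotype
#' table.  Missingness in a parent column propagates; non-positive heights
#' or hip circumferences yield a missing value with a warning.
#'
#' @param tbl data.frame; columns `weight`, `height` and/or `waist`, `hips`
#'   are used when present.
#' @return The table with `bmi` and/or `whr` columns added.
#' @examples
#' derive_traits(data.frame(weight = 81, height = 1.8,
#'                          waist = 80, hips = 100))
#' @export
derive_traits <- function(tbl) {
  if (all(c("weight", "height") %in% names(tbl))) {
    h <- tbl$height
    if (any(!is.na(h) & h <= 0)) {
      warning("non-positive height set to missing")
      h[!is.na(h) & h <= 0] <- NA
    }
    tbl$bmi <- tbl$weight / h^2
  }
  if (all(c("waist", "hips") %in% names(tbl))) {
    p <- tbl$hips
    if (any(!is.na(p) & p <= 0)) {
      warning("non-positive hip circumference set to missing")
      p[!is.na(p) & p <= 0] <- NA
    }
    tbl$whr <- tbl$waist / p
  }
  tbl
}

#' Rank-based inverse normal transformation
#'
#' Maps the value with rank `r` among `k` non-missing observations to
#' `qnorm((r - offset) / (k - 2 * offset + 1))`, with the Blom constant
#' `offset = 3/8` by default.  Ties receive average ranks, so equal values
#' map to equal quantiles (a fully constant vector maps to all zeros).
#' Missing values stay missing.
#'
#' @param values numeric vector, possibly with `NA`s; at least 2 non-missing.
#' @param offset rank offset constant (default 3/8).
#' @return Transformed vector, same length and names as the input.
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  k <- sum(!is.na(values))
  if (k < 2) stop("at least two non-missing values are required")
  r <- rank(values, na.last = "keep", ties.method = "average")
  qnorm((r - offset) / (k - 2 * offset + 1))
}

# model matrix for covariate adjustment; factors with < 2 observed levels
# are dropped (they are constant, not collinear)
adjust_formula <- function(covars, with_clinic) {
  terms <- c()
  if ("sex" %in% covars) terms <- c(terms, "sex")
  if ("age" %in% covars) terms <- c(terms, "age", "I(age^2)")
  if (with_clinic) terms <- c(terms, "clinic")
  stats::reformulate(terms, response = ".y")
}

drop_constant_factors <- function(df, cols) {
  keep <- vapply(cols, function(cl) {
    v <- df[[cl]]
    length(unique(v[!is.na(v)])) >= 2
  }, logical(1))
  cols[keep]
}

adjust_residuals <- function(y, df, use_sex, use_age, use_clinic) {
  terms <- c(if (use_sex) "sex",
             if (use_age) c("age", "I(age^2)"),
             if (use_clinic) "clinic")
  if (length(terms) == 0) return(y - mean(y, na.rm = TRUE))
  df$.y <- y
  f <- stats::reformulate(terms, response = ".y")
  mm <- model.matrix(f, data = transform(df, .y = 0))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("collinear covariate columns: ", paste(aliased, collapse = ", "))
  }
  fit <- lm(f, data = df, na.action = na.exclude)
  resid(fit)
}

#' Prepare a trait for variance-component analysis
#'
#' Standard preparation pipeline for a quantitative trait:
#' 1. least-squares adjust for sex, age and age^2;
#' 2. set residuals beyond the residual mean +/- `sd_limit` standard
#'    deviations to missing;
#' 3. re-adjust the surviving values for sex, age, age^2 and clinic;
#' 4. rank-based inverse normal transform the residuals.
#'
#' The returned values have mean 0 and unit variance (up to the discrete
#' rank grid) and are used as the response of every mixed model, so that
#' variance proportions are directly comparable across traits.
#'
#' @param tbl data.frame with the trait column plus covariates `sex`
#'   (category), `age` (years) and `clinic` (category).
#' @param trait name of the trait column.
#' @param sd_limit outlier masking threshold in residual standard
#'   deviations (default 4).
#' @param offset rank offset for the inverse normal transform
#'   (default 3/8, see [rank_inverse_normal()]).
#' @return Numeric vector aligned to the rows of `tbl` (named by
#'   `tbl$sample_id` when present); masked and originally missing entries
#'   are `NA`.  Attribute `n_masked` records the number of outliers masked.
#' @export
prepare_trait <- function(tbl, trait, sd_limit = 4, offset = 3 / 8) {
  stopifnot(trait %in% names(tbl))
  y <- tbl[[trait]]
  if (sum(!is.na(y)) < 30)
    stop("at least 30 non-missing observations are required")
  if (var(y, na.rm = TRUE) == 0) stop("trait '", trait, "' is constant")
  use_sex <- "sex" %in% names(tbl) &&
    length(drop_constant_factors(tbl, "sex")) == 1
  use_age <- "age" %in% names(tbl) && var(tbl$age, na.rm = TRUE) > 0
  use_clinic <- "clinic" %in% names(tbl) &&
    length(drop_constant_factors(tbl, "clinic")) == 1
  # (1) adjust for sex, age, age^2
  r1 <- adjust_residuals(y, tbl, use_sex, use_age, use_clinic = FALSE)
  # (2) mask residual outliers
  mu <- mean(r1, na.rm = TRUE)
  s <- sd(r1, na.rm = TRUE)
  out <- !is.na(r1) & abs(r1 - mu) > sd_limit * s
  y2 <- y
  y2[out] <- NA
  # (3) re-adjust survivors, now including clinic
  r2 <- adjust_residuals(y2, tbl, use_sex, use_age, use_clinic)
  # (4) inverse normal transform, standardized to exactly unit variance
  # (Blom scores have variance slightly below 1 at finite n)
  z <- rank_inverse_normal(r2, offset = offset)
  z <- (z - mean(z, na.rm = TRUE)) / sd(z, na.rm = TRUE)
  if (!is.null(tbl$sample_id)) names(z) <- tbl$sample_id
  attr(z, "n_masked") <- sum(out)
  z
}
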
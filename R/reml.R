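#' Specify a variance-component model
#'
#' Assembles the response, fixed-effect design and random-effect covariance
#' structures of the linear mixed model
#' \deqn{y = X\beta + \sum_i u_i + \varepsilon, \qquad
#'   u_i \sim N(0, A_i \sigma^2_i), \quad
#'   \varepsilon \sim N(0, I \sigma^2_e)}
#' where each `A_i` is a relationship matrix (genomic, kinship,
#' environment, methylation, or a Hadamard interaction product).
#' Individuals with a missing response or missing design entries are
#' dropped, and all matrices are subset to the complete cases, so every
#' model fitted from the same `vc_model` shares one sample.
#'
#' @param y numeric response vector (a prepared trait); names, when
#'   present, must match the matrices' sample ids.
#' @param components named list of `relmat` (or plain symmetric matrix)
#'   objects, one per random effect; the residual is implicit.
#' @param X fixed-effect design matrix (default: intercept only).  A
#'   data.frame is converted with [model.matrix()].
#' @return An object of class `vc_model`.
#' @export
vc_model <- function(y, components, X = NULL) {
  if (length(components) == 0 || is.null(names(components)) ||
      any(names(components) == ""))
    stop("components must be a non-empty named list")
  n_all <- length(y)
  if (is.null(X)) {
    X <- matrix(1, n_all, 1, dimnames = list(NULL, "(Intercept)"))
  } else if (is.data.frame(X)) {
    X <- model.matrix(~., data = X)
  }
  X <- as.matrix(X)
  stopifnot(nrow(X) == n_all)
  comp <- lapply(components, function(A) {
    A <- as.matrix(A)
    if (nrow(A) != n_all || ncol(A) != n_all)
      stop("component dimension does not match length(y)")
    if (max(abs(A - t(A))) > 1e-10) stop("component matrix not symmetric")
    A
  })
  ids <- rownames(comp[[1]])
  if (!is.null(names(y)) && !is.null(ids) && !identical(names(y), ids))
    stop("sample ids of y and the component matrices disagree")
  for (A in comp[-1])
    if (!is.null(ids) && !is.null(rownames(A)) &&
        !identical(rownames(A), ids))
      stop("component matrices have different sample orderings")
  keep <- !is.na(y) & complete.cases(X)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  comp <- lapply(comp, function(A) A[keep, keep, drop = FALSE])
  n <- length(y)
  # drop rank-deficient design columns is NOT done silently: error instead
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient")
  if (ncol(X) >= n) stop("more fixed effects than observations")
  structure(list(y = as.numeric(y), X = X, components = comp,
                 n = n, p = ncol(X),
                 component_names = names(comp),
                 sample_ids = if (!is.null(ids)) ids[keep] else NULL),
            class = "vc_model")
}

#' @export
print.vc_model <- function(x, ...) {
  cat("vc_model: n =", x$n, ", p =", x$p, ", components:",
      paste(x$component_names, collapse = ", "), "+ residual\n")
  invisible(x)
}

# one REML evaluation: restricted log-likelihood, scores, average
# information, and the building blocks reused by the optimizer.
# sigma2 has length k + 1, residual LAST.
reml_eval <- function(model, sigma2, need_derivs = TRUE) {
  y <- model$y; X <- model$X; n <- model$n; p <- model$p
  k <- length(model$components)
  stopifnot(length(sigma2) == k + 1)
  V <- diag(sigma2[k + 1], n)
  for (i in seq_len(k)) V <- V + sigma2[i] * model$components[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  P <- Vi - ViX %*% chol2inv(chx) %*% t(ViX)
  Py <- drop(P %*% y)
  ld_V <- 2 * sum(log(diag(ch)))
  ld_XtViX <- 2 * sum(log(diag(chx)))
  ld_XtX <- determinant(crossprod(X), logarithm = TRUE)$modulus
  logL <- -0.5 * ((n - p) * log(2 * pi) + ld_V + ld_XtViX - ld_XtX +
                    sum(y * Py))
  out <- list(logL = as.numeric(logL), Py = Py, P = P, chx = chx, Vi = Vi,
              ViX = ViX)
  if (need_derivs) {
    Tm <- matrix(0, n, k + 1)            # columns t_i = A_i P y
    trPA <- numeric(k + 1)
    for (i in seq_len(k)) {
      Tm[, i] <- model$components[[i]] %*% Py
      trPA[i] <- sum(P * model$components[[i]])   # tr(P A_i), both symmetric
    }
    Tm[, k + 1] <- Py
    trPA[k + 1] <- sum(diag(P))
    yPAPy <- drop(crossprod(Py, Tm))     # y' P A_i P y
    score <- -0.5 * (trPA - yPAPy)
    AI <- 0.5 * crossprod(Tm, P %*% Tm)  # 0.5 y'P A_i P A_j P y
    out$score <- score
    out$AI <- AI
    out$trPA <- trPA
    out$yPAPy <- yPAPy
  }
  out
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the restricted (residual) log-likelihood of
#' `y ~ N(X beta, V)` with `V = sum_i sigma2_i A_i + sigma2_e I`, including
#' all constant terms (the Harville form, with the `log|X'X|` term), so
#' values are absolute and comparable across models sharing the same
#' response and design.
#'
#' @param model a [vc_model()].
#' @param sigma2 variance components, residual last
#'   (length `length(components) + 1`).
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_loglik <- function(model, sigma2) {
  stopifnot(inherits(model, "vc_model"))
  ev <- reml_eval(model, sigma2, need_derivs = FALSE)
  if (is.null(ev))
    stop("V is not positive definite at sigma2 = (",
         paste(signif(sigma2, 4), collapse = ", "), ")")
  ev$logL
}

#' Fit a variance-component model by average-information REML
#'
#' Newton-type REML using the average of the observed and expected
#' information (AI-REML), with expectation-maximization updates for the
#' first two iterations and as a fallback whenever an AI step would
#' decrease the restricted likelihood or leave the feasible region.
#' By default components are constrained non-negative by clamping at a
#' small floor (`1e-6 * var(y)`) with active-set handling: a clamped
#' component whose score is negative stays at the floor.
#'
#' @param model a [vc_model()].
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6); iteration also stops when the largest
#'   parameter change falls below 1e-8.
#' @param max_iter maximum iterations (default 100); a non-converged fit is
#'   returned with `converged = FALSE`, not an error.
#' @param constrain clamp variance components at the non-negativity floor
#'   (default `TRUE`); set `FALSE` for unconstrained estimates.
#' @param init optional starting values (residual last).
#' @param verbose print per-iteration log-likelihoods.
#' @return An object of class `reml_fit` with elements `sigma2`,
#'   `se_sigma2`, `beta`, `se_beta`, `logL`, `proportions`,
#'   `se_proportions`, `cov_sigma2`, `converged`, `n_iter`, `n`, and the
#'   `y`/`X` used (for likelihood-ratio comparability checks).
#' @export
fit_reml <- function(model, tol = 1e-6, max_iter = 100, constrain = TRUE,
                     init = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "vc_model"))
  k <- length(model$components)
  n <- model$n
  vy <- var(model$y)
  floor_val <- if (constrain) 1e-6 * vy else -Inf
  sigma2 <- if (!is.null(init)) as.numeric(init) else rep(vy / (k + 1), k + 1)
  stopifnot(length(sigma2) == k + 1)
  ev <- reml_eval(model, sigma2)
  if (is.null(ev)) stop("V not positive definite at the starting values")
  converged <- FALSE
  it <- 0
  em_step <- function(s, ev) {
    pmax(s + s^2 * (ev$yPAPy - ev$trPA) / n, floor_val)
  }
  while (it < max_iter) {
    it <- it + 1
    if (it <= 2) {
      prop <- em_step(sigma2, ev)
    } else {
      at_floor <- constrain & (sigma2 <= floor_val * (1 + 1e-8)) &
        (ev$score < 0)
      free <- which(!at_floor)
      # damped Newton: on a ridge the raw AI step overshoots, so inflate
      # the AI diagonal (Levenberg style) until the step improves logL
      lambda <- 0
      prop <- NULL
      for (attempt in 1:9) {
        AIf <- ev$AI[free, free, drop = FALSE]
        AId <- AIf + lambda * diag(diag(AIf), nrow = length(free))
        delta <- tryCatch(solve(AId, ev$score[free]),
                          error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- sigma2
          cand[free] <- cand[free] + delta
          cand <- pmax(cand, floor_val)
          ev_try <- reml_eval(model, cand, need_derivs = FALSE)
          if (!is.null(ev_try) && ev_try$logL >= ev$logL - 1e-8) {
            prop <- cand
            break
          }
        }
        lambda <- if (lambda == 0) 1e-4 else lambda * 10
      }
      if (is.null(prop)) prop <- em_step(sigma2, ev)
    }
    ev_new <- reml_eval(model, prop)
    if (is.null(ev_new)) {          # EM landed outside PD region: shrink
      prop <- (prop + sigma2) / 2
      ev_new <- reml_eval(model, prop)
      if (is.null(ev_new)) break
    }
    dlogL <- ev_new$logL - ev$logL
    dpar <- max(abs(prop - sigma2))
    sigma2 <- prop
    ev <- ev_new
    if (verbose)
      message(sprintf("it %2d  logL %.6f  dlogL %.2e", it, ev$logL, dlogL))
    free_now <- !(constrain & (sigma2 <= floor_val * (1 + 1e-8)) &
                    (ev$score < 0))
    grad_small <- max(abs(ev$score[free_now]), 0) < 1e-3
    if (it > 2 && (abs(dlogL) < tol || dpar < 1e-8 ||
                   (grad_small && abs(dlogL) < 1e-4 && tol >= 1e-6))) {
      converged <- TRUE
      break
    }
  }
  # inference at the optimum
  cov_s <- tryCatch(solve(ev$AI), error = function(e) {
    eg <- eigen(ev$AI, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-12
    eg$vectors[, pos, drop = FALSE] %*%
      (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  })
  se_s <- sqrt(pmax(diag(cov_s), 0))
  B <- chol2inv(ev$chx)
  beta <- drop(B %*% crossprod(model$X, drop(ev$Vi %*% model$y)))
  names(beta) <- colnames(model$X)
  se_beta <- sqrt(diag(B))
  comp_names <- c(model$component_names, "residual")
  names(sigma2) <- names(se_s) <- comp_names
  total <- sum(sigma2)
  prop_frac <- sigma2 / total
  J <- (diag(k + 1) * total - matrix(sigma2, k + 1, k + 1)) / total^2
  se_prop <- sqrt(pmax(diag(J %*% cov_s %*% t(J)), 0))
  names(se_prop) <- comp_names
  structure(list(sigma2 = sigma2, se_sigma2 = se_s, beta = beta,
                 se_beta = se_beta, logL = ev$logL,
                 proportions = prop_frac, se_proportions = se_prop,
                 cov_sigma2 = cov_s, converged = converged, n_iter = it,
                 n = n, p = model$p,
                 component_names = model$component_names,
                 y = model$y, X = model$X,
                 floor = floor_val),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit: n = %d, logL = %.4f, %sconverged in %d iterations\n",
              x$n, x$logL, if (x$converged) "" else "NOT ", x$n_iter))
  print(data.frame(sigma2 = x$sigma2, se = x$se_sigma2,
                   proportion = x$proportions, se_prop = x$se_proportions))
  invisible(x)
}

#' Variance proportions with delta-method standard errors
#'
#' Expresses each variance component (including the residual) as a fraction
#' of the total phenotypic variance `sum_j sigma2_j`, with standard errors
#' by the first-order delta method using the full asymptotic covariance of
#' the estimates (inverse average-information matrix).
#'
#' @param fit a [fit_reml()] result.
#' @return data.frame with columns `component`, `variance`, `se_variance`,
#'   `proportion`, `se_proportion`.
#' @export
variance_proportions <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (sum(fit$sigma2) <= 0) stop("total variance is zero")
  data.frame(component = names(fit$sigma2),
             variance = unname(fit$sigma2),
             se_variance = unname(fit$se_sigma2),
             proportion = unname(fit$proportions),
             se_proportion = unname(fit$se_proportions),
             row.names = NULL)
}

#' Variance explained by the fixed effects
#'
#' Sample variance of the fitted fixed part `X beta` (the intercept only
#' shifts, it never contributes) divided by the sample variance of the
#' response.
#'
#' @param fit a [fit_reml()] result.
#' @return Fraction in `[0, ~1]`.
#' @export
fixed_effect_variance <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  xb <- drop(fit$X %*% fit$beta)
  var(xb) / var(fit$y)
}

#' Likelihood-ratio test for nested variance-component models
#'
#' Tests the components present in `full` but not in `reduced`.  Because a
#' variance component sits on the boundary of its parameter space under the
#' null, the statistic `2 (logL_full - logL_reduced)` (clipped at zero) is
#' referred to the mixture `0.5 chi^2_0 + 0.5 chi^2_1` when one component
#' is dropped: `p = 0.5 P(chi^2_1 >= stat)` for a positive statistic and
#' `p = 1` at zero.  For more than one dropped component a conservative
#' `chi^2_k` reference is used, with a warning.
#'
#' @param full,reduced [fit_reml()] results on the identical response and
#'   fixed design; `reduced`'s components must be a strict subset of
#'   `full`'s.
#' @return An object of class `lrt_result`: list with `statistic`,
#'   `df_extra`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  if (!all(reduced$component_names %in% full$component_names) ||
      length(reduced$component_names) >= length(full$component_names))
    stop("reduced model components must be a strict subset of the full model's")
  if (length(full$y) != length(reduced$y) ||
      max(abs(full$y - reduced$y)) > 1e-12)
    stop("responses differ: restricted likelihoods are not comparable")
  if (!isTRUE(all.equal(full$X, reduced$X, tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("fixed-effect designs differ: restricted likelihoods are not comparable")
  stat <- max(0, 2 * (full$logL - reduced$logL))
  df_extra <- length(full$component_names) - length(reduced$component_names)
  if (df_extra == 1) {
    p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    warning("more than one component dropped; conservative chi^2_",
            df_extra, " reference used")
    p <- pchisq(stat, df = df_extra, lower.tail = FALSE)
  }
  structure(list(statistic = stat, df_extra = df_extra, p_value = p),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: statistic = %.4f, extra components = %d, p = %.4g\n",
              x$statistic, x$df_extra, x$p_value))
  invisible(x)
}
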
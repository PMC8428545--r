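#' Construct a relationship matrix object
#'
#' A relationship matrix is a symmetric individual-by-individual similarity
#' matrix entering the mixed model as the covariance structure of one random
#' effect.  Kinds follow the modelling vocabulary: `G` (genomic), `K`
#' (thresholded kinship proxy), `ENV` (categorical environment indicator),
#' `SEX` (same-sex indicator), `ORM` (omics/methylation similarity),
#' `PRODUCT` (Hadamard interaction).
#'
#' @param values symmetric numeric matrix (asymmetries up to 1e-10 are
#'   symmetrized; larger ones are an error).
#' @param sample_ids individual identifiers (default: rownames).
#' @param kind one of `"G"`, `"K"`, `"ENV"`, `"SEX"`, `"ORM"`, `"PRODUCT"`.
#' @param provenance free-text build record.
#' @return A numeric matrix of class `relmat` with attributes `kind` and
#'   `provenance`; dimnames carry the sample ids.
#' @export
relationship_matrix <- function(values, sample_ids = rownames(values),
                                kind = c("G", "K", "ENV", "SEX", "ORM",
                                         "PRODUCT"),
                                provenance = "") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  asym <- max(abs(values - t(values)))
  if (asym > 1e-10) stop("matrix is not symmetric (max asymmetry ", asym, ")")
  values <- (values + t(values)) / 2
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(values)))
  stopifnot(length(sample_ids) == nrow(values))
  dimnames(values) <- list(sample_ids, sample_ids)
  structure(values, class = c("relmat", "matrix"), kind = kind,
            provenance = provenance)
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("relmat [%s] %d x %d; mean diag %.3f; provenance: %s\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x)),
              attr(x, "provenance")))
  invisible(x)
}

sample_ids <- function(m) rownames(m)

check_same_samples <- function(...) {
  mats <- list(...)
  ids <- lapply(mats, rownames)
  for (i in seq_along(ids)[-1])
    if (!identical(ids[[1]], ids[[i]]))
      stop("sample ids differ or are ordered differently between matrices")
  invisible(TRUE)
}

#' Genomic relationship matrix (GRM)
#'
#' Allele-frequency standardized GRM:
#' \deqn{G_{jk} = \frac{1}{m} \sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}
#'   {2 p_i (1 - p_i)}}
#' with allele frequencies `p_i` estimated from the analysis sample.
#' Missing dosages are mean-imputed per variant, i.e. contribute zero on the
#' standardized scale, so every pair is averaged over the same `m` markers.
#'
#' @param geno a QC'd [genotype_matrix()]; variants must be polymorphic.
#' @return A `relmat` of kind `"G"`.
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stop("monomorphic variant(s) present (allele frequency 0 or 1); run QC first")
  m <- ncol(d)
  Z <- sweep(d, 2, 2 * p, "-")
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / m
  relationship_matrix(G, geno$sample_ids, kind = "G",
                      provenance = sprintf("GRM from %d variants", m))
}

#' Kinship proxy by thresholding a GRM
#'
#' Returns a copy of the GRM with every entry strictly below `cutoff`
#' (including negative entries; the diagonal is treated like any other
#' entry but in practice exceeds the cutoff) set to zero.  The result
#' isolates close-relative allele sharing beyond the population level.
#'
#' @param G a `relmat` of kind `"G"`.
#' @param cutoff entries strictly below this value become 0 (default 0.025).
#' @return A `relmat` of kind `"K"`.
#' @export
threshold_kinship <- function(G, cutoff = 0.025) {
  stopifnot(inherits(G, "relmat"))
  if (attr(G, "kind") != "G")
    stop("threshold_kinship expects a matrix of kind 'G'")
  K <- unclass(G)
  K[K < cutoff] <- 0
  relationship_matrix(K, rownames(G), kind = "K",
                      provenance = sprintf("G thresholded at %g", cutoff))
}

#' Categorical-environment similarity matrix
#'
#' Block indicator matrix: 1 between individuals sharing the same category
#' (e.g. smoking status or sex), 0 otherwise; diagonal 1.
#'
#' @param labels per-individual category (factor or character); no missing
#'   values allowed — complete-case the cohort first.
#' @param sample_ids individual identifiers (default: names of `labels`).
#' @param kind `"ENV"` (default) or `"SEX"`.
#' @return A `relmat` block indicator matrix.
#' @export
categorical_similarity <- function(labels, sample_ids = names(labels),
                                   kind = c("ENV", "SEX")) {
  kind <- match.arg(kind)
  force(sample_ids)
  if (anyNA(labels))
    stop("missing category labels; drop incomplete individuals first")
  labels <- as.character(labels)
  S <- outer(labels, labels, "==") * 1
  diag(S) <- 1
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_along(labels))
  relationship_matrix(S, sample_ids, kind = kind,
                      provenance = sprintf("indicator over %d categories",
                                           length(unique(labels))))
}

#' Hadamard (elementwise) product of relationship matrices
#'
#' Interaction covariances are built as cell-by-cell products: similarity
#' due to an interaction requires similarity on every factor entering the
#' product (e.g. genome-by-smoking = G * SMK; three-way
#' genome-by-smoking-by-sex = G * SMK * SEX).
#'
#' @param A,B `relmat` objects with identical sample ids in identical order.
#' @param C optional third `relmat` for three-way interactions.
#' @return A `relmat` of kind `"PRODUCT"`.
#' @export
hadamard <- function(A, B, C = NULL) {
  stopifnot(inherits(A, "relmat"), inherits(B, "relmat"))
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  check_same_samples(A, B)
  out <- unclass(A) * unclass(B)
  kinds <- c(attr(A, "kind"), attr(B, "kind"))
  if (!is.null(C)) {
    stopifnot(inherits(C, "relmat"))
    if (!all(dim(A) == dim(C))) stop("dimension mismatch")
    check_same_samples(A, C)
    out <- out * unclass(C)
    kinds <- c(kinds, attr(C, "kind"))
  }
  relationship_matrix(out, rownames(A), kind = "PRODUCT",
                      provenance = paste(kinds, collapse = " o "))
}

#' Omics (methylation) relationship matrix by iterative standardization
#'
#' Alternately standardizes probes (columns) and individuals (rows) to mean
#' 0 / variance 1 (population, `1/n`, denominators) until the largest
#' absolute cell change within a half-sweep falls below `tol`
#' or `max_iter` sweeps are reached, then returns `M = W W' / c` on the
#' converged matrix `W` with `c` probes.  Zero-variance probes are dropped
#' with a warning before iterating.
#'
#' @param methyl numeric matrix, individuals x probes (e.g. residualized
#'   methylation M-values); missing cells are mean-imputed per probe.
#' @param tol convergence tolerance on the max absolute cell change
#'   (default 1e-8).
#' @param max_iter maximum number of sweeps (default 100).
#' @return A `relmat` of kind `"ORM"`; attribute `iterations` records the
#'   number of sweeps used and `W` the converged standardized matrix.
#' @export
compute_orm <- function(methyl, tol = 1e-8, max_iter = 100) {
  W <- as.matrix(methyl)
  if (ncol(W) < 2) stop("at least two probes are required")
  if (anyNA(W)) {
    mu <- colMeans(W, na.rm = TRUE)
    idx <- which(is.na(W), arr.ind = TRUE)
    W[idx] <- mu[idx[, 2]]
  }
  v <- apply(W, 2, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance probe(s) dropped")
    W <- W[, v > 0, drop = FALSE]
    if (ncol(W) < 2) stop("fewer than two probes left after dropping")
  }
  # population (1/n) denominators: with sample (1/(n-1)) variances a matrix
  # cannot have unit-variance rows and columns simultaneously (the total
  # sums of squares n(c-1) and c(n-1) disagree), so the sweep would never
  # reach a doubly standardized state
  std_cols <- function(A) {
    A <- sweep(A, 2, colMeans(A), "-")
    sweep(A, 2, sqrt(colMeans(A^2)), "/")
  }
  it <- 0L
  repeat {
    it <- it + 1L
    W1 <- std_cols(W)             # standardize probes
    d1 <- max(abs(W1 - W))
    W <- t(std_cols(t(W1)))       # standardize individuals
    d2 <- max(abs(W - W1))
    if (max(d1, d2) < tol || it >= max_iter) break
  }
  M <- tcrossprod(W) / ncol(W)
  ids <- rownames(methyl)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(W)))
  out <- relationship_matrix(M, ids, kind = "ORM",
                             provenance = sprintf(
                               "ORM from %d probes, %d standardization sweeps",
                               ncol(W), it))
  attr(out, "iterations") <- it
  attr(out, "W") <- W
  out
}

#' Select exposure-associated CpG sites
#'
#' Flags CpG sites confidently associated with the exposure in two
#' independent epigenome-wide association studies (p below `p_cutoff` in
#' both) and whose methylation is predominantly environmentally driven
#' (heritability strictly below `h2_cutoff`), so that the resulting
#' methylation similarity matrix captures environmental rather than genetic
#' variation.
#'
#' @param table data.frame with columns `cpg_id`, `p_study1`, `p_study2`
#'   (p-values in (0, 1]) and `h2` (heritability in \[0, 1\]).
#' @param p_cutoff association threshold, strict (default 1e-7).
#' @param h2_cutoff heritability threshold, strict (default 0.40).
#' @return The input with a logical `selected` column added; the number
#'   selected is reported via `message()`.
#' @export
select_smoking_cpgs <- function(table, p_cutoff = 1e-7, h2_cutoff = 0.40) {
  req <- c("cpg_id", "p_study1", "p_study2", "h2")
  if (!all(req %in% names(table)))
    stop("table must have columns ", paste(req, collapse = ", "))
  if (anyNA(table[c("p_study1", "p_study2", "h2")]))
    stop("p-value and h2 columns must be complete")
  table$selected <- table$p_study1 < p_cutoff &
    table$p_study2 < p_cutoff & table$h2 < h2_cutoff
  message(sum(table$selected), " of ", nrow(table), " CpG sites selected")
  table
}
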
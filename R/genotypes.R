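#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages (counted allele per variant, values
#' 0/1/2 or `NA`) with per-variant allele frequencies computed on the
#' non-missing calls.
#'
#' @param dosages numeric matrix, individuals in rows and variants in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param sample_ids character vector of individual identifiers
#'   (default: rownames).
#' @param variant_ids character vector of variant identifiers
#'   (default: colnames).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `variant_ids` and `allele_freq`.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 2), 2, 2,
#'   dimnames = list(c("a", "b"), c("rs1", "rs2"))))
#' g$allele_freq
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            variant_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_len(ncol(dosages)))
  stopifnot(length(sample_ids) == nrow(dosages),
            length(variant_ids) == ncol(dosages))
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA; found e.g. ",
         dosages[which(bad)[1]])
  storage.mode(dosages) <- "double"
  dimnames(dosages) <- list(sample_ids, variant_ids)
  af <- colMeans(dosages, na.rm = TRUE) / 2
  structure(list(dosages = dosages,
                 sample_ids = as.character(sample_ids),
                 variant_ids = as.character(variant_ids),
                 allele_freq = af),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "individuals x",
      length(x$variant_ids), "variants\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.3f%%; MAF range: %.3f-%.3f\n",
              100 * miss,
              min(pmin(x$allele_freq, 1 - x$allele_freq)),
              max(pmin(x$allele_freq, 1 - x$allele_freq))))
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic marker: conditional on the observed
#' allele counts, the probability of every possible heterozygote count is
#' enumerated and the p-value is the total probability of configurations no
#' more likely than the observed one.  The plain (non mid-p) version is
#' used, so the test is conservative but deterministic.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return Exact two-sided p-value in (0, 1].
#' @examples
#' hwe_exact_p(25, 50, 25)
#' hwe_exact_p(50, 0, 50)  # extreme heterozygote deficit
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotyped individual is required")
  # work with the rarer allele
  rare <- 2 * min(n_AA, n_aa) + n_Aa
  if (rare == 0) return(1)  # monomorphic: single configuration
  # possible heterozygote counts share the parity of the rare allele count
  h_min <- rare %% 2
  h_max <- min(rare, 2 * n - rare)
  hs <- seq.int(h_min, h_max, by = 2)
  # unnormalised probabilities by the standard two-way recurrence, started
  # at the modal heterozygote count for numerical stability
  h_mode <- round(rare * (2 * n - rare) / (2 * n))
  if ((h_mode %% 2) != (rare %% 2)) h_mode <- h_mode + 1
  h_mode <- min(max(h_mode, h_min), h_max)
  logp <- setNames(rep(NA_real_, length(hs)), hs)
  logp[as.character(h_mode)] <- 0
  hom_r <- function(h) (rare - h) / 2          # rare homozygotes
  hom_c <- function(h) n - h - (rare - h) / 2  # common homozygotes
  h <- h_mode
  while (h - 2 >= h_min) {  # going down in heterozygotes
    logp[as.character(h - 2)] <- logp[as.character(h)] +
      log(h * (h - 1)) - log(4 * (hom_r(h) + 1) * (hom_c(h) + 1))
    h <- h - 2
  }
  h <- h_mode
  while (h + 2 <= h_max) {  # going up
    logp[as.character(h + 2)] <- logp[as.character(h)] +
      log(4 * hom_r(h) * hom_c(h)) - log((h + 2) * (h + 1))
    h <- h + 2
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[as.character(n_Aa)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Genotype quality control
#'
#' Drops variants with call missingness above `max_missing`, minor allele
#' frequency below `min_maf`, or an exact Hardy-Weinberg equilibrium test
#' p-value below `hwe_alpha`.  All three filters are evaluated on the input
#' panel and the union of failures is removed.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing maximum tolerated per-variant missingness
#'   (default 0.02; variants with missingness strictly greater are dropped).
#' @param min_maf minimum minor allele frequency (default 0.05; strictly
#'   smaller is dropped).
#' @param hwe_alpha HWE exact-test significance threshold (default 1e-6;
#'   p strictly below is dropped).
#' @return A `genotype_matrix` restricted to passing variants, with an
#'   attribute `qc_counts` giving the number of variants failing each
#'   filter and the number retained.
#' @export
qc_genotypes <- function(geno, max_missing = 0.02, min_maf = 0.05,
                         hwe_alpha = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  if (nrow(d) < 2) stop("at least two individuals are required for QC")
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_exact_p(sum(x == 2, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
                sum(x == 0, na.rm = TRUE))
  }, numeric(1))
  fail_miss <- miss > max_missing
  fail_maf <- is.nan(maf) | maf < min_maf
  fail_hwe <- hwe_p < hwe_alpha
  keep <- !(fail_miss | fail_maf | fail_hwe)
  if (!any(keep)) stop("empty panel: all variants removed by QC")
  out <- genotype_matrix(d[, keep, drop = FALSE], geno$sample_ids,
                         geno$variant_ids[keep])
  attr(out, "qc_counts") <- c(missingness = sum(fail_miss),
                              maf = sum(fail_maf),
                              hwe = sum(fail_hwe),
                              retained = sum(keep))
  out
}
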
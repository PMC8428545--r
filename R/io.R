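#' Write a relationship matrix in GCTA binary GRM format
#'
#' Writes the standard triplet: `<prefix>.grm.bin` (lower triangle including
#' the diagonal, row-major, 4-byte little-endian floats),
#' `<prefix>.grm.N.bin` (per-pair marker counts, same layout and type) and
#' `<prefix>.grm.id` (tab-separated family/individual id columns).
#'
#' @param M a `relmat` (or plain symmetric matrix with rownames).
#' @param prefix output path prefix.
#' @param n_markers per-pair marker count written to `.grm.N.bin`; a scalar
#'   is recycled (default: parsed from the matrix provenance, else 1).
#' @return `prefix`, invisibly.
#' @export
write_grm_gcta <- function(M, prefix, n_markers = NULL) {
  vals <- as.matrix(M)
  n <- nrow(vals)
  ids <- rownames(vals)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(n_markers)) {
    m <- regmatches(attr(M, "provenance"),
                    regexpr("[0-9]+(?= variants)", attr(M, "provenance"),
                            perl = TRUE))
    n_markers <- if (length(m)) as.numeric(m) else 1
  }
  lt <- vals[lower.tri(vals, diag = TRUE)]
  # lower.tri() is column-major; GCTA wants row i, columns 1..i
  idx <- which(lower.tri(vals, diag = TRUE), arr.ind = TRUE)
  lt <- lt[order(idx[, "row"], idx[, "col"])]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lt), con, size = 4, endian = "little")
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(rep_len(n_markers, length(lt))), con, size = 4,
           endian = "little")
  close(con)
  write.table(data.frame(fid = ids, iid = ids),
              paste0(prefix, ".grm.id"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM
#'
#' @param prefix path prefix of the `.grm.bin` / `.grm.N.bin` / `.grm.id`
#'   triplet.
#' @param kind kind tag for the returned `relmat` (default `"G"`).
#' @return A `relmat`; attribute `n_markers` carries the per-pair counts.
#' @export
read_grm_gcta <- function(prefix, kind = "G") {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    colClasses = "character")
  n <- nrow(ids)
  n_pairs <- n * (n + 1) / 2
  bin <- paste0(prefix, ".grm.bin")
  sz <- file.info(bin)$size
  if (is.na(sz) || sz != 4 * n_pairs)
    stop(sprintf("size mismatch: %s has %s bytes but %d ids imply %d",
                 bin, sz, n, 4 * n_pairs))
  con <- file(bin, "rb")
  lt <- readBin(con, "numeric", n = n_pairs, size = 4, endian = "little")
  close(con)
  nb <- paste0(prefix, ".grm.N.bin")
  nm <- if (file.exists(nb)) {
    con <- file(nb, "rb")
    on.exit(close(con))
    readBin(con, "numeric", n = n_pairs, size = 4, endian = "little")
  } else rep(NA_real_, n_pairs)
  vals <- matrix(0, n, n)
  k <- 0L
  for (i in seq_len(n)) {
    vals[i, 1:i] <- lt[(k + 1):(k + i)]
    k <- k + i
  }
  vals <- vals + t(vals) - diag(diag(vals))
  out <- relationship_matrix(vals, ids[[2]], kind = kind,
                             provenance = paste("read from", prefix))
  attr(out, "n_markers") <- nm
  out
}

#' Write / read plain-text dosage matrices
#'
#' Tab-separated dialect: header row of variant ids with a leading
#' `sample_id` column; one row per individual; missing calls written as
#' `NA`.  The round trip is lossless for 0/1/2/`NA` dosages.
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv()`: `path` invisibly; `read_dosage_tsv()`:
#'   a `genotype_matrix`.
#' @export
write_dosage_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(sample_id = geno$sample_ids, geno$dosages,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = c("character", rep(NA, -1 + length(
                     strsplit(readLines(path, n = 1), "\t")[[1]]))))
  d <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  genotype_matrix(d, sample_ids = df[[1]], variant_ids = colnames(df)[-1])
}

#' Write / read PLINK binary genotype files
#'
#' SNP-major `.bed` (magic bytes `0x6c 0x1b 0x01`) with companion `.bim`
#' and `.fam` files.  Dosages count the A1 allele: the two-bit codes 00,
#' 10, 11 and 01 map to dosage 2, 1, 0 and missing respectively.  Variant
#' positions and alleles not represented internally are written as
#' placeholders (`chr 1`, position = variant index, alleles `A`/`B`).
#'
#' @param geno a [genotype_matrix()].
#' @param prefix file path prefix.
#' @return `write_plink()`: `prefix` invisibly; `read_plink()`: a
#'   `genotype_matrix`.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosages
  n <- nrow(d)
  m <- ncol(d)
  fam <- data.frame(fid = geno$sample_ids, iid = geno$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = 1, id = geno$variant_ids, cm = 0,
                    pos = seq_len(m), a1 = "A", a2 = "B")
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # dosage -> two-bit code: 2->00, 1->10, 0->11, NA->01
  code <- matrix(1L, n, m)
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L
  n_bytes <- ceiling(n / 4)
  padded <- matrix(0L, n_bytes * 4, m)
  padded[seq_len(n), ] <- code
  mult <- 4L^(0:3)
  bytes <- vapply(seq_len(m), function(j) {
    cj <- matrix(padded[, j], nrow = 4)
    as.integer(colSums(cj * mult))
  }, integer(n_bytes))
  con <- file(paste0(prefix, ".bed"), "wb")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  close(con)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  fam <- read.table(paste0(prefix, ".fam"), colClasses = "character")
  bim <- read.table(paste0(prefix, ".bim"), colClasses = "character")
  n <- nrow(fam)
  m <- nrow(bim)
  n_bytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file")
  raw <- readBin(con, "raw", n_bytes * m)
  if (length(raw) != n_bytes * m) stop("truncated .bed file")
  b <- as.integer(raw)
  # unpack the four two-bit fields of every byte, low bits first
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, b %/% 64L)
  codes <- matrix(codes, nrow = 4 * n_bytes)[seq_len(n), , drop = FALSE]
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  d <- matrix(lookup[codes + 1], n, m)
  genotype_matrix(d, sample_ids = fam[[2]], variant_ids = bim[[2]])
}
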
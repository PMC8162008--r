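# MAF filtering and VanRaden (method 1) genomic relationship matrix.

#' Remove markers below a minor-allele-frequency cutoff
#'
#' Allele frequency is `mean(dosage) / 2` per marker; a marker is removed when
#' `min(p, 1 - p)` is strictly below `min_maf` (a marker at exactly the cutoff
#' is retained).
#'
#' @param geno a [genotype_matrix()].
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return the filtered [genotype_matrix()].
#' @export
maf_filter <- function(geno, min_maf = 0.05) {
  p <- colMeans(geno$dosages) / 2
  keep <- pmin(p, 1 - p) >= min_maf
  if (!any(keep)) stop("all markers removed by the MAF filter", call. = FALSE)
  geno$dosages <- geno$dosages[, keep, drop = FALSE]
  geno$markers <- geno$markers[keep, , drop = FALSE]
  rownames(geno$markers) <- NULL
  geno
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' With observed allele frequencies `p`, `W = dosages - 2p` per marker and
#' `K = W W' / (2 * sum(p * (1 - p)))`. The result is symmetrized and any
#' negative eigenvalues (numerical noise or rank deficiency) are clipped at
#' zero so the spectral REML solver downstream receives a positive
#' semidefinite matrix.
#'
#' @param geno a [genotype_matrix()] (apply [maf_filter()] first).
#' @return a `grm`: list with `K` (genotypes x genotypes) and `genotype_ids`.
#' @export
compute_grm <- function(geno) {
  X <- geno$dosages
  if (nrow(X) < 2L) stop("need at least two genotypes", call. = FALSE)
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic: GRM denominator is zero",
                       call. = FALSE)
  W <- sweep(X, 2L, 2 * p)
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 0) {
    lam <- pmax(ev$values, 0)
    K <- ev$vectors %*% (lam * t(ev$vectors))
    K <- (K + t(K)) / 2
  }
  dimnames(K) <- list(geno$genotype_ids, geno$genotype_ids)
  structure(list(K = K, genotype_ids = geno$genotype_ids), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d genotypes (mean diagonal %.3f)\n",
              length(x$genotype_ids), mean(diag(x$K))))
  invisible(x)
}

#' Write a GRM as a square TSV with genotype ids as header
#' @param grm a [compute_grm()] result.
#' @param path output path.
#' @export
write_grm <- function(grm, path) {
  out <- cbind(genotype_id = grm$genotype_ids, as.data.frame(grm$K))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a GRM written by [write_grm()]
#' @param path input path.
#' @return a `grm` object.
#' @export
read_grm <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ids <- as.character(dt[[1L]])
  K <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, genotype_ids = ids), class = "grm")
}
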
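# Population-structure adjustment: PCA of the (column-centered, unscaled)
# dosage matrix, then per-stratum OLS residualization of expression on the top
# principal components. Strata are condition x replicate, so replicate
# structure survives for the downstream mixed models.

#' Principal components of the genotype dosage matrix
#'
#' Markers are centered by their mean dosage but not variance-scaled, the
#' usual convention for population-structure PCA. Component signs are fixed
#' deterministically: the score of largest magnitude on each component is
#' positive.
#'
#' @param geno a [genotype_matrix()].
#' @param k number of components to return
#'   (`k <= min(n_genotypes - 1, n_markers)`).
#' @return a `pca_result`: list with `scores` (genotypes x k),
#'   `variance_explained` (length k, proportions of total dosage variance) and
#'   `genotype_ids`.
#' @export
genotype_pca <- function(geno, k = 3L) {
  X <- geno$dosages
  n <- nrow(X)
  if (k > min(n - 1L, ncol(X))) {
    stop("k exceeds min(n_genotypes - 1, n_markers)", call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(Xc) < 1e-12)) stop("genotype matrix is constant: no variance",
                                 call. = FALSE)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- geno$genotype_ids
  structure(list(scores = scores,
                 variance_explained = pc$sdev[seq_len(k)]^2 / total,
                 genotype_ids = geno$genotype_ids),
            class = "pca_result")
}

#' Remove subpopulation structure from expression by PC residualization
#'
#' For each gene and each condition x replicate stratum, the unmasked log2
#' TPM values are regressed by OLS on an intercept plus the top `k` genotype
#' principal components; the residuals replace the values. Masked cells never
#' enter a fit and the mask is unchanged. Strata with fewer than `k + 2`
#' unmasked samples get undefined (NA) residuals with a warning.
#'
#' @param expr an [expression_matrix()].
#' @param pca a [genotype_pca()] result covering every genotype in `expr`.
#' @param k number of components to regress out (default 3).
#' @return an `expression_matrix` holding residuals; the `tpm` element is
#'   dropped (residuals are not TPM).
#' @export
residualize_expression <- function(expr, pca, k = 3L) {
  if (k > ncol(pca$scores)) stop("pca holds fewer than k components", call. = FALSE)
  miss <- setdiff(unique(expr$samples$genotype_id), pca$genotype_ids)
  if (length(miss)) {
    stop("genotype(s) without PC scores: ", paste(head(miss, 5L), collapse = ", "),
         call. = FALSE)
  }
  V <- expr$values
  out <- V
  pcs <- pca$scores[, seq_len(k), drop = FALSE]
  strata <- interaction(expr$samples$condition, expr$samples$replicate, drop = TRUE)
  n_bad <- 0L
  for (s in levels(strata)) {
    cols <- which(strata == s)
    X <- cbind(1, pcs[expr$samples$genotype_id[cols], , drop = FALSE])
    Ys <- V[, cols, drop = FALSE]
    complete <- !rowSums(is.na(Ys))
    if (any(complete)) {
      qr_x <- qr(X)
      Yc <- t(Ys[complete, , drop = FALSE])
      out[complete, cols] <- t(qr.resid(qr_x, Yc))
    }
    for (g in which(!complete)) {
      ok <- !is.na(Ys[g, ])
      if (sum(ok) >= k + 2L) {
        fit <- lm.fit(X[ok, , drop = FALSE], Ys[g, ok])
        out[g, cols[ok]] <- fit$residuals
      } else {
        out[g, cols] <- NA_real_
        n_bad <- n_bad + 1L
      }
    }
  }
  if (n_bad > 0L) {
    warning(n_bad, " gene-stratum fit(s) had fewer than k + 2 unmasked samples; ",
            "their residuals are undefined", call. = FALSE)
  }
  res <- expr
  res$values <- out
  res$tpm <- NULL
  res
}
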
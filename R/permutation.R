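# Permutation null for heritability significance. Expression values are
# shuffled across all of a condition's samples, which breaks both the
# genotype-kinship association and the replicate pairing; a shuffled vector
# carries no genetic signal, so the resulting h2 distribution is the
# estimator's null. A genotype-label permutation that keeps replicate pairs
# intact is available as an option, but it is not a null for the single-step
# estimator: replicate correlation survives the relabelling, so permuted
# heritable genes keep high h2. One pooled null is built across genes, and
# the (1 - alpha) empirical quantile is the significance threshold.

#' Build a permutation null distribution for single-step GREML h2
#'
#' Each iteration samples a gene (and condition) uniformly at random with
#' replacement, shuffles that gene's expression values across the condition's
#' samples, and re-estimates the single-step GREML heritability. Only genes
#' with no masked cells are used (genes entering the heritability analysis
#' are below 5% missingness, so this loses almost nothing and lets one
#' spectral decomposition serve every iteration).
#'
#' @param expr a structure-adjusted [expression_matrix()].
#' @param K a `grm` aligned with `expr`'s genotypes.
#' @param n_iterations number of permutations (default 40000).
#' @param alpha type-I error rate for the threshold (default 0.01).
#' @param seed integer seed; required so the null is reproducible.
#' @param conditions conditions to sample from.
#' @param shuffle `"samples"` (default) shuffles all of a condition's values
#'   independently, which removes every source of genetic signal and is the
#'   estimator's null; `"genotype_pairs"` permutes genotype labels with
#'   replicate pairs kept intact, which nulls only the kinship association
#'   while replicate correlation survives -- useful for diagnosing how much
#'   of a gene's h2 rides on pairing rather than on K, but not a
#'   significance null.
#' @return a `null_distribution`: list with `values` (h2 per iteration),
#'   `n_iterations`, `alpha`, `threshold` (type-7 empirical quantile).
#' @export
build_null <- function(expr, K, n_iterations = 40000L, alpha = 0.01, seed,
                       conditions = c("control", "salt"),
                       shuffle = c("samples", "genotype_pairs")) {
  shuffle <- match.arg(shuffle)
  if (missing(seed)) stop("a seed is required for a reproducible null",
                          call. = FALSE)
  if (n_iterations < 1000L) {
    warning("fewer than 1000 iterations: the (1 - alpha) quantile ",
            "estimate will be unstable", call. = FALSE)
  }
  complete <- rowSums(expr$mask) == 0L
  if (!any(complete)) stop("no gene with complete (unmasked) data", call. = FALSE)
  gidx <- which(complete)

  set.seed(seed)
  vals <- numeric(n_iterations)
  decs <- list(); ords <- list(); genos <- list()
  for (cond in conditions) {
    sel <- which(expr$samples$condition == cond)
    gstack <- expr$samples$genotype_id[sel]
    decs[[cond]] <- reml_decompose(K, gstack)
    ords[[cond]] <- sel
    genos[[cond]] <- gstack
  }
  pick_g <- gidx[sample.int(length(gidx), n_iterations, replace = TRUE)]
  pick_c <- conditions[sample.int(length(conditions), n_iterations, replace = TRUE)]
  for (it in seq_len(n_iterations)) {
    cond <- pick_c[it]
    sel <- ords[[cond]]
    y <- expr$values[pick_g[it], sel]
    gstack <- genos[[cond]]
    if (shuffle == "samples") {
      yp <- y[sample.int(length(y))]
    } else {
      # genotype j receives the replicate value-pair of genotype perm[j]
      byg <- split(seq_along(y), match(gstack, unique(gstack)))
      perm <- sample.int(length(byg))
      yp <- numeric(length(y))
      yp[unlist(byg, use.names = FALSE)] <-
        y[unlist(byg[perm], use.names = FALSE)]
    }
    fit <- tryCatch(.reml_fit_core(yp, decs[[cond]]),
                    exprherit_degenerate = function(e) NULL)
    vals[it] <- if (is.null(fit)) 0 else .h2_from_fit(fit)
  }
  structure(list(values = vals, n_iterations = n_iterations, alpha = alpha,
                 threshold = unname(quantile(vals, 1 - alpha, type = 7))),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "null_distribution: %d iterations, alpha = %g, threshold = %.4f\n",
    x$n_iterations, x$alpha, x$threshold))
  invisible(x)
}

HERITABILITY_CLASSES <- c("general", "control_specific", "salt_specific",
                          "not_heritable")

#' Classify genes by condition-specific heritability significance
#'
#' A gene is significant in a condition when its h2 estimate strictly exceeds
#' the permutation threshold. `general` = significant in both conditions;
#' `control_specific` / `salt_specific` = significant in exactly one;
#' otherwise `not_heritable`. A missing estimate in either condition flags the
#' gene unclassifiable (NA class).
#'
#' @param h2_control,h2_salt named numeric vectors of per-gene h2 estimates
#'   (names = gene ids), or data.frames with `gene_id` and `h2` columns.
#' @param null a [build_null()] result (its `threshold` is used), or a single
#'   numeric threshold.
#' @return data.frame of class `heritability_class_table` with `gene_id`,
#'   `h2_control`, `h2_salt`, `class`; the class counts are in the `counts`
#'   attribute.
#' @export
classify_heritability <- function(h2_control, h2_salt, null) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$h2, x$gene_id) else x
  }
  hc <- as_named(h2_control)
  hs <- as_named(h2_salt)
  genes <- union(names(hc), names(hs))
  if (is.null(genes)) stop("h2 vectors must carry gene ids as names", call. = FALSE)
  thr <- if (inherits(null, "null_distribution")) null$threshold else as.numeric(null)
  hc <- hc[genes]; hs <- hs[genes]
  sig_c <- !is.na(hc) & hc > thr
  sig_s <- !is.na(hs) & hs > thr
  cls <- ifelse(is.na(hc) | is.na(hs), NA_character_,
         ifelse(sig_c & sig_s, "general",
         ifelse(sig_c, "control_specific",
         ifelse(sig_s, "salt_specific", "not_heritable"))))
  out <- data.frame(gene_id = genes, h2_control = unname(hc),
                    h2_salt = unname(hs),
                    class = factor(cls, levels = HERITABILITY_CLASSES),
                    stringsAsFactors = FALSE)
  n_unclass <- sum(is.na(out$class))
  if (n_unclass) {
    warning(n_unclass, " gene(s) unclassifiable (missing estimate in one ",
            "condition)", call. = FALSE)
  }
  attr(out, "threshold") <- thr
  attr(out, "counts") <- table(out$class)
  class(out) <- c("heritability_class_table", "data.frame")
  out
}
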
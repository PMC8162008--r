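# Spectral restricted-maximum-likelihood variance components for the model
#   y = 1*mu + Z g + e,   g ~ N(0, sigma_g2 * K),   e ~ N(0, sigma_e2 * I).
#
# Following the efficient mixed-model (EMMA) strategy, the likelihood is
# profiled over the variance ratio lambda = sigma_g2 / sigma_e2 after a single
# eigendecomposition of the kinship term projected onto the orthogonal
# complement of the fixed-effect design. With U an orthonormal basis of that
# complement rotated to diagonalize U' Z K Z' U (eigenvalues xi) and
# eta = U' y, the restricted log-likelihood at delta = 1 / lambda is
#   l(delta) = 0.5 * [ m log(m / 2pi) - m - m log(sum eta^2 / (xi + delta))
#                      - sum log(xi + delta) ],   m = n - 1,
# with the profiled sigma_g2 = sum(eta^2 / (xi + delta)) / m and
# sigma_e2 = delta * sigma_g2. Because the decomposition depends only on
# (K, Z), it is computed once and reused across genes and permutations.

LOGLAM_BOUND <- 10       # lambda profiled over exp(-10) .. exp(10)
LOGLAM_GRID_N <- 100L

#' Precompute the spectral decomposition for a REML design
#'
#' @param K a [compute_grm()] result (or any symmetric PSD matrix with
#'   genotype ids as dimnames wrapped in a `grm`).
#' @param obs_genotype character vector: the genotype id of each observation
#'   (rows of `Z` are implied by this mapping).
#' @return a `reml_decomp` list with the rotated contrast basis, eigenvalues
#'   and bookkeeping; pass it to [reml_fit()] to skip the decomposition.
#' @export
reml_decompose <- function(K, obs_genotype) {
  stopifnot(inherits(K, "grm"))
  idx <- match(obs_genotype, K$genotype_ids)
  if (anyNA(idx)) {
    stop("observation genotype(s) not present in the GRM: ",
         paste(unique(obs_genotype[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  n <- length(idx)
  if (length(unique(idx)) < 3L) stop("need at least 3 genotypes", call. = FALSE)
  H <- K$K[idx, idx]
  evK <- eigen(K$K, symmetric = TRUE, only.values = TRUE)$values
  if (min(evK) < -1e-8 * max(abs(evK), 1)) {
    stop("K is not positive semidefinite; condition it upstream", call. = FALSE)
  }
  X <- matrix(1, n, 1L)
  U0 <- qr.Q(qr(X), complete = TRUE)[, -1L, drop = FALSE]
  A <- crossprod(U0, H %*% U0)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  structure(list(Ut = t(U0 %*% e$vectors),   # (n-1) x n
                 xi = pmax(e$values, 0),
                 m = n - 1L, n = n,
                 obs_genotype = obs_genotype),
            class = "reml_decomp")
}

.reml_restricted_ll <- function(loglam, eta2, xi, m) {
  delta <- exp(-loglam)
  s <- sum(eta2 / (xi + delta))
  0.5 * (m * log(m / (2 * pi)) - m - m * log(s) - sum(log(xi + delta)))
}

.reml_fit_core <- function(y, dec) {
  if (var(y) < 1e-12) {
    stop(structure(class = c("exprherit_degenerate", "error", "condition"),
                   list(message = "response has (numerically) zero variance",
                        call = NULL)))
  }
  eta2 <- as.vector(dec$Ut %*% y)^2
  xi <- dec$xi
  m <- dec$m
  grid <- seq(-LOGLAM_BOUND, LOGLAM_BOUND, length.out = LOGLAM_GRID_N)
  # vectorized grid evaluation
  delta <- exp(-grid)
  S1 <- vapply(delta, function(d) sum(eta2 / (xi + d)), 0)
  S2 <- vapply(delta, function(d) sum(log(xi + d)), 0)
  ll <- 0.5 * (m * log(m / (2 * pi)) - m - m * log(S1) - S2)
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, LOGLAM_GRID_N)]
  opt <- optimize(.reml_restricted_ll, c(lo, hi), maximum = TRUE,
                  eta2 = eta2, xi = xi, m = m, tol = 1e-9)
  loglam <- opt$maximum
  loglik <- opt$objective
  # snap to the boundary when the optimum sits at the edge of the search box
  at_lower <- loglam <= -LOGLAM_BOUND + 1e-6 && ll[1L] >= loglik
  at_upper <- loglam >= LOGLAM_BOUND - 1e-6 && ll[LOGLAM_GRID_N] >= loglik
  if (at_lower) { loglam <- -LOGLAM_BOUND; loglik <- ll[1L] }
  if (at_upper) { loglam <- LOGLAM_BOUND; loglik <- ll[LOGLAM_GRID_N] }
  d <- exp(-loglam)
  sigma_g2 <- sum(eta2 / (xi + d)) / m
  sigma_e2 <- d * sigma_g2
  if (at_lower) {            # lambda -> 0: no genetic variance
    sigma_e2 <- sigma_g2 * d # = total restricted variance
    sigma_g2 <- 0
  }
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, loglik = loglik,
       converged = TRUE, loglam = loglam, eta2 = eta2)
}

#' Fit the one-random-effect REML model by spectral profiling
#'
#' @param y numeric response, one value per observation.
#' @param obs_genotype genotype id per observation (defines `Z`).
#' @param K a `grm`.
#' @param decomp optional precomputed [reml_decompose()] for this design.
#' @return list with `sigma_g2`, `sigma_e2`, `loglik`, `converged`, `loglam`
#'   plus the decomposition internals used by the profile-likelihood CI.
#'   Boundary solutions are returned with `converged = TRUE` and
#'   `sigma_g2 = 0` (lambda -> 0) or `sigma_e2 ~ 0` (lambda -> infinity).
#' @export
reml_fit <- function(y, obs_genotype, K, decomp = NULL) {
  if (!all(is.finite(y))) stop("y must be finite", call. = FALSE)
  if (is.null(decomp)) decomp <- reml_decompose(K, obs_genotype)
  if (length(y) != decomp$n) stop("y length does not match the decomposition",
                                  call. = FALSE)
  fit <- .reml_fit_core(y, decomp)
  fit$decomp <- decomp
  fit
}

#' Profile-likelihood confidence interval for h2
#'
#' Inverts the restricted likelihood in the variance ratio at the chi-squared
#' (1 df) cutoff and maps the bounds to h2 = lambda / (1 + lambda), truncated
#' to `[0, 1]`. Used instead of Wald intervals because estimates frequently
#' sit on the boundary of the parameter space.
#'
#' @param fit a [reml_fit()] result.
#' @param level confidence level (default 0.95).
#' @return c(ci_low, ci_high).
#' @export
reml_profile_ci <- function(fit, level = 0.95) {
  crit <- fit$loglik - qchisq(level, 1L) / 2
  dec <- fit$decomp
  f <- function(ll) .reml_restricted_ll(ll, fit$eta2, dec$xi, dec$m) - crit
  lo <- if (fit$loglam <= -LOGLAM_BOUND + 1e-9 || f(-LOGLAM_BOUND) >= 0) {
    0
  } else {
    r <- uniroot(f, c(-LOGLAM_BOUND, fit$loglam), tol = 1e-8)
    1 / (1 + exp(-r$root))
  }
  hi <- if (fit$loglam >= LOGLAM_BOUND - 1e-9 || f(LOGLAM_BOUND) >= 0) {
    1
  } else {
    r <- uniroot(f, c(fit$loglam, LOGLAM_BOUND), tol = 1e-8)
    1 / (1 + exp(-r$root))
  }
  c(ci_low = lo, ci_high = hi)
}

.estimate_record <- function(gene_id, condition, method, h2,
                             sigma_g2 = NA_real_, sigma_e2 = NA_real_,
                             ci_low = NA_real_, ci_high = NA_real_,
                             converged = TRUE, n_genotypes_used = NA_integer_) {
  data.frame(gene_id = gene_id, condition = condition, method = method,
             h2 = h2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
             ci_low = ci_low, ci_high = ci_high, converged = converged,
             n_genotypes_used = n_genotypes_used, stringsAsFactors = FALSE)
}

.h2_from_fit <- function(fit) {
  tot <- fit$sigma_g2 + fit$sigma_e2
  if (tot <= 0) return(0)
  fit$sigma_g2 / tot
}

.replicate_pair <- function(expr, gene, condition) {
  sel <- expr$samples$condition == condition
  reps <- sort(unique(expr$samples$replicate[sel]))
  if (length(reps) < 2L) stop("need two replicates per condition", call. = FALSE)
  s1 <- sel & expr$samples$replicate == reps[1L]
  s2 <- sel & expr$samples$replicate == reps[2L]
  g1 <- expr$samples$genotype_id[s1]
  g2 <- expr$samples$genotype_id[s2]
  common <- intersect(g1, g2)
  i <- which(expr$gene_ids == gene)
  if (length(i) != 1L) stop("unknown gene id: ", gene, call. = FALSE)
  x <- expr$values[i, which(s1)[match(common, g1)]]
  y <- expr$values[i, which(s2)[match(common, g2)]]
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok], genotypes = common[ok])
}

#' Replicate repeatability as an upper bound on expression heritability
#'
#' Pearson or Spearman correlation between replicate 1 and replicate 2 values
#' across genotypes within one condition; genotype pairs with any masked
#' member are dropped. For inbred lines under controlled conditions this
#' bounds the heritability from above.
#'
#' @param expr an [expression_matrix()] (typically structure-adjusted).
#' @param gene gene id.
#' @param condition `"control"` or `"salt"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return a one-row heritability-estimate data.frame; a zero-variance
#'   replicate vector yields `h2 = NA` with `converged = FALSE` rather than
#'   an error.
#' @export
repeatability <- function(expr, gene, condition = c("control", "salt"),
                          method = c("pearson", "spearman")) {
  condition <- match.arg(condition)
  method <- match.arg(method)
  p <- .replicate_pair(expr, gene, condition)
  if (length(p$x) < 3L) stop("fewer than 3 genotypes with both replicates",
                             call. = FALSE)
  if (sd(p$x) == 0 || sd(p$y) == 0) {
    return(.estimate_record(gene, condition, paste0("repeatability_", method),
                            NA_real_, converged = FALSE,
                            n_genotypes_used = length(p$x)))
  }
  .estimate_record(gene, condition, paste0("repeatability_", method),
                   cor(p$x, p$y, method = method),
                   n_genotypes_used = length(p$x))
}

.gene_condition_obs <- function(expr, gene, condition, collapse_means) {
  sel <- which(expr$samples$condition == condition)
  i <- which(expr$gene_ids == gene)
  if (length(i) != 1L) stop("unknown gene id: ", gene, call. = FALSE)
  v <- expr$values[i, sel]
  g <- expr$samples$genotype_id[sel]
  ok <- !is.na(v)
  v <- v[ok]; g <- g[ok]
  if (collapse_means) {
    mu <- tapply(v, g, mean)
    list(y = as.vector(mu), genotype = names(mu))
  } else {
    list(y = v, genotype = g)
  }
}

.estimate_h2_greml <- function(expr, gene, condition, K, method, decomp, ci) {
  obs <- .gene_condition_obs(expr, gene, condition,
                             collapse_means = method == "greml_two_step")
  rec <- tryCatch({
    fit <- reml_fit(obs$y, obs$genotype, K, decomp = decomp)
    h2 <- .h2_from_fit(fit)
    bounds <- if (ci) reml_profile_ci(fit) else c(NA_real_, NA_real_)
    .estimate_record(gene, condition, method, h2,
                     sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                     ci_low = unname(bounds[1L]), ci_high = unname(bounds[2L]),
                     converged = fit$converged,
                     n_genotypes_used = length(unique(obs$genotype)))
  }, exprherit_degenerate = function(e) {
    .estimate_record(gene, condition, method, NA_real_, converged = FALSE,
                     n_genotypes_used = length(unique(obs$genotype)))
  })
  rec
}

#' Two-step GREML heritability of one gene's expression
#'
#' Step one averages the (unmasked) replicate values per genotype; step two
#' fits the kinship random-effect model on the genotype means (`Z = I`).
#'
#' @inheritParams repeatability
#' @param K a `grm`.
#' @param decomp optional precomputed [reml_decompose()] (complete-data
#'   designs only).
#' @param ci compute the 95% profile-likelihood CI (default TRUE).
#' @return a one-row heritability-estimate data.frame.
#' @export
estimate_h2_two_step <- function(expr, gene, condition = c("control", "salt"),
                                 K, decomp = NULL, ci = TRUE) {
  condition <- match.arg(condition)
  .estimate_h2_greml(expr, gene, condition, K, "greml_two_step", decomp, ci)
}

#' Single-step GREML heritability of one gene's expression
#'
#' All unmasked replicate observations enter the model; `Z` maps the stacked
#' observations to their genotypes, so replicate variance is part of the
#' residual component rather than being averaged away.
#'
#' @inheritParams estimate_h2_two_step
#' @return a one-row heritability-estimate data.frame.
#' @export
estimate_h2_single_step <- function(expr, gene, condition = c("control", "salt"),
                                    K, decomp = NULL, ci = TRUE) {
  condition <- match.arg(condition)
  .estimate_h2_greml(expr, gene, condition, K, "greml_single_step", decomp, ci)
}

#' Per-gene heritability table across methods and conditions
#'
#' Applies the missingness filter (genes with < `max_missing` missing values
#' across all samples enter the heritability analysis), then runs the
#' requested estimators. For complete-data genes the spectral decomposition
#' is computed once per condition and reused, which makes transcriptome-scale
#' runs cheap.
#'
#' @param expr a structure-adjusted [expression_matrix()].
#' @param K a `grm`.
#' @param methods subset of `c("repeatability_pearson", "repeatability_spearman",
#'   "greml_two_step", "greml_single_step")`.
#' @param conditions subset of `c("control", "salt")`.
#' @param max_missing missingness filter threshold (default 0.05, strict `<`).
#' @param ci compute profile CIs for the GREML methods (default FALSE; they
#'   dominate run time at transcriptome scale).
#' @param genes optional explicit gene subset (still subject to the filter).
#' @return data.frame of heritability-estimate rows.
#' @export
heritability_table <- function(expr, K,
                               methods = c("repeatability_pearson",
                                           "greml_two_step",
                                           "greml_single_step"),
                               conditions = c("control", "salt"),
                               max_missing = 0.05, ci = FALSE, genes = NULL) {
  methods <- match.arg(methods, c("repeatability_pearson",
                                  "repeatability_spearman",
                                  "greml_two_step", "greml_single_step"),
                       several.ok = TRUE)
  rate <- rowMeans(expr$mask)
  eligible <- expr$gene_ids[rate < max_missing]
  if (!is.null(genes)) eligible <- intersect(genes, eligible)
  if (!length(eligible)) stop("no gene passes the missingness filter", call. = FALSE)
  gi <- match(eligible, expr$gene_ids)
  complete <- rowSums(expr$mask[gi, , drop = FALSE]) == 0L
  out <- vector("list", 0L)
  for (cond in conditions) {
    sel <- which(expr$samples$condition == cond)
    gstack <- expr$samples$genotype_id[sel]
    gmean <- sort(unique(gstack))
    dec_single <- if ("greml_single_step" %in% methods && any(complete))
      reml_decompose(K, gstack) else NULL
    dec_two <- if ("greml_two_step" %in% methods && any(complete))
      reml_decompose(K, gmean) else NULL
    for (j in seq_along(eligible)) {
      g <- eligible[j]
      for (m in methods) {
        rec <- switch(m,
          repeatability_pearson = repeatability(expr, g, cond, "pearson"),
          repeatability_spearman = repeatability(expr, g, cond, "spearman"),
          greml_two_step = estimate_h2_two_step(
            expr, g, cond, K, decomp = if (complete[j]) dec_two, ci = ci),
          greml_single_step = estimate_h2_single_step(
            expr, g, cond, K, decomp = if (complete[j]) dec_single, ci = ci))
        out[[length(out) + 1L]] <- rec
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
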
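# Independent oracles and small fixture builders shared across the suite.

# Brute-force REML restricted log-likelihood: orthonormal contrasts of the
# intercept-only design, dense matrix algebra (solve/determinant), sigma_g2
# profiled out. Independent of the spectral solver path.
oracle_reml_ll <- function(y, H, loglam) {
  n <- length(y)
  X <- matrix(1, n, 1)
  U <- qr.Q(qr(X), complete = TRUE)[, -1, drop = FALSE]
  m <- n - 1
  yr <- crossprod(U, y)
  vapply(loglam, function(ll) {
    d <- exp(-ll)
    Vr <- crossprod(U, (H + d * diag(n)) %*% U)
    s <- drop(crossprod(yr, solve(Vr, yr)))
    sg2 <- s / m
    -0.5 * (m * log(2 * pi) + m * log(sg2) +
              as.numeric(determinant(Vr)$modulus) + m)
  }, 0)
}

# Exhaustive one-tailed hypergeometric tail via binomial coefficients,
# independent of stats::phyper.
oracle_hyper_tail <- function(k, n_salt, n_other, n_draw) {
  if (k <= 0) return(1)
  kk <- k:min(n_salt, n_draw)
  kk <- kk[n_draw - kk <= n_other]
  if (!length(kk)) return(0)
  sum(choose(n_salt, kk) * choose(n_other, n_draw - kk)) /
    choose(n_salt + n_other, n_draw)
}

random_grm <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * 2 * n), n)
  K <- tcrossprod(A) / (2 * n)
  ids <- paste0("g", seq_len(n))
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, genotype_ids = ids), class = "grm")
}

identity_grm <- function(n) {
  ids <- paste0("g", seq_len(n))
  K <- diag(n)
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, genotype_ids = ids), class = "grm")
}

# Desk-scale simulation spec used by most module tests.
tiny_spec <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_genes = 200L, n_markers = 400L,
                   hotspot_spec = list())
  do.call(simulation_spec, utils::modifyList(defaults, args))
}

# Expression TSV fixture: labels are full sample labels, tpm a matrix.
write_expr_tsv <- function(path, tpm, labels, gene_ids) {
  df <- data.frame(gene_id = gene_ids, tpm, check.names = FALSE)
  colnames(df) <- c("gene_id", labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Minimal single-sample-block VCF fixture.
write_vcf <- function(path, chrom, pos, ids, gt) {
  # gt: markers x genotypes character matrix of GT strings
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(chrom), ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  rows <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], ids[i], "A", "T", ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), path)
  path
}

# Expression matrix built directly from a TPM matrix with canonical labels.
expr_from_tpm <- function(tpm, genotypes, conditions = c("control", "salt"),
                          replicates = 1:2) {
  labs <- as.vector(outer(
    genotypes,
    as.vector(outer(conditions, replicates,
                    function(c, r) paste0("__", c, "__rep", r))),
    paste0))
  samples <- parse_sample_labels(labs)
  expression_matrix(tpm, samples, rownames(tpm))
}
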
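test_that("spectral REML equals the direct-inversion oracle", {
  set.seed(17)
  for (r in 1:20) {
    n_g <- sample(4:8, 1)
    grm <- random_grm(n_g, seed = 100 + r)
    obs <- rep(grm$genotype_ids, each = sample(1:2, 1))
    if (length(obs) < 5) obs <- c(obs, grm$genotype_ids)
    y <- rnorm(length(obs))
    Z <- outer(obs, grm$genotype_ids, "==") * 1
    H <- Z %*% grm$K %*% t(Z)
    fit <- reml_fit(y, obs, grm)
    # likelihood functions agree at the fitted optimum ...
    expect_equal(fit$loglik, oracle_reml_ll(y, H, fit$loglam),
                 tolerance = 1e-6)
    # ... and the fit is at least as good as a dense oracle grid
    grid_max <- max(oracle_reml_ll(y, H, seq(-10, 10, length.out = 400)))
    expect_gte(fit$loglik, grid_max - 1e-6)
  }
})

test_that("K = I with balanced replicates matches the one-way ANOVA estimators", {
  grm <- identity_grm(10)
  obs <- rep(grm$genotype_ids, each = 2)
  set.seed(55)
  y <- rnorm(10, 0, 2)[match(obs, grm$genotype_ids)] + rnorm(20, 0, 0.7)
  fit <- reml_fit(y, obs, grm)
  a <- stats::anova(stats::lm(y ~ factor(obs)))
  msb <- a$`Mean Sq`[1]; msw <- a$`Mean Sq`[2]
  expect_gt(msb, msw)
  expect_equal(fit$sigma_g2, (msb - msw) / 2, tolerance = 1e-6)
  expect_equal(fit$sigma_e2, msw, tolerance = 1e-6)
})

test_that("repeatability matches hand-computed correlations", {
  labs <- as.vector(vapply(paste0("G", 1:4), function(g)
    paste0(g, c("__control__rep1", "__control__rep2")), c("", "")))
  tpm <- matrix(2, 3, 8, dimnames = list(c("perfect", "anti", "partial"), labs))
  r1 <- seq(1, 8, 2); r2 <- seq(2, 8, 2)
  tpm["perfect", r1] <- 2^c(1, 2, 3, 4); tpm["perfect", r2] <- 2^c(2, 4, 6, 8)
  tpm["anti", r1] <- 2^c(1, 2, 3, 4);    tpm["anti", r2] <- 2^c(4, 3, 2, 1)
  tpm["partial", r1] <- 2^c(1, 2, 3, 4); tpm["partial", r2] <- 2^c(1, 3, 2, 4)
  expr <- expression_matrix(tpm, parse_sample_labels(labs), rownames(tpm))
  expect_equal(repeatability(expr, "perfect", "control")$h2, 1)
  expect_equal(repeatability(expr, "anti", "control")$h2, -1)
  expect_equal(repeatability(expr, "partial", "control")$h2, 0.8)
  sp <- repeatability(expr, "partial", "control", method = "spearman")
  expect_equal(sp$h2, cor(c(1, 2, 3, 4), c(1, 3, 2, 4), method = "spearman"))

  flat <- tpm; flat["partial", r1] <- 2
  expr2 <- expression_matrix(flat, parse_sample_labels(labs), rownames(flat))
  est <- repeatability(expr2, "partial", "control")
  expect_true(is.na(est$h2))
  expect_false(est$converged)
})

test_that("h2 estimates are invariant to affine rescaling of expression", {
  spec <- tiny_spec(seed = 41, n_genes = 20)
  sim <- simulate_expression(simulate_genotypes(spec),
                             simulate_gene_catalog(spec), spec)
  g <- sim$expr$gene_ids[which(rowSums(sim$expr$mask) == 0)[1]]
  e1 <- estimate_h2_single_step(sim$expr, g, "control", sim$K, ci = FALSE)
  expr2 <- sim$expr
  expr2$values <- 3.7 * expr2$values - 12
  e2 <- estimate_h2_single_step(expr2, g, "control", sim$K, ci = FALSE)
  expect_equal(e1$h2, e2$h2, tolerance = 1e-5)
})

test_that("identical replicates drive h2 to the upper boundary, converged", {
  grm <- identity_grm(12)
  labs <- as.vector(vapply(grm$genotype_ids, function(g)
    paste0(g, c("__control__rep1", "__control__rep2")), c("", "")))
  set.seed(2)
  gval <- rnorm(12, 5, 1)
  tpm <- matrix(2^rep(gval, each = 2), 1, 24,
                dimnames = list("g1", labs))
  expr <- expression_matrix(tpm, parse_sample_labels(labs), "g1")
  est <- estimate_h2_single_step(expr, "g1", "control", grm)
  expect_true(est$converged)
  expect_gt(est$h2, 0.99)
  expect_equal(est$ci_high, 1)
})

test_that("degenerate constant input is flagged, not thrown", {
  grm <- identity_grm(10)
  labs <- as.vector(vapply(grm$genotype_ids, function(g)
    paste0(g, c("__control__rep1", "__control__rep2")), c("", "")))
  tpm <- matrix(4, 1, 20, dimnames = list("g1", labs))
  expr <- expression_matrix(tpm, parse_sample_labels(labs), "g1")
  est <- estimate_h2_two_step(expr, "g1", "control", grm)
  expect_false(est$converged)
  expect_true(is.na(est$h2))
})

test_that("profile CI covers zero for most null genes", {
  spec <- tiny_spec(seed = 61, n_genes = 150,
                    class_fractions = c(constitutive = 1, mixed = 0,
                                        repressed = 0),
                    herit_fractions = c(general = 0, control_specific = 0,
                                        salt_specific = 0, not_heritable = 1))
  sim <- simulate_expression(simulate_genotypes(spec),
                             simulate_gene_catalog(spec), spec)
  comp <- sim$expr$gene_ids[rowSums(sim$expr$mask) == 0]
  comp <- comp[seq_len(min(50, length(comp)))]
  covers <- vapply(comp, function(g) {
    est <- estimate_h2_two_step(sim$expr, g, "control", sim$K)
    est$ci_low == 0
  }, TRUE)
  expect_gte(mean(covers), 0.9)
})

test_that("increasing genetic variance never decreases the median estimate", {
  grm <- random_grm(40, seed = 7)
  obs <- rep(grm$genotype_ids, each = 2)
  dec <- reml_decompose(grm, obs)
  ev <- eigen(grm$K, symmetric = TRUE)
  B <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  med <- vapply(c(0, 0.3, 0.6, 0.9), function(h2) {
    set.seed(123)
    ests <- replicate(30, {
      sg <- sqrt(h2 / (1 - h2))
      u <- as.vector(B %*% rnorm(40)) * sg
      y <- u[match(obs, grm$genotype_ids)] + rnorm(80)
      f <- reml_fit(y, obs, grm, decomp = dec)
      f$sigma_g2 / (f$sigma_g2 + f$sigma_e2)
    })
    median(ests)
  }, 0)
  expect_true(all(diff(med) >= 0))
})
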
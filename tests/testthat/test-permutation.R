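make_null_sim <- function(seed = 71, n_genes = 300) {
  spec <- tiny_spec(seed = seed, n_genes = n_genes,
                    class_fractions = c(constitutive = 1, mixed = 0,
                                        repressed = 0),
                    herit_fractions = c(general = 0, control_specific = 0,
                                        salt_specific = 0, not_heritable = 1))
  simulate_expression(simulate_genotypes(spec), simulate_gene_catalog(spec),
                      spec)
}

test_that("the permutation null is reproducible and quantile-consistent", {
  sim <- make_null_sim()
  expect_warning(n1 <- build_null(sim$expr, sim$K, n_iterations = 600,
                                  seed = 5), "unstable")
  suppressWarnings({
    n2 <- build_null(sim$expr, sim$K, n_iterations = 600, seed = 5)
    n3 <- build_null(sim$expr, sim$K, n_iterations = 600, seed = 6)
  })
  expect_identical(n1$values, n2$values)
  expect_identical(n1$threshold, n2$threshold)
  expect_false(identical(n1$values, n3$values))
  expect_equal(n1$threshold,
               unname(quantile(n1$values, 1 - n1$alpha, type = 7)))
  expect_true(all(n1$values >= 0 & n1$values <= 1))
  expect_error(build_null(sim$expr, sim$K, n_iterations = 600), "seed")
})

test_that("classification uses a strict threshold and the invariant table", {
  h2c <- c(a = 0.9, b = 0.3, c = 0.9, d = 0.1, e = NA)
  h2s <- c(a = 0.9, b = 0.3, c = 0.1, d = 0.9, e = 0.5)
  # threshold exactly 0.3: boundary genes are not significant
  expect_warning(cls <- classify_heritability(h2c, h2s, 0.3), "unclassifiable")
  got <- setNames(as.character(cls$class), cls$gene_id)
  expect_equal(got[["a"]], "general")
  expect_equal(got[["b"]], "not_heritable")      # equal to threshold
  expect_equal(got[["c"]], "control_specific")
  expect_equal(got[["d"]], "salt_specific")
  expect_true(is.na(got[["e"]]))
})

test_that("raising alpha never shrinks the significant set", {
  sim <- make_null_sim(seed = 81, n_genes = 200)
  suppressWarnings(null <- build_null(sim$expr, sim$K, n_iterations = 900,
                                      seed = 11))
  h2 <- setNames(runif(50), paste0("g", 1:50))
  thr_strict <- unname(quantile(null$values, 1 - 0.01, type = 7))
  thr_loose <- unname(quantile(null$values, 1 - 0.05, type = 7))
  sig_strict <- names(h2)[h2 > thr_strict]
  sig_loose <- names(h2)[h2 > thr_loose]
  expect_true(all(sig_strict %in% sig_loose))
})

test_that("planted salt-specific genes at h2 = 0.6 are recovered", {
  spec <- tiny_spec(seed = 91, n_genes = 360,
                    class_fractions = c(constitutive = 1, mixed = 0,
                                        repressed = 0),
                    herit_fractions = c(general = 0, control_specific = 0,
                                        salt_specific = 0.3,
                                        not_heritable = 0.7),
                    h2_grid = 0.6)
  sim <- simulate_expression(simulate_genotypes(spec),
                             simulate_gene_catalog(spec), spec)
  null <- build_null(sim$expr, sim$K, n_iterations = 2000, seed = 13)
  planted <- sim$truth$gene_id[sim$truth$herit_class == "salt_specific"]
  planted <- planted[seq_len(min(100, length(planted)))]
  ht <- heritability_table(sim$expr, sim$K, methods = "greml_single_step",
                          genes = planted)
  hc <- ht[ht$condition == "control", ]
  hs <- ht[ht$condition == "salt", ]
  cls <- classify_heritability(setNames(hc$h2, hc$gene_id),
                               setNames(hs$h2, hs$gene_id), null)
  expect_gte(mean(cls$class == "salt_specific", na.rm = TRUE), 0.8)
  # direction check: condition-specific genes are less heritable on average
  # than genes heritable in both would be -- here simply that their control
  # h2 hugs zero while salt h2 does not
  expect_lt(median(cls$h2_control), median(cls$h2_salt))
})
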
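test_that("the generator is deterministic for a fixed spec and seed", {
  spec <- tiny_spec(seed = 19, n_genes = 80)
  a <- simulate_dataset(spec)
  b <- simulate_dataset(spec)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$expr$tpm, b$expr$tpm)
  expect_identical(a$truth, b$truth)
  expect_identical(a$tracks$eigenvector$value, b$tracks$eigenvector$value)
  c <- simulate_dataset(tiny_spec(seed = 20, n_genes = 80))
  expect_false(identical(a$expr$tpm, c$expr$tpm))
})

test_that("genotype simulation respects dosage bounds, blocks and sorting", {
  spec <- tiny_spec(seed = 23)
  geno <- simulate_genotypes(spec)
  expect_true(all(geno$dosages %in% 0:2))
  expect_equal(dim(geno$dosages), c(84L, 400L))
  sub <- attr(geno, "subpop")
  expect_equal(sort(unique(sub)), 1:5)
  expect_true(all(diff(sub) >= 0))                 # near-equal blocks
  expect_true(max(table(sub)) - min(table(sub)) <= 1)
  ord <- order(geno$markers$chrom, geno$markers$pos)
  expect_identical(ord, seq_len(nrow(geno$markers)))
  expect_error(simulation_spec(subpop_divergence = 1.2), "\\(0, 1\\)")
})

test_that("realized missingness per class falls in its defining band", {
  spec <- tiny_spec(seed = 29, n_genes = 600)
  sim <- simulate_expression(simulate_genotypes(spec),
                             simulate_gene_catalog(spec), spec)
  for (cond in c("control", "salt")) {
    rate <- missing_rate(sim$expr, cond)
    cls <- if (cond == "control") sim$truth$class_control else
      sim$truth$class_salt
    in_band <- ifelse(cls == "constitutive", rate < 0.05,
               ifelse(cls == "repressed", rate > 0.95,
                      rate >= 0.05 & rate <= 0.95))
    expect_gte(mean(in_band), 0.99)
  }
  # mask is exactly the zero-TPM indicator
  expect_identical(sim$expr$mask, sim$expr$tpm == 0)
})

test_that("class fractions and heritability targets follow the spec", {
  spec <- tiny_spec(seed = 37, n_genes = 2000)
  sim <- simulate_expression(simulate_genotypes(spec),
                             simulate_gene_catalog(spec), spec)
  frac <- table(sim$truth$class_control) / 2000
  expect_equal(unname(frac["constitutive"]), 0.3, tolerance = 0.05)
  expect_equal(unname(frac["mixed"]), 0.4, tolerance = 0.05)
  expect_equal(unname(frac["repressed"]), 0.3, tolerance = 0.05)
  # target h2 values come from the grid; nulls are exactly zero
  expect_true(all(sim$truth$h2_control %in% c(0, spec$h2_grid)))
  expect_true(all(sim$truth$h2_salt %in% c(0, spec$h2_grid)))
  gen <- sim$truth$herit_class == "general"
  expect_true(all(sim$truth$h2_control[gen] == sim$truth$h2_salt[gen]))
  expect_true(all(sim$truth$h2_salt[sim$truth$herit_class ==
                                      "control_specific"] == 0))
  expect_error(simulation_spec(h2_grid = c(0.5, 1)), "\\[0, 1\\)")
})

test_that("hotspot genes are planted inside their intervals, salt-specific", {
  spec <- simulation_spec(seed = 43, n_markers = 400)   # default hotspots
  sim <- simulate_expression(simulate_genotypes(spec),
                             simulate_gene_catalog(spec), spec)
  catalog <- simulate_gene_catalog(spec)
  hs <- sim$truth[sim$truth$hotspot, ]
  expect_equal(nrow(hs), 34L)                            # 2 x 17
  expect_true(all(hs$herit_class == "salt_specific"))
  expect_true(all(hs$h2_salt == spec$hotspot_h2))
  expect_true(all(hs$h2_control == 0))
  expect_true(all(hs$class_control == "constitutive"))
  mid <- floor((catalog$start + catalog$end) / 2)
  for (h in spec$hotspot_spec) {
    inside <- catalog$gene_id[catalog$chrom == h$chrom &
                                mid >= h$start & mid <= h$end]
    expect_equal(sum(hs$gene_id %in% inside & hs$chrom == h$chrom),
                 h$n_salt_specific_genes)
  }
})

test_that("written datasets round trip through the standard-format readers", {
  spec <- tiny_spec(seed = 47, n_genes = 60)
  sim <- simulate_dataset(spec)
  d <- withr::local_tempdir()
  write_dataset(sim, d)
  expr <- read_expression(file.path(d, "expression_tpm.tsv"))
  expect_identical(expr$tpm, sim$expr$tpm)
  geno <- read_genotypes(file.path(d, "genotypes.tsv"), "tsv")
  expect_equal(geno$dosages, sim$geno$dosages, ignore_attr = TRUE)
  cat <- read_gene_catalog(file.path(d, "genes.gff3"))
  expect_equal(cat$start, sim$catalog$start)
  expect_equal(cat$gene_id, sim$catalog$gene_id)
  tr <- read_track(file.path(d, "ab_eigenvector.bedgraph"), "AB_eigenvector")
  expect_equal(tr$value, sim$tracks$eigenvector$value, tolerance = 1e-12)
  expect_equal(tr$start, sim$tracks$eigenvector$start)
})
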
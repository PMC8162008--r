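test_that("sliding windows follow the count formula and short-chromosome rule", {
  w <- make_windows(c(chrA = 10000000), window_spec(1500000, 100000))
  expect_equal(nrow(w), 86L)                   # floor((10e6-1.5e6)/1e5)+1
  expect_equal(w$start[1], 1)
  expect_equal(w$end[1], 1500000)
  expect_equal(w$end[86], 10000000)

  short <- make_windows(c(chrB = 1000000), window_spec(1500000, 100000))
  expect_equal(nrow(short), 1L)
  expect_equal(c(short$start, short$end), c(1, 1000000))

  tiling <- make_windows(c(chrA = 1000000), window_spec(200000, 200000))
  expect_equal(nrow(tiling), 5L)
  expect_true(all(tiling$start[-1] == tiling$end[-5] + 1))

  expect_error(window_spec(100, 200), "step_bp")
})

test_that("midpoint assignment counts genes in every covering window", {
  cat <- gene_catalog(data.frame(
    gene_id = c("a", "b", "c", "d"),
    chrom = "chr1",
    start = c(100, 150000, 150010, 900000),
    end = c(200, 150020, 150030, 900100)))
  w <- make_windows(c(chr1 = 1000000), window_spec(200000, 100000))
  lab <- setNames(rep("constitutive", 4), cat$gene_id)
  wt <- window_counts(w, cat, lab)
  # midpoint 150 of gene a: only window 1 covers [1, 200000]
  expect_equal(wt$n_constitutive[1], 3L)
  expect_equal(wt$n_constitutive[2], 2L)       # window [100001, 300000]
  # conservation under tiling windows
  tiles <- make_windows(c(chr1 = 1000000), window_spec(200000, 200000))
  wt2 <- window_counts(tiles, cat, lab)
  expect_equal(sum(wt2$n_constitutive), 4L)
  # unknown chromosome -> warning + exclusion
  cat2 <- gene_catalog(rbind(as.data.frame(cat),
                             data.frame(gene_id = "e", chrom = "chrX",
                                        start = 5, end = 10, strand = "*")))
  expect_warning(window_counts(w, cat2, lab), "without windows")
})

test_that("window Fisher p equals the enumeration oracle", {
  set.seed(3)
  for (r in 1:200) {
    N <- sample(2:30, 1)
    Ns <- sample.int(N, 1)
    nd <- sample.int(N, 1)
    k_range <- max(0, nd - (N - Ns)):min(Ns, nd)
    k <- k_range[sample.int(length(k_range), 1)]
    wt <- data.frame(chrom = "c", start = 1, end = 10,
                     n_heritable = nd, n_salt_specific = k)
    got <- fisher_enrichment(wt, Ns, N)$fisher_p
    expect_equal(got, oracle_hyper_tail(k, Ns, N - Ns, nd), tolerance = 1e-12)
    # cross-check against the standard exact test implementation
    ft <- stats::fisher.test(matrix(c(k, nd - k, Ns - k, (N - Ns) - (nd - k)),
                                    2), alternative = "greater")
    expect_equal(got, ft$p.value, tolerance = 1e-9)
  }
  # no heritable genes in the window: p = 1, flagged
  wt0 <- fisher_enrichment(data.frame(n_heritable = 0L, n_salt_specific = 0L),
                           10, 100)
  expect_equal(wt0$fisher_p, 1)
  expect_true(wt0$fisher_flagged)
})

test_that("bootstrap-adjusted p behaves at the extremes and near the median", {
  cat <- gene_catalog(data.frame(
    gene_id = sprintf("g%03d", 1:120), chrom = "chr1",
    start = seq(1000, by = 8000, length.out = 120),
    end = seq(1400, by = 8000, length.out = 120)))
  w <- data.frame(chrom = "chr1", start = 1, end = 240000, window_id = 1L)
  wt <- window_counts(w, cat, setNames(rep("heritable", 120), cat$gene_id))
  wt$n_heritable <- wt$n_genes_total
  nd <- wt$n_heritable[1]                      # genes inside the window
  n_salt <- 25
  # observed p worse than every achievable null p -> adjusted exactly 1
  wt$n_salt_specific <- 0L
  wt <- fisher_enrichment(wt, n_salt, 120)
  adj <- bootstrap_adjust(wt, cat, cat$gene_id, n_salt, B = 99, seed = 1)
  expect_equal(adj$adjusted_p, 1)
  # observed p at the analytic median of the null p distribution: the
  # exceedance probability is the exact hypergeometric tail, ~0.5
  k_med <- stats::qhyper(0.5, n_salt, 120 - n_salt, nd)
  wt$n_salt_specific <- k_med
  wt <- fisher_enrichment(wt, n_salt, 120)
  B <- 999
  adj <- bootstrap_adjust(wt, cat, cat$gene_id, n_salt, B = B, seed = 2)
  p_exceed <- oracle_hyper_tail(k_med, n_salt, 120 - n_salt, nd)
  expect_gt(p_exceed, 0.4); expect_lt(p_exceed, 0.75)
  se <- sqrt(p_exceed * (1 - p_exceed) / B)
  expect_lt(abs(adj$adjusted_p - (1 + B * p_exceed) / (1 + B)), 4 * se)
  expect_error(bootstrap_adjust(wt, cat, cat$gene_id, 200, B = 9, seed = 1),
               "exceeds")
})

test_that("regions merge overlapping/abutting significant windows only", {
  wt <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                   start = c(1, 100001, 3000001, 1),
                   end = c(1500000, 1600000, 4500000, 1500000),
                   significant = c(TRUE, TRUE, TRUE, FALSE))
  reg <- merge_regions(wt, step_bp = 100000)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start[1], 1)
  expect_equal(reg$end[1], 1600000)
  expect_equal(reg$n_windows, c(2L, 1L))
  expect_equal(nrow(merge_regions(transform(wt, significant = FALSE))), 0L)
})

test_that("compartment correlation is exact on a self-consistent track", {
  spec <- tiny_spec(seed = 101, n_genes = 3000)
  catalog <- simulate_gene_catalog(spec)
  sim <- simulate_expression(simulate_genotypes(spec), catalog, spec)
  cls <- setNames(sim$truth$class_control, sim$truth$gene_id)
  tr0 <- simulate_tracks(catalog, sim$truth, noise_sd = 0, seed = 9)
  cc <- compartment_correlation(catalog, cls, tr0$eigenvector,
                                method = "pearson")
  const <- cc[cc$label == "constitutive", ]
  expect_true(all(abs(const$rho - 1) < 1e-12))
  repr <- cc[cc$label == "repressed", ]
  expect_true(all(repr$rho < 0))
  # a chromosome with fewer than 5 bins is flagged unreliable
  small <- gene_catalog(data.frame(gene_id = c("x1", "x2"), chrom = "chrS",
                                   start = c(1, 900000),
                                   end = c(1000, 901000)))
  tr <- genomic_track(data.frame(chrom = "chrS", start = c(1, 500001),
                                 end = c(500000, 1000000),
                                 value = c(1, -1)), "AB_eigenvector")
  cs <- compartment_correlation(small, setNames(c("constitutive", "repressed"),
                                                c("x1", "x2")), tr)
  expect_true(all(!cs$reliable))
})
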
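# Synthetic data with the statistical structure the pipeline assumes:
# Balding-Nichols subpopulation-structured genotypes, polygenic expression
# with gene- and condition-specific heritability drawn against the very
# kinship matrix the estimators use, replicate noise, zero-inflated bimodal
# expression (constitutive / mixed / repressed), pericentromerically biased
# class placement, planted salt-specific-heritability hotspots, and a
# compartment eigenvector built from constitutive-gene density.

#' Simulation specification
#'
#' Defaults mirror the study design: 84 genotypes from 5 subpopulations,
#' 2 conditions x 2 replicates, and expression classes defined by zero-TPM
#' missingness bands. Sizes (markers, genes, chromosomes) are desk-scale.
#'
#' @param n_genotypes number of inbred genotypes (default 84).
#' @param n_subpops number of subpopulations (default 5).
#' @param n_markers number of biallelic markers (default 2000).
#' @param n_chromosomes number of chromosomes (default 4).
#' @param chromosome_length_bp length of each chromosome (default 30 Mb).
#' @param subpop_divergence Balding-Nichols F in (0, 1) (default 0.2).
#' @param n_genes number of genes (default 3000).
#' @param class_fractions named proportions for constitutive / mixed /
#'   repressed (must sum to 1).
#' @param herit_fractions named proportions of heritability categories among
#'   non-hotspot genes: general, control_specific, salt_specific,
#'   not_heritable.
#' @param h2_grid candidate target heritabilities for heritable genes (each in
#'   `[0, 1)`).
#' @param hotspot_spec list of hotspots, each
#'   `list(chrom =, start =, end =, n_salt_specific_genes =)`; hotspot genes
#'   are constitutive with `h2_salt = hotspot_h2`, `h2_control = 0`.
#' @param hotspot_h2 salt heritability of planted hotspot genes (default 0.6).
#' @param replicate_sd residual (replicate) standard deviation on the log2
#'   scale (default 0.7).
#' @param class_switch_prob probability that a gene's salt class differs from
#'   its control class (adjacent classes only; default 0.1).
#' @param track_noise_sd noise added to the standardized constitutive-density
#'   eigenvector (default 0.5).
#' @param seed integer seed.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_genotypes = 84L, n_subpops = 5L,
                            n_markers = 2000L, n_chromosomes = 4L,
                            chromosome_length_bp = 30000000L,
                            subpop_divergence = 0.2,
                            n_genes = 3000L,
                            class_fractions = c(constitutive = 0.3,
                                                mixed = 0.4,
                                                repressed = 0.3),
                            herit_fractions = c(general = 0.40,
                                                control_specific = 0.20,
                                                salt_specific = 0.08,
                                                not_heritable = 0.32),
                            h2_grid = c(0.3, 0.5, 0.7),
                            hotspot_spec = list(
                              list(chrom = "chr1", start = 10000001,
                                   end = 11500000, n_salt_specific_genes = 17L),
                              list(chrom = "chr3", start = 20000001,
                                   end = 21500000, n_salt_specific_genes = 17L)),
                            hotspot_h2 = 0.6,
                            replicate_sd = 0.7,
                            class_switch_prob = 0.1,
                            track_noise_sd = 0.5,
                            seed = 1L) {
  if (!(subpop_divergence > 0 && subpop_divergence < 1)) {
    stop("subpop_divergence must lie in (0, 1)", call. = FALSE)
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  if (abs(sum(herit_fractions) - 1) > 1e-8) {
    stop("herit_fractions must sum to 1", call. = FALSE)
  }
  if (any(c(h2_grid, hotspot_h2) < 0) || any(c(h2_grid, hotspot_h2) >= 1)) {
    stop("target heritabilities must lie in [0, 1)", call. = FALSE)
  }
  for (h in hotspot_spec) {
    if (h$start < 1 || h$end > chromosome_length_bp || h$start >= h$end) {
      stop("hotspot interval outside chromosome bounds", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "simulation_spec")
}

.sim_chrom_names <- function(spec) paste0("chr", seq_len(spec$n_chromosomes))

#' Simulate subpopulation-structured genotypes (Balding-Nichols)
#'
#' Ancestral allele frequency per marker is Uniform(0.1, 0.9); each
#' subpopulation's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) with
#' F = `subpop_divergence`; dosages are Binomial(2, p_subpop). Genotypes are
#' assigned to subpopulations in near-equal blocks; markers are placed
#' uniformly at random along the chromosomes and sorted.
#'
#' @param spec a [simulation_spec()].
#' @return a [genotype_matrix()] with a `subpop` attribute.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  F <- spec$subpop_divergence
  m <- spec$n_markers
  n <- spec$n_genotypes
  p_anc <- runif(m, 0.1, 0.9)
  subpop <- rep(seq_len(spec$n_subpops), length.out = n)
  subpop <- sort(subpop)                       # near-equal blocks
  pf <- matrix(0, spec$n_subpops, m)
  for (s in seq_len(spec$n_subpops)) {
    pf[s, ] <- rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  dos <- matrix(0, n, m)
  for (i in seq_len(n)) dos[i, ] <- rbinom(m, 2L, pf[subpop[i], ])
  chrom <- sample(.sim_chrom_names(spec), m, replace = TRUE)
  pos <- sample.int(spec$chromosome_length_bp, m, replace = TRUE)
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  dos <- dos[, ord, drop = FALSE]
  markers <- data.frame(marker_id = sprintf("m%06d", seq_len(m)),
                        chrom = chrom, pos = pos, stringsAsFactors = FALSE)
  rownames(dos) <- sprintf("G%03d", seq_len(n))
  g <- genotype_matrix(dos, markers)
  attr(g, "subpop") <- setNames(subpop, rownames(dos))
  g
}

#' Simulate a gene catalog
#'
#' Genes are spread near-equally across chromosomes with uniform start
#' positions and log-normal lengths (median ~3 kb).
#'
#' @param spec a [simulation_spec()].
#' @return a [gene_catalog()].
#' @export
simulate_gene_catalog <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_genes
  chrom <- sort(rep(.sim_chrom_names(spec), length.out = n))
  len <- pmin(pmax(round(rlnorm(n, log(3000), 0.5)), 200L), 20000L)
  start <- vapply(len, function(l)
    sample.int(spec$chromosome_length_bp - l, 1L), 1L)
  df <- data.frame(gene_id = "", chrom = chrom, start = start,
                   end = start + len - 1L,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), ]
  df$gene_id <- sprintf("gene%05d", seq_len(n))
  gene_catalog(df)
}

# pericentromeric tilt: class weights as a function of relative chromosome
# position; multipliers average to 1 over a uniform position so genome-wide
# class fractions match the spec.
.class_probs_at <- function(centrality, fractions) {
  w <- c(constitutive = fractions[["constitutive"]] * (1.6 - 1.2 * centrality),
         mixed = fractions[["mixed"]],
         repressed = fractions[["repressed"]] * (0.4 + 1.2 * centrality))
  w / sum(w)
}

.p0_for_class <- function(cls) {
  switch(cls,
         constitutive = runif(1, 0, 0.01),
         mixed = runif(1, 0.15, 0.85),
         repressed = runif(1, 0.985, 1))
}

.mu_for_class <- function(cls) {
  switch(cls,
         constitutive = rnorm(1, 4, 1),
         mixed = rnorm(1, -2, 0.8),
         repressed = rnorm(1, -3, 0.8))
}

#' Simulate zero-inflated, polygenic expression with known ground truth
#'
#' For each gene and condition, a genetic value `u ~ N(0, sigma_g2 * K)` is
#' drawn against the VanRaden kinship of the (MAF-filtered) simulated
#' genotypes, and each replicate observes `mu_class + u + e` with
#' `e ~ N(0, replicate_sd^2)`; the variance components are scaled so
#' `sigma_g2 / (sigma_g2 + sigma_e2)` equals the gene's target h2 in that
#' condition. Expression classes are assigned with a pericentromeric tilt
#' (constitutive genes favour chromosome arms, repressed genes the center),
#' zero-inflation is applied after the latent draw (zeros overwrite, so the
#' mask contract is exercised), and genes inside hotspot intervals are forced
#' constitutive with salt-only heritability.
#'
#' @param geno a [simulate_genotypes()] result.
#' @param catalog a [simulate_gene_catalog()] result on the same chromosomes.
#' @param spec the same [simulation_spec()].
#' @return list with `expr` (an [expression_matrix()] of raw-TPM-backed log2
#'   values), `truth` (per-gene classes, target h2 per condition, heritability
#'   category, hotspot flag) and `K` (the `grm` used to draw genetic values).
#' @export
simulate_expression <- function(geno, catalog, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!all(catalog$chrom %in% .sim_chrom_names(spec))) {
    stop("catalog genes lie off the simulated chromosomes", call. = FALSE)
  }
  set.seed(spec$seed + 2L)
  K <- compute_grm(maf_filter(geno))
  n_g <- length(K$genotype_ids)
  ev <- eigen(K$K, symmetric = TRUE)
  B <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  n_genes <- nrow(catalog)

  # class per condition, tilted by chromosome position
  mid <- .gene_midpoints(catalog)
  relpos <- mid / spec$chromosome_length_bp
  centrality <- 1 - abs(2 * relpos - 1)
  cls_control <- character(n_genes)
  for (i in seq_len(n_genes)) {
    cls_control[i] <- sample(EXPRESSION_CLASSES, 1L,
                             prob = .class_probs_at(centrality[i],
                                                    spec$class_fractions))
  }
  cls_salt <- cls_control
  switch_it <- runif(n_genes) < spec$class_switch_prob
  for (i in which(switch_it)) {
    cls_salt[i] <- switch(cls_control[i],
                          constitutive = "mixed",
                          repressed = "mixed",
                          mixed = sample(c("constitutive", "repressed"), 1L))
  }

  # heritability categories; hotspot genes are forced salt-specific
  herit <- sample(names(spec$herit_fractions), n_genes, replace = TRUE,
                  prob = spec$herit_fractions)
  hotspot <- logical(n_genes)
  for (h in spec$hotspot_spec) {
    inside <- which(catalog$chrom == h$chrom &
                      mid >= h$start & mid <= h$end & !hotspot)
    if (length(inside) < h$n_salt_specific_genes) {
      stop("hotspot on ", h$chrom, " contains only ", length(inside),
           " genes; cannot plant ", h$n_salt_specific_genes, call. = FALSE)
    }
    chosen <- sample(inside, h$n_salt_specific_genes)
    hotspot[chosen] <- TRUE
    herit[chosen] <- "salt_specific"
    cls_control[chosen] <- cls_salt[chosen] <- "constitutive"
  }

  h2_pick <- sample(spec$h2_grid, n_genes, replace = TRUE)
  h2_pick[hotspot] <- spec$hotspot_h2
  h2_control <- ifelse(herit %in% c("general", "control_specific"), h2_pick, 0)
  h2_salt <- ifelse(herit %in% c("general", "salt_specific"), h2_pick, 0)

  samples <- expand.grid(replicate = 1:2, genotype_id = K$genotype_ids,
                         condition = CONDITIONS, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  samples <- samples[, c("genotype_id", "condition", "replicate")]
  samples$sample_id <- sprintf("%s__%s__rep%d", samples$genotype_id,
                               samples$condition, samples$replicate)
  tpm <- matrix(0, n_genes, nrow(samples),
                dimnames = list(catalog$gene_id, samples$sample_id))
  sigma_e <- spec$replicate_sd
  for (cond in CONDITIONS) {
    cols <- which(samples$condition == cond)
    gidx <- match(samples$genotype_id[cols], K$genotype_ids)
    h2 <- if (cond == "control") h2_control else h2_salt
    cls <- if (cond == "control") cls_control else cls_salt
    sg <- sqrt(h2 / (1 - h2)) * sigma_e            # per-gene genetic sd scale
    U <- B %*% matrix(rnorm(n_g * n_genes), n_g)   # columns ~ N(0, K)
    mu <- vapply(cls, .mu_for_class, 0)
    lat <- matrix(mu, n_genes, length(cols)) +
      t(U[gidx, , drop = FALSE] * rep(sg, each = length(cols))) +
      matrix(rnorm(n_genes * length(cols), 0, sigma_e), n_genes)
    p0 <- vapply(cls, .p0_for_class, 0)
    zero <- matrix(runif(n_genes * length(cols)), n_genes) < p0
    vals <- 2^lat
    vals[zero] <- 0
    tpm[, cols] <- vals
  }
  expr <- expression_matrix(tpm, samples, catalog$gene_id)
  truth <- data.frame(gene_id = catalog$gene_id,
                      chrom = catalog$chrom,
                      class_control = cls_control, class_salt = cls_salt,
                      h2_control = h2_control, h2_salt = h2_salt,
                      herit_class = herit, hotspot = hotspot,
                      stringsAsFactors = FALSE)
  list(expr = expr, truth = truth, K = K)
}

#' Simulate A/B eigenvector and pericentromere tracks
#'
#' The eigenvector per fixed bin is the standardized constitutive-gene density
#' (control-condition truth class) plus Gaussian noise; positive values mean
#' the A compartment. The pericentromere track marks the central 20% of each
#' chromosome, where the class tilt concentrates repressed genes.
#'
#' @param catalog a [gene_catalog()].
#' @param truth the truth table from [simulate_expression()].
#' @param bin_bp bin width (default 500 kb).
#' @param noise_sd noise standard deviation (on the standardized density
#'   scale).
#' @param seed integer seed.
#' @return list with `eigenvector` and `pericentromere` [genomic_track()]s.
#' @export
simulate_tracks <- function(catalog, truth, bin_bp = 500000L,
                            noise_sd = 0.5, seed = 1L) {
  if (!nrow(catalog)) stop("empty gene catalog", call. = FALSE)
  stopifnot(bin_bp > 0)
  set.seed(seed)
  mid <- .gene_midpoints(catalog)
  is_const <- truth$class_control[match(catalog$gene_id, truth$gene_id)] ==
    "constitutive"
  ev_rows <- list(); peri_rows <- list()
  for (ch in unique(catalog$chrom)) {
    L <- max(catalog$end[catalog$chrom == ch])
    n_bins <- ceiling(L / bin_bp)
    gm <- mid[catalog$chrom == ch & is_const]
    counts <- tabulate(pmin(n_bins, ceiling(gm / bin_bp)), nbins = n_bins)
    z <- if (sd(counts) > 0) (counts - mean(counts)) / sd(counts) else counts * 0
    value <- z + rnorm(n_bins, 0, noise_sd)
    ev_rows[[ch]] <- data.frame(
      chrom = ch, start = (seq_len(n_bins) - 1) * bin_bp + 1,
      end = seq_len(n_bins) * bin_bp, value = value)
    peri_rows[[ch]] <- data.frame(chrom = ch,
                                  start = floor(0.4 * L) + 1,
                                  end = floor(0.6 * L), value = 1.0)
  }
  list(eigenvector = genomic_track(do.call(rbind, ev_rows),
                                   label = "AB_eigenvector"),
       pericentromere = genomic_track(do.call(rbind, peri_rows),
                                      label = "pericentromere"))
}

#' Simulate a complete dataset
#'
#' @param spec a [simulation_spec()].
#' @return list with `geno`, `catalog`, `expr`, `truth`, `K`, `tracks`.
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  geno <- simulate_genotypes(spec)
  catalog <- simulate_gene_catalog(spec)
  se <- simulate_expression(geno, catalog, spec)
  tracks <- simulate_tracks(catalog, se$truth, noise_sd = spec$track_noise_sd,
                            seed = spec$seed + 3L)
  list(geno = geno, catalog = catalog, expr = se$expr, truth = se$truth,
       K = se$K, tracks = tracks)
}

#' Write a simulated dataset to a directory of standard-format files
#'
#' Emits expression TSV (raw TPM), genotype TSV, gene GFF3, eigenvector
#' bedGraph, pericentromere BED-like bedGraph, and the truth table TSV.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression_tpm.tsv"))
  write_genotypes(sim$geno, file.path(dir, "genotypes.tsv"))
  write_gene_catalog(sim$catalog, file.path(dir, "genes.gff3"))
  write_track(sim$tracks$eigenvector, file.path(dir, "ab_eigenvector.bedgraph"))
  write_track(sim$tracks$pericentromere, file.path(dir, "pericentromere.bedgraph"))
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  invisible(dir)
}
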
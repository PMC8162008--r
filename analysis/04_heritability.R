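# Per-gene heritability of structure-adjusted expression, per condition, by
# three estimators: replicate repeatability (Pearson), two-step GREML on
# genotype means, and single-step GREML with replicates in the model.
# Genes with < 5% missing values across all samples enter the analysis.

source("analysis/00_config.R")

expr <- read_expression(file.path(DATA_DIR, "expression_tpm.tsv"))
geno <- maf_filter(read_genotypes(file.path(DATA_DIR, "genotypes.tsv"), "tsv"))
pca <- genotype_pca(geno, k = 3)
adjusted <- suppressWarnings(residualize_expression(expr, pca, k = 3))
K <- read_grm(file.path(OUT_DIR, "grm.tsv"))

t0 <- Sys.time()
h2 <- heritability_table(
  adjusted, K,
  methods = c("repeatability_pearson", "greml_two_step", "greml_single_step"),
  conditions = c("control", "salt"))
cat("estimated", nrow(h2), "gene x condition x method records in",
    round(difftime(Sys.time(), t0, units = "secs")), "s\n")
data.table::fwrite(h2, file.path(OUT_DIR, "heritability.tsv"), sep = "\t")

# method agreement (control condition), as a pairwise correlation table
ctl <- h2[h2$condition == "control", ]
wide <- Reduce(function(a, b) merge(a, b, by = "gene_id"),
               lapply(split(ctl, ctl$method), function(d)
                 stats::setNames(d[, c("gene_id", "h2")],
                                 c("gene_id", d$method[1]))))
cm <- cor(wide[, -1], use = "pairwise.complete.obs", method = "spearman")
cat("method correlations (Spearman, control):\n")
print(round(cm, 3))

truth <- data.table::fread(file.path(DATA_DIR, "truth.tsv"), data.table = FALSE)
ss <- ctl[ctl$method == "greml_single_step", ]
tr <- truth$h2_control[match(ss$gene_id, truth$gene_id)]
cat("cor(single-step estimate, true h2), control:",
    round(cor(ss$h2, tr, use = "complete.obs"), 3), "\n")
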
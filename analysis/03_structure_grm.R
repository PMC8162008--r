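# Population-structure adjustment and kinship. Genotype PCA (top 3
# components of the centered dosage matrix), per-stratum OLS residualization
# of expression, MAF >= 5% marker filter, and the VanRaden GRM.

source("analysis/00_config.R")

expr <- read_expression(file.path(DATA_DIR, "expression_tpm.tsv"))
geno <- read_genotypes(file.path(DATA_DIR, "genotypes.tsv"), "tsv")

geno_f <- maf_filter(geno, 0.05)
cat("markers:", ncol(geno$dosages), "->", ncol(geno_f$dosages),
    "after MAF filter\n")

pca <- genotype_pca(geno_f, k = 10)
cat("top-3 PC variance share:",
    round(100 * sum(pca$variance_explained[1:3]), 1), "%\n")
data.table::fwrite(
  cbind(data.frame(genotype_id = pca$genotype_ids), as.data.frame(pca$scores)),
  file.path(OUT_DIR, "pca_scores.tsv"), sep = "\t")
data.table::fwrite(
  data.frame(component = seq_along(pca$variance_explained),
             variance_explained = pca$variance_explained),
  file.path(OUT_DIR, "pca_variance.tsv"), sep = "\t")

adjusted <- residualize_expression(expr, pca, k = 3)
vals <- cbind(data.frame(gene_id = adjusted$gene_ids),
              as.data.frame(adjusted$values))
data.table::fwrite(vals, file.path(OUT_DIR, "expression_adjusted.tsv"),
                   sep = "\t")

K <- compute_grm(geno_f)
print(K)
write_grm(K, file.path(OUT_DIR, "grm.tsv"))
cat("wrote adjusted expression, PCA tables and GRM under", OUT_DIR, "\n")
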
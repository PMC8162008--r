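# Chromosome scans. First the expression-class density profile (3 Mb sliding
# windows at 100 kb steps), then the salt-specific heritability enrichment
# scan (1.5 Mb windows, one-tailed Fisher tests, bootstrap-adjusted p-values,
# alpha = 0.001) with merging of significant windows into regions.

source("analysis/00_config.R")

catalog <- read_gene_catalog(file.path(DATA_DIR, "genes.gff3"))
classes <- data.table::fread(file.path(OUT_DIR, "expression_classes.tsv"),
                             data.table = FALSE)
ctl <- classes[classes$condition == "control", ]
lens <- chromosome_lengths(catalog)

# class-density scan
dens <- window_counts(make_windows(lens, window_spec(3000000L, 100000L)),
                      catalog, stats::setNames(as.character(ctl$class),
                                               ctl$gene_id))
for (cls in c("constitutive", "mixed", "repressed")) {
  dens[[paste0("prop_", cls)]] <-
    ifelse(dens$n_genes_total > 0,
           dens[[paste0("n_", cls)]] / dens$n_genes_total, NA)
}
data.table::fwrite(dens, file.path(OUT_DIR, "class_density_windows.tsv"),
                   sep = "\t")
cat("class-density scan:", nrow(dens), "windows\n")

# salt-specific heritability enrichment scan over the analysed gene set
h2cls <- data.table::fread(file.path(OUT_DIR, "heritability_classes.tsv"),
                           data.table = FALSE)
sub <- catalog[catalog$gene_id %in% h2cls$gene_id, ]
class(sub) <- class(catalog)
w <- make_windows(lens, window_spec(1500000L, 100000L))
wt <- heritability_window_counts(w, sub, h2cls)
cat("enrichment scan:", nrow(wt), "windows;",
    attr(wt, "n_heritable_total"), "heritable genes of which",
    attr(wt, "n_salt_total"), "salt-specific\n")
wt <- fisher_enrichment(wt, attr(wt, "n_salt_total"),
                        attr(wt, "n_heritable_total"))
wt <- bootstrap_adjust(wt, sub,
                       h2cls$gene_id[h2cls$class != "not_heritable" &
                                       !is.na(h2cls$class)],
                       n_salt = attr(wt, "n_salt_total"),
                       B = 4000L, seed = SEED + 2L)
data.table::fwrite(wt, file.path(OUT_DIR, "enrichment_windows.tsv"),
                   sep = "\t")
cat("significant windows (adjusted p < 0.001):", sum(wt$significant), "\n")

regions <- merge_regions(wt, sub)
print(regions)
data.table::fwrite(regions, file.path(OUT_DIR, "enrichment_regions.tsv"),
                   sep = "\t")

truth <- data.table::fread(file.path(DATA_DIR, "truth.tsv"), data.table = FALSE)
for (h in SIM_SPEC$hotspot_spec) {
  hit <- any(regions$chrom == h$chrom & regions$start <= h$end &
               regions$end >= h$start)
  cat("planted hotspot", h$chrom, sprintf("%.1f-%.1f Mb", h$start / 1e6,
                                          h$end / 1e6),
      if (hit) "RECOVERED" else "missed", "\n")
}
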
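# Shared configuration for the analysis workflow. Scripts are run from the
# repository root in numeric order; each reads its inputs from results/ and
# writes its outputs there.

library(exprherit)

SEED <- 20260901L
DATA_DIR <- "results/data"
OUT_DIR <- "results"
dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)

# Study-style design: 84 genotypes in 5 subpopulations, 2 conditions x 2
# replicates, 3000 genes on 4 chromosomes with two planted 17-gene hotspots
# of salt-specific heritability.
SIM_SPEC <- simulation_spec(seed = SEED)

# Scan iteration budget for this desk-scale workflow; the permutation and
# bootstrap functions default to the full-scale budgets (40,000 and
# 4,000-50,000 iterations).
NULL_ITERATIONS <- 10000L
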
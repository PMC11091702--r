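#!/usr/bin/env Rscript
# Aggregation of per-residue binding free energy decomposition tables
# across replicate trajectories: averages per-residue contributions,
# filters to |mean| > kT (~0.6 kcal/mol at 300 K), and checks the
# component bookkeeping identity dG_bind = dG_gas + dG_sol on a synthetic
# complex-level record.

library(ligdyn)
dir.create("results", showWarnings = FALSE)
seed <- 1
set.seed(seed)

# synthetic per-replicate decompositions for a binding-site shell:
# strong contributors, a weak one below the kT cut, and replicate noise
residues <- data.frame(
  chain = "A",
  resid = c(125, 126, 127, 129, 155, 190, 226),
  resname = c("TRP", "SER", "ARG", "THR", "ASP", "LYS", "GLU"),
  mean_dG = c(-3.2, -1.4, -2.6, -0.4, 0.9, -1.8, 1.2))
tables <- lapply(1:3, function(k) {
  data.frame(chain = residues$chain, resid = residues$resid,
             resname = residues$resname, replicate = k,
             dG = residues$mean_dG + rnorm(nrow(residues), sd = 0.15))
})

agg <- aggregate_decomposition(tables, kT_cut = 0.6)
print(agg, digits = 3, row.names = FALSE)
cat(sprintf("%d of %d residues pass the kT filter\n",
            nrow(agg), nrow(residues)))
write.table(within(agg, { mean_dG <- round(mean_dG, 3)
                          sd_dG <- round(sd_dG, 3) }),
            "results/decomposition_aggregate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# complex-level component bookkeeping
components <- c(dE_ele = -40.3, dE_vdw = -54.7, dG_pol = 45.0, dG_np = -2.1,
                dG_gas = -95.0, dG_sol = 42.9, dG_bind = -52.1)
check_decomposition_components(components, tol = 0.2)
cat("component identity dG_bind = dG_gas + dG_sol holds within 0.2 kcal/mol\n")
write.table(data.frame(component = names(components),
                       kcal_mol = unname(components)),
            "results/decomposition_components.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/decomposition_{aggregate,components}.tsv\n")
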
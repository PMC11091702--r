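#!/usr/bin/env Rscript
# Interaction-fingerprint analysis over three replicate synthetic
# trajectories with scheduled occupancies shaped like a persistent
# receptor-ligand fingerprint: a near-constant hydrogen bond (96%), a
# strong salt bridge (92%), a moderate hydrophobic contact (50%) and two
# weaker aromatic stacks (30% face-to-face, 25% edge-to-face). Detections
# are averaged across replicates and reported after the strict 25% / 20%
# persistence filters.

library(ligdyn)
dir.create("results", showWarnings = FALSE)
seed <- 1
n_frames <- 1000
sched <- c(hbond = 0.96, salt_bridge = 0.92, hydrophobic = 0.50,
           pi_f2f = 0.30, pi_e2f = 0.25)

replicates <- lapply(1:3, function(k) {
  g <- gen_interaction_system(n_frames, occupancies = sched, seed = seed + k)
  s <- g$selections
  traces <- c(detect_hbonds(g$trajectory, s$donors, s$acceptors),
              detect_salt_bridges(g$trajectory, s$cations, s$anions),
              detect_hydrophobic(g$trajectory, s$protein_nonpolar,
                                 s$ligand_nonpolar),
              detect_pi_stacking(g$trajectory, s$rings_protein,
                                 s$rings_ligand))
  cat(sprintf("replicate %d realised occupancies: %s\n", k,
              paste(sprintf("%s %.1f%%", names(g$realized),
                            100 * g$realized), collapse = ", ")))
  persistence_filter(traces, hydrophobic_min = 0.25)
})

rep_ <- persistence_report(replicates)
print(rep_, digits = 4)
write.table(rep_, "results/interaction_persistence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/interaction_persistence.tsv\n")
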
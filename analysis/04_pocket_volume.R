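#!/usr/bin/env Rscript
# Binding-pocket volume tracking on a synthetic breathing cavity. The
# shell system encloses a spherical cavity whose radius alternates
# between two states (analytic volumes known exactly), and the grid
# algorithm is run with the same inclusion/seed spheres for every frame.
# A small convergence study shows the discretisation error shrinking with
# the grid spacing.

library(ligdyn)
dir.create("results", showWarnings = FALSE)
seed <- 1

g <- gen_cavity_system(n_frames = 10, radius = c(3.5, 4.5),
                       state_schedule = rep(1:2, 5), seed = seed)
cfg <- g$config
cfg$grid_spacing <- 0.4
vs <- volume_series(g$trajectory, cfg)
print(vs)
write.table(data.frame(frame = seq_along(vs$volumes),
                       volume_A3 = round(vs$volumes, 2),
                       true_A3 = round(g$true_volumes, 2)),
            "results/pocket_volumes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# convergence of the static r = 4 A cavity toward 4/3 pi r^3 = 268.1 A^3
st <- gen_cavity_system(n_frames = 1, radius = 4.0, seed = seed + 1)
conv <- do.call(rbind, lapply(c(1.0, 0.5, 0.4, 0.25, 0.2), function(h) {
  c2 <- st$config
  c2$grid_spacing <- h
  v <- volume_series(st$trajectory, c2)$mean
  data.frame(spacing_A = h, volume_A3 = round(v, 2),
             rel_error_pct = round(100 * abs(v - st$true_volumes[1]) /
                                     st$true_volumes[1], 3))
}))
print(conv, row.names = FALSE)
write.table(conv, "results/pocket_convergence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/pocket_{volumes,convergence}.tsv\n")
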
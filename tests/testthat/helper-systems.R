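# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately re-derive each quantity along a different
# code path (triple loops, direct formulas, numerical optimisation) so
# they can catch implementation errors in the package's vectorised paths.

# ---- tiny systems -------------------------------------------------------

toy_topology <- function(n = 3, resname = "ALA", chain = "A") {
  topology(data.frame(
    name = c("N", "CA", "C", "O", "CB")[seq_len(min(n, 5))][rep_len(seq_len(min(n, 5)), n)],
    element = "C", resid = seq_len(n), resname = resname, chain = chain,
    stringsAsFactors = FALSE))
}

# a trajectory from an explicit list of frame coordinate matrices
traj_from_frames <- function(frames, topo = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(topo)) topo <- toy_topology(n)
  coords <- array(NA_real_, dim = c(length(frames), n, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  trajectory(topo, coords)
}

# non-degenerate 4-point toy used in the superposition tests
four_point <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 1.5, 0), c(0.3, 0.4, 1.2))
}

# ---- random interaction system for oracle-equivalence tests ------------

# Random constellation of flagged atoms in a box whose distances straddle
# the cutoffs; donors carry one bonded hydrogen each.
random_interaction_system <- function(seed, n_frames = 50, box = 9) {
  set.seed(seed)
  n_don <- 6; n_acc <- 8; n_cat <- 4; n_ani <- 4; n_ppl <- 6; n_lnp <- 4
  atoms <- NULL; bonds <- NULL
  add <- function(k, name, el, resid, resname, chain, flags) {
    rbind(atoms, data.frame(name = paste0(name, seq_len(k)), element = el,
                            resid = resid + seq_len(k), resname = resname,
                            chain = chain, flags = flags,
                            stringsAsFactors = FALSE))
  }
  atoms <- add(n_don, "ND", "N", 0L, "SER", "A", "donor")
  atoms <- add(n_don, "HD", "H", 100L, "SER", "A", "hydrogen")
  for (i in seq_len(n_don)) bonds <- rbind(bonds, c(i, n_don + i))
  atoms <- add(n_acc, "OA", "O", 200L, "LIG", "L", "acceptor")
  atoms <- add(n_cat, "NZ", "N", 300L, "LYS", "A", "cation_group")
  atoms <- add(n_ani, "OP", "O", 400L, "LIG", "L", "anion_group")
  atoms <- add(n_ppl, "CD", "C", 500L, "LEU", "A", "nonpolar_carbon")
  atoms <- add(n_lnp, "C8", "C", 600L, "LIG", "L", "nonpolar_carbon")
  n <- nrow(atoms)
  nd <- n_don; base_h <- n_don
  coords <- array(runif(n_frames * n * 3, 0, box), dim = c(n_frames, n, 3))
  # keep each hydrogen ~1 A from its donor so angles are meaningful
  for (i in seq_len(n_frames)) {
    for (k in seq_len(nd)) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      coords[i, base_h + k, ] <- coords[i, k, ] + dir
    }
  }
  topo <- topology(atoms, bonds = bonds)
  list(traj = trajectory(topo, coords), topo = topo,
       donors = selection(1:n_don), acceptors = selection(2 * n_don + 1:n_acc),
       cations = selection(2 * n_don + n_acc + 1:n_cat),
       anions = selection(2 * n_don + n_acc + n_cat + 1:n_ani),
       protein_nonpolar = selection(2 * n_don + n_acc + n_cat + n_ani + 1:n_ppl),
       ligand_nonpolar = selection(2 * n_don + n_acc + n_cat + n_ani + n_ppl + 1:n_lnp))
}

# ---- brute-force detectors ---------------------------------------------

dist3 <- function(a, b) sqrt(sum((a - b)^2))

angle3 <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# occupancy[pair, frame] for every donor-acceptor pair, via triple loop
oracle_hbonds <- function(traj, donors, acceptors, cfg = interaction_config()) {
  topo <- traj$topology
  is_h <- toupper(topo$atoms$element) == "H"
  bnd <- topo$bonds
  occ <- list()
  for (d in donors$indices) {
    hs <- c(bnd[bnd[, 1] == d, 2], bnd[bnd[, 2] == d, 1])
    hs <- hs[is_h[hs]]
    if (!length(hs)) next
    for (a in acceptors$indices) {
      if (a == d) next
      key <- paste(d, a)
      v <- logical(n_frames(traj))
      for (i in seq_len(n_frames(traj))) {
        x <- frame_coords(traj, i)
        if (dist3(x[d, ], x[a, ]) > cfg$hbond_da_cut) next
        for (h in hs) {
          if (angle3(x[d, ], x[h, ], x[a, ]) >= cfg$hbond_angle_cut) {
            v[i] <- TRUE
            break
          }
        }
      }
      if (any(v)) occ[[key]] <- v
    }
  }
  occ
}

oracle_pair_contacts <- function(traj, sel_a, sel_b, cutoff, group_a_by_residue = TRUE) {
  at <- traj$topology$atoms
  ga <- if (group_a_by_residue) split(sel_a$indices, paste(at$chain[sel_a$indices], at$resid[sel_a$indices]))
        else as.list(sel_a$indices)
  occ <- list()
  for (nm in names(ga)) {
    v <- logical(n_frames(traj))
    for (i in seq_len(n_frames(traj))) {
      x <- frame_coords(traj, i)
      hit <- FALSE
      for (p in ga[[nm]]) for (q in sel_b$indices) {
        if (dist3(x[p, ], x[q, ]) <= cutoff) { hit <- TRUE; break }
      }
      v[i] <- hit
    }
    if (any(v)) occ[[nm]] <- v
  }
  occ
}

# salt bridges at residue x residue granularity
oracle_salt_bridges <- function(traj, cations, anions, cfg = interaction_config()) {
  at <- traj$topology$atoms
  ga <- split(cations$indices, paste(at$chain[cations$indices], at$resid[cations$indices]))
  gb <- split(anions$indices, paste(at$chain[anions$indices], at$resid[anions$indices]))
  occ <- list()
  for (na in names(ga)) for (nb in names(gb)) {
    v <- logical(n_frames(traj))
    for (i in seq_len(n_frames(traj))) {
      x <- frame_coords(traj, i)
      for (p in ga[[na]]) for (q in gb[[nb]]) {
        if (dist3(x[p, ], x[q, ]) <= cfg$salt_cut) { v[i] <- TRUE; break }
      }
    }
    if (any(v)) occ[[paste(na, nb)]] <- v
  }
  occ
}

# direct per-frame pocket filter: no region growth shortcut, plain
# distance checks against seeds, expansion and exclusion
oracle_pocket_volume <- function(frame, topo, grid, cfg) {
  seeds <- rep(FALSE, nrow(grid))
  for (s in cfg$seed_spheres)
    seeds <- seeds | sqrt(rowSums(sweep(grid, 2, s$center)^2)) <= s$radius
  region <- seeds
  repeat {
    added <- FALSE
    idx_in <- which(region); idx_out <- which(!region)
    for (i in idx_out) {
      for (j in idx_in) {
        if (dist3(grid[i, ], grid[j, ]) <= cfg$expansion_radius) {
          region[i] <- TRUE; added <- TRUE; break
        }
      }
    }
    if (!added) break
  }
  heavy <- which(toupper(topo$atoms$element) != "H")
  keep <- region
  for (i in which(region)) {
    for (j in heavy) {
      if (dist3(grid[i, ], frame[j, ]) <
          topo$atoms$vdw_radius[j] + cfg$exclusion_pad) {
        keep[i] <- FALSE; break
      }
    }
  }
  sum(keep) * cfg$grid_spacing^3
}

# ---- independent DBSCAN reference (core-point graph components) --------

reference_dbscan <- function(d, eps, min_pts) {
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nbr) >= min_pts
  labels <- rep(-1L, n)
  if (any(core)) {
    ci <- which(core)
    adj <- d[ci, ci, drop = FALSE] <= eps
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[ci] <- comp
    # border points: any cluster of an adjacent core point is acceptable
    for (i in which(!core)) {
      adj_cores <- intersect(nbr[[i]], ci)
      if (length(adj_cores)) labels[i] <- labels[adj_cores[1]]
    }
  }
  list(labels = labels, core = core, nbr = nbr)
}

# are two clusterings the same partition up to label permutation?
same_partition <- function(a, b) {
  ka <- split(seq_along(a), a)
  kb <- split(seq_along(b), b)
  setequal(lapply(ka, sort), lapply(kb, sort))
}

# two planted conformational states for clustering tests
two_state_traj <- function(n_per = 50, sep = 12, noise = 0.02, seed = 1) {
  set.seed(seed)
  g <- gen_two_domain_protein(n_frames = 1, mode_variances = 0,
                              noise_sigma = 0, seed = 2)
  base <- frame_coords(g$trajectory, 1)
  n <- nrow(base)
  shifted <- base
  shifted[1:(n / 2), 1] <- shifted[1:(n / 2), 1] + sep
  frames <- c(
    lapply(seq_len(n_per), function(i) base + matrix(rnorm(3 * n, sd = noise), n, 3)),
    lapply(seq_len(n_per), function(i) shifted + matrix(rnorm(3 * n, sd = noise), n, 3)))
  trajectory(g$trajectory$topology, {
    arr <- array(NA_real_, dim = c(2 * n_per, n, 3))
    for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
    arr
  })
}
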
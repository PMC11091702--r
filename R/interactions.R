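# Per-frame geometric interaction detection and persistence statistics.
#
# Cutoff conventions follow the cpptraj-style defaults: hydrogen bonds use
# donor-to-acceptor heavy-atom distance <= 3.0 A with a D-H...A angle
# (vertex at the hydrogen) >= 135 deg; salt bridges any cation-group atom
# within 4 A of an anion-group atom; hydrophobic contacts any nonpolar
# protein atom within 4 A of a ligand nonpolar carbon. Pi-stacking uses
# strict < at its cutoffs (min ring-system heavy-atom distance < 4 A, and
# for face-to-face additionally centroid distance < 5 A) with the normal
# angle folded to [0, 90] deg: <= 45 face-to-face, > 45 edge-to-face.
# Persistence is the fraction of frames an interaction is present;
# reporting filters are strict ("higher than" 25% for hydrogen bonds and
# salt bridges, 20% for stacking).

#' Interaction detection configuration
#'
#' @param hbond_da_cut donor-acceptor heavy-atom distance cutoff (A).
#' @param hbond_angle_cut D-H...A angle cutoff in degrees (vertex at H).
#' @param salt_cut cation-anion atom distance cutoff (A).
#' @param hydrophobic_cut nonpolar-atom distance cutoff (A).
#' @param pi_min_heavy_cut min ring-system heavy-atom distance cutoff (A,
#'   strict).
#' @param pi_com_cut ring-centroid distance cutoff for face-to-face (A,
#'   strict).
#' @param f2f_max_angle folded normal-angle upper bound for face-to-face
#'   stacking (deg); above it (up to 90) counts as edge-to-face.
#' @param hbond_persistence_min persistence reporting threshold for
#'   hydrogen bonds and salt bridges (fraction, strict >).
#' @param pi_persistence_min persistence reporting threshold for stacking
#'   (fraction, strict >).
#' @return list of class `ligdyn_interaction_config`.
#' @export
interaction_config <- function(hbond_da_cut = 3.0, hbond_angle_cut = 135,
                               salt_cut = 4.0, hydrophobic_cut = 4.0,
                               pi_min_heavy_cut = 4.0, pi_com_cut = 5.0,
                               f2f_max_angle = 45,
                               hbond_persistence_min = 0.25,
                               pi_persistence_min = 0.20) {
  stopifnot(hbond_da_cut > 0, salt_cut > 0, hydrophobic_cut > 0,
            pi_min_heavy_cut > 0, pi_com_cut > 0,
            hbond_angle_cut >= 0, hbond_angle_cut <= 180,
            f2f_max_angle >= 0, f2f_max_angle <= 90,
            hbond_persistence_min >= 0, hbond_persistence_min <= 1,
            pi_persistence_min >= 0, pi_persistence_min <= 1)
  structure(as.list(environment()), class = "ligdyn_interaction_config")
}

#' @keywords internal
interaction_trace <- function(kind, partner_a, partner_b, occupancy) {
  structure(list(kind = kind, partner_a = partner_a, partner_b = partner_b,
                 occupancy = as.logical(occupancy),
                 persistence = mean(occupancy)),
            class = "ligdyn_trace")
}

#' @export
print.ligdyn_trace <- function(x, ...) {
  cat(sprintf("%s  %s -- %s  persistence %.1f%% (%d frames)\n", x$kind,
              x$partner_a, x$partner_b, 100 * x$persistence,
              length(x$occupancy)))
  invisible(x)
}

#' Convert a list of interaction traces to a long data.frame
#'
#' @param traces list of `ligdyn_trace`.
#' @return data.frame (kind, partner_a, partner_b, persistence,
#'   persistence_pct, n_frames).
#' @export
traces_table <- function(traces) {
  if (!length(traces))
    return(data.frame(kind = character(0), partner_a = character(0),
                      partner_b = character(0), persistence = numeric(0),
                      persistence_pct = numeric(0), n_frames = integer(0)))
  df <- do.call(rbind, lapply(traces, function(t)
    data.frame(kind = t$kind, partner_a = t$partner_a, partner_b = t$partner_b,
               persistence = t$persistence,
               persistence_pct = 100 * t$persistence,
               n_frames = length(t$occupancy), stringsAsFactors = FALSE)))
  df[order(-df$persistence, df$kind, df$partner_a, df$partner_b), ]
}

# atom label "RESNAME RESID CHAIN:NAME"
#' @keywords internal
atom_label <- function(at, i) {
  sprintf("%s %d %s:%s", at$resname[i], at$resid[i], at$chain[i], at$name[i])
}

#' @keywords internal
residue_label <- function(at, i) {
  sprintf("%s %d %s", at$resname[i], at$resid[i], at$chain[i])
}

# per-frame distance between two atoms, vectorised over frames
#' @keywords internal
frame_dist <- function(coords, i, j) {
  sqrt((coords[, i, 1] - coords[, j, 1])^2 +
       (coords[, i, 2] - coords[, j, 2])^2 +
       (coords[, i, 3] - coords[, j, 3])^2)
}

#' Detect hydrogen bonds along a trajectory
#'
#' A donor-acceptor pair is present in a frame iff the heavy-atom distance
#' is within `hbond_da_cut` and, for at least one hydrogen bonded to the
#' donor, the D-H...A angle (vertex at the hydrogen) is at least
#' `hbond_angle_cut`. Donor-bonded hydrogens come from the topology bond
#' list; donors without a bonded hydrogen are skipped with a warning.
#' Intra-ligand pairs are detected like any other when both selections lie
#' in the ligand.
#'
#' @param traj a `ligdyn_trajectory` whose topology carries bonds.
#' @param donors selection of donor heavy atoms.
#' @param acceptors selection of acceptor heavy atoms.
#' @param cfg a `ligdyn_interaction_config`.
#' @return list of `ligdyn_trace` (kind "hbond"), one per donor-acceptor
#'   pair observed in at least one frame.
#' @export
detect_hbonds <- function(traj, donors, acceptors, cfg = interaction_config()) {
  at <- traj$topology$atoms
  bonds <- traj$topology$bonds
  if (is.null(bonds)) stop("hydrogen-bond detection needs topology bonds")
  di <- sel_indices(donors, nrow(at))
  ai <- sel_indices(acceptors, nrow(at))
  is_h <- toupper(at$element) == "H"
  bonded_h <- function(i) {
    nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    nb[is_h[nb]]
  }
  hs <- lapply(di, bonded_h)
  no_h <- lengths(hs) == 0
  if (any(no_h)) {
    warning(sum(no_h), " donor(s) without a bonded hydrogen skipped")
    di <- di[!no_h]; hs <- hs[!no_h]
  }
  coords <- traj$coords
  nf <- dim(coords)[1]
  traces <- list()
  for (k in seq_along(di)) {
    d <- di[k]
    for (a in ai) {
      if (a == d) next
      occ <- frame_dist(coords, d, a) <= cfg$hbond_da_cut
      if (!any(occ)) next
      ang_ok <- rep(FALSE, nf)
      for (h in hs[[k]]) {
        # angle at H between H->D and H->A
        u <- coords[, d, , drop = FALSE] - coords[, h, , drop = FALSE]
        v <- coords[, a, , drop = FALSE] - coords[, h, , drop = FALSE]
        dot <- rowSums(matrix(u, nf) * matrix(v, nf))
        cosang <- dot / (sqrt(rowSums(matrix(u, nf)^2)) *
                         sqrt(rowSums(matrix(v, nf)^2)))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        ang_ok <- ang_ok | ang >= cfg$hbond_angle_cut
      }
      occ <- occ & ang_ok
      if (any(occ))
        traces[[length(traces) + 1]] <-
          interaction_trace("hbond", atom_label(at, d), atom_label(at, a), occ)
    }
  }
  traces
}

#' Detect salt bridges along a trajectory
#'
#' A residue(moiety)-level contact is present in a frame iff any
#' cation-group atom of one partner lies within `salt_cut` of any
#' anion-group atom of the other. Selections are restricted to atoms
#' carrying the corresponding charge flag; an empty charged selection
#' yields an empty result with a warning.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param cations selection of positively charged-group atoms.
#' @param anions selection of negatively charged-group atoms.
#' @param cfg a `ligdyn_interaction_config`.
#' @return list of `ligdyn_trace` (kind "salt_bridge") at residue
#'   granularity.
#' @export
detect_salt_bridges <- function(traj, cations, anions,
                                cfg = interaction_config()) {
  at <- traj$topology$atoms
  ci <- intersect(sel_indices(cations, nrow(at)), which(has_flag(traj$topology, "cation_group")))
  ni <- intersect(sel_indices(anions, nrow(at)), which(has_flag(traj$topology, "anion_group")))
  if (!length(ci) || !length(ni)) {
    warning("empty charged selection; no salt bridges detectable")
    return(list())
  }
  coords <- traj$coords
  cg <- split(ci, paste(at$chain[ci], at$resid[ci]))
  ng <- split(ni, paste(at$chain[ni], at$resid[ni]))
  traces <- list()
  for (cs in cg) {
    for (as_ in ng) {
      occ <- rep(FALSE, dim(coords)[1])
      for (i in cs) for (j in as_)
        occ <- occ | (frame_dist(coords, i, j) <= cfg$salt_cut)
      if (any(occ))
        traces[[length(traces) + 1]] <-
          interaction_trace("salt_bridge", residue_label(at, cs[1]),
                            residue_label(at, as_[1]), occ)
    }
  }
  traces
}

#' Detect hydrophobic contacts along a trajectory
#'
#' Residue-level: a protein residue is in hydrophobic contact in a frame
#' iff any of its nonpolar atoms lies within `hydrophobic_cut` of any
#' ligand nonpolar carbon.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param protein_nonpolar selection of protein nonpolar atoms (flag
#'   `nonpolar_carbon`).
#' @param ligand_nonpolar_carbons selection of ligand nonpolar carbons.
#' @param cfg a `ligdyn_interaction_config`.
#' @return list of `ligdyn_trace` (kind "hydrophobic"), one per protein
#'   residue observed in contact.
#' @export
detect_hydrophobic <- function(traj, protein_nonpolar, ligand_nonpolar_carbons,
                               cfg = interaction_config()) {
  at <- traj$topology$atoms
  pi_ <- sel_indices(protein_nonpolar, nrow(at))
  li <- sel_indices(ligand_nonpolar_carbons, nrow(at))
  coords <- traj$coords
  groups <- split(pi_, paste(at$chain[pi_], at$resid[pi_]))
  traces <- list()
  for (g in groups) {
    occ <- rep(FALSE, dim(coords)[1])
    for (i in g) for (j in li)
      occ <- occ | (frame_dist(coords, i, j) <= cfg$hydrophobic_cut)
    if (any(occ))
      traces[[length(traces) + 1]] <-
        interaction_trace("hydrophobic", residue_label(at, g[1]), "ligand", occ)
  }
  traces
}

#' Centroid and best-fit plane normal of a ring
#'
#' The centroid is the unweighted mean of the ring atoms; the normal is
#' the unit normal of the least-squares plane (smallest-singular-vector of
#' the centered coordinates), which tolerates ring pucker. The normal's
#' sign is unconstrained — downstream angle logic is sign-agnostic.
#'
#' @param frame n x 3 coordinate matrix.
#' @param ring ordered atom-index cycle (>= 3 non-collinear atoms).
#' @return list with `centroid` (3-vector) and `normal` (unit 3-vector).
#' @export
ring_geometry <- function(frame, ring) {
  if (length(ring) < 3) stop("a ring needs at least 3 atoms")
  x <- frame[ring, , drop = FALSE]
  centroid <- colMeans(x)
  centered <- sweep(x, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(1, sv$d[1]))
    stop("degenerate (collinear) ring geometry")
  list(centroid = centroid, normal = sv$v[, 3])
}

# merge rings sharing >= 2 atoms into fused ring systems
#' @keywords internal
ring_systems <- function(topo, ring_ids) {
  ring_ids <- as.character(ring_ids)
  miss <- setdiff(ring_ids, names(topo$rings))
  if (length(miss)) stop("ring id(s) not in topology: ", paste(miss, collapse = ", "))
  members <- topo$rings[ring_ids]
  groups <- as.list(seq_along(members))
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (is.null(groups[[i]])) next
      for (j in seq_along(groups)) {
        if (j <= i || is.null(groups[[j]])) next
        ai <- unlist(members[groups[[i]]])
        aj <- unlist(members[groups[[j]]])
        if (length(intersect(ai, aj)) >= 2) {
          groups[[i]] <- c(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
        }
      }
    }
    if (!merged) break
  }
  groups <- Filter(Negate(is.null), groups)
  lapply(groups, function(g) {
    list(ids = paste(ring_ids[g], collapse = "+"),
         atoms = sort(unique(unlist(members[g]))),
         # the largest constituent cycle defines the plane fit
         plane_ring = members[[g[which.max(lengths(members[g]))]]])
  })
}

#' Detect pi-stacking along a trajectory
#'
#' For each pair of ring systems (fused rings sharing >= 2 atoms are
#' merged into one system) and each frame: face-to-face requires (i)
#' minimum heavy-atom distance between the systems < `pi_min_heavy_cut`,
#' (ii) centroid distance < `pi_com_cut`, and (iii) normals angle folded
#' to [0, 90] deg at most `f2f_max_angle`; otherwise edge-to-face requires
#' (i) and a folded angle above `f2f_max_angle`. The two classes are
#' mutually exclusive per ring pair per frame.
#'
#' @param traj a `ligdyn_trajectory` with ring definitions.
#' @param rings_a,rings_b ring ids (character or integer) of the two
#'   partners, e.g. tryptophan indoles vs ligand base/ribose moieties.
#' @param cfg a `ligdyn_interaction_config`.
#' @return list of `ligdyn_trace` with kinds "pi_f2f" and "pi_e2f".
#' @export
detect_pi_stacking <- function(traj, rings_a, rings_b,
                               cfg = interaction_config()) {
  topo <- traj$topology
  sys_a <- ring_systems(topo, rings_a)
  sys_b <- ring_systems(topo, rings_b)
  nf <- n_frames(traj)
  traces <- list()
  for (sa in sys_a) {
    for (sb in sys_b) {
      heavy_a <- sa$atoms[toupper(topo$atoms$element[sa$atoms]) != "H"]
      heavy_b <- sb$atoms[toupper(topo$atoms$element[sb$atoms]) != "H"]
      f2f <- logical(nf)
      e2f <- logical(nf)
      for (i in seq_len(nf)) {
        x <- frame_coords(traj, i)
        if (min_cross_dist(x[heavy_a, , drop = FALSE],
                           x[heavy_b, , drop = FALSE]) >= cfg$pi_min_heavy_cut)
          next
        ga <- ring_geometry(x, sa$plane_ring)
        gb <- ring_geometry(x, sb$plane_ring)
        folded <- acos(min(1, abs(sum(ga$normal * gb$normal)))) * 180 / pi
        if (folded <= cfg$f2f_max_angle) {
          if (vnorm(ga$centroid - gb$centroid) < cfg$pi_com_cut) f2f[i] <- TRUE
        } else {
          e2f[i] <- TRUE
        }
      }
      if (any(f2f))
        traces[[length(traces) + 1]] <-
          interaction_trace("pi_f2f", sa$ids, sb$ids, f2f)
      if (any(e2f))
        traces[[length(traces) + 1]] <-
          interaction_trace("pi_e2f", sa$ids, sb$ids, e2f)
    }
  }
  traces
}

#' Filter interaction traces by persistence
#'
#' Hydrogen bonds and salt bridges are kept iff their persistence is
#' strictly higher than `cfg$hbond_persistence_min` (default 25% of the
#' simulation time); pi-stacking iff strictly higher than
#' `cfg$pi_persistence_min` (default 20%). Hydrophobic contacts are kept
#' unconditionally unless `hydrophobic_min` is supplied.
#'
#' @param traces list of `ligdyn_trace`.
#' @param cfg a `ligdyn_interaction_config`.
#' @param hydrophobic_min optional strict persistence threshold for
#'   hydrophobic contacts.
#' @return filtered list of traces.
#' @export
persistence_filter <- function(traces, cfg = interaction_config(),
                               hydrophobic_min = NULL) {
  Filter(function(t) {
    switch(t$kind,
      hbond = ,
      salt_bridge = t$persistence > cfg$hbond_persistence_min,
      pi_f2f = ,
      pi_e2f = t$persistence > cfg$pi_persistence_min,
      hydrophobic = is.null(hydrophobic_min) || t$persistence > hydrophobic_min,
      TRUE)
  }, traces)
}

#' Average interaction persistence across replicate simulations
#'
#' Matches traces across replicates by (kind, partner_a, partner_b) and
#' reports the mean persistence as a percentage of total simulation time.
#' An interaction absent from a replicate contributes 0 to the mean for
#' that replicate and the row is flagged incomplete.
#'
#' @param replicates list of per-replicate trace lists (each a list of
#'   `ligdyn_trace`).
#' @return data.frame (kind, partner_a, partner_b, mean_persistence_pct,
#'   sd_persistence_pct, n_replicates_present, incomplete), sorted by
#'   descending mean persistence.
#' @export
persistence_report <- function(replicates) {
  if (!length(replicates)) stop("no replicates supplied")
  n_rep <- length(replicates)
  long <- do.call(rbind, lapply(seq_len(n_rep), function(k) {
    df <- traces_table(replicates[[k]])
    if (nrow(df)) df$replicate <- k
    df
  }))
  if (is.null(long) || !nrow(long))
    return(data.frame(kind = character(0), partner_a = character(0),
                      partner_b = character(0),
                      mean_persistence_pct = numeric(0),
                      sd_persistence_pct = numeric(0),
                      n_replicates_present = integer(0),
                      incomplete = logical(0)))
  key <- paste(long$kind, long$partner_a, long$partner_b, sep = "|")
  out <- do.call(rbind, lapply(split(long, key), function(g) {
    p <- rep(0, n_rep)
    p[g$replicate] <- g$persistence_pct
    data.frame(kind = g$kind[1], partner_a = g$partner_a[1],
               partner_b = g$partner_b[1],
               mean_persistence_pct = mean(p),
               sd_persistence_pct = if (n_rep > 1) stats::sd(p) else 0,
               n_replicates_present = nrow(g),
               incomplete = nrow(g) < n_rep,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$mean_persistence_pct), ]
  rownames(out) <- NULL
  out
}
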
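# Ground-truth synthetic-data generators.
#
# Each generator is a pure function of its arguments including the seed,
# and returns, alongside the data, the exact quantity its consumer is
# supposed to estimate (planted mode variances, realised interaction
# occupancies, analytic cavity volumes, directly evaluated Pnear, pucker
# phase), so recovery can be tested without external simulation output.
# The `write_dir` argument makes a generator additionally emit its
# trajectory as a multi-model PDB plus the annotation TSV, so tests can
# exercise the real I/O path.

#' @keywords internal
maybe_write <- function(traj, write_dir, prefix) {
  if (is.null(write_dir)) return(invisible(NULL))
  dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
  write_multimodel_pdb(traj, file.path(write_dir, paste0(prefix, ".pdb")))
  write_annotation(traj$topology, file.path(write_dir, paste0(prefix, "_annotation.tsv")))
  invisible(NULL)
}

#' Two-domain protein with planted collective modes
#'
#' Generates a C-alpha bead model of a two-domain protein whose frames
#' displace along one or two planted, mutually orthogonal collective
#' modes (an inter-domain "clamping" pattern along the domain-separation
#' axis and a shear pattern perpendicular to it) with prescribed
#' variances, plus isotropic Gaussian coordinate noise. The planted modes
#' are projected orthogonal to the six rigid-body modes, so least-squares
#' superposition does not absorb them and essential-dynamics PCA can
#' recover their variances and directions exactly up to sampling error.
#'
#' @param n_frames number of frames.
#' @param n_per_domain C-alpha beads per domain (default 30).
#' @param mode_variances variances (A^2) of the planted mode amplitudes;
#'   length 1 or 2 (default c(9, 4)).
#' @param noise_sigma isotropic per-coordinate noise SD in Angstrom
#'   (default 0.02, so the total noise variance 3 n sigma^2 stays a small
#'   perturbation next to the planted mode variances).
#' @param seed RNG seed.
#' @param write_dir optional directory for PDB + annotation output.
#' @return list with `trajectory`, `calpha` (selection), `modes` (3n x k
#'   orthonormal planted directions), `mode_variances`, and `amplitudes`
#'   (the realised per-frame mode amplitudes).
#' @export
gen_two_domain_protein <- function(n_frames = 1000, n_per_domain = 30,
                                   mode_variances = c(9, 4),
                                   noise_sigma = 0.02, seed = 1,
                                   write_dir = NULL) {
  stopifnot(n_frames >= 1, n_per_domain >= 4,
            length(mode_variances) %in% 1:2, all(mode_variances >= 0))
  set.seed(seed)
  n <- 2L * n_per_domain
  # each domain: a compact helical bead string, centred in x/y, domains
  # offset +/- 12 A along z
  t <- seq_len(n_per_domain)
  dom <- cbind(4 * cos(t), 4 * sin(t), 1.5 * (t - mean(t)))
  base <- rbind(sweep(dom, 2, c(0, 0, -12), "-"),
                sweep(dom, 2, c(0, 0, 12), "-") * c(1, -1, 1))
  base <- sweep(base, 2, colMeans(base))

  split_sign <- rep(c(-1, 1), each = n_per_domain)
  raw1 <- cbind(0, 0, split_sign)              # clamping: domains approach/separate
  raw2 <- cbind(split_sign, 0, 0)              # shear: domains slide oppositely
  modes_raw <- cbind(as.vector(t(raw1)), as.vector(t(raw2)))
  modes_raw <- modes_raw[, seq_along(mode_variances), drop = FALSE]
  modes <- orthogonalise_to_rigid(modes_raw, base)

  amp <- sapply(seq_along(mode_variances), function(k)
    stats::rnorm(n_frames, sd = sqrt(mode_variances[k])))
  amp <- matrix(amp, nrow = n_frames)
  coords <- array(NA_real_, dim = c(n_frames, n, 3))
  for (i in seq_len(n_frames)) {
    disp <- matrix(modes %*% amp[i, ], n, 3, byrow = TRUE)
    coords[i, , ] <- base + disp +
      matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
  }
  atoms <- data.frame(name = "CA", element = "C",
                      resid = seq_len(n), resname = "ALA",
                      chain = rep(c("A", "B"), each = n_per_domain),
                      stringsAsFactors = FALSE)
  traj <- trajectory(topology(atoms), coords)
  maybe_write(traj, write_dir, "two_domain")
  list(trajectory = traj,
       calpha = select_atoms(traj$topology, "calpha"),
       modes = modes, mode_variances = mode_variances, amplitudes = amp)
}

# project the columns of v orthogonal to the 6 rigid-body modes (3
# translations + 3 linearised rotations about the centroid) of structure
# x, then orthonormalise
#' @keywords internal
orthogonalise_to_rigid <- function(v, x) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  rigid <- matrix(0, 3 * n, 6)
  for (k in 1:3) rigid[seq(k, 3 * n, by = 3), k] <- 1      # translations
  axes <- diag(3)
  for (k in 1:3) {                                          # rotations
    w <- t(apply(xc, 1, function(r) pracma_cross(axes[k, ], r)))
    rigid[, 3 + k] <- as.vector(t(w))
  }
  basis <- qr.Q(qr(rigid))
  v <- v - basis %*% crossprod(basis, v)
  qr.Q(qr(v)) * rep(sign(colSums(qr.Q(qr(v)) * v)), each = nrow(v))
}

#' Scheduled-occupancy interaction system
#'
#' Builds a small protein-fragment/ligand system in which each interaction
#' pair (hydrogen bond, salt bridge, hydrophobic contact, face-to-face and
#' edge-to-face pi-stack) is placed inside its geometric criteria with
#' per-frame probability equal to its scheduled occupancy and displaced
#' well beyond the cutoff otherwise. Pairs live in spatial zones 60 A
#' apart so they never cross-talk. The exactly realised per-pair
#' occupancy is returned as ground truth.
#'
#' @param n_frames number of frames.
#' @param occupancies named numeric vector of target occupancies in
#'   [0, 1] for any subset of `hbond`, `salt_bridge`, `hydrophobic`,
#'   `pi_f2f`, `pi_e2f`.
#' @param seed RNG seed.
#' @param write_dir optional directory for PDB + annotation output.
#' @return list with `trajectory`, `realized` (named realised occupancy
#'   fractions), `scheduled`, and `selections` (named list of the
#'   selections each detector needs).
#' @export
gen_interaction_system <- function(n_frames = 1000,
                                   occupancies = c(hbond = 0.96,
                                                   salt_bridge = 0.92,
                                                   hydrophobic = 0.50,
                                                   pi_f2f = 0.30,
                                                   pi_e2f = 0.25),
                                   seed = 1, write_dir = NULL) {
  stopifnot(n_frames >= 1, all(occupancies >= 0), all(occupancies <= 1))
  kinds <- names(occupancies)
  bad <- setdiff(kinds, c("hbond", "salt_bridge", "hydrophobic", "pi_f2f", "pi_e2f"))
  if (length(bad)) stop("unknown interaction kind(s): ", paste(bad, collapse = ", "))
  set.seed(seed)

  hexagon <- function(center, r = 1.39) {
    a <- seq(0, 2 * pi, length.out = 7)[1:6]
    sweep(cbind(r * cos(a), r * sin(a), 0), 2, center, "+")
  }
  atoms <- NULL
  bonds <- NULL
  rings <- list()
  base <- NULL
  placements <- list()  # per kind: atom indices + on/off geometries
  add_atoms <- function(df, xyz) {
    start <- if (is.null(atoms)) 0L else nrow(atoms)
    atoms <<- rbind(atoms, df)
    base <<- rbind(base, xyz)
    start + seq_len(nrow(df))
  }
  zone <- 0
  mk <- function(n, name, element, resid, resname, chain, flags) {
    data.frame(name = name, element = element, resid = resid,
               resname = resname, chain = chain, flags = flags,
               stringsAsFactors = FALSE)
  }

  for (kind in kinds) {
    off <- c(zone, 0, 0)
    zone <- zone + 60
    if (kind == "hbond") {
      # donor N with bonded H on the protein side, acceptor O on the ligand
      i <- add_atoms(mk(3, c("ND", "HD", "OA"), c("N", "H", "O"),
                        c(10L, 10L, 900L), c("SER", "SER", "LIG"),
                        c("A", "A", "L"),
                        c("donor", "hydrogen", "acceptor")),
                     rbind(off, off + c(1.0, 0, 0), off + c(2.8, 0, 0)))
      bonds <- rbind(bonds, c(i[1], i[2]))
      placements[[kind]] <- list(atoms = i[3], on = base[i[3], , drop = FALSE],
                                 off_pos = base[i[3], , drop = FALSE] + c(4, 0, 0))
    } else if (kind == "salt_bridge") {
      i <- add_atoms(mk(2, c("NH1", "O1P"), c("N", "O"),
                        c(127L, 900L), c("ARG", "LIG"), c("A", "L"),
                        c("cation_group", "anion_group")),
                     rbind(off, off + c(3.5, 0, 0)))
      placements[[kind]] <- list(atoms = i[2], on = base[i[2], , drop = FALSE],
                                 off_pos = base[i[2], , drop = FALSE] + c(3, 0, 0))
    } else if (kind == "hydrophobic") {
      i <- add_atoms(mk(2, c("CD1", "C8"), c("C", "C"),
                        c(55L, 900L), c("LEU", "LIG"), c("A", "L"),
                        c("nonpolar_carbon", "nonpolar_carbon")),
                     rbind(off, off + c(3.6, 0, 0)))
      placements[[kind]] <- list(atoms = i[2], on = base[i[2], , drop = FALSE],
                                 off_pos = base[i[2], , drop = FALSE] + c(3, 0, 0))
    } else if (kind == "pi_f2f") {
      ring_w <- hexagon(off)
      ring_l <- hexagon(off + c(0, 0, 3.5))
      nmw <- sprintf("CW%d", 1:6); nml <- sprintf("CL%d", 1:6)
      iw <- add_atoms(mk(6, nmw, "C", 125L, "TRP", "A", ""), ring_w)
      il <- add_atoms(mk(6, nml, "C", 900L, "LIG", "L", ""), ring_l)
      rid <- length(rings) + 1:2
      rings[[as.character(rid[1])]] <- iw
      rings[[as.character(rid[2])]] <- il
      placements[[kind]] <- list(atoms = il, on = base[il, , drop = FALSE],
                                 off_pos = sweep(base[il, , drop = FALSE], 2,
                                                 c(0, 0, 8), "+"),
                                 ring_ids = as.character(rid))
    } else if (kind == "pi_e2f") {
      ring_w <- hexagon(off)
      # perpendicular ring: rotate about x, min heavy distance ~3.5 A
      rl <- hexagon(c(0, 0, 0))
      rot_x <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
      ring_l <- sweep(rl %*% t(rot_x), 2, off + c(0, 0, 3.5 + 1.39), "+")
      nmw <- sprintf("CV%d", 1:6); nml <- sprintf("CM%d", 1:6)
      iw <- add_atoms(mk(6, nmw, "C", 176L, "TRP", "A", ""), ring_w)
      il <- add_atoms(mk(6, nml, "C", 901L, "LIG", "L", ""), ring_l)
      rid <- length(rings) + 1:2
      rings[[as.character(rid[1])]] <- iw
      rings[[as.character(rid[2])]] <- il
      placements[[kind]] <- list(atoms = il, on = base[il, , drop = FALSE],
                                 off_pos = sweep(base[il, , drop = FALSE], 2,
                                                 c(0, 0, 8), "+"),
                                 ring_ids = as.character(rid))
    }
  }
  # ring ids for atoms
  atoms$ring_id <- NA_integer_
  for (rid in names(rings)) atoms$ring_id[rings[[rid]]] <- as.integer(rid)

  n_at <- nrow(atoms)
  coords <- array(NA_real_, dim = c(n_frames, n_at, 3))
  occ_mat <- matrix(NA, n_frames, length(kinds), dimnames = list(NULL, kinds))
  for (i in seq_len(n_frames)) coords[i, , ] <- base
  for (kind in kinds) {
    on <- stats::runif(n_frames) < occupancies[[kind]]
    occ_mat[, kind] <- on
    pl <- placements[[kind]]
    for (i in which(!on)) coords[i, pl$atoms, ] <- pl$off_pos
  }
  topo <- topology(atoms, bonds = bonds, rings = rings)
  traj <- trajectory(topo, coords)
  maybe_write(traj, write_dir, "interactions")

  sels <- list(
    donors = selection(which(has_flag(topo, "donor")), "donors"),
    acceptors = selection(which(has_flag(topo, "acceptor")), "acceptors"),
    cations = selection(which(has_flag(topo, "cation_group")), "cations"),
    anions = selection(which(has_flag(topo, "anion_group")), "anions"),
    protein_nonpolar = selection(
      which(has_flag(topo, "nonpolar_carbon") & topo$atoms$chain == "A"),
      "protein nonpolar"),
    ligand_nonpolar = selection(
      which(has_flag(topo, "nonpolar_carbon") & topo$atoms$chain == "L"),
      "ligand nonpolar"),
    rings_protein = unlist(lapply(placements[grep("^pi", kinds, value = TRUE)],
                                  function(p) p$ring_ids[1])),
    rings_ligand = unlist(lapply(placements[grep("^pi", kinds, value = TRUE)],
                                 function(p) p$ring_ids[2])))
  list(trajectory = traj, realized = colMeans(occ_mat),
       scheduled = occupancies, occupancy = occ_mat, selections = sels)
}

#' Spherical-shell cavity system of known analytic volume
#'
#' A hollow shell of carbon pseudo-atoms (Bondi radius 1.70 A) encloses a
#' spherical cavity: shell atoms sit at radius r + 1.70 + 1.09, so the
#' vdW + pad exclusion carves the accessible region down to exactly the
#' cavity radius r, whose analytic volume 4/3 pi r^3 is returned as
#' ground truth. An optional two-state breathing schedule alternates the
#' cavity radius between two values. Shell surface density follows the
#' coverage bound for the exclusion test (see the methods vignette), so
#' boundary leakage is negligible against grid discretisation.
#'
#' @param n_frames number of frames.
#' @param radius cavity radius in Angstrom, or length-2 vector for the
#'   two-state schedule.
#' @param state_schedule for a two-state radius: per-frame state (1/2)
#'   vector, or NULL to alternate blocks of 5 frames.
#' @param shell_spacing approximate inter-atom spacing on the shell
#'   surface (default 0.45 A).
#' @param seed RNG seed (used only to jitter shell orientation).
#' @param write_dir optional directory for PDB + annotation output.
#' @return list with `trajectory`, `config` (a matched
#'   `ligdyn_pocket_config` holding the inclusion/seed spheres),
#'   `true_volumes` (per frame, A^3) and `radii` (per frame).
#' @export
gen_cavity_system <- function(n_frames = 1, radius = 4.0,
                              state_schedule = NULL, shell_spacing = 0.45,
                              seed = 1, write_dir = NULL) {
  stopifnot(n_frames >= 1, all(radius > 0), length(radius) %in% 1:2)
  set.seed(seed)
  if (length(radius) == 2) {
    if (is.null(state_schedule))
      state_schedule <- rep(rep(1:2, each = 5), length.out = n_frames)
    stopifnot(length(state_schedule) == n_frames, all(state_schedule %in% 1:2))
    radii <- radius[state_schedule]
  } else {
    radii <- rep(radius, n_frames)
  }
  pad <- bondi_radius("C") + 1.09   # 2.79 A: exclusion reach of a shell atom
  r_max <- max(radii)
  shell_r <- r_max + pad
  n_shell <- max(200L, ceiling(4 * pi * shell_r^2 / (shell_spacing^2 * sqrt(3) / 2)))
  dirs <- fibonacci_sphere(n_shell)
  # random global orientation so the lattice never aligns with the shell
  rot <- random_rotation()
  dirs <- dirs %*% t(rot)

  coords <- array(NA_real_, dim = c(n_frames, n_shell, 3))
  for (i in seq_len(n_frames)) coords[i, , ] <- dirs * (radii[i] + pad)
  atoms <- data.frame(name = "C", element = "C", resid = seq_len(n_shell),
                      resname = "SHL", chain = "S", stringsAsFactors = FALSE)
  traj <- trajectory(topology(atoms), coords)
  maybe_write(traj, write_dir, "cavity")
  cfg <- pocket_config(
    inclusion_spheres = list(list(center = c(0, 0, 0), radius = r_max + 0.5)),
    seed_spheres = list(list(center = c(0, 0, 0), radius = min(1.5, min(radii)))))
  list(trajectory = traj, config = cfg,
       true_volumes = 4 / 3 * pi * radii^3, radii = radii)
}

#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Synthetic docking funnel ensemble with known Pnear
#'
#' Samples a score-vs-RMSD docking ensemble with a controllable funnel:
#' a fraction `1 - decoy_fraction` of near-native models (small RMSD,
#' energies lowered by `funnel_depth`) and decoys spread over larger
#' RMSD. The ground-truth Pnear is evaluated directly from the sampled
#' points (plain unshifted summation of the Boltzmann-weighted Gaussian),
#' independently of the pipeline implementation.
#'
#' @param n_models ensemble size.
#' @param funnel_depth energy gap (score units) by which near-native
#'   models sit below the decoys.
#' @param decoy_fraction fraction of decoy models in [0, 1].
#' @param rmsd_scale decoy RMSD spread in Angstrom.
#' @param native_rmsd_sd RMSD spread of the near-native models.
#' @param params a `ligdyn_pnear_params` used for the ground-truth value.
#' @param seed RNG seed.
#' @return list with `ensemble` (a `ligdyn_funnel`) and `true_pnear`.
#' @export
gen_funnel_scores <- function(n_models = 2000, funnel_depth = 4,
                              decoy_fraction = 0.7, rmsd_scale = 8,
                              native_rmsd_sd = 0.2,
                              params = pnear_params(), seed = 1) {
  stopifnot(n_models >= 1, decoy_fraction >= 0, decoy_fraction <= 1)
  set.seed(seed)
  n_decoy <- round(n_models * decoy_fraction)
  n_native <- n_models - n_decoy
  rmsd <- c(abs(stats::rnorm(n_native, sd = native_rmsd_sd)),
            2 + stats::rexp(n_decoy, rate = 1 / rmsd_scale))
  iface <- c(stats::rnorm(n_native, mean = -funnel_depth, sd = 1),
             stats::rnorm(n_decoy, mean = 0, sd = 2))
  total <- iface + stats::rnorm(n_models, mean = -20, sd = 3)
  ids <- sprintf("model_%05d", seq_len(n_models))
  ens <- funnel_ensemble(ids, total, iface, rmsd)
  w <- exp(-iface / params$kBT)
  true_pnear <- sum(exp(-rmsd^2 / params$lambda^2) * w) / sum(w)
  list(ensemble = ens, true_pnear = true_pnear)
}

#' Furanose ring coordinates at a prescribed pseudorotation state
#'
#' Builds 3D coordinates of a 5-atom furanose ring (order O4', C1', C2',
#' C3', C4') whose endocyclic torsions satisfy
#' nu_j = tau_m cos(P + 144 deg j) (nu_0 about the C2'-C3' bond, matching
#' [pseudorotation()]). Coordinates are found by quasi-Newton refinement
#' of a planar-ring start against the target torsions with soft bond-
#' length (1.54 A) and bond-angle restraints; the fit must close within
#' `tol_deg` or an error is raised.
#'
#' @param P pseudorotation phase in degrees.
#' @param tau_m pucker amplitude in degrees (>= 0).
#' @param tol_deg maximum allowed deviation of any achieved torsion from
#'   its target (default 0.3 deg).
#' @return 5 x 3 coordinate matrix with attribute `nu` (achieved
#'   torsions).
#' @export
gen_furanose <- function(P, tau_m, tol_deg = 0.3) {
  stopifnot(tau_m >= 0)
  target <- tau_m * cos((P + 144 * (0:4)) * pi / 180)
  blen <- 1.54
  # planar regular pentagon start with a small out-of-plane seed
  ang <- 2 * pi * (0:4) / 5
  r0 <- blen / (2 * sin(pi / 5))
  x0 <- cbind(r0 * cos(ang), r0 * sin(ang),
              0.2 * (tau_m / 40) * cos((P * pi / 180) + 2 * ang))
  obj <- function(par) {
    x <- matrix(par, 5, 3)
    nu <- vapply(0:4, function(j) {
      i <- (j + 1:4) %% 5 + 1
      dihedral(x[i[1], ], x[i[2], ], x[i[3], ], x[i[4], ])
    }, numeric(1))
    dnu <- (nu - target + 180) %% 360 - 180
    bl <- vapply(1:5, function(k) vnorm(x[k %% 5 + 1, ] - x[k, ]), numeric(1))
    ba <- vapply(1:5, function(k)
      angle_deg(x[(k - 2) %% 5 + 1, ], x[k, ], x[k %% 5 + 1, ]), numeric(1))
    sum(dnu^2) + 50 * sum((bl - blen)^2) + 0.02 * sum((ba - 104)^2)
  }
  fit <- stats::optim(as.vector(x0), obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  x <- matrix(fit$par, 5, 3)
  nu <- vapply(0:4, function(j) {
    i <- (j + 1:4) %% 5 + 1
    dihedral(x[i[1], ], x[i[2], ], x[i[3], ], x[i[4], ])
  }, numeric(1))
  err <- max(abs((nu - target + 180) %% 360 - 180))
  if (err > tol_deg)
    stop(sprintf("infeasible torsion set: best fit off by %.2f deg (P=%g, tau_m=%g)",
                 err, P, tau_m))
  attr(x, "nu") <- nu
  x
}

#' Trajectory of a furanose ring following a pucker schedule
#'
#' @param schedule data.frame with per-frame columns `P` and `tau_m`.
#' @param jitter_sigma optional small Gaussian coordinate noise (A).
#' @param seed RNG seed (used for jitter and random frame orientation).
#' @param write_dir optional directory for PDB + annotation output.
#' @return list with `trajectory`, `ring` (atom indices in canonical
#'   order) and the `schedule`.
#' @export
gen_furanose_trajectory <- function(schedule, jitter_sigma = 0, seed = 1,
                                    write_dir = NULL) {
  stopifnot(is.data.frame(schedule), all(c("P", "tau_m") %in% names(schedule)))
  set.seed(seed)
  nf <- nrow(schedule)
  coords <- array(NA_real_, dim = c(nf, 5, 3))
  for (i in seq_len(nf)) {
    x <- gen_furanose(schedule$P[i], schedule$tau_m[i])
    x <- x %*% t(random_rotation())         # pose should not matter
    if (jitter_sigma > 0)
      x <- x + matrix(stats::rnorm(15, sd = jitter_sigma), 5, 3)
    coords[i, , ] <- x
  }
  atoms <- data.frame(name = c("O4'", "C1'", "C2'", "C3'", "C4'"),
                      element = c("O", "C", "C", "C", "C"),
                      resid = 900L, resname = "LIG", chain = "L",
                      ring_id = 1L, stringsAsFactors = FALSE)
  topo <- topology(atoms, rings = list("1" = 1:5))
  traj <- trajectory(topo, coords)
  maybe_write(traj, write_dir, "furanose")
  list(trajectory = traj, ring = 1:5, schedule = schedule)
}
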
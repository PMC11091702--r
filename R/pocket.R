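# Grid-based binding-site volume measurement, following the POVME-style
# algorithm: an axis-aligned lattice restricted to user-supplied inclusion
# spheres, seed points near the ligand position, bounded region growth
# (grid points up to the expansion radius away from the seed set, iterated
# to closure), then removal of every grid point closer to a protein atom
# than that atom's van der Waals radius plus a 1.09 A hydrogen-bond pad.
# Volume = retained point count x spacing^3.

#' Pocket-volume grid configuration
#'
#' @param inclusion_spheres list of `list(center = c(x, y, z), radius = r)`
#'   defining the region the grid may cover (>= 1 sphere).
#' @param seed_spheres list of spheres (same form) whose grid points seed
#'   the region growth; each seed-sphere center must lie inside some
#'   inclusion sphere. May be empty when seeding from a ligand selection.
#' @param grid_spacing lattice spacing in Angstrom (default 1.0; the
#'   convergence properties of the volume estimate are covered by the
#'   finer-spacing tests).
#' @param expansion_radius region-growth radius in Angstrom (default 3.0).
#' @param exclusion_pad added to each protein atom's vdW radius for the
#'   exclusion test (default 1.09, a hydrogen-bond length).
#' @param convex_hull if TRUE, clip retained points to the convex hull of
#'   the seed-grown region before exclusion (default FALSE).
#' @param single_expansion if TRUE, grow the seed set by one dilation only
#'   instead of iterating to closure (default FALSE).
#' @param exclude_hydrogens if TRUE (default) only heavy protein atoms
#'   enter the exclusion test.
#' @return list of class `ligdyn_pocket_config`.
#' @export
pocket_config <- function(inclusion_spheres, seed_spheres = list(),
                          grid_spacing = 1.0, expansion_radius = 3.0,
                          exclusion_pad = 1.09, convex_hull = FALSE,
                          single_expansion = FALSE, exclude_hydrogens = TRUE) {
  stopifnot(grid_spacing > 0, expansion_radius > 0, exclusion_pad >= 0)
  chk <- function(s) is.list(s) && length(s$center) == 3 && s$radius > 0
  if (!length(inclusion_spheres) || !all(vapply(inclusion_spheres, chk, logical(1))))
    stop("need >= 1 valid inclusion sphere (center, radius > 0)")
  if (length(seed_spheres)) {
    if (!all(vapply(seed_spheres, chk, logical(1))))
      stop("invalid seed sphere")
    inside <- vapply(seed_spheres, function(s) {
      any(vapply(inclusion_spheres, function(inc)
        vnorm(s$center - inc$center) <= inc$radius, logical(1)))
    }, logical(1))
    if (!all(inside))
      stop("seed sphere center(s) outside every inclusion sphere")
  }
  structure(list(inclusion_spheres = inclusion_spheres,
                 seed_spheres = seed_spheres, grid_spacing = grid_spacing,
                 expansion_radius = expansion_radius,
                 exclusion_pad = exclusion_pad, convex_hull = convex_hull,
                 single_expansion = single_expansion,
                 exclude_hydrogens = exclude_hydrogens),
            class = "ligdyn_pocket_config")
}

#' Build the inclusion-region grid
#'
#' Axis-aligned lattice at the configured spacing covering the bounding
#' box of the inclusion spheres, restricted to points inside at least one
#' inclusion sphere. The lattice is anchored at the bounding-box minimum
#' corner, so the grid is deterministic for a given configuration.
#'
#' @param cfg a `ligdyn_pocket_config`.
#' @return n x 3 matrix of grid points (Angstrom).
#' @export
build_grid <- function(cfg) {
  stopifnot(inherits(cfg, "ligdyn_pocket_config"))
  centers <- do.call(rbind, lapply(cfg$inclusion_spheres, function(s) s$center))
  radii <- vapply(cfg$inclusion_spheres, function(s) s$radius, numeric(1))
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  h <- cfg$grid_spacing
  npts <- prod(floor((hi - lo) / h) + 1)
  if (npts > 1e8)
    stop("grid would have ", format(npts, big.mark = ","),
         " points; increase grid_spacing")
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = h))
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  colnames(g) <- NULL
  keep <- rep(FALSE, nrow(g))
  for (i in seq_along(radii)) {
    keep <- keep | (rowSums(sweep(g, 2, centers[i, ])^2) <= radii[i]^2)
  }
  g[keep, , drop = FALSE]
}

# squared distance from each point in g to the nearest of pts, chunked in
# both dimensions to bound memory
#' @keywords internal
min_dist2_to <- function(g, pts, chunk = 4096L, pchunk = 8192L) {
  out <- rep(Inf, nrow(g))
  for (ps in seq(1, nrow(pts), by = pchunk)) {
    pe <- min(ps + pchunk - 1L, nrow(pts))
    pp <- pts[ps:pe, , drop = FALSE]
    p2 <- rowSums(pp^2)
    for (s in seq(1, nrow(g), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(g))
      gg <- g[s:e, , drop = FALSE]
      d2 <- outer(rowSums(gg^2), p2, "+") - 2 * tcrossprod(gg, pp)
      mins <- d2[cbind(seq_len(nrow(d2)),
                       max.col(-d2, ties.method = "first"))]
      out[s:e] <- pmin(out[s:e], pmax(0, mins))
    }
  }
  out
}

#' Retained pocket points for one frame
#'
#' Seed points are the grid points inside the seed spheres (or within one
#' grid spacing of a ligand atom when `ligand` is given). The region is
#' grown to include grid points within the expansion radius of any seed
#' point, iterated to closure inside the inclusion region (or a single
#' dilation under `single_expansion`), then every point closer to a
#' protein atom than vdW radius + exclusion pad is removed.
#'
#' @param frame n x 3 coordinate matrix of the structure.
#' @param topo the matching `ligdyn_topology` (vdW radii are taken from
#'   it).
#' @param grid grid point matrix from [build_grid()].
#' @param cfg a `ligdyn_pocket_config`.
#' @param protein optional selection of protein atoms for the exclusion
#'   test; default all atoms not in `ligand`.
#' @param ligand optional selection of ligand atoms used for seeding when
#'   no seed spheres are configured.
#' @return matrix of retained grid points; a zero-row matrix (with a
#'   warning) when the seed set is empty.
#' @export
pocket_points <- function(frame, topo, grid, cfg, protein = NULL, ligand = NULL) {
  stopifnot(inherits(cfg, "ligdyn_pocket_config"))
  n <- nrow(topo$atoms)
  li <- if (is.null(ligand)) integer(0) else sel_indices(ligand, n)
  pi_ <- if (is.null(protein)) setdiff(seq_len(n), li) else sel_indices(protein, n)
  if (cfg$exclude_hydrogens)
    pi_ <- pi_[toupper(topo$atoms$element[pi_]) != "H"]

  # seeds
  seed <- rep(FALSE, nrow(grid))
  if (length(cfg$seed_spheres)) {
    for (s in cfg$seed_spheres)
      seed <- seed | (rowSums(sweep(grid, 2, s$center)^2) <= s$radius^2)
  } else if (length(li)) {
    d2 <- min_dist2_to(grid, frame[li, , drop = FALSE])
    seed <- d2 <= cfg$grid_spacing^2
  } else {
    stop("no seed spheres configured and no ligand selection given")
  }
  if (!any(seed)) {
    warning("empty seed set; pocket volume is 0")
    return(grid[integer(0), , drop = FALSE])
  }

  # region growth within the inclusion-clipped grid; only the points added
  # in the previous sweep can reach new ones, so the frontier suffices
  region <- seed
  frontier <- which(seed)
  cand <- which(!region)
  while (length(cand) && length(frontier)) {
    d2 <- min_dist2_to(grid[cand, , drop = FALSE],
                       grid[frontier, , drop = FALSE])
    add <- d2 <= cfg$expansion_radius^2
    if (!any(add)) break
    frontier <- cand[add]
    region[frontier] <- TRUE
    cand <- cand[!add]
    if (cfg$single_expansion) break
  }
  pts <- grid[region, , drop = FALSE]

  # optional convex-hull clipping: keep only grown points inside the hull
  # of the seed set
  if (cfg$convex_hull && sum(seed) >= 4 && nrow(pts)) {
    inside <- in_convex_hull(pts, grid[seed, , drop = FALSE],
                             tol = 1e-6 * max(1, cfg$grid_spacing))
    pts <- pts[inside, , drop = FALSE]
  }

  # vdW + pad exclusion
  if (length(pi_) && nrow(pts)) {
    keep <- rep(TRUE, nrow(pts))
    radii <- topo$atoms$vdw_radius[pi_] + cfg$exclusion_pad
    px <- frame[pi_, , drop = FALSE]
    chunk <- 4096L
    for (s in seq(1, nrow(pts), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(pts))
      gg <- pts[s:e, , drop = FALSE]
      d2 <- outer(rowSums(gg^2), rowSums(px^2), "+") - 2 * tcrossprod(gg, px)
      inside <- d2 < matrix(radii^2, nrow(gg), length(radii), byrow = TRUE)
      keep[s:e] <- rowSums(inside) == 0
    }
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

# Point-in-convex-hull membership by Gilbert's projection algorithm:
# minimise ||x - p|| over x in conv(cloud) by repeated support-point line
# searches; p is inside the hull iff the minimised distance is ~0. Exact
# enough for grid clipping and needs no external hull library.
#' @keywords internal
in_convex_hull <- function(pts, cloud, tol = 1e-6, max_iter = 200) {
  vapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, ]
    # start from the nearest cloud point
    d2 <- rowSums(sweep(cloud, 2, p)^2)
    x <- cloud[which.min(d2), ]
    for (it in seq_len(max_iter)) {
      d <- x - p
      nd <- sqrt(sum(d^2))
      if (nd <= tol) return(TRUE)
      # support point of the cloud in direction -d
      s <- cloud[which.min(cloud %*% d), ]
      # converged: no support point improves the distance
      if (sum(d * (x - s)) <= tol * nd) return(FALSE)
      seg <- x - s
      t_star <- min(1, max(0, sum((x - p) * seg) / sum(seg^2)))
      x <- x - t_star * seg
    }
    sqrt(sum((x - p)^2)) <= tol
  }, logical(1))
}

#' Per-frame pocket volume series
#'
#' Runs [pocket_points()] on every frame with a fixed configuration (the
#' same spheres for every frame, so unbound and bound systems are
#' comparable) and reports volume = retained point count x spacing^3 plus
#' summary statistics.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param cfg a `ligdyn_pocket_config`.
#' @param protein,ligand optional selections passed to [pocket_points()].
#' @param grid optional precomputed grid from [build_grid()].
#' @return list of class `ligdyn_pocket_series` with `volumes` (A^3 per
#'   frame), `mean`, `sd`, `min`, `max`, `spacing`.
#' @export
volume_series <- function(traj, cfg, protein = NULL, ligand = NULL,
                          grid = NULL) {
  if (is.null(grid)) grid <- build_grid(cfg)
  vols <- vapply(seq_len(n_frames(traj)), function(i) {
    pts <- pocket_points(frame_coords(traj, i), traj$topology, grid, cfg,
                         protein = protein, ligand = ligand)
    nrow(pts) * cfg$grid_spacing^3
  }, numeric(1))
  structure(list(volumes = vols, mean = mean(vols),
                 sd = if (length(vols) > 1) stats::sd(vols) else 0,
                 min = min(vols), max = max(vols),
                 spacing = cfg$grid_spacing),
            class = "ligdyn_pocket_series")
}

#' @export
print.ligdyn_pocket_series <- function(x, ...) {
  cat(sprintf(
    "ligdyn pocket volumes: %d frames, mean %.1f +/- %.1f A^3 (min %.1f, max %.1f), spacing %.2f A\n",
    length(x$volumes), x$mean, x$sd, x$min, x$max, x$spacing))
  invisible(x)
}

#' Write retained pocket points as a pseudo-atom PDB for visualisation
#'
#' @param pts matrix of retained points from [pocket_points()].
#' @param path output path.
#' @export
write_pocket_points_pdb <- function(pts, path) {
  if (!nrow(pts)) {
    writeLines("END", path)
    return(invisible(path))
  }
  atoms <- data.frame(name = "PT", element = "C",
                      resid = 1L, resname = "PKT", chain = "X",
                      stringsAsFactors = FALSE)[rep(1, nrow(pts)), ]
  atoms$resid <- seq_len(nrow(pts))
  topo <- topology(atoms)
  write_multimodel_pdb(trajectory(topo, pts), path)
}
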
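# Essential dynamics: principal component analysis of C-alpha positional
# fluctuations across concatenated ensembles.
#
# Trajectories are concatenated, every frame is least-squares fitted onto
# the first frame of the concatenation over the C-alpha selection, and the
# 3N x 3N covariance of positional fluctuations about the concatenated
# mean is diagonalised. Per-ensemble projections onto the shared
# eigenbasis let distinct states (e.g. unbound vs bound) be compared in
# one essential subspace.

#' Essential-dynamics PCA over one or more trajectories
#'
#' @param trajs a single `ligdyn_trajectory`, or a named list of
#'   trajectories (the names label the source ensembles). All must share
#'   the same atom mapping for the fit selection.
#' @param calpha selection of atoms to analyse (conventionally the
#'   C-alphas); default all atoms.
#' @param reference "first" (default) fits every frame onto the first
#'   frame of the concatenation; "mean" iterates the fit onto the mean
#'   structure.
#' @return list of class `ligdyn_essential_dynamics` with
#'   `mean_structure` (n x 3), `eigenvectors` (3n x k, columns orthonormal,
#'   descending eigenvalue order, sign fixed so each column's
#'   largest-magnitude element is positive), `eigenvalues` (A^2),
#'   `variance_fraction`, `projections` (frames x k, Angstrom) and
#'   `ensemble` (per-frame source label).
#' @export
fit_pca <- function(trajs, calpha = NULL, reference = c("first", "mean")) {
  reference <- match.arg(reference)
  if (inherits(trajs, "ligdyn_trajectory")) trajs <- list(ensemble = trajs)
  if (!length(trajs)) stop("no trajectories supplied")
  if (is.null(names(trajs)) || any(!nzchar(names(trajs))))
    names(trajs) <- paste0("ensemble", seq_along(trajs))
  nat <- dim(trajs[[1]]$coords)[2]
  idx <- sel_indices(calpha, nat)
  for (t in trajs) {
    if (dim(t$coords)[2] != nat)
      stop("trajectories disagree on atom count; C-alpha mapping must match")
  }
  coords <- do.call(abind3, lapply(trajs, function(t) t$coords))
  labels <- rep(names(trajs), vapply(trajs, n_frames, numeric(1)))
  nf <- dim(coords)[1]
  if (nf < 2) stop("need at least 2 total frames")

  sub <- coords[, idx, , drop = FALSE]
  ref <- matrix(sub[1, , ], ncol = 3)
  aligned <- superpose_frames(sub, ref, seq_along(idx))
  if (reference == "mean") {
    for (it in 1:2) {
      m <- apply(aligned, c(2, 3), mean)
      aligned <- superpose_frames(aligned, m, seq_along(idx))
    }
  }
  mstr <- apply(aligned, c(2, 3), mean)

  # frames x 3n fluctuation matrix (atom-major: x1 y1 z1 x2 ...)
  n <- length(idx)
  x <- matrix(NA_real_, nf, 3 * n)
  for (k in 1:3) x[, seq(k, 3 * n, by = 3)] <- aligned[, , k]
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  covm <- crossprod(xc) / nf
  eig <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # deterministic sign: largest-magnitude element of each column positive
  for (j in seq_len(ncol(vecs))) {
    piv <- which.max(abs(vecs[, j]))
    if (vecs[piv, j] < 0) vecs[, j] <- -vecs[, j]
  }
  proj <- xc %*% vecs
  tot <- sum(vals)
  structure(list(mean_structure = mstr,
                 eigenvectors = vecs, eigenvalues = vals,
                 variance_fraction = if (tot > 0) vals / tot else vals,
                 projections = proj, ensemble = labels,
                 atom_indices = idx, trace_covariance = sum(diag(covm))),
            class = "ligdyn_essential_dynamics")
}

# bind coordinate arrays along the frame dimension
#' @keywords internal
abind3 <- function(...) {
  arrs <- list(...)
  d2 <- dim(arrs[[1]])[2]
  nf <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, dim = c(nf, d2, 3))
  at <- 1L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at:(at + k - 1L), , ] <- a
    at <- at + k
  }
  out
}

#' @export
print.ligdyn_essential_dynamics <- function(x, ...) {
  k <- min(3, length(x$eigenvalues))
  cat("ligdyn essential dynamics:", nrow(x$projections), "frames,",
      length(x$atom_indices), "atoms\n")
  cat(sprintf("  PC%d: eigenvalue %.3f A^2 (%.1f%% of variance)\n",
              seq_len(k), x$eigenvalues[seq_len(k)],
              100 * x$variance_fraction[seq_len(k)]), sep = "")
  invisible(x)
}

#' Individual and cumulative variance fractions for the top components
#'
#' @param res a `ligdyn_essential_dynamics`.
#' @param k number of components to report.
#' @return data.frame (component, eigenvalue, variance_fraction,
#'   cumulative_fraction).
#' @export
variance_report <- function(res, k = 10) {
  k <- min(k, length(res$eigenvalues))
  data.frame(component = seq_len(k),
             eigenvalue = res$eigenvalues[seq_len(k)],
             variance_fraction = res$variance_fraction[seq_len(k)],
             cumulative_fraction = cumsum(res$variance_fraction)[seq_len(k)])
}

#' 2D Gaussian KDE basin map over two principal components
#'
#' Gaussian kernel density estimate of the (PC1, PC2) projections on a
#' regular grid, per ensemble and pooled, with local density maxima
#' reported as conformational basins. Bandwidth follows the normal
#' reference (Scott-type) rule.
#'
#' @param res a `ligdyn_essential_dynamics`.
#' @param components length-2 integer vector of component indices
#'   (default c(1, 2)).
#' @param n_grid evaluation grid size per axis (default 128).
#' @param min_density_frac basins below this fraction of the global
#'   density maximum are suppressed (default 0.1), which filters
#'   sampling-tail bumps.
#' @return list of class `ligdyn_kde_map`: per-ensemble entries plus
#'   `"pooled"`, each with `x`, `y`, `z` (density grid integrating to ~1)
#'   and `basins` (data.frame x, y, density of local maxima, strongest
#'   first).
#' @export
kde_basin_map <- function(res, components = c(1, 2), n_grid = 128,
                          min_density_frac = 0.1) {
  stopifnot(length(components) == 2,
            max(components) <= ncol(res$projections))
  p1 <- res$projections[, components[1]]
  p2 <- res$projections[, components[2]]
  if (stats::sd(p1) < 1e-12 || stats::sd(p2) < 1e-12)
    stop("degenerate (zero-variance) projections")
  groups <- c(split(seq_along(p1), res$ensemble),
              list(pooled = seq_along(p1)))
  # shared evaluation window over all frames, padded by 3 bandwidths
  h1 <- MASS::bandwidth.nrd(p1)
  h2 <- MASS::bandwidth.nrd(p2)
  lims <- c(range(p1) + c(-3, 3) * h1, range(p2) + c(-3, 3) * h2)
  out <- lapply(groups, function(ix) {
    kd <- MASS::kde2d(p1[ix], p2[ix], n = n_grid, lims = lims)
    basins <- kde_local_maxima(kd, min_density_frac)
    list(x = kd$x, y = kd$y, z = kd$z, basins = basins)
  })
  structure(out, class = "ligdyn_kde_map")
}

# strict local maxima of a density grid (8-neighbourhood) above a
# relative density floor
#' @keywords internal
kde_local_maxima <- function(kd, min_density_frac = 0.1) {
  z <- kd$z
  nr <- nrow(z); nc <- ncol(z)
  hits <- NULL
  floor_ <- min_density_frac * max(z)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      v <- z[i, j]
      if (v < floor_) next
      nb <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v >= max(nb) && sum(nb == v) == 1)
        hits <- rbind(hits, c(kd$x[i], kd$y[j], v))
    }
  }
  if (is.null(hits))
    return(data.frame(x = numeric(0), y = numeric(0), density = numeric(0)))
  df <- data.frame(x = hits[, 1], y = hits[, 2], density = hits[, 3])
  df[order(-df$density), ]
}

#' Reconstruct the motion along one principal component
#'
#' Linear interpolation `mean + t * eigenvector` between the two extreme
#' projection values t_min and t_max observed for the component, plus the
#' porcupine vectors (per-atom displacement over the full sweep: the
#' eigenvector reshaped per atom and scaled by t_max - t_min). Arrow
#' direction gives the direction of motion, arrow length the movement
#' strength.
#'
#' @param res a `ligdyn_essential_dynamics`.
#' @param component component index.
#' @param n_frames number of interpolation steps (>= 2; the first/last
#'   frames are exactly the two extreme-projection structures).
#' @return list of class `ligdyn_motion` with `frames` (n_frames x atoms
#'   x 3 array), `porcupine` (atoms x 3 displacement matrix, Angstrom),
#'   `t` (the projection values interpolated over).
#' @export
reconstruct_motion <- function(res, component = 1, n_frames = 20) {
  stopifnot(component >= 1, component <= length(res$eigenvalues),
            n_frames >= 2)
  if (res$eigenvalues[component] <= 1e-12)
    stop("component ", component, " has (numerically) zero eigenvalue")
  t_rng <- range(res$projections[, component])
  ts <- seq(t_rng[1], t_rng[2], length.out = n_frames)
  vec <- res$eigenvectors[, component]
  n <- nrow(res$mean_structure)
  per_atom <- matrix(vec, n, 3, byrow = TRUE)
  frames <- array(NA_real_, dim = c(n_frames, n, 3))
  for (i in seq_len(n_frames))
    frames[i, , ] <- res$mean_structure + ts[i] * per_atom
  structure(list(frames = frames,
                 porcupine = per_atom * (t_rng[2] - t_rng[1]),
                 t = ts, component = component),
            class = "ligdyn_motion")
}
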
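# Superposition-based structural descriptors.
#
# All operations rest on Kabsch least-squares superposition (proper
# rotations only). Fit and measure selections are decoupled so the two
# ligand-RMSD variants fall out naturally: protein-aligned ligand RMSD
# (fit backbone, measure ligand) reports displacement of the ligand
# relative to the binding site, while ligand-internal RMSD (fit and
# measure on the ligand) isolates conformational fluctuation.

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimising the RMSD of
#' `mobile` onto `reference` over the fit atoms; reflections are excluded.
#'
#' @param mobile,reference n x 3 coordinate matrices (Angstrom), same atom
#'   order.
#' @param fit_selection optional `ligdyn_selection` (or integer indices)
#'   giving the atoms to fit on; default all rows.
#' @return list of class `ligdyn_superposition` with `rotation` (3 x 3,
#'   det +1), `translation` (length-3), and `rmsd` over the fit atoms.
#'   The transform maps mobile coordinates as `x %*% t(rotation) +
#'   translation`.
#' @export
kabsch_superpose <- function(mobile, reference, fit_selection = NULL) {
  idx <- sel_indices(fit_selection, nrow(mobile))
  if (length(idx) < 3) stop("need at least 3 fit atoms")
  xm <- mobile[idx, , drop = FALSE]
  xr <- reference[idx, , drop = FALSE]
  if (nrow(xm) != nrow(xr)) stop("fit atom counts differ")
  cm <- colMeans(xm)
  cr <- colMeans(xr)
  a <- sweep(xm, 2, cm)
  b <- sweep(xr, 2, cr)
  # collinearity check: rank of the centered fit set
  if (min(svd(a)$d[1:2], svd(b)$d[1:2]) < 1e-8 * max(1, max(abs(a)), max(abs(b))))
    stop("fit atoms are collinear or degenerate")
  h <- crossprod(a, b)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- sweep(a %*% t(rot), 2, -cr, "-") # rotated+recentered fit atoms
  rmsd <- sqrt(mean(rowSums((fitted - xr)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "ligdyn_superposition")
}

# Accept a ligdyn_selection, raw indices, or NULL (= all n atoms).
#' @keywords internal
sel_indices <- function(sel, n) {
  if (is.null(sel)) return(seq_len(n))
  idx <- if (inherits(sel, "ligdyn_selection")) sel$indices else as.integer(sel)
  if (!length(idx)) stop("empty selection")
  if (any(idx < 1 | idx > n)) stop("selection index out of range")
  idx
}

#' @keywords internal
sel_label <- function(sel, default = "") {
  if (inherits(sel, "ligdyn_selection") && nzchar(sel$label)) sel$label else default
}

#' @keywords internal
descriptor_series <- function(values, label, unit = "A") {
  structure(list(values = values, selection_label = label, unit = unit,
                 median = stats::median(values), sd = stats::sd(values)),
            class = "ligdyn_series")
}

#' @export
print.ligdyn_series <- function(x, ...) {
  cat(sprintf("ligdyn series [%s]: %d values, median %.3f %s, sd %.3f %s\n",
              x$selection_label, length(x$values), x$median, x$unit,
              if (is.na(x$sd)) 0 else x$sd, x$unit))
  invisible(x)
}

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Each frame is superposed on the reference frame over `fit_selection`,
#' then the RMSD of `measure_selection` is taken. With fit == measure the
#' reference frame scores exactly zero.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param reference_frame frame index of the reference (default 1).
#' @param fit_selection atoms to superpose on (default all).
#' @param measure_selection atoms to measure (default the fit atoms).
#' @return a `ligdyn_series` with one value per frame (Angstrom) and
#'   median/SD annotations.
#' @export
rmsd_series <- function(traj, reference_frame = 1, fit_selection = NULL,
                        measure_selection = NULL) {
  nat <- dim(traj$coords)[2]
  fit <- sel_indices(fit_selection, nat)
  meas <- if (is.null(measure_selection)) fit else sel_indices(measure_selection, nat)
  ref <- frame_coords(traj, reference_frame)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)
    sp <- kabsch_superpose(x, ref, fit)
    moved <- sweep(x[meas, , drop = FALSE] %*% t(sp$rotation), 2,
                   -sp$translation, "-")
    sqrt(mean(rowSums((moved - ref[meas, , drop = FALSE])^2)))
  }, numeric(1))
  descriptor_series(vals, sel_label(fit_selection, "fit"))
}

#' Ligand RMSD after protein alignment
#'
#' The complex is first aligned on the protein backbone of the reference
#' frame, then the RMSD of the ligand heavy atoms is measured with no
#' second superposition of the ligand — so rigid displacement of the
#' ligand relative to the protein is captured.
#'
#' @param traj a `ligdyn_trajectory`.
#' @param reference_frame reference frame index.
#' @param backbone protein backbone selection (fit atoms).
#' @param ligand_heavy ligand heavy-atom selection (measured atoms); must
#'   be disjoint from `backbone`.
#' @return a `ligdyn_series` (Angstrom).
#' @export
ligand_rmsd_protein_aligned <- function(traj, reference_frame = 1,
                                        backbone, ligand_heavy) {
  nat <- dim(traj$coords)[2]
  bi <- sel_indices(backbone, nat)
  li <- sel_indices(ligand_heavy, nat)
  if (length(intersect(bi, li)))
    stop("backbone and ligand selections overlap")
  out <- rmsd_series(traj, reference_frame, fit_selection = bi,
                     measure_selection = li)
  out$selection_label <- sel_label(ligand_heavy, "ligand|protein-aligned")
  out
}

#' Ligand-internal RMSD
#'
#' Fit and measure both on the ligand heavy atoms: rigid-body motion of
#' the ligand drops out and only conformational fluctuation remains.
#'
#' @inheritParams ligand_rmsd_protein_aligned
#' @export
ligand_internal_rmsd <- function(traj, reference_frame = 1, ligand_heavy) {
  out <- rmsd_series(traj, reference_frame, fit_selection = ligand_heavy,
                     measure_selection = ligand_heavy)
  out$selection_label <- sel_label(ligand_heavy, "ligand|internal")
  out
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed over `fit_selection` onto the trajectory mean
#' structure (computed self-consistently: initial mean from a first-frame
#' alignment, then one refit). The RMSF of each measured atom is its
#' root-mean-square deviation from its mean position.
#'
#' @param traj a `ligdyn_trajectory` with >= 2 frames.
#' @param fit_selection atoms to superpose on (default all).
#' @param measure_selection atoms to report (default the fit atoms).
#' @return numeric vector of per-atom RMSF values (Angstrom), named by
#'   atom index.
#' @export
rmsf <- function(traj, fit_selection = NULL, measure_selection = NULL) {
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames")
  nat <- dim(traj$coords)[2]
  fit <- sel_indices(fit_selection, nat)
  meas <- if (is.null(measure_selection)) fit else sel_indices(measure_selection, nat)
  aligned <- superpose_frames(traj$coords, frame_coords(traj, 1), fit)
  mstr <- apply(aligned, c(2, 3), mean)
  aligned <- superpose_frames(aligned, mstr, fit)
  mstr <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), mstr)^2
  out <- sqrt(apply(dev2[, meas, , drop = FALSE], 2, mean) * 3)
  names(out) <- meas
  out
}

# Superpose every frame of a coords array onto a reference structure.
#' @keywords internal
superpose_frames <- function(coords, ref, fit) {
  out <- coords
  for (i in seq_len(dim(coords)[1])) {
    x <- matrix(coords[i, , ], ncol = 3)
    sp <- kabsch_superpose(x, ref, fit)
    out[i, , ] <- sweep(x %*% t(sp$rotation), 2, -sp$translation, "-")
  }
  out
}

#' Radius of gyration per frame
#'
#' @param traj a `ligdyn_trajectory`.
#' @param selection atoms to include (default all).
#' @param mass_weighted if TRUE, weight by atomic mass (approximate integer
#'   masses by element); default FALSE — on a C-alpha selection weighting
#'   is immaterial.
#' @return a `ligdyn_series` (Angstrom).
#' @export
radius_of_gyration <- function(traj, selection = NULL, mass_weighted = FALSE) {
  nat <- dim(traj$coords)[2]
  idx <- sel_indices(selection, nat)
  w <- rep(1, length(idx))
  if (mass_weighted) {
    masses <- c(H = 1, C = 12, N = 14, O = 16, P = 31, S = 32)
    el <- toupper(traj$topology$atoms$element[idx])
    w <- unname(masses[el])
    w[is.na(w)] <- 12
  }
  w <- w / sum(w)
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    x <- frame_coords(traj, i)[idx, , drop = FALSE]
    com <- colSums(x * w)
    sqrt(sum(w * rowSums(sweep(x, 2, com)^2)))
  }, numeric(1))
  descriptor_series(vals, sel_label(selection, "Rg"))
}

#' All-to-all (2D) RMSD matrix
#'
#' Entry (i, j) is the superposed RMSD between frames i and j over
#' `fit_selection`; the matrix is symmetric with an exactly zero diagonal.
#' Blocks of low values along the diagonal indicate a persistent state;
#' low off-diagonal blocks show the trajectory revisiting earlier states.
#'
#' @param traj a `ligdyn_trajectory` with >= 2 frames.
#' @param fit_selection atoms to superpose and measure on.
#' @param stride keep every stride-th frame (default 1); for large
#'   trajectories the full matrix is quadratic in frames.
#' @return symmetric numeric matrix (Angstrom) with attribute `frames`
#'   giving the original frame indices used.
#' @export
pairwise_rmsd_matrix <- function(traj, fit_selection = NULL, stride = 1) {
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  keep <- seq(1, n_frames(traj), by = stride)
  nat <- dim(traj$coords)[2]
  fit <- sel_indices(fit_selection, nat)
  nf <- length(keep)
  frames <- lapply(keep, function(i) frame_coords(traj, i)[fit, , drop = FALSE])
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      m[i, j] <- m[j, i] <- kabsch_superpose(frames[[j]], frames[[i]])$rmsd
    }
  }
  attr(m, "frames") <- keep
  m
}
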
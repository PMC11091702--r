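# Conformational state analysis: density-based clustering of trajectory
# frames on the pairwise superposed-RMSD metric, and furanose
# pseudorotation (sugar pucker) classification.
#
# Pucker follows the Altona-Sundaralingam pseudorotation convention: the
# five endocyclic torsions of the O4'-C1'-C2'-C3'-C4' ring obey
# nu_j = tau_m * cos(P + 144 deg * j), so phase P and amplitude tau_m are
# recovered by the discrete Fourier inversion of the torsion set. The
# pucker wheel is divided into twenty 18-degree windows; C3'-endo is the
# north window P in [0, 36) and C2'-endo the south window P in [144, 180).

#' DBSCAN clustering of trajectory frames on pairwise RMSD
#'
#' Classic DBSCAN over the all-to-all superposed-RMSD matrix. A frame is
#' a core point when at least `min_points` frames (itself included) lie
#' within `eps`; clusters are grown from core points in frame order, so
#' border points reachable from several clusters deterministically join
#' the first-discovered one. Noise frames get label -1. Each cluster's
#' representative is its medoid (the member minimising summed within-
#' cluster RMSD).
#'
#' @param traj a `ligdyn_trajectory` (or a precomputed symmetric distance
#'   matrix via `dist_matrix`).
#' @param fit_selection atoms for the superposed RMSD (default all);
#'   ignored when `dist_matrix` is given.
#' @param eps neighbourhood radius in Angstrom (default 1.0).
#' @param min_points minimum neighbourhood size for a core point,
#'   including the point itself (default 42).
#' @param stride frame stride for the pairwise matrix.
#' @param dist_matrix optional precomputed symmetric frame-by-frame
#'   distance matrix; overrides `traj`/`fit_selection`/`stride`.
#' @return list of class `ligdyn_clusters` with `labels` (per frame, -1 =
#'   noise), `eps`, `min_points`, `n_clusters`, `representative_frames`
#'   (medoid frame index per cluster) and `frames` (original frame
#'   indices, after any stride).
#' @export
dbscan_rmsd <- function(traj = NULL, fit_selection = NULL, eps = 1.0,
                        min_points = 42, stride = 1, dist_matrix = NULL) {
  stopifnot(eps > 0, min_points >= 1)
  if (is.null(dist_matrix)) {
    if (is.null(traj)) stop("need a trajectory or a distance matrix")
    dist_matrix <- pairwise_rmsd_matrix(traj, fit_selection, stride = stride)
  }
  frames <- as.integer(attr(dist_matrix, "frames") %||% seq_len(nrow(dist_matrix)))
  n <- nrow(dist_matrix)
  if (!isTRUE(all.equal(dist_matrix, t(dist_matrix), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")

  nbr <- lapply(seq_len(n), function(i) which(dist_matrix[i, ] <= eps))
  core <- lengths(nbr) >= min_points
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbr[[i]]
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]
      qpos <- qpos + 1L
      if (is.na(labels[j]) || labels[j] == -1L) {
        newly <- is.na(labels[j])
        labels[j] <- cl
        if (newly && core[j]) queue <- c(queue, nbr[[j]])
      }
    }
  }
  labels[is.na(labels)] <- -1L

  reps <- integer(0)
  if (cl > 0) {
    reps <- vapply(seq_len(cl), function(k) {
      members <- which(labels == k)
      sums <- rowSums(dist_matrix[members, members, drop = FALSE])
      frames[members[which.min(sums)]]
    }, integer(1))
  }
  structure(list(labels = labels, eps = eps, min_points = min_points,
                 n_clusters = cl, representative_frames = reps,
                 frames = frames),
            class = "ligdyn_clusters")
}

#' @export
print.ligdyn_clusters <- function(x, ...) {
  cat(sprintf("ligdyn DBSCAN (eps %.2f A, minPts %d): %d cluster(s), %d noise frame(s) of %d\n",
              x$eps, x$min_points, x$n_clusters, sum(x$labels == -1L),
              length(x$labels)))
  if (x$n_clusters > 0) {
    sizes <- table(x$labels[x$labels > 0])
    cat("  sizes:", paste(sizes, collapse = ", "),
        "| medoid frames:", paste(x$representative_frames, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pseudorotation phase and amplitude of a furanose ring
#'
#' Computes the five endocyclic torsions of the canonical ring
#' O4'-C1'-C2'-C3'-C4', indexed so that nu_0 is the C1'-C2'-C3'-C4'
#' torsion (about the C2'-C3' bond) and subsequent nu_j advance around
#' the ring. With that indexing the pseudorotation model reads
#' nu_j = tau_m cos(P + 144 deg j), so nu_0 = tau_m cos(P) — the
#' classical relation placing C3'-endo near P = 18 deg and C2'-endo near
#' P = 162 deg. P and tau_m are recovered by the discrete Fourier
#' inversion: A = (2/5) sum nu_j cos(144 j), B = -(2/5) sum nu_j
#' sin(144 j), tau_m = sqrt(A^2 + B^2), P = atan2(B, A) in [0, 360).
#'
#' @param frame n x 3 coordinate matrix.
#' @param ring integer atom indices of the ring in canonical order
#'   O4', C1', C2', C3', C4'.
#' @return list with `P` (degrees in [0, 360), NA when the ring is
#'   essentially planar), `amplitude` (tau_m, degrees >= 0) and `nu`
#'   (the five torsions).
#' @export
pseudorotation <- function(frame, ring) {
  if (length(ring) != 5) stop("a furanose ring has exactly 5 atoms")
  x <- frame[ring, , drop = FALSE]
  if (ring_span_degenerate(x)) stop("degenerate ring geometry")
  # nu_0 = C1'-C2'-C3'-C4' (ring positions 2-3-4-5), advancing cyclically
  nu <- vapply(0:4, function(j) {
    i <- (j + 1:4) %% 5 + 1
    dihedral(x[i[1], ], x[i[2], ], x[i[3], ], x[i[4], ])
  }, numeric(1))
  jj <- 0:4
  a <- (2 / 5) * sum(nu * cos(2 * pi * 144 * jj / 360))
  b <- -(2 / 5) * sum(nu * sin(2 * pi * 144 * jj / 360))
  tau_m <- sqrt(a^2 + b^2)
  p <- atan2(b, a) * 180 / pi
  if (p < 0) p <- p + 360
  list(P = if (tau_m < 1e-6) NA_real_ else p, amplitude = tau_m, nu = nu)
}

#' @keywords internal
ring_span_degenerate <- function(x) {
  sv <- svd(sweep(x, 2, colMeans(x)))$d
  sv[2] < 1e-8 * max(1, sv[1])
}

# the twenty 18-degree windows of the pseudorotation wheel, by the phase
# of the window centre: window k covers P in [18k - 9, 18k + 9) ... the
# conventional naming instead anchors windows at [0,36) = C3'-endo etc.,
# i.e. window k covers [18k, 18(k+1)) in pairs (twist, envelope).
PUCKER_WHEEL <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                  "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Classify a pucker phase into a conformer label
#'
#' Twenty-window (18 degrees each) pseudorotation wheel, paired into the
#' ten canonical envelope/twist families: C3'-endo covers P in [0, 36),
#' C2'-endo covers P in [144, 180), and so on around the wheel. A ring
#' with amplitude below `min_amplitude` is reported as
#' "planar/undefined".
#'
#' @param P pseudorotation phase in degrees.
#' @param amplitude pucker amplitude tau_m in degrees.
#' @param min_amplitude amplitude tolerance below which the ring counts
#'   as planar (default 5 degrees).
#' @return conformer label string.
#' @export
classify_pucker <- function(P, amplitude, min_amplitude = 5) {
  if (is.na(P) || amplitude < min_amplitude) return("planar/undefined")
  p <- P %% 360
  PUCKER_WHEEL[floor(p / 36) + 1]
}

#' Per-frame pucker assignment for a trajectory
#'
#' @param traj a `ligdyn_trajectory`.
#' @param ring furanose ring atom indices in canonical order (or a ring id
#'   present in the topology).
#' @param min_amplitude passed to [classify_pucker()].
#' @return data.frame (frame, P, amplitude, label).
#' @export
pucker_series <- function(traj, ring, min_amplitude = 5) {
  if (is.character(ring) || (length(ring) == 1 && !is.null(traj$topology$rings[[as.character(ring)]])))
    ring <- traj$topology$rings[[as.character(ring)]]
  out <- lapply(seq_len(n_frames(traj)), function(i) {
    ps <- pseudorotation(frame_coords(traj, i), ring)
    data.frame(frame = i, P = ps$P, amplitude = ps$amplitude,
               label = classify_pucker(ps$P, ps$amplitude, min_amplitude),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of frames in a given pucker class
#'
#' @param traj a `ligdyn_trajectory`.
#' @param ring ring atom indices (canonical order) or topology ring id.
#' @param label conformer class, e.g. "C2'-endo".
#' @param min_amplitude passed to [classify_pucker()].
#' @return fraction in [0, 1]; multiply by 100 for the percentage of
#'   simulation time.
#' @export
pucker_fraction <- function(traj, ring, label = "C2'-endo", min_amplitude = 5) {
  ser <- pucker_series(traj, ring, min_amplitude)
  mean(ser$label == label)
}
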
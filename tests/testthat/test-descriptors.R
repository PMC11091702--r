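test_that("kabsch superposition recovers rigid motions exactly", {
  x <- four_point()
  sp <- kabsch_superpose(x, x)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- x %*% t(rot90) + matrix(c(3, -2, 5), 4, 3, byrow = TRUE)
  sp2 <- kabsch_superpose(moved, x)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(sp2$rotation), 1, tolerance = 1e-8)
})

test_that("kabsch rejects degenerate fit sets", {
  line <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(four_point()[1:2, ], four_point()[1:2, ]),
               "3 fit atoms")
})

test_that("kabsch RMSD matches a rotation-space optimisation oracle", {
  # independent oracle: minimise RMSD over Euler angles (translation =
  # centroid match) by Nelder-Mead from several starts
  oracle_rmsd <- function(mobile, ref) {
    am <- sweep(mobile, 2, colMeans(mobile))
    ar <- sweep(ref, 2, colMeans(ref))
    euler <- function(p) {
      cz <- cos(p[1]); sz <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
      cx <- cos(p[3]); sx <- sin(p[3])
      matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
        matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
        matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    }
    f <- function(p) sqrt(mean(rowSums((am %*% t(euler(p)) - ar)^2)))
    best <- Inf
    set.seed(11)
    for (k in 1:12) {
      st <- runif(3, -pi, pi)
      o <- optim(st, f, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-14))
      best <- min(best, o$value)
    }
    best
  }
  set.seed(5)
  for (case in 1:3) {
    ref <- four_point()
    mobile <- ref + matrix(rnorm(12, sd = 0.4), 4, 3)
    expect_equal(kabsch_superpose(mobile, ref)$rmsd, oracle_rmsd(mobile, ref),
                 tolerance = 1e-3)
  }
})

test_that("kabsch agrees with the bio3d reference implementation", {
  set.seed(8)
  for (k in 1:5) {
    n <- 10
    ref <- matrix(rnorm(3 * n, sd = 3), n, 3)
    mobile <- ref + matrix(rnorm(3 * n, sd = 0.5), n, 3)
    ours <- kabsch_superpose(mobile, ref)$rmsd
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                              mobile = as.vector(t(mobile))))
    theirs <- sqrt(mean((fitted - as.vector(t(ref)))^2) * 3)
    expect_equal(ours, theirs, tolerance = 1e-6)
  }
})

test_that("rmsd_series composes per-frame kabsch calls and zeroes the reference", {
  set.seed(3)
  frames <- lapply(1:4, function(i) four_point() + matrix(rnorm(12, sd = 0.3), 4, 3))
  traj <- traj_from_frames(frames)
  ser <- rmsd_series(traj, reference_frame = 2)
  direct <- vapply(frames, function(f)
    kabsch_superpose(f, frames[[2]])$rmsd, numeric(1))
  expect_equal(ser$values, direct, tolerance = 1e-10)
  expect_equal(ser$values[2], 0, tolerance = 1e-12)

  # translated copy of the reference scores 0 when fit == measure
  traj2 <- traj_from_frames(list(four_point(), four_point() + 5))
  expect_equal(rmsd_series(traj2)$values, c(0, 0), tolerance = 1e-10)
})

test_that("protein-aligned ligand RMSD captures rigid ligand displacement", {
  # atoms 1-4 protein backbone, atoms 5-7 ligand
  prot <- rbind(four_point() * 2)
  lig <- rbind(c(5, 5, 5), c(6.5, 5, 5), c(5, 6.5, 5.8))
  f1 <- rbind(prot, lig)
  f2 <- rbind(prot, sweep(lig, 2, c(2, 0, 0), "+"))
  topo <- topology(data.frame(
    name = c("N", "CA", "C", "O", "C1", "C2", "C3"),
    element = "C", resid = c(1, 1, 1, 1, 9, 9, 9),
    resname = c(rep("ALA", 4), rep("LIG", 3)), chain = c(rep("A", 4), rep("L", 3)),
    stringsAsFactors = FALSE))
  traj <- traj_from_frames(list(f1, f2), topo)
  bb <- selection(1:4); lg <- selection(5:7)
  ser <- ligand_rmsd_protein_aligned(traj, 1, bb, lg)
  expect_equal(ser$values, c(0, 2), tolerance = 1e-9)
  expect_error(ligand_rmsd_protein_aligned(traj, 1, selection(1:5), lg),
               "overlap")
  # internal RMSD ignores the rigid shift entirely
  expect_equal(ligand_internal_rmsd(traj, 1, lg)$values, c(0, 0),
               tolerance = 1e-9)
  # and equals rmsd_series with fit == measure == ligand by definition
  expect_equal(ligand_internal_rmsd(traj, 1, lg)$values,
               rmsd_series(traj, 1, lg, lg)$values, tolerance = 1e-12)
})

test_that("rmsf reproduces the closed form for a two-point oscillation", {
  # one atom oscillating +/- a along x against a rigid frame
  a <- 0.8
  base <- rbind(four_point() * 3, c(2, 2, 2))
  frames <- lapply(1:40, function(i) {
    f <- base
    f[5, 1] <- f[5, 1] + a * (-1)^i
    f
  })
  traj <- traj_from_frames(frames)
  out <- rmsf(traj, fit_selection = selection(1:4),
              measure_selection = selection(1:5))
  expect_equal(unname(out[5]), a, tolerance = 1e-6)
  expect_lt(max(out[1:4]), 1e-6)
  # frame order is immaterial
  out2 <- rmsf(traj_from_frames(frames[sample(40)]),
               fit_selection = selection(1:4), measure_selection = selection(1:5))
  expect_equal(unname(out2), unname(out), tolerance = 1e-8)
  expect_error(rmsf(traj_from_frames(frames[1])), "2 frames")
})

test_that("radius of gyration matches hand geometry and is translation invariant", {
  topo <- toy_topology(2)
  traj <- traj_from_frames(list(rbind(c(0, 0, 0), c(2, 0, 0))), topo)
  expect_equal(radius_of_gyration(traj)$values, 1.0)
  point <- traj_from_frames(list(rbind(c(1, 1, 1), c(1, 1, 1))), topo)
  expect_equal(radius_of_gyration(point)$values, 0)
  shifted <- traj_from_frames(list(rbind(c(10, -3, 7), c(12, -3, 7))), topo)
  expect_equal(radius_of_gyration(shifted)$values,
               radius_of_gyration(traj)$values)
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and matches nested kabsch", {
  set.seed(9)
  frames <- lapply(1:4, function(i) four_point() + matrix(rnorm(12, sd = 0.5), 4, 3))
  traj <- traj_from_frames(frames)
  m <- pairwise_rmsd_matrix(traj)
  expect_equal(diag(m), rep(0, 4))
  expect_equal(m, t(m), tolerance = 1e-8)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(m[i, j], kabsch_superpose(frames[[j]], frames[[i]])$rmsd,
                 tolerance = 1e-10)
  ident <- pairwise_rmsd_matrix(traj_from_frames(frames[c(1, 1)]))
  expect_equal(ident, matrix(0, 2, 2), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("descriptors are invariant under global rigid motion of every frame", {
  set.seed(13)
  frames <- lapply(1:5, function(i) four_point() * 2 + matrix(rnorm(12, sd = 0.3), 4, 3))
  traj <- traj_from_frames(frames)
  rot <- {
    m <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(m) < 0) m[, 1] <- -m[, 1]
    m
  }
  moved <- traj_from_frames(lapply(frames, function(f)
    f %*% t(rot) + matrix(c(4, -7, 2), 4, 3, byrow = TRUE)))
  expect_equal(rmsd_series(moved)$values, rmsd_series(traj)$values,
               tolerance = 1e-8)
  expect_equal(radius_of_gyration(moved)$values,
               radius_of_gyration(traj)$values, tolerance = 1e-8)
  expect_equal(pairwise_rmsd_matrix(moved), pairwise_rmsd_matrix(traj),
               tolerance = 1e-8)
  expect_equal(unname(rmsf(moved)), unname(rmsf(traj)), tolerance = 1e-8)
})
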
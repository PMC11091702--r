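make_hbond_frame <- function(da_dist, angle_deg) {
  # hydrogen at the origin, donor 1.0 A away along x; the acceptor sits at
  # distance r in the direction making exactly angle_deg at the hydrogen,
  # with r chosen so the donor-acceptor distance equals da_dist
  ca <- cos(angle_deg * pi / 180)
  r <- ca + sqrt(ca^2 - 1 + da_dist^2)
  d <- c(1, 0, 0)
  h <- c(0, 0, 0)
  a <- r * c(ca, sin(angle_deg * pi / 180), 0)
  rbind(d, h, a)
}

hbond_toy <- function(frames) {
  topo <- topology(data.frame(
    name = c("ND", "HD", "OA"), element = c("N", "H", "O"),
    resid = c(10L, 10L, 900L), resname = c("SER", "SER", "LIG"),
    chain = c("A", "A", "L"),
    flags = c("donor", "hydrogen", "acceptor"), stringsAsFactors = FALSE),
    bonds = matrix(c(1L, 2L), 1, 2))
  traj_from_frames(frames, topo)
}

test_that("hydrogen bonds respect both the distance and the angle gate", {
  # exactly representable collinear frame: D-A distance 3.0, angle 180
  boundary <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))
  traj <- hbond_toy(list(make_hbond_frame(2.9, 180),    # present
                         make_hbond_frame(3.1, 180),    # distance gate
                         make_hbond_frame(2.9, 120),    # angle gate
                         boundary,                      # <= 3.0 A inclusive
                         make_hbond_frame(2.9, 134.5),  # just below angle cut
                         make_hbond_frame(2.9, 135.5))) # just above
  tr <- detect_hbonds(traj, selection(1), selection(3))
  expect_length(tr, 1)
  expect_equal(tr[[1]]$occupancy, c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(tr[[1]]$persistence, 0.5)
})

test_that("donors without a bonded hydrogen are skipped with a warning", {
  topo <- topology(data.frame(
    name = c("ND", "OA"), element = c("N", "O"), resid = c(1L, 2L),
    resname = c("SER", "LIG"), chain = c("A", "L"),
    flags = c("donor", "acceptor"), stringsAsFactors = FALSE),
    bonds = matrix(integer(0), 0, 2))
  traj <- traj_from_frames(list(rbind(c(0, 0, 0), c(2.8, 0, 0))), topo)
  expect_warning(tr <- detect_hbonds(traj, selection(1), selection(2)),
                 "without a bonded hydrogen")
  expect_length(tr, 0)
})

test_that("salt bridges gate on the 4 A charged-group distance", {
  mk <- function(d) {
    topo <- topology(data.frame(
      name = c("NH1", "O1P"), element = c("N", "O"),
      resid = c(127L, 900L), resname = c("ARG", "LIG"), chain = c("A", "L"),
      flags = c("cation_group", "anion_group"), stringsAsFactors = FALSE))
    traj_from_frames(list(rbind(c(0, 0, 0), c(d, 0, 0))), topo)
  }
  expect_length(detect_salt_bridges(mk(3.5), selection(1), selection(2)), 1)
  expect_length(detect_salt_bridges(mk(4.2), selection(1), selection(2)), 0)
  expect_length(detect_salt_bridges(mk(4.0), selection(1), selection(2)), 1)
  expect_warning(
    detect_salt_bridges(mk(3.5), selection(2), selection(2)),
    "empty charged selection")
})

test_that("hydrophobic contacts gate on the 4 A nonpolar distance", {
  mk <- function(d) {
    topo <- topology(data.frame(
      name = c("CD1", "C8"), element = c("C", "C"),
      resid = c(55L, 900L), resname = c("LEU", "LIG"), chain = c("A", "L"),
      flags = "nonpolar_carbon", stringsAsFactors = FALSE))
    traj_from_frames(list(rbind(c(0, 0, 0), c(d, 0, 0))), topo)
  }
  expect_length(detect_hydrophobic(mk(3.8), selection(1), selection(2)), 1)
  expect_length(detect_hydrophobic(mk(4.5), selection(1), selection(2)), 0)
})

test_that("detectors equal their brute-force oracles on random systems", {
  for (seed in 1:20) {
    sys <- random_interaction_system(seed, n_frames = 50)
    hb <- detect_hbonds(sys$traj, sys$donors, sys$acceptors)
    hb_or <- oracle_hbonds(sys$traj, sys$donors, sys$acceptors)
    got <- lapply(hb, function(t) t$occupancy)
    expect_equal(length(got), length(hb_or))
    expect_identical(unname(got), unname(unclass(hb_or)))

    sb <- detect_salt_bridges(sys$traj, sys$cations, sys$anions)
    sb_or <- oracle_salt_bridges(sys$traj, sys$cations, sys$anions)
    expect_identical(unname(lapply(sb, function(t) t$occupancy)),
                     unname(unclass(sb_or)))

    hp <- detect_hydrophobic(sys$traj, sys$protein_nonpolar, sys$ligand_nonpolar)
    hp_or <- oracle_pair_contacts(sys$traj, sys$protein_nonpolar,
                                  sys$ligand_nonpolar, 4.0)
    expect_identical(unname(lapply(hp, function(t) t$occupancy)),
                     unname(unclass(hp_or)))
  }
})

hex_ring <- function(center = c(0, 0, 0), rot = diag(3), r = 1.39) {
  a <- seq(0, 2 * pi, length.out = 7)[1:6]
  sweep(cbind(r * cos(a), r * sin(a), 0) %*% t(rot), 2, center, "+")
}

two_ring_traj <- function(frames_b, frames_a = NULL) {
  if (is.null(frames_a)) frames_a <- replicate(length(frames_b), hex_ring(),
                                               simplify = FALSE)
  atoms <- data.frame(
    name = c(sprintf("CW%d", 1:6), sprintf("CL%d", 1:6)),
    element = "C", resid = c(rep(125L, 6), rep(900L, 6)),
    resname = c(rep("TRP", 6), rep("LIG", 6)),
    chain = c(rep("A", 6), rep("L", 6)),
    ring_id = c(rep(1L, 6), rep(2L, 6)), stringsAsFactors = FALSE)
  topo <- topology(atoms, rings = list("1" = 1:6, "2" = 7:12))
  traj_from_frames(mapply(function(a, b) rbind(a, b), frames_a, frames_b,
                          SIMPLIFY = FALSE), topo)
}

test_that("ring geometry returns the centroid and a least-squares normal", {
  g <- ring_geometry(hex_ring(), 1:6)
  expect_equal(g$centroid, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(abs(g$normal[3]), 1, tolerance = 1e-10)
  # puckered 5-ring: compare to a direct least-squares plane fit (svd on
  # another code path: eigen of the covariance)
  set.seed(3)
  ring5 <- cbind(cos(2 * pi * (0:4) / 5), sin(2 * pi * (0:4) / 5),
                 rnorm(5, sd = 0.2))
  g5 <- ring_geometry(ring5, 1:5)
  cen <- sweep(ring5, 2, colMeans(ring5))
  ev <- eigen(crossprod(cen))$vectors[, 3]
  expect_equal(abs(sum(g5$normal * ev)), 1, tolerance = 1e-8)
  expect_error(ring_geometry(cbind(1:4, 0, 0), 1:4), "collinear")
})

test_that("pi-stacking classifies canonical stack and T-shape geometries", {
  # parallel rings, 3.5 A plane separation, normals angle 0 -> f2f
  stacked <- hex_ring(center = c(0, 0, 3.5))
  # perpendicular ring close enough in heavy atoms -> e2f
  rot_x90 <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE)
  tshape <- hex_ring(center = c(0, 0, 3.5 + 1.39), rot = rot_x90)
  # parallel but centroid distance 6 A -> absent
  offset <- hex_ring(center = c(6, 0, 0))
  traj <- two_ring_traj(list(stacked, tshape, offset))
  tr <- detect_pi_stacking(traj, "1", "2")
  kinds <- sapply(tr, function(t) t$kind)
  f2f <- tr[[which(kinds == "pi_f2f")]]
  e2f <- tr[[which(kinds == "pi_e2f")]]
  expect_equal(f2f$occupancy, c(TRUE, FALSE, FALSE))
  expect_equal(e2f$occupancy, c(FALSE, TRUE, FALSE))
  expect_error(detect_pi_stacking(traj, "1", "7"), "ring id")
})

test_that("f2f and e2f are mutually exclusive frame by frame", {
  set.seed(17)
  frames <- lapply(1:40, function(i) {
    m <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    if (det(m) < 0) m[, 1] <- -m[, 1]
    hex_ring(center = runif(3, -1, 1) + c(0, 0, runif(1, 2.5, 6)), rot = m)
  })
  traj <- two_ring_traj(frames)
  tr <- detect_pi_stacking(traj, "1", "2")
  occ <- sapply(tr, function(t) t$occupancy)
  if (length(tr) == 2) expect_false(any(occ[, 1] & occ[, 2]))
  # detections survive global rigid motion of each frame
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- two_ring_traj(
    lapply(frames, function(f) f %*% t(rot) + 5),
    lapply(seq_along(frames), function(i) hex_ring() %*% t(rot) + 5))
  tr2 <- detect_pi_stacking(moved, "1", "2")
  expect_equal(lapply(tr2, function(t) t$occupancy),
               lapply(tr, function(t) t$occupancy))
})

test_that("persistence equals mean occupancy and filters are strict", {
  mk <- function(kind, occ) ligdyn:::interaction_trace(kind, "a", "b", occ)
  traces <- list(
    mk("hbond", c(1, 1, 0, 0)),                 # 0.50 -> kept
    mk("hbond", c(1, 0, 0, 0)),                 # 0.25 -> dropped (strict)
    mk("salt_bridge", rep(c(TRUE, FALSE), c(26, 74))),  # 0.26 -> kept
    mk("pi_f2f", rep(c(TRUE, FALSE), c(21, 79))),       # 0.21 -> kept
    mk("pi_e2f", rep(c(TRUE, FALSE), c(20, 80))),       # 0.20 -> dropped
    mk("hydrophobic", c(TRUE, rep(FALSE, 99))))         # kept by default
  for (t in traces) expect_equal(t$persistence, mean(t$occupancy))
  kept <- persistence_filter(traces)
  expect_equal(sapply(kept, function(t) t$kind),
               c("hbond", "salt_bridge", "pi_f2f", "hydrophobic"))
  kept2 <- persistence_filter(traces, hydrophobic_min = 0.5)
  expect_false("hydrophobic" %in% sapply(kept2, function(t) t$kind))
})

test_that("persistence report averages replicates, zero-filling absences", {
  mk <- function(p, n = 100) ligdyn:::interaction_trace(
    "hbond", "SER 126 A:OG", "LIG 900 L:N7",
    rep(c(TRUE, FALSE), c(round(p * n), n - round(p * n))))
  rep_ <- persistence_report(list(list(mk(0.90)), list(mk(0.96)), list(mk(1.00))))
  expect_equal(rep_$mean_persistence_pct, 95.33333, tolerance = 1e-5)
  one <- persistence_report(list(list(mk(0.42))))
  expect_equal(one$mean_persistence_pct, 42)
  # absent from one replicate: averaged with 0 and flagged
  other <- ligdyn:::interaction_trace("hbond", "x", "y", c(TRUE, TRUE))
  rep2 <- persistence_report(list(list(mk(0.9)), list(other)))
  row <- rep2[rep2$partner_a == "SER 126 A:OG", ]
  expect_equal(row$mean_persistence_pct, 45)
  expect_true(row$incomplete)
})

test_that("scheduled occupancies are recovered exactly as realised fractions", {
  g <- gen_interaction_system(
    n_frames = 400,
    occupancies = c(hbond = 0.96, salt_bridge = 0.92, hydrophobic = 0.50),
    seed = 14)
  s <- g$selections
  hb <- detect_hbonds(g$trajectory, s$donors, s$acceptors)
  expect_equal(hb[[1]]$persistence, unname(g$realized["hbond"]))
  sb <- detect_salt_bridges(g$trajectory, s$cations, s$anions)
  expect_equal(sb[[1]]$persistence, unname(g$realized["salt_bridge"]))
  hp <- detect_hydrophobic(g$trajectory, s$protein_nonpolar, s$ligand_nonpolar)
  expect_equal(hp[[1]]$persistence, unname(g$realized["hydrophobic"]))
})
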
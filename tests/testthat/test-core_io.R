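test_that("multi-model PDB round-trip preserves coordinates and atom order", {
  set.seed(42)
  frames <- lapply(1:3, function(i) matrix(round(runif(15, -20, 20), 3), 5, 3))
  topo <- topology(data.frame(
    name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
    resid = 7L, resname = "TRP", chain = "A", stringsAsFactors = FALSE))
  traj <- traj_from_frames(frames, topo)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, f)
  back <- read_multimodel_pdb(f)
  expect_equal(dim(back$coords), c(3, 5, 3))
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)  # values were
  # pre-rounded to PDB precision, so the round-trip is exact
  expect_identical(back$topology$atoms$name, topo$atoms$name)
  expect_identical(back$topology$atoms$resname, rep("TRP", 5))
  expect_identical(back$topology$atoms$element, topo$atoms$element)
})

test_that("unrounded coordinates survive the round-trip to PDB precision", {
  set.seed(7)
  frames <- list(matrix(runif(12, -5, 5), 4, 3), matrix(runif(12, -5, 5), 4, 3))
  traj <- traj_from_frames(frames)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(traj, f)
  back <- read_multimodel_pdb(f)
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 2)
})

test_that("a single-structure file reads as a 1-frame trajectory", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       2.500   2.000   3.000  1.00  0.00           C",
    "END"), f)
  traj <- read_multimodel_pdb(f)
  expect_equal(n_frames(traj), 1)
  expect_equal(frame_coords(traj, 1)[2, 1], 2.5)
})

test_that("frame atom-count mismatch names the offending MODEL", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       2.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL"), f)
  expect_error(read_multimodel_pdb(f), "MODEL 2")
})

test_that("an unparseable ATOM line is reported with its line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       xxxxx   2.000   3.000  1.00  0.00           C"), f)
  expect_error(read_multimodel_pdb(f), "line 2")
})

test_that("writer refuses empty trajectories and oversized coordinates", {
  topo <- toy_topology(3)
  traj <- traj_from_frames(list(matrix(0, 3, 3)), topo)
  bad <- traj
  bad$coords[1, 1, 1] <- 1e5
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_multimodel_pdb(bad, f), "field")
  expect_error(trajectory(topo, array(0, dim = c(0, 3, 3))), "frame")
})

test_that("annotation sidecar fills flags, radii and rings; defaults are Bondi", {
  topo <- topology(data.frame(
    name = c("NE1", "CD1", "CE2", "CD2", "CA", "P1"),
    element = c("N", "C", "C", "C", "C", "P"),
    resid = c(rep(125L, 5), 900L),
    resname = c(rep("TRP", 5), "LIG"),
    chain = c(rep("A", 5), "L"), stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresid\tname\telement\tvdw_radius\tflags\tring_id",
               "A\t125\tNE1\tN\t1.55\tdonor;acceptor\t3",
               "A\t125\tCD1\tC\t1.70\t\t3",
               "A\t125\tCE2\tC\t1.70\t\t3",
               "A\t125\tCD2\tC\t1.70\t\t3",
               "L\t999\tZZ\tC\t1.7\t\t"), f)
  expect_warning(out <- load_annotation(f, topo), "1 annotation row")
  expect_equal(attr(out, "n_unmatched"), 1)
  expect_true(has_flag(out, "donor")[1])
  expect_equal(out$atoms$ring_id[1], 3L)
  expect_equal(out$rings[["3"]], 1:4)
  # unannotated atoms keep Bondi defaults
  expect_equal(out$atoms$vdw_radius[5], 1.70)
  expect_equal(out$atoms$vdw_radius[6], 1.80)
  expect_equal(bondi_radius("C"), 1.70)
})

test_that("a lone ring-flagged atom marks membership without a cycle", {
  topo <- topology(data.frame(
    name = c("NE1", "CA"), element = c("N", "C"), resid = 125L,
    resname = "TRP", chain = "A", stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresid\tname\tring_id", "A\t125\tNE1\t3"), f)
  expect_warning(out <- load_annotation(f, topo), "fewer than 4")
  expect_equal(out$atoms$ring_id[1], 3L)
  expect_length(out$rings, 0)
})

test_that("annotation round-trips through write_annotation", {
  g <- gen_interaction_system(n_frames = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(g$trajectory$topology, f)
  bare <- topology(g$trajectory$topology$atoms[
    c("name", "element", "resid", "resname", "chain")])
  back <- load_annotation(f, bare)
  expect_identical(back$atoms$flags, g$trajectory$topology$atoms$flags)
  expect_identical(lapply(back$rings, sort),
                   lapply(g$trajectory$topology$rings[names(back$rings)], sort))
})

test_that("topology invariants are enforced", {
  df <- data.frame(name = "X", element = "C", resid = 1L, resname = "ALA",
                   chain = "A", stringsAsFactors = FALSE)
  bad <- df; bad$flags <- "cation_group;anion_group"
  expect_error(topology(bad), "both")
  bad2 <- df; bad2$flags <- "hydrogen"
  expect_error(topology(bad2), "hydrogen")
  expect_error(topology(df, bonds = matrix(c(1, 2), 1, 2)), "out of range")
  expect_error(topology(rbind(df, df, df, df), rings = list("1" = 1:3)), ">= 4")
})

test_that("selection grammar resolves shortcuts, ranges and boolean logic", {
  atoms <- data.frame(
    name = rep(c("N", "CA", "C", "O"), 5),
    element = rep(c("N", "C", "C", "O"), 5),
    resid = rep(125:129, each = 4), resname = "GLY", chain = "A",
    stringsAsFactors = FALSE)
  lig <- data.frame(name = c("C1", "H1"), element = c("C", "H"),
                    resid = 900L, resname = "LIG", chain = "L",
                    stringsAsFactors = FALSE)
  topo <- topology(rbind(atoms, lig))
  expect_equal(length(select_atoms(topo, "calpha")), 5)
  expect_equal(length(select_atoms(topo, "backbone")), 20)
  expect_equal(select_atoms(topo, "heavy and not protein")$indices, 21L)
  expect_equal(length(select_atoms(topo, "resid 125-129")), 20)
  expect_equal(length(select_atoms(topo, "resid 126-127 and name CA")), 2)
  expect_equal(select_atoms(topo, "chain L or name O")$indices,
               sort(c(which(topo$atoms$name == "O"), 21L, 22L)))
  expect_equal(select_atoms(topo, "(not protein) and element C")$indices, 21L)
})

test_that("selection is idempotent and conjunction is commutative", {
  g <- gen_interaction_system(n_frames = 1, seed = 3)
  topo <- g$trajectory$topology
  exprs <- c("heavy", "flag donor or flag acceptor", "chain A and heavy")
  for (e in exprs)
    expect_identical(select_atoms(topo, e)$indices, select_atoms(topo, e)$indices)
  expect_identical(select_atoms(topo, "chain A and heavy")$indices,
                   select_atoms(topo, "heavy and chain A")$indices)
})

test_that("selection syntax errors report a position", {
  topo <- toy_topology(3)
  expect_error(select_atoms(topo, "resid 1-"), "position")
  expect_error(select_atoms(topo, "bogus"), "position 1")
  expect_error(select_atoms(topo, "(name CA"), "parenthesis")
  expect_error(select_atoms(topo, "name CA extra)"), "position")
})
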
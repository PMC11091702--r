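test_that("score tables parse in CSV, whitespace and Rosetta dialects", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("description,total_score,interface_delta_X,ligand_rms",
               "m1,-310.2,-12.1,0.05", "m2,-305.5,-10.0,1.4",
               "m3,-280.0,-2.0,8.3", "m4,-300.1,-8.8,2.2",
               "m5,-299.0,NA,3.0"), f)
  expect_warning(ens <- read_score_table(f), "1 row")
  expect_equal(length(ens), 4)
  expect_equal(attr(ens, "n_dropped"), 1)

  f2 <- withr::local_tempfile(fileext = ".sc")
  writeLines(c("SCORE: total_score interface_delta_X ligand_rms description",
               "SCORE: -310.2 -12.1 0.05 m1",
               "SCORE: -305.5 -10.0 1.40 m2"), f2)
  ens2 <- read_score_table(f2)
  expect_equal(ens2$model_ids, c("m1", "m2"))
  expect_equal(ens2$interface_score, c(-12.1, -10.0))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,E,bind,r", "m1,-1,-2,0.1"), f3)
  expect_error(read_score_table(f3), "available headers")
  ens3 <- read_score_table(f3, column_map = c(model_id = "id",
                                              total_score = "E",
                                              interface_score = "bind",
                                              ligand_rmsd = "r"))
  expect_equal(length(ens3), 1)
})

test_that("two-stage top-model selection matches a brute-force sort oracle", {
  set.seed(21)
  n <- 200
  ens <- funnel_ensemble(sprintf("m%03d", 1:n), rnorm(n), rnorm(n),
                         abs(rnorm(n, 3)))
  top <- select_top_models(ens, 50, 10)
  # oracle: plain nested sorts
  keep1 <- order(ens$total_score, ens$model_ids)[1:50]
  keep2 <- keep1[order(ens$interface_score[keep1], ens$model_ids[keep1])][1:10]
  expect_identical(top$model_ids, ens$model_ids[keep2])
  # n_by_total = ensemble size reduces to pure interface ranking
  pure <- select_top_models(ens, n, 5)
  expect_identical(pure$model_ids,
                   ens$model_ids[order(ens$interface_score, ens$model_ids)][1:5])
  # all-equal scores: tie rule keeps lexicographically first ids
  tied <- funnel_ensemble(c("b", "a", "d", "c"), rep(1, 4), rep(2, 4), 1:4)
  expect_identical(select_top_models(tied, 4, 2)$model_ids, c("a", "b"))
  expect_error(select_top_models(ens, n + 1, 1), "exceeds")
  expect_error(select_top_models(ens, 5, 6), "exceeds")
})

test_that("selection is independent of input row order", {
  set.seed(33)
  n <- 100
  ens <- funnel_ensemble(sprintf("m%03d", 1:n), rnorm(n), rnorm(n), runif(n, 0, 9))
  perm <- sample(n)
  ens_p <- funnel_ensemble(ens$model_ids[perm], ens$total_score[perm],
                           ens$interface_score[perm], ens$ligand_rmsd[perm])
  expect_identical(select_top_models(ens, 30, 7)$model_ids,
                   select_top_models(ens_p, 30, 7)$model_ids)
})

test_that("pnear hits its analytic anchors", {
  set.seed(2)
  native <- funnel_ensemble(1:100, runif(100, -10, 0), runif(100, -10, 0),
                            rep(0, 100))
  expect_equal(pnear(native), 1.0)
  far <- funnel_ensemble(1:100, runif(100, -10, 0), runif(100, -10, 0),
                         rep(50, 100))
  expect_lt(pnear(far), 1e-6)
  two <- funnel_ensemble(1:2, c(-3, -3), c(-5, -5), c(0, 10))
  expect_equal(pnear(two), 0.5, tolerance = 1e-6)
})

test_that("pnear is shift-invariant and equals direct unshifted summation", {
  set.seed(4)
  for (k in 1:20) {
    n <- 50
    rmsd <- runif(n, 0, 12)
    e <- rnorm(n, sd = 3)
    ens <- funnel_ensemble(1:n, e, e, rmsd)
    p <- pnear(ens)
    # direct evaluation, no overflow guard
    lam <- 1.5; kbt <- 0.62
    direct <- sum(exp(-rmsd^2 / lam^2) * exp(-e / kbt)) / sum(exp(-e / kbt))
    expect_equal(p, direct, tolerance = 1e-10)
    shifted <- funnel_ensemble(1:n, e, e + 123.4, rmsd)
    expect_equal(pnear(shifted), p, tolerance = 1e-10)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("pnear is non-increasing when one model's RMSD grows", {
  set.seed(6)
  n <- 30
  e <- rnorm(n)
  rmsd <- runif(n, 0, 8)
  for (k in 1:10) {
    i <- sample(n, 1)
    worse <- rmsd
    worse[i] <- worse[i] + runif(1, 0.1, 5)
    p0 <- pnear(funnel_ensemble(1:n, e, e, rmsd))
    p1 <- pnear(funnel_ensemble(1:n, e, e, worse))
    expect_lte(p1, p0 + 1e-12)
  }
})

test_that("funnel report composes pnear, top models and the reference pose", {
  g <- gen_funnel_scores(n_models = 500, seed = 12)
  rep_ <- funnel_report(g$ensemble, n_by_total = 100, n_by_interface = 10)
  expect_equal(rep_$pnear, pnear(g$ensemble))
  expect_equal(nrow(rep_$top_models), 10)
  expect_equal(rep_$reference_model,
               rep_$top_models$model_id[which.min(rep_$top_models$interface_score)])
  expect_equal(nrow(rep_$scatter), 500)
  rep2 <- funnel_report(g$ensemble, n_by_total = 100, n_by_interface = 10)
  expect_identical(rep_, rep2)
})

test_that("decomposition aggregation averages replicates and applies the kT filter", {
  mk <- function(resid, dG) data.frame(chain = "A", resid = resid,
                                       resname = "TRP", dG = dG,
                                       stringsAsFactors = FALSE)
  reps <- list(mk(c(125, 226), c(-1.0, -0.5)),
               mk(c(125, 226), c(-1.2, -0.5)),
               mk(c(125, 226), c(-0.8, -0.5)))
  out <- aggregate_decomposition(reps, kT_cut = 0.6)
  expect_equal(nrow(out), 1)               # -0.5 falls below the kT cut
  expect_equal(out$mean_dG, -1.0)
  expect_equal(out$sd_dG, sd(c(-1.0, -1.2, -0.8)))
  # single replicate: identity with SD 0
  one <- aggregate_decomposition(list(mk(125, -2.5)), kT_cut = 0.6)
  expect_equal(one$mean_dG, -2.5)
  expect_equal(one$sd_dG, 0)
  # residue present in a subset of replicates is kept but flagged
  reps2 <- list(mk(c(125, 190), c(-1.0, -3.0)), mk(125, -1.0))
  expect_warning(out2 <- aggregate_decomposition(reps2, kT_cut = 0.6), "subset")
  expect_true(out2$incomplete[out2$resid == 190])
})

test_that("binding free energy component bookkeeping closes", {
  comp <- c(dE_ele = -40.0, dE_vdw = -55.0, dG_pol = 45.0, dG_np = -2.1,
            dG_gas = -95.0, dG_sol = 42.9, dG_bind = -52.1)
  expect_true(check_decomposition_components(comp))
  bad <- comp; bad["dG_bind"] <- -40.0
  expect_error(check_decomposition_components(bad), "dG_bind")
})

test_that("residue_shell finds protein residues near the ligand", {
  prot <- rbind(c(0, 0, 0), c(1.5, 0, 0),       # residue 1 close
                c(20, 0, 0), c(21.5, 0, 0))     # residue 2 far
  lig <- rbind(c(3, 0, 0), c(4, 0, 0))
  topo <- topology(data.frame(
    name = c("CA", "CB", "CA", "CB", "C1", "C2"),
    element = "C", resid = c(1, 1, 2, 2, 900, 900),
    resname = c(rep("ALA", 4), rep("LIG", 2)),
    chain = c(rep("A", 4), rep("L", 2)), stringsAsFactors = FALSE))
  traj <- traj_from_frames(list(rbind(prot, lig)), topo)
  sh <- residue_shell(traj, 1, selection(5:6), cutoff = 5)
  expect_equal(sh$resid, 1)
  expect_equal(sh$min_dist, 1.5)
})
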
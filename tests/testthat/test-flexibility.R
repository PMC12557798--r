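test_that("RMSD matches the printed formula and superposition removes rigid motion", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(ref, ref, fit = FALSE), 0)
  expect_equal(rmsd(ref, ref, fit = TRUE), 0, tolerance = 1e-12)

  # single atom displaced by (3, 4, 0): RMSD = 5 by Pythagoras
  a <- matrix(0, 1, 3)
  b <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(rmsd(b, a, fit = FALSE), 5)

  # a rigid rotation + translation is removed by the fit
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  moved <- ref %*% t(R) + matrix(c(1, -2, 3), 10, 3, byrow = TRUE)
  expect_gt(rmsd(moved, ref, fit = FALSE), 0.5)
  expect_equal(rmsd(moved, ref, fit = TRUE), 0, tolerance = 1e-9)

  expect_error(rmsd(matrix(0, 3, 3), matrix(0, 4, 3)), "mismatch")
})

test_that("fitted RMSD never exceeds unfitted RMSD", {
  set.seed(4)
  for (i in 1:20) {
    ref <- matrix(rnorm(24), 8, 3)
    frame <- ref + matrix(rnorm(24, sd = 0.3), 8, 3)
    expect_lte(rmsd(frame, ref, fit = TRUE),
               rmsd(frame, ref, fit = FALSE) + 1e-12)
  }
})

test_that("RMSF matches its formula on toy and random trajectories", {
  # static trajectory: zero fluctuation
  coords <- array(rep(matrix(rnorm(15), 5, 3), 4), dim = c(5, 3, 4))
  tr <- toy_traj(coords)
  expect_equal(unname(rmsf(tr, window = c(0, 3))), rep(0, 5))

  # one atom alternating between (0,0,0) and (2,0,0): RMSF 1 about its mean
  coords <- array(0, dim = c(1, 3, 10))
  coords[1, 1, ] <- rep(c(0, 2), 5)
  tr <- toy_traj(coords)
  expect_equal(unname(rmsf(tr, window = c(0, 9), fit = FALSE)), 1)

  # brute-force double loop oracle, atoms mapped to residues
  set.seed(6)
  coords <- array(rnorm(5 * 3 * 50), dim = c(5, 3, 50))
  tr <- toy_traj(coords, residues = c(1, 1, 2, 2, 3))
  got <- rmsf(tr, window = c(0, 49), fit = FALSE)
  mean_pos <- apply(coords, c(1, 2), mean)
  atom_rmsf <- numeric(5)
  for (i in 1:5) {
    acc <- 0
    for (t in 1:50) acc <- acc + sum((coords[i, , t] - mean_pos[i, ])^2)
    atom_rmsf[i] <- sqrt(acc / 50)
  }
  oracle <- as.numeric(tapply(atom_rmsf, c(1, 1, 2, 2, 3), mean))
  expect_equal(unname(got), oracle, tolerance = 1e-12)

  expect_error(rmsf(tr, window = c(100, 200)), "no frames")
})

test_that("RMSF is invariant to a global translation of all frames", {
  set.seed(8)
  coords <- array(rnorm(4 * 3 * 20), dim = c(4, 3, 20))
  shifted <- coords + array(rep(c(5, -3, 11), each = 4),
                            dim = c(4, 3, 20))
  t1 <- toy_traj(coords); t2 <- toy_traj(shifted)
  expect_equal(rmsf(t1, c(0, 19), fit = FALSE),
               rmsf(t2, c(0, 19), fit = FALSE), tolerance = 1e-12)
})

test_that("delta-RMSD identities hold", {
  set.seed(10)
  ref <- matrix(rnorm(18), 6, 3)
  n_frames <- 30
  times <- seq(0, 20, length.out = n_frames)
  disp <- array(rnorm(6 * 3 * n_frames, sd = 0.2), dim = c(6, 3, n_frames))
  disp[, , 1] <- 0
  cold <- toy_traj(array(ref, dim = c(6, 3, n_frames)) + disp, times, 10)
  warm <- toy_traj(array(ref, dim = c(6, 3, n_frames)) + 2 * disp, times, 30)

  # identical trajectories: zero contrast
  expect_equal(delta_rmsd(cold, cold), 0)
  # doubled displacement (fit off): delta equals the mean cold RMSD
  idx <- which(times >= 10 & times <= 20)
  cold_rmsd <- mean(rmsd_series(cold, fit = FALSE)[idx])
  expect_equal(delta_rmsd(cold, warm, fit = FALSE), cold_rmsd,
               tolerance = 1e-12)
  # antisymmetry under swapping the trajectories
  expect_equal(delta_rmsd(warm, cold), -delta_rmsd(cold, warm),
               tolerance = 1e-12)
  expect_error(delta_rmsd(cold, toy_traj(disp, times - 100, 30)),
               "window")
})

test_that("trajectory constructor and XYZ round trip preserve data", {
  expect_error(trajectory(array(0, c(2, 3, 0)), numeric(0)),
               "at least one frame")
  expect_error(trajectory(array(0, c(2, 3, 2)), c(1, 1)),
               "strictly increasing")
  set.seed(12)
  tr <- toy_traj(array(rnorm(2 * 3 * 3), dim = c(2, 3, 3)),
                 times = c(0, 0.5, 1), temperature = 30,
                 residues = c(1, 2))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(tr, path)
  back <- read_xyz_trajectory(path)
  expect_equal(back$coords, tr$coords, tolerance = 1e-8)
  expect_equal(back$times, tr$times)
  expect_equal(back$temperature, 30)
  expect_equal(back$atom_residue, c(1L, 2L))
})

test_that("flexibility regression matches OLS and its null behaves", {
  d <- data.frame(mean_temp = c(0, 10, 20, 30),
                  delta_rmsd = 0.08 - 0.002 * c(0, 10, 20, 30))
  # points on an exact line: lm warns that the fit is perfect, as intended
  reg <- suppressWarnings(regress_flexibility(d))
  expect_equal(reg$slope, -0.002, tolerance = 1e-12)
  expect_equal(reg$r2, 1, tolerance = 1e-12)
  expect_error(regress_flexibility(d[1:2, ]), "at least three")
  expect_error(regress_flexibility(
    data.frame(mean_temp = rep(1, 5), delta_rmsd = rnorm(5))),
    "zero variance")

  # permutation null: slope sign is a coin flip, mean R2 ~ 1/(n-1)
  set.seed(14)
  temps <- seq(0, 30, length.out = 9)
  resp <- rnorm(9)
  signs <- 0; r2s <- numeric(400)
  for (i in 1:400) {
    reg <- regress_flexibility(data.frame(mean_temp = temps,
                                          delta_rmsd = sample(resp)))
    signs <- signs + (reg$slope > 0)
    r2s[i] <- reg$r2
  }
  expect_gt(signs / 400, 0.38)
  expect_lt(signs / 400, 0.62)
  expect_lt(abs(mean(r2s) - 1 / 8), 0.06)
})

test_that("planted variance gaps surface as positive delta-RMSD and negative slopes", {
  set.seed(16)
  pos <- 0
  for (r in 1:20) {
    cfg <- small_cfg(seed = 300 + r, traj_isoforms = 4,
                     traj_replicates = 2, traj_atoms = 15, traj_dt = 1)
    fs <- flexibility_summaries(simulate_trajectories(cfg))
    expect_true(all(fs$delta_rmsd > -0.02))
    pos <- pos + (regress_flexibility(fs)$slope < 0)
  }
  expect_gte(pos, 18)
})
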
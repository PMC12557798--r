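rand_samples <- function(n, seed = 1, k = 5, f = 4) {
  set.seed(seed)
  x <- array(rnorm(n * k * f), dim = c(n, k, f))
  structure(list(species_id = sprintf("s%03d", seq_len(n)), x = x,
                 flags = matrix(0, n, k), center = rep(0, f),
                 scale = rep(1, f), key_sites = seq_len(k)),
            class = "graph_samples")
}

test_that("the renormalized path operator matches hand linear algebra", {
  A <- normalized_adjacency(5)
  expect_equal(A[1, 1], 1 / 2)
  expect_equal(A[1, 2], 1 / sqrt(6))
  expect_equal(A[2, 2], 1 / 3)
  expect_equal(A, t(A))
  expect_true(all(A >= 0))
  expect_lte(max(abs(eigen(A, only.values = TRUE)$values)), 1 + 1e-12)

  # Laplacian variant is I - D^{-1/2} A D^{-1/2}
  L <- normalized_adjacency(5, type = "laplacian")
  expect_equal(diag(L), rep(1, 5))
  expect_equal(L[1, 2], -1 / sqrt(1 * 2))
  expect_equal(L[2, 3], -1 / 2)

  Af <- normalized_adjacency(5, topology = "full")
  expect_equal(Af, t(Af))
  expect_equal(unique(round(diag(Af), 12)), 1 / 5)
})

test_that("graph samples standardize features and fix node order", {
  fr <- expand.grid(species_id = c("b", "a"), site = c(233L, 173L, 190L,
                                                       174L, 230L))
  fr$hbond_n <- seq_len(nrow(fr))
  fr$hbond_dist_A <- 3
  fr$sasa_A2 <- 50 + seq_len(nrow(fr))
  fr$residue <- "A"
  s1 <- build_graph_samples(fr)
  fr_shuffled <- fr[sample(nrow(fr)), ]
  s2 <- build_graph_samples(fr_shuffled)
  expect_equal(s1$x, s2$x)
  expect_equal(dimnames(s1$x)[[2]], c("173", "174", "190", "230", "233"))

  # a feature constant across all species standardizes to zero
  expect_true(all(s1$x[, , "hbond_dist"] == 0))

  expect_error(build_graph_samples(fr[fr$site != 190, ]), "missing key site")
  fr2 <- fr; fr2$sasa_A2[1] <- NA
  expect_error(build_graph_samples(fr2), "non-finite|missing values")
})

test_that("the forward pass matches a pencil-and-paper single layer", {
  X <- matrix(c(1, 0, 2, -1, 3, 1, 0, 2, -2, 1, 4, 0, 1, 1, 0, -3, 2, 2,
                1, 0), 5, 4)
  Ahat <- normalized_adjacency(5)
  w <- init_network(4, hidden = 4, seed = 1)
  w$W[[1]] <- diag(4)
  w$b[[1]] <- c(0.5, 0, -0.5, 0)
  fp <- network_forward(X, w, Ahat)
  # oracle: direct arithmetic
  Z <- Ahat %*% X %*% diag(4) +
    matrix(c(0.5, 0, -0.5, 0), 5, 4, byrow = TRUE)
  H <- pmax(Z, 0)
  oracle <- c(colMeans(X), colMeans(H))
  expect_equal(fp, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # all-zero weights: every hidden fingerprint block vanishes
  w0 <- init_network(4, hidden = c(8, 8), seed = 1)
  w0$W <- lapply(w0$W, function(m) m * 0)
  fp0 <- network_forward(X, w0, Ahat)
  expect_equal(unname(fp0[5:20]), rep(0, 16))
  expect_equal(unname(fp0[1:4]), colMeans(X))
})

test_that("fingerprints are invariant under consistent node permutation", {
  set.seed(19)
  X <- matrix(rnorm(20), 5, 4)
  Ahat <- normalized_adjacency(5)
  w <- init_network(4, hidden = c(6, 6), seed = 3)
  fp <- network_forward(X, w, Ahat)
  for (i in 1:5) {
    perm <- sample(5)
    fp_perm <- network_forward(X[perm, ], w, Ahat[perm, perm])
    expect_equal(fp_perm, fp, tolerance = 1e-12)
  }
})

test_that("network training is deterministic and fits constants instantly", {
  s <- rand_samples(40, seed = 5)
  y <- rep(7.5, 40)
  w <- train_network(s, y, epochs = 30, seed = 2)
  expect_lt(attr(w, "loss"), 1e-4)
  pred <- drop(network_fingerprints(w, s) %*% w$w) + w$c
  expect_equal(pred, rep(7.5, 40), tolerance = 0.05)

  s2 <- rand_samples(30, seed = 6)
  y2 <- rnorm(30)
  wa <- train_network(s2, y2, epochs = 20, seed = 4)
  wb <- train_network(s2, y2, epochs = 20, seed = 4)
  expect_identical(wa, wb)
})

test_that("a noise-free linear function of mean node features is recovered", {
  n <- 150
  s <- rand_samples(n, seed = 42)
  y <- 3 + 2 * apply(s$x[, , 2], 1, mean) - 1.5 * apply(s$x[, , 4], 1, mean)
  tr <- 1:105; te <- 106:150
  s_tr <- s; s_tr$x <- s$x[tr, , , drop = FALSE]
  s_tr$species_id <- s$species_id[tr]
  w <- train_network(s_tr, y[tr], epochs = 600, seed = 1)
  pred <- drop(network_fingerprints(w, s) %*% w$w) + w$c
  r2 <- 1 - sum((y[te] - pred[te])^2) / sum((y[te] - mean(y[te]))^2)
  expect_gte(r2, 0.99)
})

test_that("boosted CV picks the grid minimum and interpolates exact targets", {
  set.seed(33)
  X <- matrix(rnorm(120 * 4), 120, 4)
  y <- X[, 2]
  # single-point grid: selected trivially
  g1 <- data.frame(eta = 0.3, max_delta_step = 0, max_depth = 3,
                   lambda = 1, nrounds = 50, min_child_weight = 1)
  fit1 <- fit_boosted_model(X, y, cv_grid = g1, seed = 7)
  expect_equal(fit1$best_index, 1L)

  # an exact single-feature target is interpolated by a deep-enough grid
  g2 <- data.frame(eta = 0.3, max_delta_step = 0, max_depth = 6,
                   lambda = 0, nrounds = 400, min_child_weight = 1)
  fit2 <- fit_boosted_model(X, y, cv_grid = g2, seed = 7)
  pred <- predict(fit2$booster, xgboost::xgb.DMatrix(X))
  expect_lt(mean((pred - y)^2), 1e-3)

  expect_error(fit_boosted_model(X, y, cv_grid = g1[0, ]), "empty")
})

test_that("the CV winner has minimal mean fold MSE by exhaustive recount", {
  set.seed(35)
  X <- matrix(rnorm(100 * 5), 100, 5)
  y <- X[, 1] - 2 * X[, 3] + rnorm(100, 0, 0.5)
  grid <- expand.grid(eta = c(0.1, 0.3), max_delta_step = 0,
                      max_depth = c(2, 4), lambda = 1, nrounds = 60,
                      min_child_weight = 1)
  fit <- fit_boosted_model(X, y, cv_grid = grid, seed = 9)
  # independent recomputation with plain xgboost calls on the stored folds
  recomputed <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    fold_mse <- numeric(5)
    for (fd in 1:5) {
      trn <- fit$folds != fd
      set.seed(9)
      bst <- xgboost::xgb.train(
        params = list(objective = "reg:squarederror", eta = grid$eta[g],
                      max_delta_step = grid$max_delta_step[g],
                      max_depth = grid$max_depth[g],
                      lambda = grid$lambda[g],
                      min_child_weight = grid$min_child_weight[g],
                      nthread = 1),
        data = xgboost::xgb.DMatrix(X[trn, ], label = y[trn]),
        nrounds = grid$nrounds[g], verbose = 0)
      pred <- predict(bst, xgboost::xgb.DMatrix(X[!trn, ]))
      fold_mse[fd] <- mean((pred - y[!trn])^2)
    }
    recomputed[g] <- mean(fold_mse)
  }
  expect_equal(fit$cv_table$mean_cv_mse, recomputed, tolerance = 1e-9)
  expect_equal(fit$best_index, which.min(recomputed))
})

test_that("prediction reports score perfect and constant predictors correctly", {
  obs <- c(10, 12, 15, 20)
  expect_equal(prediction_report(obs, obs)$mse, 0)
  expect_equal(prediction_report(obs, obs)$r2, 1)
  const <- prediction_report(obs, rep(mean(obs), 4))
  expect_equal(const$r2, 0)
  expect_error(prediction_report(1, 1), "at least 2")
})

test_that("the end-to-end fit is deterministic and predict matches the report", {
  cfg <- small_cfg(seed = 45, n_species = 80, n_planted_trss = 5,
                   limit_mode = "linear_features")
  ds <- simulate_thermal_dataset(cfg)
  grid <- data.frame(eta = 0.3, max_delta_step = 0, max_depth = 3,
                     lambda = 1, nrounds = 80, min_child_weight = 1)
  fit1 <- fit_thermal_limit_model(ds$features, ds$flags, ds$profiles,
                                  target = "t99", epochs = 100,
                                  cv_grid = grid)
  fit2 <- fit_thermal_limit_model(ds$features, ds$flags, ds$profiles,
                                  target = "t99", epochs = 100,
                                  cv_grid = grid)
  expect_equal(fit1$report$mse, fit2$report$mse, tolerance = 1e-12)
  expect_identical(fit1$test_ids, fit2$test_ids)

  pred <- predict(fit1, ds$features, ds$flags)
  rep_pred <- fit1$report$predictions
  m <- match(rep_pred$species_id, pred$species_id)
  expect_equal(pred$predicted[m], rep_pred$predicted, tolerance = 1e-6)
})
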
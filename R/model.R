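#' Normalized graph operator over the key sites
#'
#' Builds the propagation operator used to mix node features. With
#' `type = "renormalized"` (default) this is the renormalized graph
#' convolution operator `D~^{-1/2} (A + I) D~^{-1/2}` over the path graph
#' connecting the sequence-ordered key sites; `type = "laplacian"` gives
#' the symmetric normalized Laplacian `I - D^{-1/2} A D^{-1/2}` verbatim.
#' `topology = "full"` replaces the path with a complete graph.
#'
#' For the 5-node path the renormalized operator has entries
#' `A^[1,1] = 1/2`, `A^[1,2] = 1/sqrt(6)`, `A^[2,2] = 1/3`.
#'
#' @param n_nodes Number of graph nodes (default 5).
#' @param type `"renormalized"` or `"laplacian"`.
#' @param topology `"path"` (sequence order) or `"full"`.
#' @return Symmetric `n_nodes x n_nodes` matrix.
#' @export
normalized_adjacency <- function(n_nodes = 5,
                                 type = c("renormalized", "laplacian"),
                                 topology = c("path", "full")) {
  type <- match.arg(type)
  topology <- match.arg(topology)
  A <- matrix(0, n_nodes, n_nodes)
  if (topology == "path") {
    for (i in seq_len(n_nodes - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  } else {
    A[] <- 1
    diag(A) <- 0
  }
  if (type == "renormalized") {
    At <- A + diag(n_nodes)
    dinv <- 1 / sqrt(rowSums(At))
    dinv * At %*% diag(dinv)  # D~^{-1/2} (A+I) D~^{-1/2}
  } else {
    dinv <- 1 / sqrt(pmax(rowSums(A), 1))
    diag(n_nodes) - dinv * A %*% diag(dinv)
  }
}

#' Assemble per-species graph samples at the key sites
#'
#' Each species becomes a 5-node graph: one node per key site in sequence
#' order, with the four structural features (hydrogen-bond count,
#' hydrogen-bond distance, SASA, RSA) as node features, feature-wise
#' standardized with supplied (training-set) constants.
#'
#' @param feature_rows data.frame with `species_id`, `site`, `hbond_n`,
#'   `hbond_dist_A`, `sasa_A2` and either `rsa` or `residue` (RSA then
#'   derived via [compute_rsa]).
#' @param flags data.frame `species_id`, `site`, `flag` in {-1, 0, +1}
#'   (cold-adapted / reference / warm-adapted), or `NULL` for all-zero
#'   flags.
#' @param key_sites Integer positions, sorted into sequence order
#'   internally (default `c(173, 174, 190, 230, 233)`).
#' @param standardize List with `center` and `scale` (4-vectors) to apply,
#'   or `NULL` to compute from these samples.
#' @return List of class `graph_samples`: `species_id`, `x` (array
#'   n x 5 x 4, standardized), `flags` (n x 5 matrix), `center`, `scale`,
#'   `key_sites`.
#' @export
build_graph_samples <- function(feature_rows, flags = NULL,
                                key_sites = c(173L, 174L, 190L, 230L, 233L),
                                standardize = NULL) {
  key_sites <- sort(as.integer(key_sites))
  fr <- feature_rows
  if (!"rsa" %in% names(fr)) {
    if (!"residue" %in% names(fr)) stop("need `rsa` or `residue` column")
    fr$rsa <- suppressWarnings(compute_rsa(fr$sasa_A2, fr$residue))
  }
  ids <- sort(unique(as.character(fr$species_id)))
  n <- length(ids)
  k <- length(key_sites)
  x <- array(NA_real_, dim = c(n, k, 4),
             dimnames = list(ids, as.character(key_sites),
                             c("hbond_n", "hbond_dist", "sasa", "rsa")))
  for (j in seq_len(k)) {
    sub <- fr[fr$site == key_sites[j], , drop = FALSE]
    idx <- match(ids, sub$species_id)
    if (anyNA(idx)) {
      stop("species missing key site ", key_sites[j], ": ",
           paste(ids[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
    }
    x[, j, ] <- as.matrix(sub[idx, c("hbond_n", "hbond_dist_A", "sasa_A2",
                                     "rsa")])
  }
  if (!all(is.finite(x))) stop("non-finite node features")
  fl <- matrix(0, n, k, dimnames = list(ids, as.character(key_sites)))
  if (!is.null(flags)) {
    for (j in seq_len(k)) {
      sub <- flags[flags$site == key_sites[j], , drop = FALSE]
      idx <- match(ids, sub$species_id)
      fl[, j] <- ifelse(is.na(idx), 0, sub$flag[idx])
    }
  }
  if (is.null(standardize)) {
    center <- apply(x, 3, mean)
    scl <- apply(x, 3, stats::sd)
    scl[scl == 0] <- 1
  } else {
    center <- standardize$center
    scl <- standardize$scale
  }
  for (f in 1:4) x[, , f] <- (x[, , f] - center[f]) / scl[f]
  structure(list(species_id = ids, x = x, flags = fl, center = center,
                 scale = scl, key_sites = key_sites),
            class = "graph_samples")
}

# Glorot-uniform weight initialization
glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

#' Initialize graph-network weights
#'
#' @param n_features Input features per node (4).
#' @param hidden Integer vector of hidden layer widths (default
#'   `c(16, 16)`).
#' @param seed Integer seed for reproducible initialization.
#' @return List of class `network_weights`: `W`, `b` (per layer), `w`, `c`
#'   (linear head over the fingerprint), `hidden`, `fingerprint_dim`.
#' @export
init_network <- function(n_features = 4, hidden = c(16, 16), seed = 1L) {
  set.seed(seed)
  dims <- c(n_features, hidden)
  W <- list(); b <- list()
  for (l in seq_along(hidden)) {
    W[[l]] <- glorot(dims[l], dims[l + 1])
    b[[l]] <- rep(0, dims[l + 1])
  }
  fp_dim <- n_features + sum(hidden)
  structure(list(W = W, b = b,
                 w = stats::runif(fp_dim, -0.01, 0.01), c = 0,
                 hidden = hidden, fingerprint_dim = fp_dim, seed = seed),
            class = "network_weights")
}

# batched forward pass; X array n x k x f, returns fingerprints and caches.
# The fingerprint concatenates the node-mean of every layer (input
# included), neural-fingerprint style, so a linear function of the plain
# node mean is exactly representable by the linear head.
gcn_forward <- function(weights, x, ahat, ops = NULL) {
  n <- dim(x)[1]; k <- dim(x)[2]; f <- dim(x)[3]
  # stack samples vertically: (k*n) x f, sample-major blocks
  Xbig <- matrix(aperm(x, c(2, 1, 3)), nrow = k * n, ncol = f)
  if (is.null(ops)) ops <- gcn_ops(n, k, ahat)
  Abig <- ops$Abig
  Pmat <- ops$Pmat
  pool <- function(H) as.matrix(Pmat %*% H)
  H <- Xbig
  pooled <- list(pool(Xbig))
  Zs <- list(); Hs <- list(Xbig); AHs <- list()
  for (l in seq_along(weights$W)) {
    AH <- as.matrix(Abig %*% H)
    Z <- AH %*% weights$W[[l]] +
      matrix(weights$b[[l]], nrow(AH), length(weights$b[[l]]), byrow = TRUE)
    H <- pmax(Z, 0)
    AHs[[l]] <- AH; Zs[[l]] <- Z; Hs[[l + 1]] <- H
    pooled[[l + 1]] <- pool(H)
  }
  fp <- do.call(cbind, pooled)
  list(fingerprints = fp, Zs = Zs, Hs = Hs, AHs = AHs, Abig = Abig,
       Pmat = Pmat, n = n, k = k)
}

# sparse batched propagation / pooling operators, built once per cohort
gcn_ops <- function(n, k, ahat) {
  list(Abig = Matrix::bdiag(rep(list(ahat), n)),
       Pmat = Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                                   j = seq_len(n * k), x = 1 / k))
}

#' Graph-network fingerprint of one sample
#'
#' Forward pass for a single species: `H_0` is the standardized 5 x 4 node
#' feature matrix, `H_{l+1} = relu(A^ H_l W_l + b_l)`, and the fingerprint
#' concatenates the column-wise node mean of every layer (input included).
#'
#' @param x 5 x 4 node-feature matrix (standardized).
#' @param weights A `network_weights` object.
#' @param ahat Propagation operator from [normalized_adjacency].
#' @return Numeric fingerprint vector.
#' @export
network_forward <- function(x, weights, ahat = normalized_adjacency(nrow(x))) {
  if (!is.matrix(x)) stop("x must be a node x feature matrix")
  if (nrow(ahat) != nrow(x)) stop("operator / node count mismatch")
  xarr <- array(x, dim = c(1, nrow(x), ncol(x)))
  xarr[1, , ] <- x
  drop(gcn_forward(weights, xarr, ahat)$fingerprints)
}

#' Train the graph network end-to-end on a thermal limit
#'
#' Minimizes the mean squared error of a linear head on the pooled
#' fingerprint by full-batch Adam; deterministic under the seed.
#'
#' @param samples A `graph_samples` object.
#' @param targets Numeric response per species (deg C), e.g. `t99`.
#' @param hidden Hidden widths (default `c(16, 16)`).
#' @param epochs Training epochs (default 300).
#' @param lr Adam learning rate (default 0.02).
#' @param seed Seed for weight initialization.
#' @param ahat Propagation operator (default the renormalized path
#'   operator).
#' @return A `network_weights` object with attribute `loss` (final
#'   training MSE).
#' @export
train_network <- function(samples, targets, hidden = c(16, 16),
                          epochs = 300, lr = 0.02, seed = 1L,
                          ahat = NULL) {
  stopifnot(inherits(samples, "graph_samples"))
  x <- samples$x
  n <- dim(x)[1]; k <- dim(x)[2]; f <- dim(x)[3]
  stopifnot(length(targets) == n)
  if (is.null(ahat)) ahat <- normalized_adjacency(k)
  w <- init_network(f, hidden, seed = seed)
  w$c <- mean(targets)
  # Adam state
  params <- c(w$W, w$b, list(w$w), list(w$c))
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  L <- length(w$W)
  ops <- gcn_ops(n, k, ahat)
  for (epoch in seq_len(epochs)) {
    fw <- gcn_forward(w, x, ahat, ops)
    fp <- fw$fingerprints
    yhat <- drop(fp %*% w$w) + w$c
    resid <- yhat - targets
    loss <- mean(resid^2)
    if (!is.finite(loss)) {
      stop("training diverged at epoch ", epoch, " (loss non-finite)")
    }
    r <- 2 * resid / n
    gw_head <- drop(crossprod(fp, r))
    gc_head <- sum(r)
    dfp <- outer(r, w$w)  # n x fp_dim
    # split fingerprint gradient into per-layer pooled blocks
    widths <- c(f, w$hidden)
    offs <- cumsum(c(0, widths))
    gW <- vector("list", L); gb <- vector("list", L)
    dH <- NULL
    for (l in L:1) {
      dml <- dfp[, (offs[l + 1] + 1):offs[l + 2], drop = FALSE]
      dHl <- as.matrix(Matrix::crossprod(fw$Pmat, dml))
      if (!is.null(dH)) dHl <- dHl + dH
      dZ <- dHl * (fw$Zs[[l]] > 0)
      gW[[l]] <- crossprod(fw$AHs[[l]], dZ)
      gb[[l]] <- colSums(dZ)
      dH <- as.matrix(fw$Abig %*% tcrossprod(dZ, w$W[[l]]))
    }
    grads <- c(gW, gb, list(gw_head), list(gc_head))
    for (pi in seq_along(grads)) {
      mstate[[pi]] <- beta1 * mstate[[pi]] + (1 - beta1) * grads[[pi]]
      vstate[[pi]] <- beta2 * vstate[[pi]] + (1 - beta2) * grads[[pi]]^2
      mhat <- mstate[[pi]] / (1 - beta1^epoch)
      vhat <- vstate[[pi]] / (1 - beta2^epoch)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (pi <= L) {
        w$W[[pi]] <- w$W[[pi]] - upd
      } else if (pi <= 2 * L) {
        w$b[[pi - L]] <- w$b[[pi - L]] - upd
      } else if (pi == 2 * L + 1) {
        w$w <- w$w - upd
      } else {
        w$c <- w$c - upd
      }
    }
    attr(w, "loss") <- loss
  }
  w
}

#' Extract fingerprints for a set of graph samples
#'
#' @param weights A `network_weights`.
#' @param samples A `graph_samples`.
#' @param ahat Propagation operator (default renormalized path).
#' @return Matrix n x fingerprint_dim.
#' @export
network_fingerprints <- function(weights, samples, ahat = NULL) {
  if (is.null(ahat)) ahat <- normalized_adjacency(dim(samples$x)[2])
  gcn_forward(weights, samples$x, ahat)$fingerprints
}

#' Default hyperparameter grid for the boosted regressor
#'
#' Spans the six tuned dimensions: learning rate, maximum delta step,
#' maximal tree depth, L2 regularization, number of boosting rounds, and
#' minimum child weight.
#'
#' @return data.frame grid (one row per combination).
#' @export
default_cv_grid <- function() {
  expand.grid(eta = c(0.1, 0.3), max_delta_step = 0, max_depth = c(2, 4),
              lambda = 1, nrounds = c(100, 300), min_child_weight = c(1, 3))
}

#' Fit the gradient-boosted thermal-limit regressor with 5-fold CV
#'
#' Grid-searches the six stated hyperparameters by k-fold cross-validation
#' on the training features (GNN fingerprints joined with the functional
#' variant-type flags), selecting the combination with minimal mean fold
#' MSE, then refits on the full training matrix. Deterministic under
#' `seed` (single-threaded).
#'
#' @param features Numeric matrix (training rows x features).
#' @param targets Numeric response.
#' @param cv_grid data.frame with columns `eta`, `max_delta_step`,
#'   `max_depth`, `lambda`, `nrounds`, `min_child_weight`.
#' @param nfold Folds (default 5).
#' @param seed Seed controlling fold assignment and boosting.
#' @return List of class `boosted_model`: `booster` (xgboost handle),
#'   `best` (selected row), `cv_table` (grid with `mean_cv_mse`),
#'   `folds` (fold id per training row).
#' @export
fit_boosted_model <- function(features, targets, cv_grid = default_cv_grid(),
                              nfold = 5, seed = 1L) {
  if (!nrow(cv_grid)) stop("empty hyperparameter grid")
  features <- as.matrix(features)
  n <- nrow(features)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(nfold), n))
  cv_mse <- numeric(nrow(cv_grid))
  for (g in seq_len(nrow(cv_grid))) {
    hp <- cv_grid[g, ]
    fold_mse <- numeric(nfold)
    for (fd in seq_len(nfold)) {
      tr <- folds != fd
      bst <- xgb_fit(features[tr, , drop = FALSE], targets[tr], hp, seed)
      pred <- stats::predict(bst, xgboost::xgb.DMatrix(
        features[!tr, , drop = FALSE]))
      fold_mse[fd] <- mean((pred - targets[!tr])^2)
    }
    cv_mse[g] <- mean(fold_mse)
  }
  best_idx <- which.min(cv_mse)
  booster <- xgb_fit(features, targets, cv_grid[best_idx, ], seed)
  cv_table <- cv_grid
  cv_table$mean_cv_mse <- cv_mse
  structure(list(booster = booster, best = cv_grid[best_idx, ],
                 best_index = best_idx, cv_table = cv_table, folds = folds),
            class = "boosted_model")
}

xgb_fit <- function(x, y, hp, seed) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
  params <- list(objective = "reg:squarederror", eta = hp$eta,
                 max_delta_step = hp$max_delta_step,
                 max_depth = hp$max_depth, lambda = hp$lambda,
                 min_child_weight = hp$min_child_weight,
                 nthread = 1)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = hp$nrounds, verbose = 0)
}

#' Fit the two-stage thermal-limit predictor
#'
#' End-to-end pipeline for one thermal limit (`t99` or `t01`): a random
#' 70/30 train/test split, feature standardization on the training split,
#' end-to-end graph-network training on the target, fingerprint
#' extraction, gradient-boosted regression on fingerprints plus functional
#' flags with 5-fold CV hyperparameter search, and evaluation on the
#' held-out split.
#'
#' @param feature_rows,flags See [build_graph_samples].
#' @param profiles data.frame with `species_id` and the target column.
#' @param target `"t99"` (upper limit) or `"t01"` (lower limit).
#' @param key_sites Graph node positions.
#' @param train_fraction Training share of the split (default 0.7).
#' @param hidden,epochs,lr Graph-network settings (see [train_network]).
#' @param cv_grid Boosting grid (see [fit_boosted_model]).
#' @param split_seed,network_seed,booster_seed Seeds for the split, the
#'   network initialization and the booster.
#' @param operator `"renormalized"` or `"laplacian"`; `topology` `"path"`
#'   or `"full"` (see [normalized_adjacency]).
#' @param topology Graph topology over the key sites.
#' @return Object of class `thermal_limit_fit` with the trained network,
#'   booster, standardization constants, split ids and a `report` (list
#'   with `mse`, `r2`, per-species predicted vs observed).
#' @export
fit_thermal_limit_model <- function(feature_rows, flags, profiles,
                                    target = c("t99", "t01"),
                                    key_sites = c(173L, 174L, 190L, 230L,
                                                  233L),
                                    train_fraction = 0.7,
                                    hidden = c(16, 16), epochs = 300,
                                    lr = 0.02,
                                    cv_grid = default_cv_grid(),
                                    split_seed = 1L, network_seed = 1L,
                                    booster_seed = 1L,
                                    operator = "renormalized",
                                    topology = "path") {
  target <- match.arg(target)
  stopifnot(target %in% names(profiles))
  raw <- build_graph_samples(feature_rows, flags, key_sites)
  ids <- raw$species_id
  y <- profiles[[target]][match(ids, profiles$species_id)]
  keep <- !is.na(y)
  ids <- ids[keep]; y <- y[keep]
  n <- length(ids)
  if (n < 20) stop("need at least 20 species with targets")
  set.seed(split_seed)
  tr_idx <- sort(sample(n, round(train_fraction * n)))
  te_idx <- setdiff(seq_len(n), tr_idx)
  if (length(te_idx) < 2) stop("test split too small")
  sub_rows <- feature_rows[feature_rows$species_id %in% ids, , drop = FALSE]
  train_samples <- build_graph_samples(
    sub_rows[sub_rows$species_id %in% ids[tr_idx], , drop = FALSE],
    flags, key_sites)
  constants <- list(center = train_samples$center,
                    scale = train_samples$scale)
  all_samples <- build_graph_samples(sub_rows, flags, key_sites,
                                     standardize = constants)
  ord <- match(ids, all_samples$species_id)
  ahat <- normalized_adjacency(length(key_sites), type = operator,
                               topology = topology)
  weights <- train_network(train_samples, y[tr_idx], hidden = hidden,
                           epochs = epochs, lr = lr, seed = network_seed,
                           ahat = ahat)
  fp_all <- network_fingerprints(weights, all_samples, ahat)[ord, ,
                                                             drop = FALSE]
  xmat <- cbind(fp_all, all_samples$flags[ord, , drop = FALSE])
  colnames(xmat) <- c(paste0("fp", seq_len(ncol(fp_all))),
                      paste0("flag", seq_len(ncol(all_samples$flags))))
  boosted <- fit_boosted_model(xmat[tr_idx, , drop = FALSE], y[tr_idx],
                               cv_grid = cv_grid, seed = booster_seed)
  pred_te <- stats::predict(boosted$booster,
                            xgboost::xgb.DMatrix(xmat[te_idx, ,
                                                      drop = FALSE]))
  report <- prediction_report(y[te_idx], pred_te, ids[te_idx],
                              split_seed = split_seed)
  structure(list(target = target, key_sites = key_sites,
                 weights = weights, boosted = boosted,
                 constants = constants, ahat = ahat,
                 train_ids = ids[tr_idx], test_ids = ids[te_idx],
                 seeds = c(split = split_seed, network = network_seed,
                           booster = booster_seed),
                 report = report),
            class = "thermal_limit_fit")
}

#' Evaluate predictions against observed thermal limits
#'
#' `mse` is the mean squared error (deg C^2) and `r2 = 1 - SS_res/SS_tot`
#' with the total sum of squares about the test-split mean (so a constant
#' test-mean prediction scores exactly 0).
#'
#' @param observed,predicted Numeric vectors (length >= 2).
#' @param species_id Optional identifiers.
#' @param split_seed Recorded split seed.
#' @return List of class `prediction_report`: `mse`, `r2`, `n`,
#'   `predictions` (data.frame), `split_seed`.
#' @export
prediction_report <- function(observed, predicted, species_id = NULL,
                              split_seed = NA_integer_) {
  if (length(observed) < 2) stop("need at least 2 evaluation points")
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  structure(list(
    mse = mean((observed - predicted)^2),
    r2 = 1 - ss_res / ss_tot,
    n = length(observed),
    predictions = data.frame(
      species_id = if (is.null(species_id)) seq_along(observed) else
        species_id,
      observed = observed, predicted = predicted,
      stringsAsFactors = FALSE),
    split_seed = split_seed),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("Held-out evaluation: n = %d, MSE = %.3f degC^2, R2 = %.3f\n",
              x$n, x$mse, x$r2))
  invisible(x)
}

#' @export
print.thermal_limit_fit <- function(x, ...) {
  cat("Thermal-limit predictor (", x$target, ") over key sites ",
      paste(x$key_sites, collapse = ", "), "\n", sep = "")
  cat("  graph network: hidden", paste(x$weights$hidden, collapse = "/"),
      "-> fingerprint dim", x$weights$fingerprint_dim, "\n")
  cat("  booster:", paste(names(x$boosted$best),
                          unlist(x$boosted$best), sep = "=",
                          collapse = " "), "\n")
  print(x$report)
  invisible(x)
}

#' @export
summary.thermal_limit_fit <- function(object, ...) {
  print(object)
  cat("\nCV grid (mean fold MSE):\n")
  print(object$boosted$cv_table, row.names = FALSE)
  invisible(object)
}

#' Predict thermal limits for new species
#'
#' @param object A `thermal_limit_fit`.
#' @param feature_rows,flags New feature rows / functional flags (see
#'   [build_graph_samples]); standardized with the training constants.
#' @param ... Unused.
#' @return data.frame `species_id`, `predicted`.
#' @export
predict.thermal_limit_fit <- function(object, feature_rows, flags = NULL,
                                      ...) {
  samples <- build_graph_samples(feature_rows, flags, object$key_sites,
                                 standardize = object$constants)
  fp <- network_fingerprints(object$weights, samples, object$ahat)
  xmat <- cbind(fp, samples$flags)
  colnames(xmat) <- c(paste0("fp", seq_len(ncol(fp))),
                      paste0("flag", seq_len(ncol(samples$flags))))
  data.frame(species_id = samples$species_id,
             predicted = stats::predict(object$boosted$booster,
                                        xgboost::xgb.DMatrix(xmat)),
             stringsAsFactors = FALSE)
}
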
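# small, fast cohort used across tests
small_cfg <- function(seed = 1L, ...) {
  args <- list(n_species = 120, n_planted_trss = 5, n_neutral_sites = 20,
               records_per_species = 100, traj_isoforms = 4,
               traj_replicates = 2, traj_atoms = 20, traj_dt = 1,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# alignment from a species x column character matrix
aln_from_matrix <- function(m) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("sp%02d", seq_len(nrow(m)))
  ortholog_set(apply(m, 1, paste, collapse = ""), ids)
}

# independent per-column scan used as the substitution-site oracle
brute_force_sites <- function(m) {
  hits <- list()
  for (j in seq_len(ncol(m))) {
    res <- m[, j][m[, j] != "-"]
    if (length(unique(res)) >= 2) {
      hits[[as.character(j)]] <- sort(table(res))
    }
  }
  hits
}

# percentile by explicit linear interpolation between order statistics
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force negative log-likelihood logistic fit (independent of glm)
logistic_brute_force <- function(y, x) {
  nll <- function(b) {
    eta <- b[1] + b[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(b) {
    p <- plogis(b[1] + b[2] * x)
    -c(sum(y - p), sum((y - p) * x))
  }
  fit <- optim(c(0, 0), nll, gr, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  # polish with explicit Newton steps on the textbook score / information
  b <- fit$par
  X <- cbind(1, x)
  for (i in 1:8) {
    p <- plogis(drop(X %*% b))
    score <- drop(t(X) %*% (y - p))
    info <- t(X * (p * (1 - p))) %*% X
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  # intercept-only maximum is the empirical log-odds, in closed form
  nll_null <- nll(c(qlogis(mean(y)), 0))
  list(coef = unname(b),
       p = pchisq(2 * (nll_null - nll(b)), df = 1, lower.tail = FALSE))
}

# direct xgboost fit used as an independent route in control checks
xgb_fit_for_test <- function(x, y, hp) {
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = hp$eta,
                  max_delta_step = hp$max_delta_step,
                  max_depth = hp$max_depth, lambda = hp$lambda,
                  min_child_weight = hp$min_child_weight, nthread = 1),
    data = xgboost::xgb.DMatrix(as.matrix(x), label = y),
    nrounds = hp$nrounds, verbose = 0)
}

# simple trajectory with explicit coordinates
toy_traj <- function(coords, times = seq_len(dim(coords)[3]) - 1,
                     temperature = 10, residues = NULL) {
  trajectory(coords, times, temperature, atom_residue = residues)
}
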
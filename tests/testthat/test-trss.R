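test_that("variant filtering removes singletons and degenerate sites", {
  m <- rbind(matrix(rep(c("A", "K"), each = 277), ncol = 2))
  m[1, 1] <- "V"; m[2, 1] <- "L"          # two singletons at site 1
  m[1:77, 2] <- "V"                        # common variant at site 2
  rownames(m) <- sprintf("sp%03d", 1:277)
  sites <- find_substitution_sites(aln_from_matrix(m))
  filt <- filter_variants(sites)
  # site 1 loses both singletons -> monomorphic -> dropped
  expect_length(filt$sites, 1)
  expect_equal(filt$sites[[1]]$position, 2)
  expect_equal(sort(filt$sites[[1]]$counts),
               sort(c(K = 200L, V = 77L)))
})

test_that("filtered variant counts equal a brute-force recount", {
  cfg <- small_cfg(seed = 21, n_species = 150, n_neutral_sites = 40)
  sp <- simulate_species(cfg)
  al <- simulate_alignment(cfg, sp$species)
  sites <- find_substitution_sites(al$alignment)
  filt <- filter_variants(sites)
  m <- do.call(rbind, strsplit(unname(al$alignment$sequences), ""))
  for (s in filt$sites) {
    tab <- table(m[, s$position])
    tab <- tab[names(tab) != "-"]
    tab <- tab[tab >= 2]
    expect_equal(sort(s$counts), sort(tab), ignore_attr = TRUE)
  }
})

test_that("binomial regression handles degenerate and regular inputs", {
  ass <- binomial_association(rep(1, 30), rnorm(30))
  expect_true(ass$degenerate)
  expect_equal(ass$p, 1)
  expect_true(is.na(ass$slope))

  set.seed(5)
  temps <- runif(200, -2, 30)
  y <- rbinom(200, 1, plogis(-4 + 0.3 * temps))
  ass <- binomial_association(y, temps)
  expect_false(ass$degenerate)
  expect_false(ass$separation)
  expect_true(ass$slope > 0)
  expect_true(ass$p < 0.01)
})

test_that("logistic MLE and LRT match brute-force likelihood maximization", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(30:80, 1)
    x <- rnorm(n, 10, 6)
    y <- rbinom(n, 1, plogis(-1 + 0.15 * x))
    if (sum(y) < 3 || sum(y) > n - 3) next
    ass <- binomial_association(y, x)
    if (ass$separation) next
    oracle <- logistic_brute_force(y, x)
    expect_equal(c(ass$intercept, ass$slope), oracle$coef, tolerance = 1e-6)
    expect_equal(ass$p, oracle$p, tolerance = 1e-6)
  }
})

test_that("complete separation is flagged and the penalized fit reports", {
  x <- c(1:10, 21:30)
  y <- c(rep(0, 10), rep(1, 10))
  ass <- binomial_association(y, x)
  expect_true(ass$separation)
  expect_true(is.finite(ass$slope))
  expect_true(ass$slope > 0)
  expect_true(ass$p < 0.01)
})

test_that("Wald interval covers the true slope near the nominal rate", {
  set.seed(23)
  covered <- 0; reps <- 300
  for (r in 1:reps) {
    x <- runif(500, -2, 30)
    y <- rbinom(500, 1, plogis(-4.2 + 0.3 * x))
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    ci <- coef(fit)[2] + c(-1, 1) * 1.96 * sqrt(vcov(fit)[2, 2])
    covered <- covered + (ci[1] <= 0.3 && 0.3 <= ci[2])
  }
  expect_gt(covered / reps, 0.92)
  expect_lt(covered / reps, 0.98)
})

test_that("group test matches the closed-form F statistic", {
  set.seed(31)
  g1 <- rnorm(30, 10, 2); g2 <- rnorm(25, 12, 2); g3 <- rnorm(40, 9, 2)
  temps <- c(g1, g2, g3)
  groups <- rep(c("A", "V", "I"), c(30, 25, 40))
  gt <- group_significance_test(temps, groups)
  # textbook one-way ANOVA F from sums of squares
  grand <- mean(temps)
  ni <- c(30, 25, 40)
  mi <- c(mean(g1), mean(g2), mean(g3))
  ssb <- sum(ni * (mi - grand)^2)
  ssw <- sum((g1 - mi[1])^2) + sum((g2 - mi[2])^2) + sum((g3 - mi[3])^2)
  f_oracle <- (ssb / 2) / (ssw / (95 - 3))
  p_oracle <- pf(f_oracle, 2, 92, lower.tail = FALSE)
  if (gt$method == "anova_lsd") {
    expect_equal(gt$omnibus_p, p_oracle, tolerance = 1e-9)
  } else {
    succeed("nonparametric path selected by the normality screen")
  }
})

test_that("group test separates far-apart groups and ties identical ones", {
  set.seed(41)
  gt <- group_significance_test(c(rnorm(50, 0, 1), rnorm(50, 10, 1)),
                                rep(c("I", "L"), each = 50))
  expect_lt(gt$omnibus_p, 1e-4)
  expect_false(gt$letters[["I"]] == gt$letters[["L"]])

  # identical values in both groups: no significance, shared letter
  gt0 <- group_significance_test(rep(5, 20), rep(c("I", "L"), each = 10))
  expect_equal(gt0$omnibus_p, 1)
  expect_equal(gt0$letters[["I"]], gt0$letters[["L"]])
})

test_that("letters share exactly when adjusted pairwise p >= alpha", {
  set.seed(53)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    shifts <- cumsum(sample(c(0, 2, 6), k, replace = TRUE))
    temps <- unlist(lapply(shifts, function(s) rnorm(12, s, 1.5)))
    groups <- rep(LETTERS[1:k], each = 12)
    gt <- group_significance_test(temps, groups)
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      share <- any(strsplit(gt$letters[[a]], "")[[1]] %in%
                     strsplit(gt$letters[[b]], "")[[1]])
      expect_equal(share, gt$pairwise[a, b] >= 0.05)
    }
  }
})

test_that("TRSS detection recovers planted sites and types variants", {
  cfg <- small_cfg(seed = 9, n_species = 160, n_planted_trss = 5,
                   n_neutral_sites = 30)
  sp <- simulate_species(cfg)
  al <- simulate_alignment(cfg, sp$species)
  prof <- species_thermal_profiles(sp$records)
  trss <- detect_trss(find_substitution_sites(al$alignment), prof)
  det <- trss$site[trss$trss]
  expect_gte(sum(al$truth$planted$site %in% det), 4)
  expect_lte(sum(det %in% al$truth$neutral_sites), 1)
  # planted warm variants land on the warm pole
  hits <- trss[trss$trss & trss$site %in% al$truth$planted$site, ]
  for (i in seq_len(nrow(hits))) {
    truth_warm <- al$truth$planted$warm[al$truth$planted$site ==
                                          hits$site[i]]
    expect_true(truth_warm %in% strsplit(hits$warm_variants[i], "/")[[1]])
    truth_cold <- al$truth$planted$cold[al$truth$planted$site ==
                                          hits$site[i]]
    expect_true(truth_cold %in% strsplit(hits$cold_variants[i], "/")[[1]])
  }
  # cold and warm pole sets never overlap
  for (i in seq_len(nrow(trss))) {
    cw <- intersect(strsplit(trss$cold_variants[i], "/")[[1]],
                    strsplit(trss$warm_variants[i], "/")[[1]])
    expect_length(cw, 0)
  }
})

test_that("a monomorphic alignment yields no TRSS", {
  m <- matrix("A", 30, 10)
  rownames(m) <- sprintf("sp%02d", 1:30)
  prof <- data.frame(species_id = rownames(m), mean_temp = runif(30))
  trss <- detect_trss(find_substitution_sites(aln_from_matrix(m)), prof)
  expect_equal(nrow(trss), 0)
})

test_that("detection power is nondecreasing in the planted effect size", {
  power_at <- function(beta) {
    hits <- 0
    for (s in 1:3) {
      cfg <- small_cfg(seed = 60 + s, n_species = 150, n_planted_trss = 5,
                       n_neutral_sites = 0, logistic_slope = beta)
      sp <- simulate_species(cfg)
      al <- suppressWarnings(simulate_alignment(cfg, sp$species))
      prof <- species_thermal_profiles(sp$records)
      trss <- detect_trss(find_substitution_sites(al$alignment), prof)
      hits <- hits + sum(al$truth$planted$site %in% trss$site[trss$trss])
    }
    hits / 15
  }
  powers <- vapply(c(0.03, 0.12, 0.5), power_at, numeric(1))
  expect_true(all(diff(powers) >= 0))
  expect_lt(powers[1], 0.5)
  expect_gt(powers[3], 0.9)
})
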
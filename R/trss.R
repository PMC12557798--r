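#' Filter rare variants at substitution sites
#'
#' Variants observed in fewer than `min_count` species are removed (their
#' carriers are excluded from that site's tests); sites left with fewer
#' than two variants are dropped altogether. The default threshold keeps
#' only variants with frequency greater than one (n >= 2), guarding against
#' sequencing errors.
#'
#' @param sites A `substitution_sites` object (see
#'   [find_substitution_sites]).
#' @param min_count Minimum carrier count per retained variant.
#' @return A `substitution_sites` object containing only the retained
#'   sites, with singleton residues at retained sites replaced by `-` in
#'   `site_residues` (so downstream tests skip those species).
#' @export
filter_variants <- function(sites, min_count = 2) {
  stopifnot(inherits(sites, "substitution_sites"))
  keep <- list()
  sr <- sites$site_residues
  keep_cols <- character(0)
  for (s in sites$sites) {
    cnt <- s$counts[s$counts >= min_count]
    if (length(cnt) < 2L) next
    dropped <- setdiff(names(s$counts), names(cnt))
    col <- as.character(s$position)
    if (length(dropped)) {
      v <- sr[, col]
      v[v %in% dropped] <- "-"
      sr[, col] <- v
    }
    s$counts <- cnt
    keep[[length(keep) + 1L]] <- s
    keep_cols <- c(keep_cols, col)
  }
  structure(list(sites = keep,
                 site_residues = sr[, keep_cols, drop = FALSE],
                 gap_columns = sites$gap_columns,
                 n_species = sites$n_species,
                 species_ids = sites$species_ids),
            class = "substitution_sites")
}

#' Binomial regression of variant presence on habitat temperature
#'
#' Fits the logistic model `presence ~ intercept + slope * temperature` by
#' maximum likelihood and reports a likelihood-ratio p-value against the
#' intercept-only model. A constant response is degenerate (p = 1 by
#' convention, no slope). Complete or quasi-complete separation is detected
#' from the fitted probabilities; the reported slope and p-value then come
#' from a Jeffreys-penalized (Firth) fit, and the record is flagged.
#'
#' @param presence 0/1 vector: does the species carry the variant?
#' @param temps Species mean habitat temperatures (deg C), same length.
#' @return List of class `variant_association`: `n_carriers`, `slope`
#'   (per deg C), `intercept`, `p` (likelihood-ratio), `degenerate`
#'   (constant response), `separation` (penalized fallback used).
#' @export
binomial_association <- function(presence, temps) {
  stopifnot(length(presence) == length(temps))
  ok <- !is.na(presence) & !is.na(temps)
  presence <- as.integer(presence[ok])
  temps <- temps[ok]
  n1 <- sum(presence)
  out <- list(n_carriers = n1, slope = NA_real_, intercept = NA_real_,
              p = 1, degenerate = FALSE, separation = FALSE)
  class(out) <- "variant_association"
  if (n1 == 0L || n1 == length(presence)) {
    out$degenerate <- TRUE
    return(out)
  }
  fit <- suppressWarnings(
    stats::glm(presence ~ temps, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  eps <- 1e-7
  sep <- !fit$converged || any(fit$fitted.values < eps) ||
    any(fit$fitted.values > 1 - eps)
  if (sep) {
    ff <- firth_logistic(presence, temps)
    out$slope <- ff$slope
    out$intercept <- ff$intercept
    out$p <- ff$p
    out$separation <- TRUE
  } else {
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
    out$p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                           lower.tail = FALSE)
  }
  out
}

# Jeffreys-penalized logistic regression (Firth 1993) for one covariate,
# with a penalized likelihood-ratio p-value for the slope. Used only as the
# separation fallback of binomial_association().
firth_logistic <- function(y, x, max_iter = 100, tol = 1e-10) {
  X <- cbind(1, x)
  fit_pen <- function(Xm) {
    beta <- rep(0, ncol(Xm))
    for (it in seq_len(max_iter)) {
      eta <- drop(Xm %*% beta)
      p <- stats::plogis(eta)
      w <- pmax(p * (1 - p), 1e-12)
      XtW <- t(Xm * w)
      info <- XtW %*% Xm
      # hat diagonal of the weighted design
      Xw <- Xm * sqrt(w)
      h <- rowSums((Xw %*% solve(info)) * Xw)
      score <- drop(t(Xm) %*% (y - p + h * (0.5 - p)))
      step <- solve(info, score)
      beta <- beta + step
      if (max(abs(step)) < tol) break
    }
    eta <- drop(Xm %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    info <- t(Xm * w) %*% Xm
    ll <- sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(info)$modulus
    list(beta = beta, loglik = as.numeric(ll))
  }
  full <- fit_pen(X)
  null <- fit_pen(X[, 1, drop = FALSE])
  lrt <- max(0, 2 * (full$loglik - null$loglik))
  list(intercept = full$beta[1], slope = full$beta[2],
       p = stats::pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Omnibus group test on habitat temperature with post hoc letters
#'
#' Compares species mean habitat temperature across the variant groups of a
#' substitution site. The parametric path (one-way ANOVA with LSD pairwise
#' t-tests on the pooled residual variance) is taken when every group
#' passes Shapiro-Wilk normality (alpha = 0.05) and Levene's test finds no
#' variance heterogeneity (alpha = 0.05); otherwise the Kruskal-Wallis test
#' with Dunn's tie-corrected pairwise z-tests is used. Pairwise p-values
#' are Bonferroni-adjusted and summarized as a compact letter display:
#' groups share a letter exactly when their adjusted pairwise p >= alpha.
#'
#' A zero-variance group on the parametric path forces the nonparametric
#' path (the switch is recorded in `switched`).
#'
#' @param temps Numeric vector of species mean temperatures.
#' @param groups Factor (or coercible) of variant labels, same length.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List of class `group_test`: `method` (`"anova_lsd"` or
#'   `"kw_dunn"`), `omnibus_p`, `pairwise` (adjusted p matrix), `letters`
#'   (named character), `group_means`, `group_n`, `switched`.
#' @export
group_significance_test <- function(temps, groups, alpha = 0.05) {
  groups <- factor(groups)
  ok <- !is.na(temps) & !is.na(groups)
  temps <- temps[ok]
  groups <- droplevels(groups[ok])
  n_by <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(n_by < 2L)) stop("every group needs at least two members")
  means <- tapply(temps, groups, mean)
  vars <- tapply(temps, groups, stats::var)

  normal_ok <- all(vapply(levels(groups), function(g) {
    v <- temps[groups == g]
    if (stats::var(v) == 0 || length(v) < 3L) return(FALSE)
    tryCatch(stats::shapiro.test(v)$p.value >= 0.05, error = function(e) FALSE)
  }, logical(1)))
  switched <- FALSE
  use_parametric <- FALSE
  if (normal_ok) {
    lev_p <- car::leveneTest(temps ~ groups)[1, "Pr(>F)"]
    use_parametric <- !is.na(lev_p) && lev_p >= 0.05
  }
  if (!normal_ok && any(vars == 0)) switched <- TRUE

  lv <- levels(groups)
  k <- length(lv)
  pw <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  n_pairs <- k * (k - 1) / 2

  if (use_parametric) {
    fit <- stats::aov(temps ~ groups)
    tab <- summary(fit)[[1]]
    omnibus_p <- tab[["Pr(>F)"]][1]
    mse <- tab[["Mean Sq"]][2]
    df_res <- tab[["Df"]][2]
    for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
      se <- sqrt(mse * (1 / n_by[a] + 1 / n_by[b]))
      tstat <- (means[a] - means[b]) / se
      p <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
      pw[a, b] <- pw[b, a] <- min(1, p * n_pairs)
    }
    method <- "anova_lsd"
  } else {
    omnibus_p <- stats::kruskal.test(temps, groups)$p.value
    if (!is.finite(omnibus_p)) omnibus_p <- 1  # all observations tied
    pw <- dunn_pairwise(temps, groups) * n_pairs
    pw[pw > 1] <- 1
    method <- "kw_dunn"
  }
  diag(pw) <- 1
  letters <- compact_letters(pw, means, alpha = alpha)
  structure(list(method = method, omnibus_p = omnibus_p, pairwise = pw,
                 letters = letters, group_means = means,
                 group_n = as.integer(n_by), switched = switched),
            class = "group_test")
}

# Dunn's pairwise z-tests on joint ranks with tie-corrected variance;
# returns the matrix of unadjusted two-sided p-values.
dunn_pairwise <- function(x, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  k <- length(lv)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, groups, mean)
  n_by <- table(groups)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  p <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    se <- sqrt(max(0, v0) * (1 / n_by[a] + 1 / n_by[b]))
    z <- if (se > 0) (rbar[a] - rbar[b]) / se else 0  # all-tie degeneracy
    p[a, b] <- p[b, a] <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  diag(p) <- 1
  p
}

# Compact letter display by insert-and-absorb: groups share a letter iff
# their adjusted pairwise p >= alpha. Letters assigned in order of
# decreasing group mean (so 'a' tags the warmest pole).
compact_letters <- function(p_adj, means, alpha = 0.05) {
  lv <- rownames(p_adj)
  k <- length(lv)
  sets <- list(seq_len(k))
  for (a in seq_len(k - 1)) for (b in seq(a + 1, k)) {
    if (is.na(p_adj[a, b]) || p_adj[a, b] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) for (j in seq_along(new_sets)) {
      if (i != j && keep[i] && keep[j] &&
          all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
    sets <- new_sets[keep]
  }
  # order letter sets by the warmest member they contain
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)))
  sets <- sets[ord]
  out <- character(k)
  for (i in seq_along(sets)) {
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  }
  names(out) <- lv
  out
}

#' Detect thermal adaptation-related sequence sites (TRSS)
#'
#' A substitution site qualifies as a TRSS when all three criteria hold:
#' (1) it carries at least two variants each observed in >= 2 species,
#' (2) some variant's binomial-regression p-value against species mean
#' habitat temperature is below `alpha`, and (3) the omnibus group test on
#' mean habitat temperature across variants is below `alpha`. At each TRSS,
#' variants whose carriers have significantly lower mean habitat
#' temperature (sharing a letter with the coldest group but not the
#' warmest) are typed cold-adapted, and conversely warm-adapted; variants
#' bridging both poles stay untyped.
#'
#' Species with a gap (or a filtered singleton) at a site are excluded from
#' that site's tests; species lacking a thermal profile are excluded with a
#' warning.
#'
#' @param sites A `substitution_sites` object (already variant-filtered, or
#'   raw; [filter_variants] is applied with `min_count`).
#' @param profiles data.frame from [species_thermal_profiles] (needs
#'   `species_id`, `mean_temp`).
#' @param alpha Dual significance threshold for criteria (2) and (3)
#'   (default 1e-4).
#' @param min_count Carrier-count filter for criterion (1) (default 2).
#' @param letter_alpha Significance level for post hoc letters and typing.
#' @return data.frame of class `trss_table`, one row per tested site:
#'   `site`, `n_variants`, `variants`, `min_p_binomial`, `omnibus_p`,
#'   `method`, `letters`, `cold_variants`, `warm_variants`, `trss`
#'   (logical), plus `n_separation` (variants needing the penalized
#'   fallback).
#' @export
detect_trss <- function(sites, profiles, alpha = 1e-4, min_count = 2,
                        letter_alpha = 0.05) {
  stopifnot(inherits(sites, "substitution_sites"))
  fs <- filter_variants(sites, min_count = min_count)
  prof <- profiles[match(fs$species_ids, profiles$species_id), , drop = FALSE]
  missing_prof <- is.na(prof$mean_temp)
  if (any(missing_prof)) {
    warning(sum(missing_prof), " species lack a thermal profile; excluded")
  }
  temps_all <- prof$mean_temp
  rows <- list()
  for (s in fs$sites) {
    col <- fs$site_residues[, as.character(s$position)]
    use <- col != "-" & !missing_prof
    res <- col[use]
    temps <- temps_all[use]
    tab <- table(res)
    tab <- tab[tab >= min_count]
    if (length(tab) < 2L) next
    use2 <- res %in% names(tab)
    res <- res[use2]
    temps <- temps[use2]
    # criterion 2: per-variant one-vs-rest binomial regression
    assoc <- lapply(names(tab), function(v) {
      binomial_association(as.integer(res == v), temps)
    })
    p_bin <- vapply(assoc, `[[`, numeric(1), "p")
    n_sep <- sum(vapply(assoc, `[[`, logical(1), "separation"))
    # criterion 3: omnibus group test
    gt <- group_significance_test(temps, res, alpha = letter_alpha)
    is_trss <- min(p_bin) < alpha && gt$omnibus_p < alpha
    typing <- if (is_trss) type_variants(gt) else
      list(cold = character(0), warm = character(0))
    rows[[length(rows) + 1L]] <- data.frame(
      site = s$position,
      n_variants = length(tab),
      variants = paste(names(tab), collapse = "/"),
      min_p_binomial = min(p_bin),
      omnibus_p = gt$omnibus_p,
      method = gt$method,
      letters = paste(paste0(names(gt$letters), ":", gt$letters),
                      collapse = ","),
      cold_variants = paste(typing$cold, collapse = "/"),
      warm_variants = paste(typing$warm, collapse = "/"),
      n_separation = n_sep,
      trss = is_trss,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site = integer(0), n_variants = integer(0),
               variants = character(0), min_p_binomial = numeric(0),
               omnibus_p = numeric(0), method = character(0),
               letters = character(0), cold_variants = character(0),
               warm_variants = character(0), n_separation = integer(0),
               trss = logical(0))
  class(out) <- c("trss_table", "data.frame")
  out
}

# Assign letter-separated variants to the cold or warm pole. A variant is
# warm-adapted if it shares a letter with the warmest group but none with
# the coldest, cold-adapted in the mirror case; otherwise untyped. The
# cold and warm sets are disjoint by construction.
type_variants <- function(gt) {
  m <- gt$group_means
  letset <- strsplit(gt$letters, "")
  warm_ref <- letset[[which.max(m)]]
  cold_ref <- letset[[which.min(m)]]
  warm <- character(0); cold <- character(0)
  for (i in seq_along(m)) {
    w <- any(letset[[i]] %in% warm_ref)
    c_ <- any(letset[[i]] %in% cold_ref)
    if (w && !c_) warm <- c(warm, names(m)[i])
    if (c_ && !w) cold <- c(cold, names(m)[i])
  }
  list(cold = cold, warm = warm)
}

#' @export
print.trss_table <- function(x, ...) {
  cat("TRSS detection:", sum(x$trss), "of", nrow(x),
      "tested substitution sites pass the three criteria\n")
  if (sum(x$trss)) {
    print.data.frame(x[x$trss, c("site", "variants", "min_p_binomial",
                                 "omnibus_p", "cold_variants",
                                 "warm_variants")], row.names = FALSE)
  }
  invisible(x)
}
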
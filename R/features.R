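#' Contrast structural features between cold and warm variant carriers
#'
#' For each TRSS and each structural feature (hydrogen-bond count,
#' hydrogen-bond distance, SASA, RSA), compares the distributions between
#' carriers of cold-adapted and warm-adapted variants. The parametric path
#' (pooled-variance two-sample t-test, i.e. two-group ANOVA/LSD) is taken
#' when both groups pass Shapiro-Wilk normality and Levene's test at 0.05;
#' otherwise the rank test (two-group Kruskal-Wallis / Dunn, equivalent to
#' a Wilcoxon-type z-test with tie correction) is used. With a single
#' comparison per site x feature the Bonferroni family is of size one, so
#' the adjusted p equals the raw p.
#'
#' RSA is derived from SASA via [compute_rsa] when a `residue` column is
#' present and no `rsa` column is supplied.
#'
#' @param feature_rows data.frame with columns `species_id`, `site`,
#'   `hbond_n`, `hbond_dist_A`, `sasa_A2`, optionally `residue` and `rsa`.
#' @param trss A `trss_table` from [detect_trss] (only rows with
#'   `trss == TRUE` and both poles typed are used).
#' @param carriers data.frame mapping `species_id` x `site` to the residue
#'   carried (defaults to the `residue` column of `feature_rows`).
#' @param alpha Significance level (default 0.05).
#' @return data.frame: `site`, `feature`, `cold_mean`, `warm_mean`,
#'   `n_cold`, `n_warm`, `p_adjusted`, `method`, `direction` in
#'   `{"cold_higher", "warm_higher", "ns"}`.
#' @export
contrast_variant_features <- function(feature_rows, trss, carriers = NULL,
                                      alpha = 0.05) {
  stopifnot(all(c("species_id", "site", "hbond_n", "hbond_dist_A",
                  "sasa_A2") %in% names(feature_rows)))
  fr <- feature_rows
  if (!"rsa" %in% names(fr)) {
    if (!"residue" %in% names(fr)) {
      stop("need either an `rsa` or a `residue` column to derive RSA")
    }
    fr$rsa <- suppressWarnings(compute_rsa(fr$sasa_A2, fr$residue))
  }
  if (is.null(carriers)) {
    if (!"residue" %in% names(fr)) stop("carrier residues are required")
    carriers <- fr[, c("species_id", "site", "residue")]
  }
  feats <- c(hbond_n = "hbond_n", hbond_dist = "hbond_dist_A",
             sasa = "sasa_A2", rsa = "rsa")
  hits <- trss[trss$trss & nzchar(trss$cold_variants) &
                 nzchar(trss$warm_variants), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    site <- hits$site[i]
    cold <- strsplit(hits$cold_variants[i], "/")[[1]]
    warm <- strsplit(hits$warm_variants[i], "/")[[1]]
    sub <- fr[fr$site == site, , drop = FALSE]
    car_site <- carriers[carriers$site == site, , drop = FALSE]
    lab <- car_site$residue[match(sub$species_id, car_site$species_id)]
    pole <- ifelse(lab %in% cold, "cold", ifelse(lab %in% warm, "warm", NA))
    if (sum(pole == "cold", na.rm = TRUE) < 2L ||
        sum(pole == "warm", na.rm = TRUE) < 2L) {
      warning("site ", site, ": a pole has fewer than 2 carriers; skipped")
      next
    }
    for (fn in names(feats)) {
      v <- sub[[feats[[fn]]]]
      ok <- !is.na(pole) & !is.na(v)
      res <- two_group_contrast(v[ok], pole[ok], alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        site = site, feature = fn,
        cold_mean = res$means[["cold"]], warm_mean = res$means[["warm"]],
        n_cold = res$n[["cold"]], n_warm = res$n[["warm"]],
        p_adjusted = res$p, method = res$method,
        direction = if (res$p >= alpha) "ns" else
          if (res$means[["cold"]] > res$means[["warm"]]) "cold_higher"
          else "warm_higher",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(site = integer(0), feature = character(0),
                      cold_mean = numeric(0), warm_mean = numeric(0),
                      n_cold = integer(0), n_warm = integer(0),
                      p_adjusted = numeric(0), method = character(0),
                      direction = character(0)))
  }
  do.call(rbind, rows)
}

# two-group contrast with the same parametric/nonparametric switch as the
# site-level omnibus tests
two_group_contrast <- function(v, pole, alpha = 0.05) {
  pole <- factor(pole, levels = c("cold", "warm"))
  means <- tapply(v, pole, mean)
  n <- tapply(v, pole, length)
  normal_ok <- all(vapply(levels(pole), function(g) {
    x <- v[pole == g]
    if (length(x) < 3L || stats::var(x) == 0) return(FALSE)
    tryCatch(stats::shapiro.test(x)$p.value >= 0.05, error = function(e) FALSE)
  }, logical(1)))
  use_par <- FALSE
  if (normal_ok) {
    lev_p <- car::leveneTest(v ~ pole)[1, "Pr(>F)"]
    use_par <- !is.na(lev_p) && lev_p >= 0.05
  }
  if (use_par) {
    p <- stats::t.test(v ~ pole, var.equal = TRUE)$p.value
    method <- "anova_lsd"
  } else {
    p <- dunn_pairwise(v, pole)["cold", "warm"]
    method <- "kw_dunn"
  }
  list(p = p, means = means, n = n, method = method)
}

#' Tally significant feature contrasts by direction
#'
#' @param contrasts data.frame from [contrast_variant_features].
#' @return data.frame with one row per feature: `feature`, `cold_higher`,
#'   `warm_higher`, `ns` (counts of sites).
#' @export
summarize_direction_counts <- function(contrasts) {
  feats <- c("hbond_n", "hbond_dist", "sasa", "rsa")
  out <- data.frame(feature = feats, cold_higher = 0L, warm_higher = 0L,
                    ns = 0L, stringsAsFactors = FALSE)
  if (!nrow(contrasts)) return(out)
  for (i in seq_along(feats)) {
    sub <- contrasts[contrasts$feature == feats[i], , drop = FALSE]
    out$cold_higher[i] <- sum(sub$direction == "cold_higher")
    out$warm_higher[i] <- sum(sub$direction == "warm_higher")
    out$ns[i] <- sum(sub$direction == "ns")
  }
  out
}
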
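#' Configuration for the synthetic thermal-adaptation cohort
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design this package targets: 277 marine fish species with mean
#' habitat temperatures spanning -1.6 to 29.5 deg C, 332-column aligned
#' LDH-A orthologs with invariant catalytic residues (Arg106, Asp166,
#' Arg169, His193), planted thermally associated sites whose warm-variant
#' probability follows a logistic curve in species mean temperature, and
#' structural features in which warm-adapted variants are more hydrophobic
#' (lower SASA/RSA, more and shorter hydrogen bonds).
#'
#' @param n_species Number of species (default 277).
#' @param temp_range Low/high bounds (deg C) for species mean habitat
#'   temperatures (default `c(-1.6, 29.5)`).
#' @param records_per_species Habitat-temperature records per species
#'   (default 500, enough for stable 1st/99th percentiles).
#' @param record_sd Within-species SD of habitat records (deg C, default 2).
#' @param alignment_length Alignment columns (default 332).
#' @param n_planted_trss Planted thermally associated sites (default 10);
#'   the first five default to the key positions 173, 174, 190, 230, 233.
#' @param n_neutral_sites Neutral polymorphic columns (default 100).
#' @param logistic_slope Per-deg-C effect of mean temperature on the
#'   warm-variant log-odds at planted sites (default 0.4).
#' @param logistic_intercept Intercept of the planted logistic curve;
#'   `NULL` centers the curve at the midpoint of `temp_range`.
#' @param effect_sizes Named shifts applied to warm-variant carriers:
#'   `hbond_n` (count), `hbond_dist` (Angstrom), `sasa` (Angstrom^2).
#' @param noise_sds Named per-feature Gaussian noise SDs.
#' @param flexibility_slope Change of delta-RMSD (nm) per deg C of species
#'   mean temperature (default -0.002, i.e. warm-adapted backbones stiffen).
#' @param delta_rmsd_intercept delta-RMSD (nm) extrapolated to 0 deg C
#'   (default 0.08).
#' @param base_sigma Stationary per-coordinate fluctuation SD (nm) of the
#'   cold (10 deg C) trajectories (default 0.1).
#' @param traj_isoforms,traj_replicates Number of isoforms (default 8) and
#'   replicate simulations per isoform and temperature (default 5).
#' @param traj_atoms Atoms per structure (default `alignment_length`, one
#'   backbone bead per residue).
#' @param traj_ns,traj_dt Trajectory length and frame spacing (ns;
#'   defaults 20 and 0.1, so the 10-20 ns window is selectable).
#' @param limit_noise_sd Noise SD (deg C) added to thermal limits in
#'   `limit_mode = "linear_features"` (default 2).
#' @param limit_mode `"percentile"` (limits are the 1st/99th percentiles
#'   of habitat records) or `"linear_features"` (limits are a fixed linear
#'   function of the planted key-site features plus noise; used for model
#'   recovery studies).
#' @param variant_pairs List of `c(cold=..., warm=...)` residue pairs for
#'   planted sites (defaults drawn from pairs observed to distinguish
#'   cold- and warm-adapted orthologs, e.g. I/L, I/M, I/V).
#' @param key_sites Alignment positions used as graph nodes downstream.
#' @param notothenioid_gap If `TRUE`, the 29 coldest species carry a
#'   deletion (gap) at column 75.
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_species = 277,
                       temp_range = c(-1.6, 29.5),
                       records_per_species = 500,
                       record_sd = 2,
                       alignment_length = 332,
                       n_planted_trss = 10,
                       n_neutral_sites = 100,
                       logistic_slope = 0.4,
                       logistic_intercept = NULL,
                       effect_sizes = c(hbond_n = 1, hbond_dist = -0.2,
                                        sasa = -20),
                       noise_sds = c(hbond_n = 0.5, hbond_dist = 0.1,
                                     sasa = 5),
                       flexibility_slope = -0.002,
                       delta_rmsd_intercept = 0.08,
                       base_sigma = 0.1,
                       traj_isoforms = 8,
                       traj_replicates = 5,
                       traj_atoms = NULL,
                       traj_ns = 20,
                       traj_dt = 0.1,
                       limit_noise_sd = 2,
                       limit_mode = c("percentile", "linear_features"),
                       variant_pairs = NULL,
                       key_sites = c(173L, 174L, 190L, 230L, 233L),
                       notothenioid_gap = FALSE,
                       seed = 1L) {
  limit_mode <- match.arg(limit_mode)
  if (n_species < 2) stop("n_species must be at least 2")
  if (temp_range[1] >= temp_range[2]) stop("temp_range low must be < high")
  if (is.null(logistic_intercept)) {
    logistic_intercept <- -logistic_slope * mean(temp_range)
  }
  if (is.null(variant_pairs)) {
    variant_pairs <- list(c(cold = "I", warm = "L"), c(cold = "I", warm = "M"),
                          c(cold = "I", warm = "V"), c(cold = "V", warm = "A"),
                          c(cold = "K", warm = "R"), c(cold = "E", warm = "M"))
  }
  if (is.null(traj_atoms)) traj_atoms <- alignment_length
  conserved <- c(106L, 166L, 169L, 193L)
  if (n_planted_trss + n_neutral_sites + length(conserved) >
      alignment_length) {
    stop("planted + neutral + conserved sites exceed the alignment length")
  }
  structure(list(
    n_species = as.integer(n_species), temp_range = temp_range,
    records_per_species = as.integer(records_per_species),
    record_sd = record_sd, alignment_length = as.integer(alignment_length),
    n_planted_trss = as.integer(n_planted_trss),
    n_neutral_sites = as.integer(n_neutral_sites),
    logistic_slope = logistic_slope, logistic_intercept = logistic_intercept,
    effect_sizes = effect_sizes, noise_sds = noise_sds,
    flexibility_slope = flexibility_slope,
    delta_rmsd_intercept = delta_rmsd_intercept, base_sigma = base_sigma,
    traj_isoforms = as.integer(traj_isoforms),
    traj_replicates = as.integer(traj_replicates),
    traj_atoms = as.integer(traj_atoms), traj_ns = traj_ns,
    traj_dt = traj_dt, limit_noise_sd = limit_noise_sd,
    limit_mode = limit_mode, variant_pairs = variant_pairs,
    key_sites = as.integer(key_sites), conserved_sites = conserved,
    notothenioid_gap = isTRUE(notothenioid_gap), seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate species and their habitat-temperature records
#'
#' Species mean temperatures are drawn uniformly on `temp_range`; each
#' species then receives `records_per_species` occurrence records whose
#' temperatures are Normal(mean, record_sd). Longitude, latitude and depth
#' are decorative but plausible (latitude anti-correlated with
#' temperature).
#'
#' @param config A [sim_config].
#' @return List: `species` (data.frame `species_id`, `mean_temp`) and
#'   `records` (data.frame `species_id`, `lon`, `lat`, `depth`,
#'   `temperature`).
#' @export
simulate_species <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_species
  ids <- sprintf("sp%03d", seq_len(n))
  means <- stats::runif(n, config$temp_range[1], config$temp_range[2])
  m <- config$records_per_species
  temps <- stats::rnorm(n * m, rep(means, each = m), config$record_sd)
  lat0 <- 70 * (1 - (rep(means, each = m) - config$temp_range[1]) /
                  diff(config$temp_range))
  records <- data.frame(
    species_id = rep(ids, each = m),
    lon = stats::runif(n * m, -180, 180),
    lat = pmax(-89, pmin(89, lat0 + stats::rnorm(n * m, 0, 3))),
    depth = stats::runif(n * m, 0, 200),
    temperature = temps,
    stringsAsFactors = FALSE)
  list(species = data.frame(species_id = ids, mean_temp = means,
                            stringsAsFactors = FALSE),
       records = records)
}

#' Simulate an aligned ortholog set with planted thermal associations
#'
#' Conserved catalytic columns are identical across species; each planted
#' column assigns its warm variant with probability
#' `plogis(intercept + slope * mean_temp)`; neutral columns assign a minor
#' variant independently of temperature (minor frequency uniform on
#' 0.05-0.5). Optionally the 29 coldest species carry a gap at column 75.
#'
#' @param config A [sim_config].
#' @param species data.frame with `species_id` and `mean_temp` (from
#'   [simulate_species]).
#' @return List: `alignment` (an `ortholog_set`) and `truth` (list of class
#'   `synthetic_truth` with `planted` data.frame (`site`, `cold`, `warm`),
#'   `neutral_sites`, `conserved_sites`, `logistic_intercept`,
#'   `logistic_slope`).
#' @export
simulate_alignment <- function(config, species) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(species)
  L <- config$alignment_length
  aas <- names(residue_categories)
  consensus <- sample(aas, L, replace = TRUE)
  conserved <- config$conserved_sites
  consensus[conserved] <- c("R", "D", "R", "H")  # Arg106 Asp166 Arg169 His193

  n_planted <- config$n_planted_trss
  planted <- integer(0)
  if (n_planted > 0) {
    planted <- config$key_sites[seq_len(min(n_planted, length(config$key_sites)))]
    extra <- n_planted - length(planted)
    if (extra > 0) {
      pool <- setdiff(seq_len(L), c(conserved, planted, 75L))
      planted <- c(planted, sample(pool, extra))
    }
  }
  pool <- setdiff(seq_len(L), c(conserved, planted, 75L))
  neutral <- if (config$n_neutral_sites > 0) {
    sample(pool, config$n_neutral_sites)
  } else integer(0)

  mat <- matrix(rep(consensus, each = n), nrow = n)
  pairs <- config$variant_pairs
  planted_df <- data.frame(site = integer(0), cold = character(0),
                           warm = character(0), stringsAsFactors = FALSE)
  for (k in seq_along(planted)) {
    pr <- pairs[[(k - 1L) %% length(pairs) + 1L]]
    p_warm <- stats::plogis(config$logistic_intercept +
                              config$logistic_slope * species$mean_temp)
    is_warm <- stats::rbinom(n, 1, p_warm) == 1L
    exp_minor <- min(sum(p_warm), sum(1 - p_warm))
    if (exp_minor < 2) {
      warning("planted site ", planted[k],
              ": expected minor-variant count below 2")
    }
    mat[, planted[k]] <- ifelse(is_warm, pr[["warm"]], pr[["cold"]])
    planted_df <- rbind(planted_df, data.frame(
      site = planted[k], cold = pr[["cold"]], warm = pr[["warm"]],
      stringsAsFactors = FALSE))
  }
  for (s in neutral) {
    maf <- stats::runif(1, 0.05, 0.5)
    alt <- sample(setdiff(aas, consensus[s]), 1)
    carrier <- stats::rbinom(n, 1, maf) == 1L
    mat[carrier, s] <- alt
  }
  if (config$notothenioid_gap) {
    coldest <- order(species$mean_temp)[seq_len(min(29L, n))]
    mat[coldest, 75L] <- "-"
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  names(seqs) <- species$species_id
  truth <- structure(list(planted = planted_df, neutral_sites = sort(neutral),
                          conserved_sites = conserved,
                          logistic_intercept = config$logistic_intercept,
                          logistic_slope = config$logistic_slope),
                     class = "synthetic_truth")
  list(alignment = ortholog_set(seqs), truth = truth)
}

#' Simulate per-species structural features at planted sites
#'
#' Each planted site receives baseline hydrogen-bond count, hydrogen-bond
#' distance and SASA values; warm-variant carriers are shifted by the
#' configured effect sizes (warm-adapted variants more hydrophobic: lower
#' SASA, more and shorter hydrogen bonds), Gaussian noise is added, counts
#' are rounded and all features clipped to their physical ranges (>= 0).
#'
#' @param config A [sim_config].
#' @param alignment The `ortholog_set` from [simulate_alignment].
#' @param truth The matching `synthetic_truth`.
#' @return data.frame: `species_id`, `site`, `residue`, `hbond_n`,
#'   `hbond_dist_A`, `sasa_A2`.
#' @export
simulate_structure_features <- function(config, alignment, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  m <- alignment_matrix(alignment)
  es <- config$effect_sizes
  ns <- config$noise_sds
  rows <- list()
  for (i in seq_len(nrow(truth$planted))) {
    site <- truth$planted$site[i]
    warm_aa <- truth$planted$warm[i]
    res <- m[, site]
    is_warm <- res == warm_aa
    n <- length(res)
    base_hn <- sample(2:5, 1)
    base_hd <- stats::runif(1, 2.8, 3.2)
    base_sa <- stats::runif(1, 60, 120)
    hn <- base_hn + es[["hbond_n"]] * is_warm + stats::rnorm(n, 0, ns[["hbond_n"]])
    hd <- base_hd + es[["hbond_dist"]] * is_warm + stats::rnorm(n, 0, ns[["hbond_dist"]])
    sa <- base_sa + es[["sasa"]] * is_warm + stats::rnorm(n, 0, ns[["sasa"]])
    rows[[i]] <- data.frame(
      species_id = rownames(m), site = site, residue = res,
      hbond_n = pmax(0, round(hn)),
      hbond_dist_A = pmax(0.1, hd),
      sasa_A2 = pmax(0, sa),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Functional variant-type flags at planted sites
#'
#' Encodes each species' variant at every planted site as +1 (warm-adapted
#' variant), -1 (cold-adapted variant) or 0 (neither / gap).
#'
#' @param alignment `ortholog_set` from [simulate_alignment].
#' @param truth Matching `synthetic_truth`.
#' @return data.frame: `species_id`, `site`, `flag`.
#' @export
variant_type_flags <- function(alignment, truth) {
  m <- alignment_matrix(alignment)
  rows <- lapply(seq_len(nrow(truth$planted)), function(i) {
    site <- truth$planted$site[i]
    res <- m[, site]
    flag <- ifelse(res == truth$planted$warm[i], 1L,
                   ifelse(res == truth$planted$cold[i], -1L, 0L))
    data.frame(species_id = rownames(m), site = site, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate paired 10/30 deg C trajectories for a set of isoforms
#'
#' Isoform mean adaptation temperatures are evenly spaced across
#' `temp_range`. Atom displacements about a fixed random reference follow a
#' stationary AR(1) process (relaxation time 1 ns) so the 10-20 ns window
#' is genuinely equilibrated; the stationary fluctuation SD at 30 deg C
#' exceeds that at 10 deg C by an amount that makes the expected delta-RMSD
#' equal `delta_rmsd_intercept + flexibility_slope * mean_temp` (floored at
#' ~0).
#'
#' @param config A [sim_config].
#' @return List of isoform entries: `isoform_id`, `mean_temp`, `cold` and
#'   `warm` (lists of `traj_replicates` [trajectory] objects at 10 and 30
#'   deg C).
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$traj_ns <= 0 || config$traj_dt <= 0) {
    stop("trajectory length and frame spacing must be positive")
  }
  set.seed(config$seed + 3L)
  n_iso <- config$traj_isoforms
  temps <- seq(config$temp_range[1], config$temp_range[2],
               length.out = n_iso)
  times <- seq(0, config$traj_ns, by = config$traj_dt)
  n_frames <- length(times)
  if (n_frames < 1) stop("nonpositive frame count")
  n_atoms <- config$traj_atoms
  phi <- exp(-config$traj_dt / 1)  # 1 ns relaxation time
  make_traj <- function(ref, sigma, temp_label) {
    d <- matrix(stats::rnorm(n_atoms * 3, 0, sigma), n_atoms, 3)
    coords <- array(0, dim = c(n_atoms, 3, n_frames))
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (f in seq_len(n_frames)) {
      coords[, , f] <- ref + d
      d <- phi * d + matrix(stats::rnorm(n_atoms * 3, 0, innov_sd),
                            n_atoms, 3)
    }
    trajectory(coords, times, temperature = temp_label)
  }
  out <- vector("list", n_iso)
  for (i in seq_len(n_iso)) {
    ref <- matrix(stats::rnorm(n_atoms * 3, 0, 1), n_atoms, 3)
    target <- max(0.002, config$delta_rmsd_intercept +
                    config$flexibility_slope * temps[i])
    sigma_cold <- config$base_sigma
    # decorrelated frames differ from the t=0 reference by ~ sigma*sqrt(6)
    sigma_warm <- sigma_cold + target / sqrt(6)
    cold <- lapply(seq_len(config$traj_replicates), function(r) {
      make_traj(ref, sigma_cold, 10)
    })
    warm <- lapply(seq_len(config$traj_replicates), function(r) {
      make_traj(ref, sigma_warm, 30)
    })
    out[[i]] <- list(isoform_id = sprintf("iso%02d", i),
                     mean_temp = temps[i], cold = cold, warm = warm)
  }
  out
}

#' Flexibility summaries for simulated isoforms
#'
#' @param traj_sets Output of [simulate_trajectories].
#' @param window Analysis window (ns).
#' @param fit Superpose before RMSD (default TRUE).
#' @return data.frame: `isoform_id`, `mean_temp`, `delta_rmsd`.
#' @export
flexibility_summaries <- function(traj_sets, window = c(10, 20), fit = TRUE) {
  rows <- lapply(traj_sets, function(ts) {
    data.frame(isoform_id = ts$isoform_id, mean_temp = ts$mean_temp,
               delta_rmsd = delta_rmsd(ts$cold, ts$warm, window = window,
                                       fit = fit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate the full synthetic dataset
#'
#' Runs every generator stage under one seeded configuration and (when
#' `outdir` is given) writes the standard file formats: aligned FASTA,
#' species-record TSV, feature TSV, variant-flag TSV, profile TSV,
#' XYZ-style trajectories and a JSON description of the planted truth.
#'
#' In `limit_mode = "linear_features"` the species thermal limits (`t99`,
#' `t01`) in the returned profiles are replaced by a fixed linear function
#' of the key-site structural features plus Gaussian noise
#' (`limit_noise_sd`), which makes the thermal-limit model's recovery
#' measurable against a known signal.
#'
#' @param config A [sim_config].
#' @param outdir Optional output directory (created if needed).
#' @param write_trajectories Also serialize trajectories (large; default
#'   FALSE when `outdir` is set).
#' @return List: `config`, `species`, `records`, `alignment`, `truth`,
#'   `features`, `flags`, `profiles`, `trajectories`, and `files` (named
#'   paths when written).
#' @export
simulate_thermal_dataset <- function(config = sim_config(), outdir = NULL,
                                     write_trajectories = FALSE) {
  sp <- simulate_species(config)
  al <- simulate_alignment(config, sp$species)
  feats <- simulate_structure_features(config, al$alignment, al$truth)
  flags <- variant_type_flags(al$alignment, al$truth)
  profiles <- species_thermal_profiles(sp$records)
  if (config$limit_mode == "linear_features") {
    profiles <- linear_feature_limits(config, feats, profiles)
  }
  trajs <- simulate_trajectories(config)
  files <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      alignment = file.path(outdir, "alignment.fasta"),
      records = file.path(outdir, "species_records.tsv"),
      features = file.path(outdir, "structure_features.tsv"),
      flags = file.path(outdir, "variant_flags.tsv"),
      profiles = file.path(outdir, "thermal_profiles.tsv"),
      truth = file.path(outdir, "truth.json"))
    write_aligned_fasta(al$alignment, files[["alignment"]])
    wtsv <- function(d, p) utils::write.table(d, p, sep = "\t",
                                              row.names = FALSE, quote = FALSE)
    wtsv(sp$records, files[["records"]])
    wtsv(feats, files[["features"]])
    wtsv(flags, files[["flags"]])
    wtsv(profiles, files[["profiles"]])
    jsonlite::write_json(
      list(planted = al$truth$planted,
           neutral_sites = al$truth$neutral_sites,
           conserved_sites = al$truth$conserved_sites,
           logistic_intercept = al$truth$logistic_intercept,
           logistic_slope = al$truth$logistic_slope,
           flexibility_slope = config$flexibility_slope,
           effect_sizes = as.list(config$effect_sizes)),
      files[["truth"]], auto_unbox = TRUE, digits = NA)
    if (write_trajectories) {
      for (ts in trajs) {
        for (side in c("cold", "warm")) {
          for (r in seq_along(ts[[side]])) {
            p <- file.path(outdir, sprintf("traj_%s_%s_rep%d.xyz",
                                           ts$isoform_id, side, r))
            write_xyz_trajectory(ts[[side]][[r]], p)
            files[[basename(p)]] <- p
          }
        }
      }
    }
  }
  list(config = config, species = sp$species, records = sp$records,
       alignment = al$alignment, truth = al$truth, features = feats,
       flags = flags, profiles = profiles, trajectories = trajs,
       files = files)
}

# Thermal limits as a fixed linear function of the key-site features plus
# noise. Each of the four structural features acts with the same weight at
# every key site (the stability physics is shared across sites): more and
# shorter hydrogen bonds and lower solvent exposure push the limits up.
linear_feature_limits <- function(config, feats, profiles) {
  set.seed(config$seed + 4L)
  key <- intersect(config$key_sites, unique(feats$site))
  if (length(key) < 2) {
    stop("limit_mode = 'linear_features' needs planted features at the key sites")
  }
  ids <- profiles$species_id
  M <- matrix(0, length(ids), 4)
  for (s in key) {
    sub <- feats[feats$site == s, , drop = FALSE]
    sub <- sub[match(ids, sub$species_id), , drop = FALSE]
    rsa <- suppressWarnings(compute_rsa(sub$sasa_A2, sub$residue))
    M <- M + cbind(sub$hbond_n, sub$hbond_dist_A, sub$sasa_A2, rsa)
  }
  M <- M / length(key)
  Mz <- scale(M)
  beta <- c(1, -1, -1.5, -1)
  raw <- drop(Mz %*% beta)
  signal <- (raw - mean(raw)) / stats::sd(raw) * 6  # 6 degC signal SD
  profiles$t99 <- 24 + signal + stats::rnorm(length(raw), 0,
                                             config$limit_noise_sd)
  profiles$t01 <- 6 + signal + stats::rnorm(length(raw), 0,
                                            config$limit_noise_sd)
  profiles
}
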
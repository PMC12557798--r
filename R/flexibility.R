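#' Construct a coordinate trajectory
#'
#' @param coords Numeric array `c(n_atoms, 3, n_frames)` in nm.
#' @param times Strictly increasing frame times (ns), length `n_frames`.
#' @param temperature Simulation temperature label (deg C).
#' @param atom_residue Integer vector mapping each atom to its residue
#'   (defaults to one residue per atom).
#' @param backbone Logical backbone mask per atom (defaults to all TRUE).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(coords, times, temperature = NA_real_,
                       atom_residue = NULL, backbone = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  n_atoms <- dim(coords)[1]
  n_frames <- dim(coords)[3]
  if (n_frames < 1L) stop("trajectory needs at least one frame")
  if (length(times) != n_frames) stop("one time per frame required")
  if (n_frames > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (is.null(atom_residue)) atom_residue <- seq_len(n_atoms)
  if (is.null(backbone)) backbone <- rep(TRUE, n_atoms)
  stopifnot(length(atom_residue) == n_atoms, length(backbone) == n_atoms)
  structure(list(coords = coords, times = as.numeric(times),
                 temperature = temperature,
                 atom_residue = as.integer(atom_residue),
                 backbone = as.logical(backbone)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[1], "atoms,", dim(x$coords)[3],
      "frames,", sprintf("%.3f-%.3f ns", min(x$times), max(x$times)),
      if (!is.na(x$temperature)) paste0("at ", x$temperature, " degC"), "\n")
  invisible(x)
}

#' Write / read a multi-frame XYZ-style text trajectory
#'
#' Plain-text format: per frame, an atom-count line, a comment line
#' `t=<ns> temperature=<degC>`, then one `name x y z` line per atom
#' (coordinates in nm). The atom-to-residue map and backbone mask travel in
#' a sidecar TSV (`atom`, `residue`, `backbone`).
#'
#' @param traj A `trajectory`.
#' @param path Trajectory text path; the residue map goes to
#'   `paste0(path, ".map.tsv")`.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  n_atoms <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n_atoms), con)
    writeLines(sprintf("t=%.6f temperature=%g", traj$times[f],
                       traj$temperature), con)
    xyz <- traj$coords[, , f, drop = FALSE]
    writeLines(sprintf("CA %.9f %.9f %.9f", xyz[, 1, 1], xyz[, 2, 1],
                       xyz[, 3, 1]), con)
  }
  utils::write.table(
    data.frame(atom = seq_len(n_atoms), residue = traj$atom_residue,
               backbone = traj$backbone),
    paste0(path, ".map.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_xyz_trajectory
#' @param path Trajectory text path written by [write_xyz_trajectory].
#' @return For `read_xyz_trajectory`, the reconstructed `trajectory`.
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  temperature <- NA_real_
  while (i <= length(lines)) {
    n_atoms <- as.integer(lines[i])
    hdr <- lines[i + 1L]
    times <- c(times, as.numeric(sub("^t=([-0-9.eE+]+).*", "\\1", hdr)))
    temperature <- as.numeric(sub(".*temperature=([-0-9.eE+]+).*", "\\1", hdr))
    block <- lines[(i + 2L):(i + 1L + n_atoms)]
    m <- do.call(rbind, lapply(strsplit(block, "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n_atoms
  }
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  map_path <- paste0(path, ".map.tsv")
  if (file.exists(map_path)) {
    mp <- utils::read.delim(map_path)
    trajectory(coords, times, temperature, mp$residue, as.logical(mp$backbone))
  } else {
    trajectory(coords, times, temperature)
  }
}

# optimal rigid-body superposition (Kabsch): rotate/translate `frame` onto
# `reference`, both n x 3
kabsch_superpose <- function(frame, reference) {
  cf <- colMeans(frame)
  cr <- colMeans(reference)
  P <- sweep(frame, 2, cf)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(P %*% t(R), 2, cr, `+`)
}

#' Root-mean-square deviation between a frame and a reference
#'
#' RMSD = sqrt((1/N) * sum_i ||r_i - r_ref,i||^2). With `fit = TRUE`
#' (default), an optimal least-squares rigid-body superposition
#' (translation + rotation, Kabsch) is applied before evaluating the
#' formula; with `fit = FALSE` the literal formula is used on the raw
#' coordinates.
#'
#' @param frame,reference Numeric n x 3 coordinate matrices (nm), matching
#'   atom counts.
#' @param fit Superpose before measuring?
#' @return RMSD in nm.
#' @export
rmsd <- function(frame, reference, fit = TRUE) {
  frame <- as.matrix(frame); reference <- as.matrix(reference)
  if (!all(dim(frame) == dim(reference))) {
    stop("atom count mismatch between frame and reference")
  }
  if (fit) frame <- kabsch_superpose(frame, reference)
  sqrt(mean(rowSums((frame - reference)^2)))
}

#' Per-frame RMSD series of a trajectory
#'
#' @param traj A `trajectory`.
#' @param reference_frame Index of the reference frame (default 1, the
#'   starting structure).
#' @param fit Superpose each frame first (default TRUE).
#' @param backbone_only Restrict to backbone atoms (default TRUE).
#' @return Numeric vector, one RMSD (nm) per frame.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, fit = TRUE,
                        backbone_only = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- if (backbone_only) traj$backbone else rep(TRUE, dim(traj$coords)[1])
  ref <- traj$coords[sel, , reference_frame]
  vapply(seq_along(traj$times), function(f) {
    rmsd(traj$coords[sel, , f], ref, fit = fit)
  }, numeric(1))
}

#' Per-residue root-mean-square fluctuation over a time window
#'
#' RMSF_i = sqrt((1/T) * sum_t ||r_t,i - r_ref,i||^2) where the reference
#' is each atom's time-average position within the window; per-atom values
#' are averaged into per-residue values via the atom-to-residue map.
#'
#' @param traj A `trajectory`.
#' @param window Length-2 numeric `c(start, end)` in ns (inclusive).
#' @param fit Superpose frames onto the first window frame before
#'   measuring fluctuations (default TRUE).
#' @return Named numeric vector of per-residue RMSF (nm).
#' @export
rmsf <- function(traj, window = c(10, 20), fit = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  idx <- which(traj$times >= window[1] & traj$times <= window[2])
  if (!length(idx)) stop("no frames inside the window")
  n_atoms <- dim(traj$coords)[1]
  frames <- lapply(idx, function(f) traj$coords[, , f])
  if (fit && length(idx) > 1L) {
    ref0 <- frames[[1]]
    frames <- c(frames[1], lapply(frames[-1], kabsch_superpose,
                                  reference = ref0))
  }
  arr <- array(unlist(frames), dim = c(n_atoms, 3, length(frames)))
  mean_pos <- apply(arr, c(1, 2), mean)
  dev2 <- vapply(seq_along(frames), function(f) {
    rowSums((arr[, , f] - mean_pos)^2)
  }, numeric(n_atoms))
  atom_rmsf <- sqrt(rowMeans(matrix(dev2, nrow = n_atoms)))
  res <- tapply(atom_rmsf, traj$atom_residue, mean)
  out <- as.numeric(res)
  names(out) <- names(res)
  out
}

#' Flexibility contrast between a cold and a warm trajectory
#'
#' Mean windowed RMSD of the warm trajectory minus that of the cold
#' trajectory. Each trajectory's RMSD is measured against its own starting
#' structure; replicate trajectories (lists) are averaged before the
#' difference is taken.
#'
#' @param traj_cold,traj_warm A `trajectory` or a list of replicate
#'   trajectories (the 10 and 30 deg C simulations).
#' @param window Analysis window in ns (default the 10-20 ns equilibrated
#'   stage).
#' @param fit Superpose before measuring (default TRUE).
#' @return delta-RMSD in nm (positive = warm more mobile).
#' @export
delta_rmsd <- function(traj_cold, traj_warm, window = c(10, 20), fit = TRUE) {
  mean_windowed <- function(tr) {
    if (inherits(tr, "trajectory")) tr <- list(tr)
    vals <- vapply(tr, function(t1) {
      idx <- which(t1$times >= window[1] & t1$times <= window[2])
      if (!length(idx)) stop("trajectory does not cover the window")
      r <- rmsd_series(t1, fit = fit)
      mean(r[idx])
    }, numeric(1))
    mean(vals)
  }
  mean_windowed(traj_warm) - mean_windowed(traj_cold)
}

#' Regression of delta-RMSD on species adaptation temperature
#'
#' Ordinary least squares of the flexibility contrast on mean habitat
#' temperature across isoforms; a negative slope indicates that backbone
#' stiffness increases with adaptation temperature.
#'
#' @param summaries data.frame with columns `mean_temp` (deg C) and
#'   `delta_rmsd` (nm), one row per isoform.
#' @return List: `slope` (nm per deg C), `intercept`, `r2`, `p` (slope
#'   t-test), `n`.
#' @export
regress_flexibility <- function(summaries) {
  stopifnot(all(c("mean_temp", "delta_rmsd") %in% names(summaries)))
  if (nrow(summaries) < 3L) stop("need at least three isoforms")
  if (stats::var(summaries$mean_temp) == 0) {
    stop("zero variance in adaptation temperature")
  }
  fit <- stats::lm(delta_rmsd ~ mean_temp, data = summaries)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = nrow(summaries))
}
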
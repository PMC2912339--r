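# Essential dynamics: the 3N x 3N positional covariance of the selected
# atoms (after iterated mean-structure superposition), its eigen-spectrum,
# per-mode variance fractions, trajectory projections on the principal
# modes, and extraction/interpolation of extreme conformers.

#' Build the positional covariance model of a trajectory
#'
#' Frames (after the equilibration drop) are superposed onto the iterated
#' mean structure of the selection, then the sample covariance
#' `C = <(r - <r>)(r - <r>)^T>` of the flattened 3N coordinate vector is
#' eigen-decomposed.  Covariance is computed on the selection only
#' (C-alpha atoms by convention for proteins).  Eigenvalues are sorted
#' descending, tiny negative round-off values (> -1e-8) are clipped to
#' zero, and each eigenvector's largest-magnitude component is made
#' positive so projections are reproducible across platforms.
#'
#' @param traj a [trajectory()].
#' @param sel a [select()] result; default all atoms.
#' @param equilibration_drop leading frames to discard (default: first 25%).
#' @return object of class `covariance_model`: `mean_coords` (n x 3),
#'   `eigenvalues` (Angstrom^2), `eigenvectors` (3n x 3n, orthonormal
#'   columns), `variance_fraction`, `n_frames`, `n_atoms`, `selection`,
#'   plus the fitted frame matrix used (`fitted_xyz`).
#' @export
build_covariance <- function(traj, sel = NULL, equilibration_drop = NULL) {
  if (is.null(sel)) sel <- select(traj$top, "resid 1-999999", label = "all")
  if (length(sel$indices) == 0) stop("build_covariance: empty selection")
  m <- n_frames(traj)
  if (is.null(equilibration_drop)) equilibration_drop <- floor(m / 4)
  keep <- seq_len(m) > equilibration_drop
  if (sum(keep) < 2) stop("build_covariance: need at least 2 retained frames")
  sub <- trajectory(traj$top, traj$xyz[keep, , drop = FALSE],
                    times = traj$times[keep])
  fit <- .iterated_mean_fit(sub, sel)
  mu <- as.numeric(t(fit$mean))
  x <- sweep(fit$xyz, 2, mu)
  mm <- nrow(x)
  cmat <- crossprod(x) / (mm - 1)
  eig <- eigen(cmat, symmetric = TRUE)
  lam <- eig$values
  if (any(lam < -1e-8))
    stop("build_covariance: covariance not PSD (eigenvalue ", min(lam), ")")
  lam[lam < 0] <- 0
  vec <- eig$vectors
  # sign convention: largest-|component| of each mode positive
  for (k in seq_len(ncol(vec))) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  vf <- if (sum(lam) > 0) lam / sum(lam) else rep(0, length(lam))
  structure(list(mean_coords = fit$mean, eigenvalues = lam,
                 eigenvectors = vec, variance_fraction = vf,
                 n_frames = mm, n_atoms = length(sel$indices),
                 selection = sel, fitted_xyz = fit$xyz,
                 equilibration_drop = equilibration_drop,
                 kept_frames = which(keep)),
            class = "covariance_model")
}

#' @export
print.covariance_model <- function(x, ...) {
  cat("covariance model: ", x$n_atoms, " atoms (3N = ", 3 * x$n_atoms,
      "), ", x$n_frames, " frames\n", sep = "")
  k <- min(5, length(x$eigenvalues))
  cat("top eigenvalues (A^2):",
      paste(signif(x$eigenvalues[1:k], 4), collapse = ", "), "\n")
  cat("variance captured by 2 modes:",
      sprintf("%.1f%%", 100 * variance_captured(x, min(2, k))), "\n")
  invisible(x)
}

#' Cumulative variance fraction captured by the top k modes
#' @param model a [build_covariance()] result.
#' @param k number of leading modes, `1 <= k <= 3N`.
#' @export
variance_captured <- function(model, k) {
  nk <- length(model$eigenvalues)
  if (k < 1 || k > nk) stop("variance_captured: k must be in [1, ", nk, "]")
  sum(model$variance_fraction[seq_len(k)])
}

#' Project a trajectory onto principal modes
#'
#' Each frame is superposed onto the model's mean structure on the model's
#' selection, then `p_k(t) = V_k . (r(t) - <r>)`.
#'
#' @param traj a [trajectory()] with the same atom order as the model's
#'   source (the model's stored selection is applied).
#' @param model a [build_covariance()] result.
#' @param modes integer vector of mode ids (default 1:2).
#' @return object of class `projection_series`: `values` (frames x k,
#'   Angstrom), `mode_ids`, `times`.
#' @export
project <- function(traj, model, modes = 1:2) {
  sel <- model$selection
  if (max(sel$indices) > traj$top$n_atoms)
    stop("project: trajectory atom count does not match the model selection")
  if (any(modes < 1 | modes > ncol(model$eigenvectors)))
    stop("project: mode id out of range")
  mu_mat <- model$mean_coords
  mu <- as.numeric(t(mu_mat))
  m <- n_frames(traj)
  vals <- matrix(NA_real_, m, length(modes))
  for (f in seq_len(m)) {
    co <- frame_coords(traj, f, sel)
    fit <- kabsch(co, mu_mat)
    d <- as.numeric(t(apply_superposition(fit, co))) - mu
    vals[f, ] <- as.numeric(d %*% model$eigenvectors[, modes, drop = FALSE])
  }
  structure(list(values = vals, mode_ids = modes, times = traj$times),
            class = "projection_series")
}

#' Extreme conformers along one principal mode
#'
#' Returns the frames attaining the minimum and maximum projection on the
#' mode, the corresponding structures superposed onto the model mean
#' (optionally averaged over the `average` frames with the most extreme
#' projections, which suppresses uncorrelated thermal jitter by
#' `sqrt(average)` at the cost of a slight shrinkage of the extreme
#' amplitude), and optionally `m_interp` structures evenly interpolated
#' from the minimum-extreme structure along the eigenvector up to the
#' maximum projection (the first interpolant equals the min-extreme
#' structure).
#'
#' @param series a [project()] result containing the mode.
#' @param traj the trajectory the series was computed from.
#' @param model the [build_covariance()] model.
#' @param mode mode id.
#' @param m_interp number of interpolated structures (0 = none).
#' @param average frames averaged per extreme (default 1 = the single
#'   extreme frame).
#' @return list: `min_frame`, `max_frame`, `min_value`, `max_value`,
#'   `min_structure`, `max_structure` (n x 3, selection atoms, in the
#'   model-mean frame), `interpolants` (a [trajectory()] on the selection
#'   atoms, or NULL).
#' @export
extreme_conformers <- function(series, traj, model, mode, m_interp = 0,
                               average = 1) {
  j <- match(mode, series$mode_ids)
  if (is.na(j)) stop("extreme_conformers: mode ", mode, " not in series")
  p <- series$values[, j]
  if (diff(range(p)) < 1e-12)
    stop("extreme_conformers: degenerate mode (constant projection)")
  imin <- which.min(p)
  imax <- which.max(p)
  sel <- model$selection
  fitted <- function(f) {
    co <- frame_coords(traj, f, sel)
    apply_superposition(kabsch(co, model$mean_coords), co)
  }
  avg_structure <- function(frames) {
    acc <- 0
    for (f in frames) acc <- acc + fitted(f)
    acc / length(frames)
  }
  k <- max(1, min(average, length(p)))
  min_structure <- avg_structure(order(p)[seq_len(k)])
  max_structure <- avg_structure(order(p, decreasing = TRUE)[seq_len(k)])
  interp <- NULL
  if (m_interp > 0) {
    x0 <- as.numeric(t(min_structure))
    v <- model$eigenvectors[, mode]
    s <- seq(0, p[imax] - p[imin], length.out = m_interp)
    frames <- t(vapply(s, function(si) x0 + si * v, numeric(length(x0))))
    sub_top <- topology(traj$top$atoms[sel$indices, , drop = FALSE])
    interp <- trajectory(sub_top, frames,
                         times = seq(0, by = 1, length.out = m_interp))
  }
  list(min_frame = imin, max_frame = imax,
       min_value = p[imin], max_value = p[imax],
       min_structure = min_structure, max_structure = max_structure,
       interpolants = interp)
}

#' Write spectrum and projections as tab-separated text
#' @param model a [build_covariance()] result.
#' @param series optional [project()] result.
#' @param dir output directory.
#' @param prefix file prefix.
#' @export
write_pca_tables <- function(model, series = NULL, dir = ".",
                             prefix = "pca") {
  spec <- data.frame(mode = seq_along(model$eigenvalues),
                     eigenvalue = model$eigenvalues,
                     variance_fraction = model$variance_fraction,
                     cumulative = cumsum(model$variance_fraction))
  f1 <- file.path(dir, paste0(prefix, "_spectrum.tsv"))
  write.table(format(spec, digits = 8), f1, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- f1
  if (!is.null(series)) {
    pj <- data.frame(time = series$times, series$values)
    names(pj) <- c("time_ps", paste0("pc", series$mode_ids))
    f2 <- file.path(dir, paste0(prefix, "_projections.tsv"))
    write.table(format(pj, digits = 8), f2, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, f2)
  }
  invisible(paths)
}
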
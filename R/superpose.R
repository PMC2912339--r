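# Least-squares superposition and fluctuation statistics: weighted Kabsch
# fits, RMSD time series against a reference frame, RMSF profiles with
# B-factors B = (8*pi^2/3) * RMSF^2 and their z-score normalization.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the weighted RMSD
#' between two matched point sets; reflection solutions are rejected by the
#' determinant correction.
#'
#' @param mobile n x 3 coordinates to be moved.
#' @param reference n x 3 target coordinates.
#' @param weights optional per-atom weights (default uniform).
#' @return list of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3; the fit is `x %*% t(R) + translation`) and
#'   `rmsd` (Angstrom).
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference) || ncol(mobile) != 3 || ncol(reference) != 3)
    stop("kabsch: point sets must be matched n x 3 matrices")
  if (n < 3) stop("kabsch: need at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  a <- sweep(mobile, 2, cm)
  b <- sweep(reference, 2, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  # collinearity: two near-zero singular values leave the rotation undefined
  if (sv$d[2] <= max(sv$d[1], 1) * 1e-12)
    stop("kabsch: degenerate (collinear) geometry")
  d <- sign(det(sv$v %*% t(sv$u)))
  r <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(r)
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  structure(list(rotation = r, translation = cr - as.numeric(r %*% cm),
                 rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition to coordinates
#' @param fit result of [kabsch()].
#' @param coords n x 3 matrix.
#' @export
apply_superposition <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' RMSD of two matched coordinate sets after optimal superposition
#' @keywords internal
.fit_rmsd <- function(a, b) kabsch(a, b)$rmsd

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is first superposed onto the reference frame on the selection,
#' then the RMSD over the selection is reported, so rigid-body motion does
#' not contribute.
#'
#' @param traj a [trajectory()].
#' @param ref_frame reference frame index (default 1, the starting
#'   structure).
#' @param sel a [select()] result (default all atoms).
#' @return numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, ref_frame = 1, sel = NULL) {
  if (is.null(sel)) sel <- select(traj$top, "resid 1-999999", label = "all")
  if (length(sel$indices) == 0) stop("rmsd_series: empty selection")
  ref <- frame_coords(traj, ref_frame, sel)
  vapply(seq_len(n_frames(traj)), function(f)
    kabsch(frame_coords(traj, f, sel), ref)$rmsd, numeric(1))
}

# Iterated mean-structure superposition: fit all frames to a running mean
# until the mean stops moving.  Returns the fitted per-frame coordinate
# matrix (M x 3n, selection atoms only) and the converged mean (n x 3).
.iterated_mean_fit <- function(traj, sel, tol = 1e-9, max_iter = 200) {
  xyz <- sel_xyz(traj, sel)
  m <- nrow(xyz)
  n <- length(sel$indices)
  as_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)
  ref <- as_mat(xyz[1, ])
  for (it in seq_len(max_iter)) {
    for (f in seq_len(m)) {
      fit <- kabsch(as_mat(xyz[f, ]), ref)
      xyz[f, ] <- as.numeric(t(apply_superposition(fit, as_mat(xyz[f, ]))))
    }
    new_mean <- as_mat(colMeans(xyz))
    shift <- sqrt(max(rowSums((new_mean - ref)^2)))
    ref <- new_mean
    if (it > 1 && shift < tol) break
  }
  list(xyz = xyz, mean = ref, iterations = it, shift = shift)
}

#' Root-mean-square fluctuations and normalized B-factors
#'
#' Frames (after discarding an equilibration prefix) are superposed to the
#' iterated mean structure on the selection; then
#' `RMSF_i = sqrt(mean(|r_i - <r_i>|^2))`, `B_i = (8*pi^2/3) * RMSF_i^2`,
#' and the normalized B is the z-score `(B - mean(B)) / sd(B)` over the
#' selection, which places profiles from different systems on one
#' dimensionless axis.
#'
#' @param traj a [trajectory()].
#' @param sel a [select()] result (default: all atoms).
#' @param equilibration_drop number of leading frames to discard; the
#'   default `NULL` drops the first 25% of frames.
#' @return data.frame of class `fluctuation_profile` with columns
#'   `resid`, `chain`, `name`, `rmsf` (Angstrom), `b` (Angstrom^2),
#'   `b_norm`.
#' @export
rmsf <- function(traj, sel = NULL, equilibration_drop = NULL) {
  if (is.null(sel)) sel <- select(traj$top, "resid 1-999999", label = "all")
  if (length(sel$indices) == 0) stop("rmsf: empty selection")
  m <- n_frames(traj)
  if (is.null(equilibration_drop)) equilibration_drop <- floor(m / 4)
  keep <- seq_len(m) > equilibration_drop
  if (sum(keep) < 2) stop("rmsf: need at least 2 retained frames")
  sub <- trajectory(traj$top, traj$xyz[keep, , drop = FALSE],
                    times = traj$times[keep])
  fit <- .iterated_mean_fit(sub, sel)
  mu <- as.numeric(t(fit$mean))
  dev2 <- sweep(fit$xyz, 2, mu)^2
  per_coord <- colMeans(dev2)
  rmsf_v <- sqrt(rowSums(matrix(per_coord, ncol = 3, byrow = TRUE)))
  b <- (8 * pi^2 / 3) * rmsf_v^2
  b_norm <- if (length(b) > 1 && sd(b) > 0) (b - mean(b)) / sd(b)
            else rep(0, length(b))
  at <- traj$top$atoms[sel$indices, ]
  out <- data.frame(resid = at$resid, chain = at$chain, name = at$name,
                    rmsf = rmsf_v, b = b, b_norm = b_norm)
  class(out) <- c("fluctuation_profile", "data.frame")
  attr(out, "mean_structure") <- fit$mean
  attr(out, "fitted_xyz") <- fit$xyz
  out
}

#' Write a fluctuation profile as tab-separated text
#' @param profile result of [rmsf()].
#' @param path output path.
#' @export
write_fluctuation_profile <- function(profile, path) {
  write.table(format(as.data.frame(profile), digits = 8), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
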
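# Quasi-rigid domain decomposition between two conformers.  A sliding
# window of residues is rigid-fit A -> B; the per-residue rotation vectors
# (axis * angle, degrees) are clustered; the largest cluster is the fixed
# domain; residues between clusters along the chain become hinge residues.
# Each moving domain's motion in the fixed domain's frame is decomposed
# into a screw: effective rotation angle, translation along the axis, and
# a % closure defined from the squared projection of the rotation axis on
# the closure axis.

# rotation matrix about unit axis by angle (degrees)
.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

# rotation matrix -> list(angle deg in [0,180], unit axis)
.rotation_axis_angle <- function(r) {
  tr <- sum(diag(r))
  ct <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(ct)
  if (angle < 1e-9) return(list(angle = 0, axis = c(0, 0, 1)))
  if (pi - angle < 1e-6) {
    # near 180 deg: axis from the symmetric part
    b <- (r + diag(3)) / 2
    j <- which.max(diag(b))
    ax <- b[, j] / sqrt(max(b[j, j], .Machine$double.eps))
  } else {
    ax <- c(r[3, 2] - r[2, 3], r[1, 3] - r[3, 1], r[2, 1] - r[1, 2]) /
      (2 * sin(angle))
  }
  list(angle = angle * 180 / pi, axis = ax / sqrt(sum(ax^2)))
}

#' Per-residue local rotation field between two conformers
#'
#' For each residue of the selection, the sliding window of `window`
#' residues centered on it (clamped at the chain ends) is rigid-fit from
#' conformer A to conformer B; the fit's rotation is reported as a rotation
#' vector (unit axis scaled by the angle in degrees).
#'
#' @param confA,confB n x 3 coordinate matrices over the same selection
#'   (one atom per residue, e.g. C-alpha).
#' @param resid residue ids of the rows (default `1:n`).
#' @param window odd window length in residues (default 5).
#' @return data.frame of class `rotation_field`: `resid`, `rx`, `ry`, `rz`,
#'   `angle` (vector magnitude, degrees).
#' @export
local_rotation_field <- function(confA, confB, resid = NULL, window = 5) {
  confA <- as.matrix(confA); confB <- as.matrix(confB)
  n <- nrow(confA)
  if (nrow(confB) != n) stop("local_rotation_field: conformer size mismatch")
  if (window %% 2 != 1) stop("local_rotation_field: window must be odd")
  if (n < window) stop("local_rotation_field: chain shorter than window")
  if (is.null(resid)) resid <- seq_len(n)
  h <- (window - 1) / 2
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    if (hi - lo + 1 < window) {        # clamp keeps the window length fixed
      if (lo == 1) hi <- window else lo <- n - window + 1
    }
    idx <- lo:hi
    fit <- kabsch(confA[idx, , drop = FALSE], confB[idx, , drop = FALSE])
    aa <- .rotation_axis_angle(fit$rotation)
    out[i, ] <- aa$axis * aa$angle
  }
  df <- data.frame(resid = resid, rx = out[, 1], ry = out[, 2], rz = out[, 3],
                   angle = sqrt(rowSums(out^2)))
  class(df) <- c("rotation_field", "data.frame")
  df
}

#' Partition residues into quasi-rigid domains from a rotation field
#'
#' Rotation vectors are clustered hierarchically with a merge radius in
#' rotation-vector space (degrees); complete linkage is the default because
#' single linkage chains the fixed and moving clusters together through the
#' intermediate rotation vectors of the hinge residues themselves whenever
#' the hinge amplitude is within a few window-lengths of the radius.
#' Clusters of at least `min_domain` residues are domains; the largest is
#' the fixed domain.  Residues in
#' sub-threshold clusters lying between two domain segments along the chain
#' are hinge residues, assigned to the adjacent moving domain (when two
#' domains abut directly, the two boundary residues are taken as the
#' hinge).
#'
#' @param field a [local_rotation_field()] result.
#' @param min_domain minimum residues per domain (default 20).
#' @param cluster_radius merge radius, degrees (default 5).
#' @param linkage hierarchical linkage: `"complete"` (default) or
#'   `"single"`.
#' @return object of class `domain_partition`: `fixed_domain` (residue
#'   ids), `moving_domains` (list of residue id vectors),
#'   `hinge_residues` (list, parallel to `moving_domains`), `cluster`
#'   (per-residue cluster id, 0 = unassigned/hinge pool).
#' @export
partition_domains <- function(field, min_domain = 20, cluster_radius = 5,
                              linkage = c("complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(field, "rotation_field"))
  v <- as.matrix(field[, c("rx", "ry", "rz")])
  n <- nrow(v)
  if (n < 2) stop("partition_domains: need at least 2 residues")
  hc <- hclust(dist(v), method = linkage)
  cl <- cutree(hc, h = cluster_radius)
  sizes <- table(cl)
  domain_ids <- as.integer(names(sizes)[sizes >= min_domain])
  if (length(domain_ids) == 0)
    stop("partition_domains: no cluster reaches min_domain = ", min_domain)
  assigned <- ifelse(cl %in% domain_ids, cl, 0L)
  fixed_id <- domain_ids[which.max(sizes[as.character(domain_ids)])]
  moving_ids <- setdiff(domain_ids, fixed_id)
  fixed <- field$resid[assigned == fixed_id]
  moving <- lapply(moving_ids, function(id) field$resid[assigned == id])
  # hinge residues: unassigned runs bordering each moving domain, plus the
  # flanking boundary residues when the transition is abrupt
  hinges <- lapply(moving_ids, function(id) {
    pos <- which(assigned == id)
    h <- integer(0)
    lo <- min(pos); hi <- max(pos)
    i <- lo - 1
    while (i >= 1 && assigned[i] == 0L) { h <- c(h, i); i <- i - 1 }
    if (i >= 1) h <- c(h, i, lo)
    i <- hi + 1
    while (i <= n && assigned[i] == 0L) { h <- c(h, i); i <- i + 1 }
    if (i <= n) h <- c(h, i, hi)
    sort(unique(field$resid[h]))
  })
  structure(list(fixed_domain = sort(fixed), moving_domains = moving,
                 hinge_residues = hinges, cluster = assigned,
                 resid = field$resid,
                 min_domain = min_domain, cluster_radius = cluster_radius),
            class = "domain_partition")
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("domain partition: fixed", length(x$fixed_domain), "residues;",
      length(x$moving_domains), "moving domain(s)\n")
  for (k in seq_along(x$moving_domains))
    cat(sprintf("  moving %d: %d residues, hinge at [%s]\n", k,
                length(x$moving_domains[[k]]),
                paste(range(x$hinge_residues[[k]]), collapse = "-")))
  invisible(x)
}

#' Hinge (screw) parameters of one moving domain between two conformers
#'
#' Conformer B is first superposed onto conformer A on the fixed domain, so
#' the moving domain's residual transform is expressed in the fixed
#' domain's frame.  That rigid transform is decomposed into a screw:
#' effective rotation angle about a unit axis through `axis_point`, and a
#' signed translation along the axis (right-hand rule orientation).
#' Closure is `100 * (n . c)^2` where `n` is the unit rotation axis and the
#' closure axis `c` is the unit vector `(g - p) x d` -- with `g` the moving
#' domain centroid, `p` its projection target on the screw axis and `d` the
#' unit fixed-to-moving centroid direction -- i.e. the axis direction that
#' maximally changes the interdomain centroid distance under an
#' infinitesimal rotation.  A pure closure rotation scores 100, a pure
#' twist about the centroid line scores 0.
#'
#' @param confA,confB n x 3 coordinates over the same selection.
#' @param partition a [partition_domains()] result.
#' @param moving moving-domain index (default 1).
#' @param resid residue ids of the rows (default `1:n`).
#' @return object of class `hinge_parameters`: `rotation_angle` (degrees,
#'   0-180), `translation` (Angstrom along the axis), `closure` (% in
#'   [0, 100], NA when the rotation is degenerate), `axis`, `axis_point`.
#' @export
hinge_parameters <- function(confA, confB, partition, moving = 1,
                             resid = NULL) {
  confA <- as.matrix(confA); confB <- as.matrix(confB)
  n <- nrow(confA)
  if (is.null(resid)) resid <- seq_len(n)
  if (moving < 1 || moving > length(partition$moving_domains))
    stop("hinge_parameters: no moving domain ", moving)
  mov_res <- partition$moving_domains[[moving]]
  if (length(mov_res) == 0) stop("hinge_parameters: empty moving domain")
  fix_idx <- which(resid %in% partition$fixed_domain)
  mov_idx <- which(resid %in% mov_res)
  # express B in the fixed domain's frame
  fitF <- kabsch(confB[fix_idx, , drop = FALSE],
                 confA[fix_idx, , drop = FALSE])
  b_al <- apply_superposition(fitF, confB)
  fitM <- kabsch(confA[mov_idx, , drop = FALSE],
                 b_al[mov_idx, , drop = FALSE])
  aa <- .rotation_axis_angle(fitM$rotation)
  if (aa$angle < 0.1) {
    return(structure(list(rotation_angle = aa$angle, translation = 0,
                          closure = NA_real_, axis = aa$axis,
                          axis_point = colMeans(confA[mov_idx, ,
                                                      drop = FALSE])),
                     class = "hinge_parameters"))
  }
  r <- fitM$rotation; tvec <- fitM$translation
  nhat <- aa$axis
  tau <- sum(tvec * nhat)                      # screw translation
  # axis point: solve (I - R) p = t_perp in the plane perpendicular to n
  t_perp <- tvec - tau * nhat
  a_mat <- diag(3) - r
  p <- tryCatch(qr.solve(a_mat + nhat %o% nhat, t_perp),
                error = function(e) rep(NA_real_, 3))
  g_fix <- colMeans(confA[fix_idx, , drop = FALSE])
  g_mov <- colMeans(confA[mov_idx, , drop = FALSE])
  d <- g_mov - g_fix
  d <- d / sqrt(sum(d^2))
  # lever arm from the axis to the moving centroid
  rvec <- g_mov - p
  rvec <- rvec - sum(rvec * nhat) * nhat
  cvec <- .cross3(rvec, d)
  closure <- if (sqrt(sum(cvec^2)) < 1e-8) {
    # degenerate lever arm: fall back to the component of n perpendicular
    # to the centroid line
    100 * (1 - sum(nhat * d)^2)
  } else {
    chat <- cvec / sqrt(sum(cvec^2))
    100 * sum(nhat * chat)^2
  }
  structure(list(rotation_angle = aa$angle, translation = tau,
                 closure = min(100, max(0, closure)),
                 axis = nhat, axis_point = as.numeric(p)),
            class = "hinge_parameters")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.hinge_parameters <- function(x, ...) {
  cat(sprintf(
    "hinge: rotation %.2f deg, translation %.2f A, closure %s%%\n",
    x$rotation_angle, x$translation,
    if (is.na(x$closure)) "NA" else sprintf("%.1f", x$closure)))
  invisible(x)
}

#' Write a hinge table mirroring the standard report layout
#' @param hinges list of [hinge_parameters()] (optionally named).
#' @param path output path.
#' @param pc principal-component label per hinge (recycled).
#' @export
write_hinge_table <- function(hinges, path, pc = 1) {
  pc <- rep(pc, length.out = length(hinges))
  df <- data.frame(
    hinge = if (is.null(names(hinges))) seq_along(hinges) else names(hinges),
    pc = pc,
    rotation_deg = vapply(hinges, `[[`, numeric(1), "rotation_angle"),
    translation_A = vapply(hinges, `[[`, numeric(1), "translation"),
    closure_pct = vapply(hinges, `[[`, numeric(1), "closure"))
  write.table(format(df, digits = 6), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
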
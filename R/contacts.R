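# Geometric interaction analyses over trajectories: hydrogen-bond distance
# series and occupancies, base-pair dihedral series, hydration sites with
# molecule-resolved residence episodes, ion coordination geometry
# (mean +/- sd distances, triad angles, planarity), and channel metrics
# (interdomain centroid distance, projected entrance area).

.pair_dist_series <- function(traj, i, j) {
  ci <- .xyz_cols(i); cj <- .xyz_cols(j)
  d <- traj$xyz[, ci, drop = FALSE] - traj$xyz[, cj, drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Scan donor/acceptor pairs for hydrogen bonds
#'
#' Every donor-acceptor pair that comes within `d_cut` in at least one
#' frame yields a full per-frame series.  The default `distance-only` mode
#' uses the heavy-atom distance criterion; `distance+angle` additionally
#' requires a donor-H-acceptor angle of at least `angle_cut` degrees, with
#' donor hydrogens located automatically (atoms named `H*`/element H in the
#' same residue within 1.3 Angstrom of the donor in the first frame).
#'
#' @param traj a [trajectory()].
#' @param donors,acceptors [select()] results (heavy atoms).
#' @param mode `"distance-only"` or `"distance+angle"`.
#' @param d_cut heavy-atom distance cutoff, Angstrom (default 3.5; 3.0 is
#'   the stricter convention used for seed base pairs).
#' @param angle_cut donor-H-acceptor angle cutoff, degrees (default 120).
#' @return list of `hbond_series`: `donor`, `acceptor` (atom indices),
#'   `distance` (per frame, Angstrom), `bonded` (logical per frame),
#'   `occupancy` (fraction of frames).
#' @export
hbond_scan <- function(traj, donors, acceptors,
                       mode = c("distance-only", "distance+angle"),
                       d_cut = 3.5, angle_cut = 120) {
  mode <- match.arg(mode)
  if (length(donors$indices) == 0 || length(acceptors$indices) == 0)
    stop("hbond_scan: empty donor or acceptor selection")
  out <- list()
  at <- traj$top$atoms
  f1 <- frame_coords(traj, 1)
  hyd_of <- NULL
  if (mode == "distance+angle") {
    is_h <- toupper(substr(trimws(at$element), 1, 1)) == "H"
    hyd_of <- lapply(donors$indices, function(i) {
      cand <- which(is_h & at$resid == at$resid[i] & at$chain == at$chain[i])
      if (length(cand) == 0) return(integer(0))
      dd <- sqrt(rowSums(sweep(f1[cand, , drop = FALSE], 2, f1[i, ])^2))
      cand[dd <= 1.3]
    })
  }
  for (a in seq_along(donors$indices)) {
    i <- donors$indices[a]
    for (b in seq_along(acceptors$indices)) {
      j <- acceptors$indices[b]
      if (i == j) next
      d <- .pair_dist_series(traj, i, j)
      if (!any(d <= d_cut)) next
      bonded <- d <= d_cut
      if (mode == "distance+angle") {
        hs <- hyd_of[[a]]
        if (length(hs) == 0) { bonded[] <- FALSE } else {
          ang_ok <- rep(FALSE, n_frames(traj))
          for (f in which(bonded)) {
            co <- frame_coords(traj, f)
            best <- max(vapply(hs, function(h) {
              v1 <- co[i, ] - co[h, ]; v2 <- co[j, ] - co[h, ]
              ct <- sum(v1 * v2) /
                sqrt(sum(v1^2) * sum(v2^2))
              acos(max(-1, min(1, ct))) * 180 / pi
            }, numeric(1)))
            ang_ok[f] <- best >= angle_cut
          }
          bonded <- bonded & ang_ok
        }
      }
      out[[length(out) + 1L]] <- structure(
        list(donor = i, acceptor = j,
             donor_label = sprintf("%s%d:%s", at$resname[i], at$resid[i],
                                   at$name[i]),
             acceptor_label = sprintf("%s%d:%s", at$resname[j], at$resid[j],
                                      at$name[j]),
             distance = d, bonded = bonded, occupancy = mean(bonded)),
        class = "hbond_series")
    }
  }
  out
}

#' Signed dihedral angle series of four atoms
#'
#' Standard torsion about the a2-a3 axis, reported in degrees in
#' (-180, 180].  Frames whose middle bond is collinear with either flank
#' (undefined torsion) are reported as `NA`.
#'
#' @param traj a [trajectory()].
#' @param a1,a2,a3,a4 distinct atom indices.
#' @return numeric vector (degrees) per frame.
#' @export
pair_dihedral <- function(traj, a1, a2, a3, a4) {
  ids <- c(a1, a2, a3, a4)
  if (anyDuplicated(ids)) stop("pair_dihedral: atoms must be distinct")
  m <- n_frames(traj)
  out <- numeric(m)
  for (f in seq_len(m)) {
    co <- frame_coords(traj, f)
    b1 <- co[a2, ] - co[a1, ]
    b2 <- co[a3, ] - co[a2, ]
    b3 <- co[a4, ] - co[a3, ]
    n1 <- .cross3(b1, b2)
    n2 <- .cross3(b2, b3)
    if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
      out[f] <- NA_real_
      next
    }
    b2h <- b2 / sqrt(sum(b2^2))
    x <- sum(n1 * n2)
    y <- sum(.cross3(n1, n2) * b2h)
    ang <- atan2(y, x) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    out[f] <- ang
  }
  out
}

#' Hydration sites from time-averaged water density
#'
#' Water-oxygen positions inside the region (a sphere of `region_radius`
#' around `region_center`, or around the centroid of a selection) are
#' histogrammed on a cubic grid.  Grid voxels whose occupancy (fraction of
#' frames with a water oxygen inside) exceeds `occ_threshold` become
#' candidate sites; local maxima are merged within `merge_radius`.  Each
#' site's occupancy is then re-measured as the fraction of frames with any
#' water oxygen within `merge_radius` of the site centroid, and residence
#' episodes track each individual water molecule's continuous presence,
#' tolerating absences of up to `gap_tolerance` frames.
#'
#' @param traj a [trajectory()] whose topology labels water (`molecule ==
#'   "water"`); oxygen atoms are rows whose element is O (or all water
#'   atoms when the model is oxygen-only).
#' @param region_center length-3 point or a [select()] result.
#' @param region_radius Angstrom (default 8).
#' @param grid grid spacing, Angstrom (default 1.0).
#' @param occ_threshold occupancy threshold (default 0.40).
#' @param merge_radius site merge radius, Angstrom (default 1.5).
#' @param gap_tolerance frames an episode may skip (default 2).
#' @return list of `hydration_site`: `centroid`, `occupancy`,
#'   `residence_episodes` (data.frame water/start_ps/end_ps),
#'   `longest_residence_ns`.
#' @export
hydration_sites <- function(traj, region_center, region_radius = 8,
                            grid = 1.0, occ_threshold = 0.40,
                            merge_radius = 1.5, gap_tolerance = 2) {
  at <- traj$top$atoms
  wat <- which(at$molecule == "water")
  if (length(wat) == 0) stop("hydration_sites: no water in topology")
  wox <- wat[toupper(substr(trimws(at$element[wat]), 1, 1)) == "O"]
  if (length(wox) == 0) wox <- wat
  if (inherits(region_center, "selection")) {
    region_center <- colMeans(frame_coords(traj, 1, region_center))
  }
  region_center <- as.numeric(region_center)
  m <- n_frames(traj)
  # voxel occupancy: fraction of frames with any water O in the voxel
  voxel_frames <- new.env(parent = emptyenv())
  for (f in seq_len(m)) {
    co <- frame_coords(traj, f)[wox, , drop = FALSE]
    d <- sqrt(rowSums(sweep(co, 2, region_center)^2))
    inside <- which(d <= region_radius)
    if (length(inside) == 0) next
    keys <- unique(apply(floor(sweep(co[inside, , drop = FALSE], 2,
                                     region_center - region_radius) / grid),
                         1, paste, collapse = ","))
    for (k in keys) {
      prev <- voxel_frames[[k]]
      voxel_frames[[k]] <- if (is.null(prev)) 1L else prev + 1L
    }
  }
  keys <- ls(voxel_frames)
  if (length(keys) == 0) return(list())
  occ <- vapply(keys, function(k) voxel_frames[[k]] / m, numeric(1))
  hot <- keys[occ > occ_threshold]
  if (length(hot) == 0) return(list())
  centers <- t(vapply(strsplit(hot, ","), function(v)
    (as.numeric(v) + 0.5) * grid + region_center - region_radius,
    numeric(3)))
  occ_hot <- occ[match(hot, keys)]
  # merge voxels within merge_radius, highest occupancy first
  ord <- order(-occ_hot)
  site_centers <- list()
  for (k in ord) {
    p <- centers[k, ]
    if (length(site_centers) > 0) {
      dd <- vapply(site_centers, function(s) sqrt(sum((s - p)^2)),
                   numeric(1))
      if (any(dd < merge_radius)) next
    }
    site_centers[[length(site_centers) + 1L]] <- p
  }
  lapply(site_centers, function(ctr) {
    # per-frame, per-molecule presence within merge_radius of the centroid
    present <- matrix(FALSE, m, length(wox))
    for (f in seq_len(m)) {
      co <- frame_coords(traj, f)[wox, , drop = FALSE]
      present[f, ] <- sqrt(rowSums(sweep(co, 2, ctr)^2)) <= merge_radius
    }
    episodes <- do.call(rbind, lapply(seq_along(wox), function(w) {
      .residence_episodes(present[, w], traj$times, gap_tolerance, wox[w])
    }))
    if (is.null(episodes))
      episodes <- data.frame(water = integer(0), start_ps = numeric(0),
                             end_ps = numeric(0))
    episodes <- episodes[order(episodes$start_ps), , drop = FALSE]
    longest <- if (nrow(episodes) > 0)
      max(episodes$end_ps - episodes$start_ps) / 1000 else 0
    structure(list(centroid = ctr, occupancy = mean(rowSums(present) > 0),
                   residence_episodes = episodes,
                   longest_residence_ns = longest),
              class = "hydration_site")
  })
}

# contiguous TRUE runs, merging gaps <= gap_tolerance frames
.residence_episodes <- function(present, times, gap_tolerance, water_id) {
  idx <- which(present)
  if (length(idx) == 0) return(NULL)
  gaps <- c(0, diff(idx))
  ep_id <- cumsum(gaps > gap_tolerance + 1)
  do.call(rbind, lapply(split(idx, ep_id), function(ii)
    data.frame(water = water_id, start_ps = times[min(ii)],
               end_ps = times[max(ii)])))
}

#' Coordination geometry of a center atom
#'
#' For every partner atom within `cutoff` of the center in at least one
#' frame: the mean and standard deviation of the center-partner distance
#' over frames.  Partner-center-partner angles are computed per frame
#' between consecutive partners (ordered by azimuth in the partners'
#' best-fit plane) and averaged, so a planar N-coordination sums to about
#' 360 degrees.  `out_of_plane` is the center's mean distance from the
#' best-fit plane of the coordinating atoms.
#'
#' @param traj a [trajectory()].
#' @param center atom index.
#' @param partners a [select()] result.
#' @param cutoff Angstrom (default 3.0).
#' @return object of class `coordination_report`: `pairs` (data.frame
#'   partner/label/mean_A/sd_A), `angles` (data.frame with mean per
#'   consecutive pair), `angle_sum` (degrees), `out_of_plane` (Angstrom).
#' @export
coordination_geometry <- function(traj, center, partners, cutoff = 3.0) {
  at <- traj$top$atoms
  part <- setdiff(partners$indices, center)
  if (length(part) == 0) stop("coordination_geometry: no partner atoms")
  dmat <- vapply(part, function(j) .pair_dist_series(traj, center, j),
                 numeric(n_frames(traj)))
  dmat <- matrix(dmat, nrow = n_frames(traj))
  keep <- which(apply(dmat, 2, function(d) any(d <= cutoff)))
  if (length(keep) == 0)
    stop("coordination_geometry: no partner ever within cutoff = ", cutoff)
  part <- part[keep]
  dmat <- dmat[, keep, drop = FALSE]
  pairs <- data.frame(
    partner = part,
    label = sprintf("%s%d %s", at$resname[part], at$resid[part],
                    at$name[part]),
    mean_A = colMeans(dmat),
    sd_A = apply(dmat, 2, function(d) if (length(d) > 1) sd(d) else 0))
  np <- length(part)
  angle_sum_f <- numeric(n_frames(traj))
  oop_f <- numeric(n_frames(traj))
  angle_acc <- NULL
  for (f in seq_len(n_frames(traj))) {
    co <- frame_coords(traj, f)
    ctr <- co[center, ]
    pp <- co[part, , drop = FALSE]
    pc <- sweep(pp, 2, colMeans(pp))
    sv <- svd(pc)
    normal <- sv$v[, 3]
    oop_f[f] <- abs(sum((ctr - colMeans(pp)) * normal))
    if (np >= 2) {
      e1 <- sv$v[, 1]; e2 <- sv$v[, 2]
      az <- atan2(pc %*% e2, pc %*% e1)
      ordp <- order(az)
      vecs <- sweep(pp, 2, ctr)
      ang <- vapply(seq_len(np), function(k) {
        a <- vecs[ordp[k], ]; b <- vecs[ordp[k %% np + 1], ]
        ct <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
        acos(max(-1, min(1, ct))) * 180 / pi
      }, numeric(1))
      if (np == 2) ang <- ang[1]
      angle_sum_f[f] <- sum(ang)
      if (is.null(angle_acc)) angle_acc <- 0
      angle_acc <- angle_acc + ang
    }
  }
  angles <- if (!is.null(angle_acc))
    data.frame(angle = paste0("a", seq_along(angle_acc)),
               mean_deg = angle_acc / n_frames(traj))
  else data.frame(angle = character(0), mean_deg = numeric(0))
  structure(list(pairs = pairs, angles = angles,
                 angle_sum = mean(angle_sum_f),
                 out_of_plane = mean(oop_f)),
            class = "coordination_report")
}

#' @export
print.coordination_report <- function(x, ...) {
  cat("coordination report:", nrow(x$pairs), "partners\n")
  print(x$pairs, row.names = FALSE)
  cat(sprintf("angle sum %.1f deg, out-of-plane %.2f A\n",
              x$angle_sum, x$out_of_plane))
  invisible(x)
}

#' Channel metrics: centroid separation and projected entrance area
#'
#' `centroid_distance` is the distance between the geometric centers of two
#' selections.  `entrance_area` is the area of the 2-D convex hull of the
#' entrance atoms projected onto the plane perpendicular to the channel
#' axis (by default the centroid(A) to centroid(B) direction).
#'
#' @param traj a [trajectory()].
#' @param frame frame index.
#' @param set_a,set_b,entrance [select()] results.
#' @param axis `"auto"` or an explicit length-3 vector.
#' @return list of class `channel_metrics`: `centroid_distance` (Angstrom),
#'   `entrance_area` (Angstrom^2).
#' @export
channel_metrics <- function(traj, frame = 1, set_a, set_b, entrance,
                            axis = "auto") {
  if (length(set_a$indices) == 0 || length(set_b$indices) == 0)
    stop("channel_metrics: empty selection")
  co <- frame_coords(traj, frame)
  ca <- colMeans(co[set_a$indices, , drop = FALSE])
  cb <- colMeans(co[set_b$indices, , drop = FALSE])
  cd <- sqrt(sum((ca - cb)^2))
  if (length(entrance$indices) < 3)
    stop("channel_metrics: need at least 3 entrance atoms for an area")
  ax <- if (identical(axis, "auto")) cb - ca else as.numeric(axis)
  if (sqrt(sum(ax^2)) < 1e-10)
    stop("channel_metrics: degenerate channel axis")
  ax <- ax / sqrt(sum(ax^2))
  # orthonormal in-plane basis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .cross3(ax, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(ax, e1)
  pts <- co[entrance$indices, , drop = FALSE]
  uv <- cbind(pts %*% e1, pts %*% e2)
  hull <- chull(uv)
  hx <- uv[hull, 1]; hy <- uv[hull, 2]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  structure(list(centroid_distance = cd, entrance_area = area),
            class = "channel_metrics")
}
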
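# Seeded generators producing trajectories and complexes with planted
# ground truth: a two-lobe C-alpha chain hinging about a known axis, an
# atom pair switching between bonded/unbonded distances on a schedule
# (with an optional scheduled water site), and randomly packed charged
# complexes whose reference interface energies are computed by an
# independent double loop and shipped in the manifest.  Every generator is
# a pure function of its spec + seed.

#' Specification for a planted two-domain hinge fixture
#'
#' @param n_fixed,n_moving residues per lobe (>= 20 each by default
#'   convention for domain detection).
#' @param pivot_residue hinge residue id (default `n_fixed`).
#' @param axis rotation axis (normalized internally).
#' @param amplitude hinge amplitude, degrees in (0, 180).
#' @param motion `"sinusoid"` or `"two-state"`.
#' @param noise_sigma isotropic Gaussian jitter per coordinate, Angstrom.
#' @param n_frames frame count.
#' @param seed RNG seed (mandatory).
#' @export
hinge_spec <- function(n_fixed = 100, n_moving = 80, pivot_residue = NULL,
                       axis = c(0, 0, 1), amplitude = 25,
                       motion = c("sinusoid", "two-state"),
                       noise_sigma = 0, n_frames = 200, seed = 1) {
  motion <- match.arg(motion)
  if (amplitude <= 0 || amplitude >= 180)
    stop("hinge_spec: amplitude must be in (0, 180)")
  if (noise_sigma < 0) stop("hinge_spec: noise_sigma must be >= 0")
  if (is.null(pivot_residue)) pivot_residue <- n_fixed
  structure(list(n_fixed = n_fixed, n_moving = n_moving,
                 pivot_residue = pivot_residue,
                 axis = axis / sqrt(sum(axis^2)), amplitude = amplitude,
                 motion = motion, noise_sigma = noise_sigma,
                 n_frames = n_frames, seed = seed),
            class = "hinge_spec")
}

# compact random lobe: points uniform in a ball, ordered along x for a
# vaguely chain-like progression
.random_lobe <- function(n, radius, center) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  while (got < n) {
    cand <- matrix(runif(3 * (n - got), -radius, radius), ncol = 3)
    keep <- rowSums(cand^2) <= radius^2
    take <- cand[keep, , drop = FALSE]
    if (nrow(take) > 0) {
      pts[(got + 1):(got + nrow(take)), ] <- take
      got <- got + nrow(take)
    }
  }
  pts <- pts[order(pts[, 1]), , drop = FALSE]
  sweep(pts, 2, center, "+")
}

#' Build the two-domain C-alpha chain of a hinge fixture
#'
#' Two compact lobes (uniform-ball point clouds) joined at the pivot
#' residue, separated along x by three lobe radii so the centroid
#' separation safely exceeds twice the lobe radius of gyration.
#' Reproducible under the spec's seed.
#'
#' @param spec a [hinge_spec()].
#' @return list: `top` (a [topology()]) and `ref` (N x 3 reference
#'   coordinates).
#' @export
make_two_domain_chain <- function(spec) {
  if (spec$n_fixed < 20 || spec$n_moving < 20)
    stop("make_two_domain_chain: lobes need >= 20 residues")
  n <- spec$n_fixed + spec$n_moving
  radius <- 2.2 * n^(1/3)                    # loose packing, protein-like
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  lobe_f <- .random_lobe(spec$n_fixed, radius, c(0, 0, 0))
  lobe_m <- .random_lobe(spec$n_moving, radius, c(3 * radius, 0, 0))
  ref <- rbind(lobe_f, lobe_m)
  top <- topology(data.frame(
    serial = seq_len(n), name = "CA", resname = "ALA", resid = seq_len(n),
    chain = "A", element = "C", molecule = "protein", mass = 12.011))
  list(top = top, ref = ref)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a hinge trajectory with planted rotation
#'
#' The moving lobe is rotated about the planted axis through the pivot
#' residue by a scheduled angle per frame (`sinusoid`: `amplitude/2 *
#' (1 - cos)` sweeping 0 to `amplitude`; `two-state`: alternating halves at
#' 0 and `amplitude`), then isotropic Gaussian jitter of `noise_sigma` per
#' coordinate is added.  The planted parameters are recorded in
#' `attr(, "manifest")`.
#'
#' @param chain result of [make_two_domain_chain()].
#' @param spec the same [hinge_spec()].
#' @return a [trajectory()] with a `manifest` attribute.
#' @export
make_hinge_trajectory <- function(chain, spec) {
  n <- spec$n_fixed + spec$n_moving
  pivot_xyz <- chain$ref[spec$pivot_residue, ]
  mov <- which(seq_len(n) > spec$n_fixed)
  ang <- switch(spec$motion,
    "sinusoid" = spec$amplitude / 2 *
      (1 - cos(2 * pi * (seq_len(spec$n_frames) - 1) /
               max(1, spec$n_frames - 1))),
    "two-state" = ifelse(seq_len(spec$n_frames) %%
                           2 == 0, spec$amplitude, 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed + 1)
  frames <- matrix(NA_real_, spec$n_frames, 3 * n)
  for (f in seq_len(spec$n_frames)) {
    co <- chain$ref
    r <- .rotation_matrix(spec$axis, ang[f])
    co[mov, ] <- sweep(sweep(co[mov, , drop = FALSE], 2, pivot_xyz) %*%
                         t(r), 2, pivot_xyz, "+")
    if (spec$noise_sigma > 0)
      co <- co + matrix(rnorm(3 * n, sd = spec$noise_sigma), n, 3)
    frames[f, ] <- as.numeric(t(co))
  }
  traj <- trajectory(chain$top, frames)
  attr(traj, "manifest") <- c(unclass(spec),
                              list(schedule_deg = ang,
                                   pivot_xyz = pivot_xyz,
                                   moving_residues = mov))
  traj
}

#' Specification for a scheduled-occupancy fixture
#'
#' @param schedule per-frame logical vector, or a single Bernoulli
#'   probability in [0, 1] drawn per frame.
#' @param n_frames frame count (ignored when `schedule` is a vector).
#' @param seed RNG seed.
#' @export
occupancy_spec <- function(schedule = 0.5, n_frames = 200, seed = 1) {
  if (is.numeric(schedule) && length(schedule) == 1) {
    if (schedule < 0 || schedule > 1)
      stop("occupancy_spec: Bernoulli p must be in [0, 1]")
  } else if (!is.logical(schedule))
    stop("occupancy_spec: schedule must be a probability or logical vector")
  structure(list(schedule = schedule, n_frames = n_frames, seed = seed),
            class = "occupancy_spec")
}

#' Generate an interaction trajectory with a scheduled H-bond and water
#'
#' A donor/acceptor atom pair sits at the bonded distance (2.8 A) in
#' frames scheduled "on" and at 6.0 A otherwise.  A water oxygen is placed
#' inside a site 10 A away on the same schedule (and parked 30 A away when
#' "off"), giving hydration-site analyses a molecule-resolved ground
#' truth.  The realized schedule is recorded in `attr(, "manifest")`.
#'
#' @param spec an [occupancy_spec()].
#' @param bonded_distance,unbonded_distance Angstrom (defaults 2.8 / 6.0).
#' @return a [trajectory()] of 4 atoms (donor, acceptor, water O, anchor)
#'   with a `manifest` attribute.
#' @export
make_interaction_trajectory <- function(spec, bonded_distance = 2.8,
                                        unbonded_distance = 6.0) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  on_sched <- if (is.logical(spec$schedule)) spec$schedule
              else runif(spec$n_frames) < spec$schedule
  m <- length(on_sched)
  top <- topology(data.frame(
    serial = 1:4,
    name = c("OD1", "N1", "OW", "CA"),
    resname = c("ASP", "ADE", "HOH", "ALA"),
    resid = c(1L, 2L, 3L, 4L),
    chain = c("A", "B", "W", "A"),
    element = c("O", "N", "O", "C"),
    molecule = c("protein", "guide-RNA", "water", "protein"),
    mass = c(15.999, 14.007, 15.999, 12.011)))
  site <- c(10, 0, 0)
  frames <- matrix(NA_real_, m, 12)
  for (f in seq_len(m)) {
    d <- if (on_sched[f]) bonded_distance else unbonded_distance
    wat <- if (on_sched[f]) site else c(30, 30, 30)
    co <- rbind(c(0, 0, 0), c(d, 0, 0), wat, c(0, 5, 0))
    frames[f, ] <- as.numeric(t(co))
  }
  traj <- trajectory(top, frames)
  attr(traj, "manifest") <- list(schedule = on_sched,
                                 occupancy = mean(on_sched),
                                 bonded_distance = bonded_distance,
                                 unbonded_distance = unbonded_distance,
                                 site_center = site, seed = spec$seed)
  traj
}

#' Generate a randomly packed charged receptor-ligand complex
#'
#' Receptor atoms are packed (rejection sampling, minimum separation
#' 2.5 A) in a ball at the origin and ligand atoms in a displaced ball;
#' charges follow the charge plan, and every atom gets generic
#' Lennard-Jones, Born and van der Waals parameters.  The manifest carries
#' brute-force double-loop reference energies (interface Coulomb and
#' Lennard-Jones) computed independently of the energetics module.
#'
#' @param n_receptor_atoms,n_ligand_atoms atom counts (>= 1).
#' @param charge_plan `"alternating"` (+1/-1), `"zero"`, or a numeric
#'   vector of length `n_receptor_atoms + n_ligand_atoms`.
#' @param seed RNG seed.
#' @param separation centroid separation of the two balls, Angstrom.
#' @return list: `top` (parameterized [topology()]), `coords` (N x 3),
#'   `receptor`/`ligand` ([select()] results), `manifest` with
#'   `ref_coulomb` and `ref_lj` (kcal/mol).
#' @export
make_charged_complex <- function(n_receptor_atoms = 10, n_ligand_atoms = 5,
                                 charge_plan = "alternating", seed = 1,
                                 separation = 12) {
  if (n_receptor_atoms < 1 || n_ligand_atoms < 1)
    stop("make_charged_complex: counts must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pack <- function(n, center, radius, avoid = NULL) {
    pts <- matrix(NA_real_, n, 3)
    got <- 0
    tries <- 0
    while (got < n) {
      tries <- tries + 1
      if (tries > 20000)
        stop("make_charged_complex: packing failed, box too tight")
      p <- runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      p <- p + center
      taken <- rbind(avoid, pts[seq_len(got), , drop = FALSE])
      if (!is.null(taken) && nrow(taken) > 0) {
        dmin <- min(sqrt(rowSums(sweep(taken, 2, p)^2)))
        if (dmin < 2.5) next
      }
      got <- got + 1
      pts[got, ] <- p
    }
    pts
  }
  n <- n_receptor_atoms + n_ligand_atoms
  radius <- max(4, 2.0 * n^(1/3) + 2)
  rec <- pack(n_receptor_atoms, c(0, 0, 0), radius)
  lig <- pack(n_ligand_atoms, c(separation, 0, 0), radius, avoid = rec)
  coords <- rbind(rec, lig)
  q <- if (identical(charge_plan, "alternating"))
    rep_len(c(1, -1), n)
  else if (identical(charge_plan, "zero")) rep(0, n)
  else if (is.numeric(charge_plan) && length(charge_plan) == n)
    charge_plan
  else stop("make_charged_complex: bad charge plan")
  top <- topology(data.frame(
    serial = seq_len(n), name = "DU",
    resname = ifelse(seq_len(n) <= n_receptor_atoms, "REC", "LIG"),
    resid = seq_len(n), chain = ifelse(seq_len(n) <= n_receptor_atoms,
                                       "R", "L"),
    element = "C",
    molecule = ifelse(seq_len(n) <= n_receptor_atoms, "protein",
                      "guide-RNA"),
    charge = q, lj_sigma = 3.4, lj_epsilon = 0.1, born_radius = 1.7,
    vdw_radius = 1.7, mass = 12.011))
  # independent brute-force reference energies (plain double loop)
  ref_c <- 0; ref_lj <- 0
  for (i in seq_len(n_receptor_atoms)) {
    for (j in (n_receptor_atoms + 1):n) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      ref_c <- ref_c + 332.0636 * q[i] * q[j] / r
      sij <- (3.4 + 3.4) / 2
      eij <- sqrt(0.1 * 0.1)
      ref_lj <- ref_lj + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  rec_sel <- structure(list(indices = seq_len(n_receptor_atoms),
                            label = "receptor"), class = "selection")
  lig_sel <- structure(list(indices = (n_receptor_atoms + 1):n,
                            label = "ligand"), class = "selection")
  list(top = top, coords = coords, receptor = rec_sel, ligand = lig_sel,
       manifest = list(seed = seed, ref_coulomb = ref_c, ref_lj = ref_lj,
                       charges = q))
}

#' Write a generator manifest as structured text (YAML)
#' @param manifest list (e.g. `attr(traj, "manifest")`).
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(lapply(manifest, function(x)
    if (is.matrix(x)) as.data.frame(x) else x), path)
  invisible(path)
}

#' Read back a generator manifest
#' @param path manifest path.
#' @export
read_manifest <- function(path) yaml::read_yaml(path)
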
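# End-state binding thermodynamics: pairwise interface Coulomb and
# Lennard-Jones energies (no cutoff), Shrake-Rupley solvent-accessible
# surface area with a deterministic sphere lattice, the linear nonpolar
# solvation term gamma*SASA + beta, a generalized-Born polar term with
# pairwise-descreening effective radii, the single-trajectory MM-GBSA
# ledger (ele / vdw / np / polar / ele+polar / dH / TdS / dG_bind), and
# per-residue decomposition of the interface energy.

#' Nonpolar solvation parameters
#'
#' The linear SASA model `G_np = gamma * SASA + beta` with the conventional
#' parametrization gamma = 0.00542 kcal/(A^2 mol), beta = 0.92 kcal/mol and
#' a 1.4 A solvent probe.
#'
#' @param gamma surface tension coefficient, kcal/(A^2 mol).
#' @param beta intercept, kcal/mol.
#' @param probe probe radius, Angstrom.
#' @export
nonpolar_params <- function(gamma = 0.00542, beta = 0.92, probe = 1.4) {
  if (gamma <= 0 || probe <= 0)
    stop("nonpolar_params: gamma and probe must be positive")
  structure(list(gamma = gamma, beta = beta, probe = probe),
            class = "nonpolar_params")
}

.check_params <- function(top, cols, what) {
  for (col in cols)
    if (any(is.na(top$atoms[[col]])))
      stop(what, ": parameter '", col, "' missing for atoms ",
           paste(head(top$atoms$serial[is.na(top$atoms[[col]])], 5),
                 collapse = ", "))
}

.pair_r <- function(coords, ia, ib) {
  # |ia| x |ib| distance matrix
  a <- coords[ia, , drop = FALSE]
  b <- coords[ib, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Interface Coulomb energy between two atom sets
#'
#' `sum_{i in A, j in B} k q_i q_j / (eps * r_ij)` with
#' k = 332.0636 kcal A/(mol e^2) and no distance cutoff.
#'
#' @param top parameterized [topology()] (charges assigned).
#' @param coords N x 3 frame coordinates.
#' @param set_a,set_b disjoint [select()] results.
#' @param eps_interior interior dielectric constant (default 1).
#' @return energy in kcal/mol.
#' @export
coulomb_interface <- function(top, coords, set_a, set_b, eps_interior = 1) {
  if (length(intersect(set_a$indices, set_b$indices)) > 0)
    stop("coulomb_interface: sets must be disjoint")
  .check_params(top, "charge", "coulomb_interface")
  r <- .pair_r(coords, set_a$indices, set_b$indices)
  if (any(r < 1e-3))
    stop("coulomb_interface: overlapping atoms (r < 1e-3 A)")
  q <- top$atoms$charge
  qq <- outer(q[set_a$indices], q[set_b$indices])
  sum(.COULOMB_K * qq / (eps_interior * r))
}

#' Interface Lennard-Jones energy between two atom sets
#'
#' 12-6 potential `sum 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]` with
#' Lorentz-Berthelot combining (arithmetic sigma, geometric epsilon) and no
#' cutoff.
#'
#' @inheritParams coulomb_interface
#' @return energy in kcal/mol.
#' @export
lj_interface <- function(top, coords, set_a, set_b) {
  if (length(intersect(set_a$indices, set_b$indices)) > 0)
    stop("lj_interface: sets must be disjoint")
  .check_params(top, c("lj_sigma", "lj_epsilon"), "lj_interface")
  r <- .pair_r(coords, set_a$indices, set_b$indices)
  if (any(r < 1e-3))
    stop("lj_interface: overlapping atoms (r < 1e-3 A)")
  at <- top$atoms
  sig <- outer(at$lj_sigma[set_a$indices], at$lj_sigma[set_b$indices],
               "+") / 2
  eps <- sqrt(outer(at$lj_epsilon[set_a$indices],
                    at$lj_epsilon[set_b$indices]))
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6))
}

# deterministic near-uniform unit sphere points (Fibonacci lattice)
.sphere_lattice <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic Fibonacci sphere lattice (no RNG):
#' for each atom, test points on the sphere of radius `vdw_radius + probe`
#' are kept when outside every other atom's expanded sphere.
#'
#' @param top parameterized [topology()] (`vdw_radius` assigned).
#' @param coords N x 3 frame coordinates.
#' @param sel [select()] result (default all atoms).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points lattice points per atom (default 960, minimum 60).
#' @return numeric vector of per-atom areas (A^2) for the selection; the
#'   total is `sum()` of it.
#' @export
sasa <- function(top, coords, sel = NULL, probe = 1.4, n_points = 960) {
  if (is.null(sel)) sel <- select(top, "resid 1-999999", label = "all")
  if (n_points < 60) stop("sasa: n_points must be >= 60")
  idx <- sel$indices
  .check_params(top, "vdw_radius", "sasa")
  rad <- top$atoms$vdw_radius[idx] + probe
  co <- as.matrix(coords)[idx, , drop = FALSE]
  pts <- .sphere_lattice(n_points)
  n <- length(idx)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rad[i], 2, co[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((co[i, ] - co[j, ])^2))
      if (dij >= rad[i] + rad[j]) next
      d2 <- rowSums(sweep(p, 2, co[j, ])^2)
      exposed <- exposed & d2 > rad[j]^2
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * rad[i]^2 * sum(exposed) / n_points
  }
  areas
}

#' Nonpolar solvation energy from a total SASA
#'
#' `G_np = gamma * SASA + beta`.  In a binding difference
#' `np(complex) - np(receptor) - np(ligand)` the intercept beta cancels
#' once (net `-beta`).
#'
#' @param total_sasa total area, A^2 (>= 0).
#' @param params a [nonpolar_params()].
#' @return energy in kcal/mol.
#' @export
nonpolar_energy <- function(total_sasa, params = nonpolar_params()) {
  if (total_sasa < 0) stop("nonpolar_energy: negative SASA")
  params$gamma * total_sasa + params$beta
}

## ------------------------------------------------------------ generalized Born

# HCT pairwise-descreening scale factors by element (fixed table)
.gb_scale <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96, P = 0.86)
.gb_scale_default <- 0.80

.gb_scales_for <- function(top, idx) {
  el <- toupper(substr(trimws(top$atoms$element[idx]), 1, 1))
  s <- .gb_scale[el]
  s[is.na(s)] <- .gb_scale_default
  as.numeric(s)
}

# HCT descreening integral of sphere (r_ij away, scaled radius a) on atom i
# with intrinsic radius rho_i; equals (1/4pi) Int_{V_j \ B_i} s^-4 dV
.hct_integral <- function(rho_i, r, a) {
  if (r + a <= rho_i) return(0)
  u <- r + a
  l <- max(rho_i, abs(r - a))
  0.5 * ((1 / l - 1 / u) +
         (r / 4) * (1 / u^2 - 1 / l^2) +
         (1 / (2 * r)) * log(l / u) +
         (a^2 / (4 * r)) * (1 / l^2 - 1 / u^2))
}

#' Effective Born radii by pairwise descreening
#'
#' Hawkins-Cramer-Truhlar style: `1/R_i = 1/rho_i - sum_j H(r_ij, S_j
#' rho_j)` with a fixed per-element scaling table (H/O 0.85, C 0.72,
#' N 0.79, S 0.96, P 0.86, default 0.80).  An isolated atom's effective
#' radius equals its intrinsic radius, which anchors the Born-ion limit.
#'
#' @param top parameterized [topology()] (`born_radius` assigned).
#' @param coords N x 3 frame coordinates.
#' @param sel [select()] result.
#' @return effective radii (Angstrom) for the selection.
#' @export
gb_effective_radii <- function(top, coords, sel) {
  idx <- sel$indices
  .check_params(top, "born_radius", "gb_effective_radii")
  rho <- top$atoms$born_radius[idx]
  if (any(rho <= 0)) stop("gb_effective_radii: nonpositive Born radius")
  s <- .gb_scales_for(top, idx)
  co <- as.matrix(coords)[idx, , drop = FALSE]
  n <- length(idx)
  inv <- 1 / rho
  if (n > 1) {
    r <- .pair_r(co, seq_len(n), seq_len(n))
    for (i in seq_len(n)) {
      acc <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        acc <- acc + .hct_integral(rho[i], r[i, j], s[j] * rho[j])
      }
      inv[i] <- inv[i] - acc
    }
  }
  if (any(inv <= 0))
    stop("gb_effective_radii: descreening drove an inverse radius ",
         "nonpositive; check intrinsic radii")
  1 / inv
}

#' Generalized-Born polar solvation energy
#'
#' `-(k/2) (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r_ij, R_i, R_j)`
#' with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))` (Still's
#' interpolation) and effective radii from [gb_effective_radii()].  The
#' double sum includes the self terms (`f_GB(i,i) = R_i`), so a single ion
#' reduces exactly to the Born closed form.
#'
#' @param top parameterized [topology()].
#' @param coords N x 3 frame coordinates.
#' @param sel [select()] result.
#' @param eps_in,eps_out interior/exterior dielectric (defaults 1 and 80).
#' @return energy in kcal/mol.
#' @export
gb_polar <- function(top, coords, sel, eps_in = 1, eps_out = 80) {
  idx <- sel$indices
  .check_params(top, "charge", "gb_polar")
  q <- top$atoms$charge[idx]
  reff <- gb_effective_radii(top, coords, sel)
  co <- as.matrix(coords)[idx, , drop = FALSE]
  pref <- -(.COULOMB_K / 2) * (1 / eps_in - 1 / eps_out)
  n <- length(idx)
  e <- sum(q^2 / reff)
  if (n > 1) {
    r <- .pair_r(co, seq_len(n), seq_len(n))
    rr <- outer(reff, reff)
    fgb <- sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
    qq <- outer(q, q)
    off <- sum(qq / fgb) - sum(diag(qq) / diag(fgb))
    e <- e + off
  }
  pref * e
}

## ------------------------------------------------------- binding assembly

#' Assemble a binding free-energy report from component statistics
#'
#' Builds the standard single-trajectory end-state ledger from component
#' means (and optional standard deviations): the enthalpy
#' `dH = ele + vdw + np + polar`, the electrostatic balance `ele + polar`,
#' and `dG_bind = dH - TdS`.  The identities hold exactly on the means by
#' construction.
#'
#' @param ele,vdw,np,polar,TdS component means, kcal/mol (TdS is the
#'   T-weighted entropy change; unfavorable binding entropy is negative).
#' @param sd named numeric vector of component standard deviations
#'   (`ele`, `vdw`, `np`, `polar`, `TdS`), optional.
#' @param n_snapshots snapshot count the means came from.
#' @param temperature K.
#' @return object of class `binding_report` with a `table` data.frame in
#'   the conventional row order (ele, vdw, np, polar, ele+polar, dH, TdS,
#'   dG_bind).
#' @export
binding_report <- function(ele, vdw, np, polar, TdS, sd = NULL,
                           n_snapshots = NA_integer_, temperature = 300) {
  dh <- ele + vdw + np + polar
  dg <- dh - TdS
  get_sd <- function(k) if (!is.null(sd) && k %in% names(sd)) sd[[k]]
                        else NA_real_
  tab <- data.frame(
    component = c("dE_ele", "dE_vdw", "dG_np", "dG_polar",
                  "dE_ele+dG_polar", "dH", "TdS", "dG_bind"),
    mean = c(ele, vdw, np, polar, ele + polar, dh, TdS, dg),
    sd = c(get_sd("ele"), get_sd("vdw"), get_sd("np"), get_sd("polar"),
           get_sd("ele_polar"), get_sd("dH"), get_sd("TdS"),
           get_sd("dG")))
  structure(list(table = tab, components = list(ele = ele, vdw = vdw,
                                                np = np, polar = polar),
                 TdS = TdS, dH = dh, dG_bind = dg,
                 n_snapshots = n_snapshots, temperature = temperature),
            class = "binding_report")
}

#' @export
print.binding_report <- function(x, ...) {
  cat("binding free energy report (", x$n_snapshots, " snapshots, T = ",
      x$temperature, " K)\n", sep = "")
  tab <- x$table
  tab$mean <- sprintf("%10.2f", tab$mean)
  tab$sd <- ifelse(is.na(tab$sd), "", sprintf("%8.2f", tab$sd))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a binding report as tab-separated text
#' @param report a [binding_report()].
#' @param path output path.
#' @export
write_binding_report <- function(report, path) {
  write.table(format(report$table, digits = 8), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single-trajectory MM-GBSA binding free energy
#'
#' For snapshots of the complex trajectory (receptor and ligand geometries
#' extracted from the same frames), computes per snapshot the interface
#' electrostatic and van der Waals energies, the nonpolar SASA difference
#' term and the generalized-Born polar difference
#' `polar(complex) - polar(receptor) - polar(ligand)`; reports
#' means +/- sd and assembles `dG_bind = dH - TdS`.  Because the protocol
#' is single-trajectory, intramolecular Coulomb/LJ terms cancel exactly in
#' the difference, so `ele`/`vdw` equal the pure interface sums.
#'
#' @param traj complex [trajectory()] (parameterized topology).
#' @param receptor,ligand disjoint [select()] results.
#' @param snapshot_stride take every k-th frame (default 1).
#' @param entropy_stride entropy snapshots are every k-th energy snapshot
#'   (default 5, mirroring the convention of 100 entropy snapshots out of
#'   500).
#' @param T temperature, K (default 300).
#' @param entropy `"quasiharmonic"` or `"none"`.
#' @param sasa_points SASA lattice points per atom (default 240).
#' @param params a [nonpolar_params()].
#' @return a [binding_report()] (with `TdS = 0` when `entropy = "none"`).
#' @export
mmgbsa_binding <- function(traj, receptor, ligand, snapshot_stride = 1,
                           entropy_stride = 5, T = 300,
                           entropy = c("quasiharmonic", "none"),
                           sasa_points = 240,
                           params = nonpolar_params()) {
  entropy <- match.arg(entropy)
  if (length(intersect(receptor$indices, ligand$indices)) > 0)
    stop("mmgbsa_binding: receptor and ligand selections overlap")
  top <- traj$top
  complex_sel <- structure(list(indices = sort(c(receptor$indices,
                                                 ligand$indices)),
                                label = "complex"), class = "selection")
  frames <- seq(1, n_frames(traj), by = snapshot_stride)
  comp <- matrix(NA_real_, length(frames), 4,
                 dimnames = list(NULL, c("ele", "vdw", "np", "polar")))
  for (k in seq_along(frames)) {
    co <- frame_coords(traj, frames[k])
    ele <- coulomb_interface(top, co, receptor, ligand)
    vdw <- lj_interface(top, co, receptor, ligand)
    s_c <- sum(sasa(top, co, complex_sel, probe = params$probe,
                    n_points = sasa_points))
    s_r <- sum(sasa(top, co, receptor, probe = params$probe,
                    n_points = sasa_points))
    s_l <- sum(sasa(top, co, ligand, probe = params$probe,
                    n_points = sasa_points))
    np <- nonpolar_energy(s_c, params) - nonpolar_energy(s_r, params) -
      nonpolar_energy(s_l, params)
    pol <- gb_polar(top, co, complex_sel) - gb_polar(top, co, receptor) -
      gb_polar(top, co, ligand)
    comp[k, ] <- c(ele, vdw, np, pol)
  }
  mu <- colMeans(comp)
  sds <- apply(comp, 2, function(v) if (length(v) > 1) sd(v) else 0)
  tds <- 0
  if (entropy == "quasiharmonic") {
    ent_frames <- frames[seq(1, length(frames), by = entropy_stride)]
    if (length(ent_frames) < 2) ent_frames <- frames
    if (length(ent_frames) < 2)
      stop("mmgbsa_binding: quasiharmonic entropy needs >= 2 snapshots; ",
           "use entropy = \"none\" for single-snapshot runs")
    sub <- trajectory(traj$top, traj$xyz[ent_frames, , drop = FALSE],
                      times = traj$times[ent_frames])
    e_c <- entropy_estimate(sub, complex_sel, method = "quasiharmonic",
                            T = T)
    e_r <- entropy_estimate(sub, receptor, method = "quasiharmonic", T = T)
    e_l <- entropy_estimate(sub, ligand, method = "quasiharmonic", T = T)
    tds <- e_c$total - e_r$total - e_l$total
  }
  rep <- binding_report(mu[["ele"]], mu[["vdw"]], mu[["np"]], mu[["polar"]],
                        TdS = tds,
                        sd = c(ele = sds[["ele"]], vdw = sds[["vdw"]],
                               np = sds[["np"]], polar = sds[["polar"]]),
                        n_snapshots = length(frames), temperature = T)
  rep$per_snapshot <- comp
  rep
}

#' Per-residue decomposition of the interface binding energy
#'
#' Decomposes the snapshot-averaged interaction energy (interface Coulomb +
#' Lennard-Jones + generalized-Born cross terms, entropy omitted) into the
#' contribution of each residue on one side: a residue's share is the sum
#' over its atoms of their pairwise terms with every atom of the other
#' side, GB cross terms evaluated with the complex's effective radii.
#' Contributions sum exactly to the decomposed total.
#'
#' @param traj complex [trajectory()] (parameterized topology).
#' @param receptor,ligand disjoint [select()] results.
#' @param side decompose over `"receptor"` residues or `"ligand"`
#'   residues/nucleotides.
#' @param threshold_fraction flag residues whose |fraction| of the total
#'   exceeds this percentage (default 1.4; the ternary-complex convention
#'   is 1.5).
#' @param snapshot_stride take every k-th frame (default 1).
#' @return data.frame of class `residue_contributions`: `chain`, `resid`,
#'   `resname`, `contribution` (kcal/mol), `fraction_pct`, `flagged`;
#'   `attr(,"total")` is the decomposed total.
#' @export
decompose_per_residue <- function(traj, receptor, ligand,
                                  side = c("receptor", "ligand"),
                                  threshold_fraction = 1.4,
                                  snapshot_stride = 1) {
  side <- match.arg(side)
  if (threshold_fraction <= 0 || threshold_fraction >= 100)
    stop("decompose_per_residue: threshold must be inside (0, 100)")
  if (length(intersect(receptor$indices, ligand$indices)) > 0)
    stop("decompose_per_residue: receptor and ligand selections overlap")
  top <- traj$top
  .check_params(top, c("charge", "lj_sigma", "lj_epsilon", "born_radius"),
                "decompose_per_residue")
  own <- if (side == "receptor") receptor else ligand
  other <- if (side == "receptor") ligand else receptor
  at <- top$atoms
  res_key <- paste(at$chain[own$indices], at$resid[own$indices])
  groups <- split(own$indices, factor(res_key, levels = unique(res_key)))
  complex_sel <- structure(list(indices = sort(c(receptor$indices,
                                                 ligand$indices)),
                                label = "complex"), class = "selection")
  frames <- seq(1, n_frames(traj), by = snapshot_stride)
  acc <- numeric(length(groups))
  for (f in frames) {
    co <- frame_coords(traj, f)
    reff_all <- gb_effective_radii(top, co, complex_sel)
    reff <- setNames(reff_all, complex_sel$indices)
    q <- at$charge
    pref <- -(.COULOMB_K) * (1 - 1 / 80)   # cross-term prefactor (x2 of k/2)
    for (g in seq_along(groups)) {
      ia <- groups[[g]]
      sel_a <- structure(list(indices = ia, label = "res"),
                         class = "selection")
      e <- coulomb_interface(top, co, sel_a, other) +
        lj_interface(top, co, sel_a, other)
      r <- .pair_r(co, ia, other$indices)
      rr <- outer(reff[as.character(ia)], reff[as.character(other$indices)])
      fgb <- sqrt(r^2 + rr * exp(-r^2 / (4 * rr)))
      e <- e + pref * sum(outer(q[ia], q[other$indices]) / fgb)
      acc[g] <- acc[g] + e
    }
  }
  contrib <- acc / length(frames)
  total <- sum(contrib)
  frac <- if (abs(total) > 0) 100 * contrib / total else rep(0, length(contrib))
  first <- vapply(groups, `[`, numeric(1), 1)
  out <- data.frame(chain = at$chain[first], resid = at$resid[first],
                    resname = at$resname[first], contribution = contrib,
                    fraction_pct = frac,
                    flagged = abs(frac) > threshold_fraction)
  class(out) <- c("residue_contributions", "data.frame")
  attr(out, "total") <- total
  attr(out, "threshold_fraction") <- threshold_fraction
  out
}

#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd)` with R = 1.9872e-3 kcal/(mol K).
#'
#' @param Kd dissociation constant, molar (> 0).
#' @param T temperature, K (default 300).
#' @return kcal/mol.
#' @export
experimental_dg <- function(Kd, T = 300) {
  if (Kd <= 0) stop("experimental_dg: Kd must be positive")
  .R_GAS * T * log(Kd)
}
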
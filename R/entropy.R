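# Solute entropy estimates for end-state binding thermodynamics, reported
# as T*S (kcal/mol) split into translational (ideal gas, 1 M standard
# state), rotational (classical rigid rotor) and vibrational
# (harmonic-oscillator sum) parts.  Vibrational frequencies come either
# from the mass-weighted covariance of snapshots (quasiharmonic) or from
# the mass-weighted Hessian of a truncated, minimized system (normal
# mode).

# physical constants (SI)
.KB_SI <- 1.380649e-23
.H_SI <- 6.62607015e-34
.HBAR_SI <- .H_SI / (2 * pi)
.AMU_KG <- 1.66053907e-27
.NA_AVOG <- 6.02214076e23
.A2_M2 <- 1e-20
# 1 kcal/mol in J per molecule
.KCALMOL_J <- 4184 / .NA_AVOG

# harmonic-oscillator entropy in units of R, x = hbar*omega/(kB*T)
.ho_entropy_R <- function(x) {
  ifelse(x > 500, 0, x / (exp(x) - 1) - log1p(-exp(-x)))
}

# Sackur-Tetrode translational entropy (units of R) at concentration conc
# (mol/L); m_amu total mass
.trans_entropy_R <- function(m_amu, T, conc = 1) {
  m <- m_amu * .AMU_KG
  v <- 1 / (conc * 1000 * .NA_AVOG)          # m^3 per molecule
  lam3 <- (2 * pi * m * .KB_SI * T / .H_SI^2)^1.5
  log(lam3 * v) + 2.5
}

# classical rigid-rotor entropy (units of R) from principal moments
# (amu A^2); handles linear (one ~zero moment) and single atoms
.rot_entropy_R <- function(moments_amuA2, T, sigma_sym = 1) {
  mom <- sort(moments_amuA2 * .AMU_KG * .A2_M2, decreasing = TRUE)
  tol <- max(mom) * 1e-10
  nz <- mom[mom > tol]
  if (length(nz) == 0) return(0)
  if (length(nz) <= 2) {               # linear rotor (two equal moments)
    i1 <- nz[1]
    return(1 + log(8 * pi^2 * i1 * .KB_SI * T / (sigma_sym * .H_SI^2)))
  }
  q <- (sqrt(pi) / sigma_sym) *
    (8 * pi^2 * .KB_SI * T / .H_SI^2)^1.5 * sqrt(prod(nz))
  1.5 + log(q)
}

.inertia_moments <- function(coords, masses) {
  cm <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, cm)
  r2 <- rowSums(x^2)
  i_mat <- diag(c(sum(masses * (r2 - x[, 1]^2)),
                  sum(masses * (r2 - x[, 2]^2)),
                  sum(masses * (r2 - x[, 3]^2))))
  i_mat[1, 2] <- i_mat[2, 1] <- -sum(masses * x[, 1] * x[, 2])
  i_mat[1, 3] <- i_mat[3, 1] <- -sum(masses * x[, 1] * x[, 3])
  i_mat[2, 3] <- i_mat[3, 2] <- -sum(masses * x[, 2] * x[, 3])
  eigen(i_mat, symmetric = TRUE, only.values = TRUE)$values
}

#' Solute entropy estimate (quasiharmonic or normal mode)
#'
#' Translational entropy uses the ideal-gas (Sackur-Tetrode) closed form
#' at the stated temperature and a 1 M standard concentration; rotational
#' entropy the classical rigid-rotor formula from the principal moments of
#' inertia of the mean structure (zero for a single atom, linear-rotor
#' form for collinear geometries); vibrational entropy the
#' harmonic-oscillator sum over mode frequencies.
#'
#' Quasiharmonic frequencies are `omega_k = sqrt(kB T / lambda_k)` with
#' `lambda_k` the eigenvalues of the mass-weighted covariance of the
#' superposed snapshots (rigid-body modes have `lambda ~ 0` and are
#' skipped).  Normal-mode frequencies come from the mass-weighted Hessian
#' of a truncated system: only residues with an atom within
#' `truncation_radius` of the ligand's mass center are kept, the subsystem
#' is minimized (Coulomb with distance-dependent dielectric eps = 4r, plus
#' Lennard-Jones) until the gradient RMS drops below `grad_tol`, and the
#' six (five for linear) near-zero rigid modes are discarded by an
#' eigenvalue threshold.
#'
#' @param traj snapshot [trajectory()] (>= 2 frames for quasiharmonic;
#'   frame 1 is the starting point for normal mode).
#' @param sel [select()] result defining the solute (the "ligand" for the
#'   truncation rule when `method = "normal-mode"`).
#' @param method `"quasiharmonic"` or `"normal-mode"`.
#' @param T temperature, K (default 300).
#' @param truncation_radius Angstrom (default 9) for normal mode.
#' @param ligand optional [select()] whose mass center defines the
#'   truncation sphere (defaults to `sel`).
#' @param grad_tol gradient RMS tolerance, kcal/mol/A (default 5e-5).
#' @param max_iter minimizer iteration cap (default 5000).
#' @return object of class `entropy_components` with `trans`, `rot`,
#'   `vib`, `total` (all T*S in kcal/mol) and `temperature`.
#' @export
entropy_estimate <- function(traj, sel = NULL,
                             method = c("quasiharmonic", "normal-mode"),
                             T = 300, truncation_radius = 9, ligand = NULL,
                             grad_tol = 5e-5, max_iter = 5000) {
  method <- match.arg(method)
  if (is.null(sel)) sel <- select(traj$top, "resid 1-999999", label = "all")
  .check_params(traj$top, "mass", "entropy_estimate")
  masses <- traj$top$atoms$mass[sel$indices]
  rt <- .R_GAS * T
  if (method == "quasiharmonic") {
    if (n_frames(traj) < 2)
      stop("entropy_estimate: quasiharmonic needs >= 2 snapshots")
    n <- length(sel$indices)
    if (n >= 3) {
      fit <- .iterated_mean_fit(traj, sel)
      xyz <- fit$xyz
      mean_co <- fit$mean
    } else {
      # too few atoms to superpose: remove translation only
      xyz <- sel_xyz(traj, sel)
      mean_co <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
    }
    x <- sweep(xyz, 2, as.numeric(t(mean_co)))
    sqm <- rep(sqrt(masses), each = 3)
    cm <- crossprod(x) / nrow(x)
    cm <- t(t(cm * sqm) * sqm)               # mass-weighted covariance
    lam <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10]                  # amu A^2; drops rigid modes
    vib <- 0
    if (length(lam) > 0) {
      lam_si <- lam * .AMU_KG * .A2_M2
      omega <- sqrt(.KB_SI * T / lam_si)
      x_ad <- .HBAR_SI * omega / (.KB_SI * T)
      vib <- rt * sum(.ho_entropy_R(x_ad))
    }
    trans <- rt * .trans_entropy_R(sum(masses), T)
    rot <- if (length(sel$indices) == 1) 0
           else rt * .rot_entropy_R(.inertia_moments(mean_co, masses), T)
  } else {
    res <- .nma_truncated(traj, sel, ligand, truncation_radius, grad_tol,
                          max_iter)
    lam_h <- res$eigenvalues                 # kcal/mol/A^2/amu
    tol <- max(abs(lam_h)) * 1e-8
    lam_h <- lam_h[lam_h > tol]
    omega <- sqrt(lam_h * 4.184e26)          # 1/s
    x_ad <- .HBAR_SI * omega / (.KB_SI * T)
    vib <- rt * sum(.ho_entropy_R(x_ad))
    trans <- rt * .trans_entropy_R(sum(masses), T)
    rot <- if (length(sel$indices) == 1) 0
           else rt * .rot_entropy_R(
             .inertia_moments(frame_coords(traj, 1, sel),
                              traj$top$atoms$mass[sel$indices]), T)
  }
  structure(list(trans = trans, rot = rot, vib = vib,
                 total = trans + rot + vib, temperature = T,
                 method = method),
            class = "entropy_components")
}

#' @export
print.entropy_components <- function(x, ...) {
  cat(sprintf(
    "T*S (%s, %g K): trans %.2f + rot %.2f + vib %.2f = %.2f kcal/mol\n",
    x$method, x$temperature, x$trans, x$rot, x$vib, x$total))
  invisible(x)
}

# energy and gradient of the minimization force field: Coulomb with
# eps = 4r (distance-dependent dielectric) plus 12-6 Lennard-Jones
.ff_energy_grad <- function(flat, q, sig, eps) {
  n <- length(q)
  co <- matrix(flat, ncol = 3, byrow = TRUE)
  e <- 0
  g <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) {
    dv <- sweep(co[(i + 1):n, , drop = FALSE], 2, co[i, ], "-")
    r2 <- rowSums(dv^2)
    r <- sqrt(r2)
    js <- (i + 1):n
    # Coulomb / (4 r^2)
    qe <- .COULOMB_K * q[i] * q[js] / (4 * r2)
    sij <- (sig[i] + sig[js]) / 2
    eij <- sqrt(eps[i] * eps[js])
    sr6 <- (sij / r)^6
    lj <- 4 * eij * (sr6^2 - sr6)
    e <- e + sum(qe + lj)
    # dE/dr
    dedr <- -2 * qe / r + 4 * eij * (-12 * sr6^2 + 6 * sr6) / r
    gi <- dv * (dedr / r)
    g[js, ] <- g[js, ] + gi
    g[i, ] <- g[i, ] - colSums(gi)
  }
  list(energy = e, grad = as.numeric(t(g)))
}

.nma_truncated <- function(traj, sel, ligand, truncation_radius, grad_tol,
                           max_iter) {
  top <- traj$top
  .check_params(top, c("charge", "lj_sigma", "lj_epsilon", "mass"),
                "entropy_estimate (normal-mode)")
  co_full <- frame_coords(traj, 1)
  if (is.null(ligand)) ligand <- sel
  lm <- top$atoms$mass[ligand$indices]
  mass_ctr <- colSums(co_full[ligand$indices, , drop = FALSE] * lm) / sum(lm)
  # keep whole residues with any atom inside the truncation sphere,
  # restricted to the analysis selection
  d <- sqrt(rowSums(sweep(co_full, 2, mass_ctr)^2))
  res_key <- paste(top$atoms$chain, top$atoms$resid)
  keep_res <- unique(res_key[d <= truncation_radius])
  keep <- intersect(sel$indices, which(res_key %in% keep_res))
  keep <- sort(union(keep, ligand$indices))
  if (length(keep) > 500)
    stop("entropy_estimate: truncated system still has ", length(keep),
         " atoms (> 500); normal mode is limited to small systems")
  q <- top$atoms$charge[keep]
  sig <- top$atoms$lj_sigma[keep]
  eps <- top$atoms$lj_epsilon[keep]
  mass <- top$atoms$mass[keep]
  flat <- as.numeric(t(co_full[keep, , drop = FALSE]))
  fn <- function(x) .ff_energy_grad(x, q, sig, eps)$energy
  gr <- function(x) .ff_energy_grad(x, q, sig, eps)$grad
  for (round in 1:10) {
    opt <- optim(flat, fn, gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-14))
    flat <- opt$par
    grms <- sqrt(mean(gr(flat)^2))
    if (grms < grad_tol) break
  }
  if (grms >= grad_tol)
    stop("entropy_estimate: minimization did not reach gradient RMS < ",
         grad_tol, " (reached ", signif(grms, 3), ")")
  # numeric Hessian from central differences of the analytic gradient
  nc <- length(flat)
  h <- 1e-4
  hess <- matrix(0, nc, nc)
  for (k in seq_len(nc)) {
    xp <- flat; xp[k] <- xp[k] + h
    xm <- flat; xm[k] <- xm[k] - h
    hess[, k] <- (gr(xp) - gr(xm)) / (2 * h)
  }
  hess <- (hess + t(hess)) / 2
  sqm <- rep(sqrt(mass), each = 3)
  hess <- hess / outer(sqm, sqm)
  list(eigenvalues = eigen(hess, symmetric = TRUE,
                           only.values = TRUE)$values,
       atoms = keep, minimized = matrix(flat, ncol = 3, byrow = TRUE))
}
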
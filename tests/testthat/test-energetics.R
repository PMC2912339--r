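# Interface energies, SASA, generalized Born, entropy, ledger assembly.

test_that("coulomb interface matches closed forms and scales with the
           dielectric", {
  top <- charged_topology(c(1, -1))
  co <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  sa <- select(top, "resid 1"); sb <- select(top, "resid 2")
  expect_equal(coulomb_interface(top, co, sa, sb), -100, tolerance = 1e-10)
  expect_equal(coulomb_interface(top, co, sa, sb, eps_interior = 2), -50,
               tolerance = 1e-10)
  top0 <- charged_topology(c(0, -1))
  expect_equal(coulomb_interface(top0, co, sa, sb), 0)
  expect_error(coulomb_interface(top, rbind(c(0, 0, 0), c(1e-4, 0, 0)),
                                 sa, sb), "overlapping")
  expect_error(coulomb_interface(top, co, sa, sa), "disjoint")
})

test_that("interface energies equal a brute-force double loop", {
  cx <- make_charged_complex(30, 20, seed = 5)
  ele <- coulomb_interface(cx$top, cx$coords, cx$receptor, cx$ligand)
  vdw <- lj_interface(cx$top, cx$coords, cx$receptor, cx$ligand)
  # independent plain double loop
  ref_e <- 0; ref_v <- 0
  q <- cx$top$atoms$charge
  for (i in cx$receptor$indices) {
    for (j in cx$ligand$indices) {
      r <- sqrt(sum((cx$coords[i, ] - cx$coords[j, ])^2))
      ref_e <- ref_e + 332.0636 * q[i] * q[j] / r
      sij <- (cx$top$atoms$lj_sigma[i] + cx$top$atoms$lj_sigma[j]) / 2
      eij <- sqrt(cx$top$atoms$lj_epsilon[i] * cx$top$atoms$lj_epsilon[j])
      ref_v <- ref_v + 4 * eij * ((sij / r)^12 - (sij / r)^6)
    }
  }
  expect_equal(ele, ref_e, tolerance = 1e-10)
  expect_equal(vdw, ref_v, tolerance = 1e-10)
  # and the generator's own manifest oracle agrees
  expect_equal(ele, cx$manifest$ref_coulomb, tolerance = 1e-10)
  expect_equal(vdw, cx$manifest$ref_lj, tolerance = 1e-10)
})

test_that("lennard-jones takes the textbook values at sigma and the
           minimum", {
  top <- charged_topology(c(0, 0), sigma = 3.4, eps = 0.25)
  sa <- select(top, "resid 1"); sb <- select(top, "resid 2")
  at_min <- rbind(c(0, 0, 0), c(2^(1 / 6) * 3.4, 0, 0))
  expect_equal(lj_interface(top, at_min, sa, sb), -0.25, tolerance = 1e-12)
  at_sig <- rbind(c(0, 0, 0), c(3.4, 0, 0))
  expect_equal(lj_interface(top, at_sig, sa, sb), 0, tolerance = 1e-12)
  # pairwise additivity on a three-atom system
  top3 <- charged_topology(c(0, 0, 0), sigma = 3.4, eps = 0.25)
  co3 <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4.5, 0))
  s1 <- select(top3, "resid 1")
  s23 <- select(top3, "resid 2-3")
  pair <- function(i, j) {
    si <- select(top3, paste("resid", i))
    sj <- select(top3, paste("resid", j))
    lj_interface(top3, co3, si, sj)
  }
  expect_equal(lj_interface(top3, co3, s1, s23),
               pair(1, 2) + pair(1, 3), tolerance = 1e-12)
})

test_that("sasa reproduces isolated spheres, burial and distant
           additivity", {
  top <- charged_topology(0, rvdw = 2.0)
  a1 <- sum(sasa(top, matrix(0, 1, 3), n_points = 960))
  expect_equal(a1, 4 * pi * 3.4^2, tolerance = 0.02 * 4 * pi * 3.4^2)
  # atom buried inside a tight shell of neighbors: zero area
  shell <- rbind(c(0, 0, 0), 2.2 * trajscope:::.sphere_lattice(40))
  top_sh <- charged_topology(rep(0, 41), rvdw = 2.0)
  areas <- sasa(top_sh, shell, n_points = 240)
  expect_equal(areas[1], 0)
  # two atoms far apart: total equals the sum of isolated values
  top2 <- charged_topology(c(0, 0), rvdw = 2.0)
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(sum(sasa(top2, far, n_points = 960)), 2 * a1,
               tolerance = 1e-9)
  # convergence: doubling the lattice changes the total by < 1%
  set.seed(51)
  blob <- matrix(rnorm(60, sd = 3), 20, 3)
  top20 <- charged_topology(rep(0, 20), rvdw = 1.7)
  t1 <- sum(sasa(top20, blob, n_points = 480))
  t2 <- sum(sasa(top20, blob, n_points = 960))
  expect_lt(abs(t2 - t1) / t2, 0.01)
  expect_error(sasa(top, matrix(0, 1, 3), n_points = 10), ">= 60")
})

test_that("nonpolar energy is the linear SASA model with the standard
           constants", {
  expect_equal(nonpolar_energy(0), 0.92, tolerance = 1e-12)
  expect_equal(nonpolar_energy(1000), 6.34, tolerance = 1e-12)
  expect_error(nonpolar_energy(-1), "negative")
  # in a binding difference the intercept cancels exactly once
  s_c <- 500; s_r <- 400; s_l <- 300
  dnp <- nonpolar_energy(s_c) - nonpolar_energy(s_r) - nonpolar_energy(s_l)
  expect_equal(dnp, 0.00542 * (s_c - s_r - s_l) - 0.92, tolerance = 1e-12)
})

test_that("the HCT descreening integral matches numeric quadrature", {
  cases <- list(c(1.5, 5.0, 1.2), c(1.5, 2.4, 1.2), c(1.2, 1.8, 1.5),
                c(2.0, 2.1, 0.8))
  for (cs in cases) {
    num <- integrate(function(s)
      s^-2 * (1 - (s^2 + cs[2]^2 - cs[3]^2) / (2 * s * cs[2])) / 2,
      max(cs[1], abs(cs[2] - cs[3])), cs[2] + cs[3],
      rel.tol = 1e-12)$value
    expect_equal(trajscope:::.hct_integral(cs[1], cs[2], cs[3]), num,
                 tolerance = 1e-9)
  }
  # fully enclosed descreener contributes nothing
  expect_equal(trajscope:::.hct_integral(5, 1, 0.5), 0)
})

test_that("generalized Born reduces to the Born ion and obeys limits", {
  top <- charged_topology(1, rho = 2.0)
  co <- matrix(0, 1, 3)
  sel <- select(top, "resid 1")
  born <- -(332.0636 / 2) * (1 - 1 / 80) / 2.0
  expect_equal(gb_polar(top, co, sel), born, tolerance = 1e-10)
  # all charges zero
  top0 <- charged_topology(c(0, 0))
  co2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(gb_polar(top0, co2, select(top0, "resid 1-2")), 0)
  # eps_out -> eps_in limit vanishes
  topq <- charged_topology(c(1, -1))
  expect_equal(gb_polar(topq, co2, select(topq, "resid 1-2"),
                        eps_in = 80, eps_out = 80), 0)
  # rigid-transform invariance of the total GB energy
  cx <- make_charged_complex(12, 6, seed = 9)
  all_sel <- select(cx$top, "resid 1-18")
  e1 <- gb_polar(cx$top, cx$coords, all_sel)
  set.seed(52)
  rt <- random_rigid()
  e2 <- gb_polar(cx$top, apply_rigid(cx$coords, rt), all_sel)
  expect_equal(e1, e2, tolerance = 1e-8)
  bad <- charged_topology(1, rho = -1)
  expect_error(gb_polar(bad, co, select(bad, "resid 1")), "Born radius")
})

test_that("entropy closed forms: free atom, rigid snapshots, harmonic
           diatomic", {
  # single free atom: rot = vib = 0, trans = Sackur-Tetrode at 1 M
  top <- charged_topology(0, mass = 39.948)
  traj <- trajectory(top, rbind(rep(0, 3), rep(0, 3)), times = c(0, 2))
  e <- entropy_estimate(traj, method = "quasiharmonic", T = 300)
  kb <- 1.380649e-23; hp <- 6.62607015e-34; na <- 6.02214076e23
  m_kg <- 39.948 * 1.66053907e-27
  s_r <- log((2 * pi * m_kg * kb * 300 / hp^2)^1.5 / (1000 * na)) + 2.5
  expect_equal(e$trans, 1.9872e-3 * 300 * s_r, tolerance = 1e-6)
  expect_equal(e$rot, 0)
  expect_equal(e$vib, 0)
  expect_equal(e$total, e$trans + e$rot + e$vib)
  # rigid multi-atom snapshots: quasiharmonic vib = 0
  st <- blob_trajectory(10, 5, sigma = 0, seed = 53)
  st$top$atoms$mass <- 12.011
  e0 <- entropy_estimate(st, method = "quasiharmonic", T = 300)
  expect_equal(e0$vib, 0, tolerance = 1e-8)
  # harmonic diatomic (normal mode): vib matches the HO closed form with
  # the force constant from the pair potential's curvature
  top2 <- charged_topology(c(0, 0), sigma = 3.4, eps = 0.5,
                           mass = 12.011)
  rmin <- 2^(1 / 6) * 3.4
  tr2 <- one_frame(top2, rbind(c(0, 0, 0), c(rmin + 0.05, 0, 0)))
  e2 <- entropy_estimate(tr2, method = "normal-mode", T = 300)
  vfun <- function(r) 4 * 0.5 * ((3.4 / r)^12 - (3.4 / r)^6)
  kf <- (vfun(rmin + 1e-4) - 2 * vfun(rmin) + vfun(rmin - 1e-4)) / 1e-8
  omega <- sqrt(kf / (12.011 / 2) * 4.184e26)
  x <- (hp / (2 * pi)) * omega / (kb * 300)
  s_vib <- x / (exp(x) - 1) - log(1 - exp(-x))
  expect_equal(e2$vib, 1.9872e-3 * 300 * s_vib, tolerance = 1e-5)
  expect_error(entropy_estimate(one_frame(top, matrix(0, 1, 3)),
                                method = "quasiharmonic"),
               ">= 2 snapshots")
})

test_that("mmgbsa ledger identities hold and a ghost ligand binds with
           zero energy", {
  cx <- make_charged_complex(10, 5, seed = 3)
  co <- cx$coords
  traj <- trajectory(cx$top, rbind(as.numeric(t(co)),
                                   as.numeric(t(co + 0.02))),
                     times = c(0, 2))
  rep1 <- mmgbsa_binding(traj, cx$receptor, cx$ligand,
                         entropy = "quasiharmonic")
  tab <- setNames(rep1$table$mean, rep1$table$component)
  expect_equal(tab[["dH"]],
               tab[["dE_ele"]] + tab[["dE_vdw"]] + tab[["dG_np"]] +
                 tab[["dG_polar"]], tolerance = 1e-12)
  expect_equal(tab[["dG_bind"]], tab[["dH"]] - tab[["TdS"]],
               tolerance = 1e-12)
  expect_equal(tab[["dE_ele+dG_polar"]],
               tab[["dE_ele"]] + tab[["dG_polar"]], tolerance = 1e-12)
  expect_true(all(rep1$table$sd[1:4] >= 0))
  # single-trajectory protocol: ele equals the pure interface Coulomb mean
  iface <- mean(c(coulomb_interface(cx$top, co, cx$receptor, cx$ligand),
                  coulomb_interface(cx$top, co + 0.02, cx$receptor,
                                    cx$ligand)))
  expect_equal(tab[["dE_ele"]], iface, tolerance = 1e-10)
  # ghost ligand: zero charges and LJ epsilon, far away -> all deltas 0
  n <- 15
  ghost_top <- charged_topology(c(rep_len(c(1, -1), 10), rep(0, 5)))
  ghost_top$atoms$lj_epsilon[11:15] <- 0
  ghost_co <- rbind(matrix(rnorm(30, sd = 3), 10, 3),
                    matrix(rnorm(15, sd = 2), 5, 3) + 5000)
  gtraj <- one_frame(ghost_top, ghost_co)
  rec <- select(ghost_top, "resid 1-10")
  lig <- select(ghost_top, "resid 11-15")
  rep2 <- mmgbsa_binding(gtraj, rec, lig, entropy = "none",
                         sasa_points = 240)
  tab2 <- setNames(rep2$table$mean, rep2$table$component)
  expect_lt(abs(tab2[["dE_ele"]]), 1e-8)
  expect_lt(abs(tab2[["dE_vdw"]]), 1e-8)
  expect_lt(abs(tab2[["dG_polar"]]), 1e-8)
  # beta cancels once: with no area change the np delta is exactly -beta
  expect_equal(tab2[["dG_np"]], -0.92, tolerance = 1e-9)
  # sd of a single-snapshot ensemble is zero
  expect_true(all(rep2$table$sd[1:4] == 0))
  expect_error(mmgbsa_binding(gtraj, rec, rec, entropy = "none"),
               "overlap")
})

test_that("per-residue decomposition sums to the interface total and
           localizes charge", {
  cx <- make_charged_complex(10, 5, seed = 13)
  traj <- one_frame(cx$top, cx$coords)
  dec <- decompose_per_residue(traj, cx$receptor, cx$ligand, "receptor",
                               threshold_fraction = 5)
  expect_equal(sum(dec$contribution), attr(dec, "total"),
               tolerance = 1e-6)
  expect_equal(sum(dec$fraction_pct), 100, tolerance = 1e-6)
  # a complex whose only receptor charges sit on one residue
  q <- c(2, rep(0, 9), rep_len(c(1, -1), 5))
  cq <- make_charged_complex(10, 5, charge_plan = q, seed = 13,
                             separation = 8)
  # suppress LJ so electrostatics dominates the decomposition
  cq$top$atoms$lj_epsilon <- 1e-12
  traj2 <- one_frame(cq$top, cq$coords)
  dec2 <- decompose_per_residue(traj2, cq$receptor, cq$ligand, "receptor",
                                threshold_fraction = 50)
  expect_gt(abs(dec2$fraction_pct[1]), 99)
  expect_true(dec2$flagged[1])
  expect_error(decompose_per_residue(traj, cx$receptor, cx$ligand,
                                     threshold_fraction = 101), "(0, 100)")
  # ligand-side decomposition sums to the same interface total
  dec_l <- decompose_per_residue(traj, cx$receptor, cx$ligand, "ligand",
                                 threshold_fraction = 5)
  expect_equal(attr(dec_l, "total"), attr(dec, "total"), tolerance = 1e-9)
})

test_that("experimental dG follows RT ln(Kd)", {
  expect_equal(experimental_dg(1, 300), 0)
  expect_equal(experimental_dg(1e-10, 300), 1.9872e-3 * 300 * log(1e-10),
               tolerance = 1e-12)
  expect_equal(round(experimental_dg(1e-10, 300), 2), -13.73)
  expect_gt(experimental_dg(1e-6, 300), experimental_dg(1e-9, 300))
  expect_error(experimental_dg(0), "positive")
})

test_that("binding report assembly validates identities and spread", {
  rep0 <- binding_report(-10, -5, -1, 8, TdS = -4, n_snapshots = 1)
  expect_equal(rep0$dH, -8)
  expect_equal(rep0$dG_bind, -4)
  expect_equal(rep0$table$mean[5], -2)  # ele + polar
})
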
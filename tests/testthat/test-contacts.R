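# Hydrogen bonds, dihedrals, hydration sites, coordination, channels.

test_that("hbond occupancy follows planted schedules", {
  # fixed bonded pair: occupancy 1
  it_on <- make_interaction_trajectory(occupancy_spec(rep(TRUE, 20)))
  don <- select(it_on$top, "name OD1")
  acc <- select(it_on$top, "name N1")
  hb <- hbond_scan(it_on, don, acc, d_cut = 3.5)
  expect_length(hb, 1)
  expect_equal(hb[[1]]$occupancy, 1.0)
  expect_true(all(hb[[1]]$bonded == (hb[[1]]$distance <= 3.5)))
  # square wave: occupancy 0.5
  sq <- make_interaction_trajectory(
    occupancy_spec(rep(c(TRUE, FALSE), 50)))
  hb2 <- hbond_scan(sq, select(sq$top, "name OD1"),
                    select(sq$top, "name N1"), d_cut = 3.5)
  expect_equal(hb2[[1]]$occupancy, 0.5)
  # never within cutoff: absent from output
  far <- make_interaction_trajectory(occupancy_spec(rep(FALSE, 10)))
  expect_length(hbond_scan(far, select(far$top, "name OD1"),
                           select(far$top, "name N1"), d_cut = 3.5), 0)
  expect_error(hbond_scan(far, select(far$top, "name ZZ"), acc),
               "empty donor")
})

test_that("Bernoulli-planted occupancy is recovered within 3 binomial
           standard errors", {
  p <- 0.5
  m <- 2000
  it <- make_interaction_trajectory(occupancy_spec(p, m, seed = 101))
  hb <- hbond_scan(it, select(it$top, "name OD1"),
                   select(it$top, "name N1"), d_cut = 3.5)
  se <- sqrt(p * (1 - p) / m)
  expect_lt(abs(hb[[1]]$occupancy - p), 3 * se)
  # the measured occupancy matches the realized schedule exactly
  expect_equal(hb[[1]]$occupancy, attr(it, "manifest")$occupancy)
})

test_that("dihedral series match analytic geometry and the field
           convention", {
  top <- ca_topology(4)
  mk <- function(theta_deg) {
    th <- theta_deg * pi / 180
    rbind(c(1, 0, -1), c(0, 0, 0), c(0, 0, 1), c(cos(th), sin(th), 2))
  }
  expect_equal(pair_dihedral(one_frame(top, mk(0)), 1, 2, 3, 4), 0,
               tolerance = 1e-10)
  expect_equal(pair_dihedral(one_frame(top, mk(180)), 1, 2, 3, 4), 180,
               tolerance = 1e-10)
  expect_equal(pair_dihedral(one_frame(top, mk(120)), 1, 2, 3, 4), 120,
               tolerance = 1e-6)
  expect_equal(pair_dihedral(one_frame(top, mk(-120)), 1, 2, 3, 4), -120,
               tolerance = 1e-6)
  # collinear middle bond: undefined, reported as NA
  collinear <- rbind(c(0, 0, -1), c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  expect_true(is.na(pair_dihedral(one_frame(top, collinear), 1, 2, 3, 4)))
  expect_error(pair_dihedral(one_frame(top, mk(10)), 1, 2, 2, 4),
               "distinct")
})

test_that("dihedrals agree with the bio3d torsion oracle", {
  skip_if_not_installed("bio3d")
  set.seed(41)
  top <- ca_topology(4)
  for (k in 1:10) {
    co <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- pair_dihedral(one_frame(top, co), 1, 2, 3, 4)
    ref <- bio3d::torsion.xyz(as.numeric(t(co)))
    if (!is.na(mine) && !is.na(ref))
      expect_equal(mine, as.numeric(ref), tolerance = 1e-6)
  }
})

test_that("hydration sites report planted occupancy and episodes", {
  # water fixed in the site for all frames: one site, occupancy 1,
  # one episode spanning the trajectory
  it <- make_interaction_trajectory(occupancy_spec(rep(TRUE, 50)))
  hs <- hydration_sites(it, c(10, 0, 0), region_radius = 5)
  expect_length(hs, 1)
  expect_equal(hs[[1]]$occupancy, 1.0)
  expect_equal(nrow(hs[[1]]$residence_episodes), 1)
  expect_equal(hs[[1]]$residence_episodes$start_ps, it$times[1])
  expect_equal(hs[[1]]$residence_episodes$end_ps, it$times[50])
  # present first half only: occupancy 0.5, one half-length episode
  half <- make_interaction_trajectory(
    occupancy_spec(rep(c(TRUE, FALSE), each = 50)))
  hs2 <- hydration_sites(half, c(10, 0, 0), region_radius = 5)
  expect_equal(hs2[[1]]$occupancy, 0.5)
  expect_equal(nrow(hs2[[1]]$residence_episodes), 1)
  expect_equal(hs2[[1]]$residence_episodes$end_ps -
                 hs2[[1]]$residence_episodes$start_ps,
               diff(range(half$times)) / 2, tolerance = 0.05)
  expect_error(hydration_sites(blob_trajectory(5, 3, seed = 1),
                               c(0, 0, 0)), "no water")
})

test_that("swapping waters give molecule-resolved episodes and gaps
           merge within tolerance", {
  # two waters alternate in the same site with no vacant frame
  m <- 40
  site <- c(10, 0, 0)
  park <- c(30, 30, 30)
  top <- topology(data.frame(
    serial = 1:2, name = "OW", resname = "HOH", resid = 1:2,
    chain = "W", element = "O", molecule = "water", mass = 15.999))
  xyz <- t(vapply(seq_len(m), function(f) {
    if (f %% 2 == 1) as.numeric(t(rbind(site, park)))
    else as.numeric(t(rbind(park, site)))
  }, numeric(6)))
  swap <- trajectory(top, xyz)
  hs <- hydration_sites(swap, site, region_radius = 5, gap_tolerance = 0)
  expect_length(hs, 1)
  expect_equal(hs[[1]]$occupancy, 1.0)
  # 2 molecules x episodes; with zero gap tolerance each visit separate
  expect_equal(nrow(hs[[1]]$residence_episodes), m)
  # with gap tolerance 1 the alternating visits merge per molecule
  hs2 <- hydration_sites(swap, site, region_radius = 5, gap_tolerance = 1)
  expect_equal(nrow(hs2[[1]]$residence_episodes), 2)
  # episodes of one molecule never overlap and cover its occupied frames
  ep <- hs2[[1]]$residence_episodes
  for (w in unique(ep$water)) {
    e <- ep[ep$water == w, ]
    e <- e[order(e$start_ps), ]
    if (nrow(e) > 1)
      expect_true(all(e$start_ps[-1] > e$end_ps[-nrow(e)]))
  }
})

test_that("coordination geometry reports distances, angle sums and
           planarity", {
  # perfect square-planar 4-coordination
  top <- topology(data.frame(
    serial = 1:5, name = c("MG", rep("OD1", 4)),
    resname = c("MG", rep("ASP", 4)), resid = 1:5, chain = "A",
    element = c("MG", rep("O", 4)), molecule = c("ion",
                                                 rep("protein", 4)),
    mass = c(24.3, rep(16, 4))))
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(-2, 0, 0),
              c(0, -2, 0))
  traj <- one_frame(top, sq)
  partners <- select(top, "name OD1")
  rep1 <- coordination_geometry(traj, 1, partners, cutoff = 3)
  expect_equal(rep1$angle_sum, 360, tolerance = 1e-6)
  expect_equal(rep1$out_of_plane, 0, tolerance = 1e-8)
  expect_equal(rep1$pairs$mean_A, rep(2, 4), tolerance = 1e-10)
  expect_equal(rep1$pairs$sd_A, rep(0, 4))
  # center lifted h above a planar triad
  h <- 1.2
  tri <- rbind(c(0, 0, h), c(2, 0, 0), c(-1, 1.732, 0), c(-1, -1.732, 0))
  top3 <- topology(data.frame(
    serial = 1:4, name = c("MG", rep("OD1", 3)),
    resname = c("MG", rep("ASP", 3)), resid = 1:4, chain = "A",
    element = c("MG", rep("O", 3)), mass = 16))
  rep2 <- coordination_geometry(one_frame(top3, tri), 1,
                                select(top3, "name OD1"), cutoff = 4)
  expect_equal(rep2$out_of_plane, h, tolerance = 1e-8)
  expect_lt(rep2$angle_sum, 360)
  expect_error(coordination_geometry(traj, 1, partners, cutoff = 0.5),
               "within cutoff")
})

test_that("channel metrics follow projection geometry", {
  top <- ca_topology(6)
  a <- 2
  # square perpendicular to the axis: area a^2
  sq <- rbind(c(0, 0, 0), c(a, 0, 0), c(a, a, 0), c(0, a, 0))
  co <- rbind(c(-5, 0, 0), c(5, 0, 0), sq)
  traj <- one_frame(top, co)
  s1 <- select(top, "resid 1"); s2 <- select(top, "resid 2")
  en <- select(top, "resid 3-6")
  cm <- channel_metrics(traj, 1, s1, s2, en, axis = c(0, 0, 1))
  expect_equal(cm$entrance_area, a^2, tolerance = 1e-10)
  expect_equal(cm$centroid_distance, 10, tolerance = 1e-10)
  # square tilted 60 degrees to the projection plane: area a^2 / 2
  tilt <- rbind(c(0, 0, 0), c(a, 0, 0),
                c(a, a * cos(pi / 3), a * sin(pi / 3)),
                c(0, a * cos(pi / 3), a * sin(pi / 3)))
  co2 <- rbind(c(-5, 0, 0), c(5, 0, 0), tilt)
  cm2 <- channel_metrics(one_frame(top, co2), 1, s1, s2, en,
                         axis = c(0, 0, 1))
  expect_equal(cm2$entrance_area, a^2 / 2, tolerance = 1e-10)
  expect_error(channel_metrics(traj, 1, s1, s2, select(top, "resid 3-4")),
               "3 entrance atoms")
})

test_that("geometric outputs are invariant under global rigid
           transforms", {
  set.seed(43)
  it <- make_interaction_trajectory(occupancy_spec(0.4, 60, seed = 3))
  rt <- random_rigid()
  it2 <- transform_trajectory(it, rt)
  hb <- hbond_scan(it, select(it$top, "name OD1"),
                   select(it$top, "name N1"), d_cut = 3.5)
  hb2 <- hbond_scan(it2, select(it2$top, "name OD1"),
                    select(it2$top, "name N1"), d_cut = 3.5)
  expect_equal(hb[[1]]$distance, hb2[[1]]$distance, tolerance = 1e-8)
  expect_equal(hb[[1]]$occupancy, hb2[[1]]$occupancy)
  top <- ca_topology(4)
  co <- matrix(rnorm(12, sd = 3), 4, 3)
  d1 <- pair_dihedral(one_frame(top, co), 1, 2, 3, 4)
  d2 <- pair_dihedral(one_frame(top, apply_rigid(co, rt)), 1, 2, 3, 4)
  expect_equal(d1, d2, tolerance = 1e-8)
})
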
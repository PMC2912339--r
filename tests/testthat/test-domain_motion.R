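# Domain decomposition and hinge parameters on planted fixtures.

make_hinge_pair <- function(amplitude, seed = 7, n_fixed = 100,
                            n_moving = 80) {
  spec <- hinge_spec(n_fixed = n_fixed, n_moving = n_moving,
                     amplitude = amplitude, seed = seed, n_frames = 2,
                     motion = "two-state")
  chain <- make_two_domain_chain(spec)
  traj <- make_hinge_trajectory(chain, spec)
  list(confA = frame_coords(traj, 1), confB = frame_coords(traj, 2),
       spec = spec)
}

test_that("rotation field is zero for identical conformers and uniform for
           rigid rotation", {
  set.seed(31)
  conf <- matrix(rnorm(90, sd = 5), 30, 3)
  f0 <- local_rotation_field(conf, conf)
  expect_lt(max(f0$angle), 1e-4)
  r <- rotation_about(c(1, 1, 0), 30)
  f1 <- local_rotation_field(conf, conf %*% t(r))
  expect_lt(max(abs(f1$angle - 30)), 1e-6)
  expect_error(local_rotation_field(conf[1:3, ], conf[1:3, ], window = 5),
               "shorter than window")
  expect_error(local_rotation_field(conf, conf, window = 4), "odd")
})

test_that("two-domain fixture produces a bimodal rotation field", {
  fx <- make_hinge_pair(25)
  field <- local_rotation_field(fx$confA, fx$confB)
  n <- fx$spec$n_fixed + fx$spec$n_moving
  core_fixed <- field$angle[1:(fx$spec$n_fixed - 3)]
  core_moving <- field$angle[(fx$spec$n_fixed + 4):n]
  expect_lt(max(core_fixed), 0.5)
  expect_lt(max(abs(core_moving - 25)), 0.5)
})

test_that("rigid motion partitions into a single domain", {
  set.seed(32)
  conf <- matrix(rnorm(150, sd = 6), 50, 3)
  r <- rotation_about(c(0, 1, 0), 18)
  field <- local_rotation_field(conf, conf %*% t(r))
  part <- partition_domains(field)
  expect_equal(length(part$moving_domains), 0)
  expect_equal(length(part$fixed_domain), 50)
})

test_that("planted hinge partitions into two domains with a localized
           pivot", {
  fx <- make_hinge_pair(25)
  field <- local_rotation_field(fx$confA, fx$confB)
  part <- partition_domains(field)
  expect_equal(length(part$moving_domains), 1)
  expect_equal(length(part$fixed_domain) +
                 length(part$moving_domains[[1]]) >= 170, TRUE)
  pivot_est <- stats::median(part$hinge_residues[[1]])
  expect_lte(abs(pivot_est - fx$spec$pivot_residue), 2)
})

test_that("three-domain fixture (two independent axes) yields three
           domains", {
  set.seed(33)
  spec <- hinge_spec(n_fixed = 60, n_moving = 40, amplitude = 25,
                     seed = 11, n_frames = 2, motion = "two-state")
  chain <- make_two_domain_chain(spec)
  confA <- chain$ref
  # graft a third lobe beyond the moving one and rotate it about its own axis
  third <- sweep(trajscope:::.random_lobe(40, 10, c(0, 0, 0)), 2,
                 c(2 * max(confA[, 1]), 0, 0), "+")
  confA <- rbind(confA, third)
  confB <- confA
  mov1 <- 61:100
  piv1 <- confA[60, ]
  r1 <- rotation_about(c(0, 0, 1), 25)
  confB[mov1, ] <- sweep(sweep(confB[mov1, , drop = FALSE], 2, piv1) %*%
                           t(r1), 2, piv1, "+")
  mov2 <- 101:140
  piv2 <- confA[100, ]
  r2 <- rotation_about(c(0, 1, 0), 12)
  confB[mov2, ] <- sweep(sweep(confB[mov2, , drop = FALSE], 2, piv2) %*%
                           t(r2), 2, piv2, "+")
  field <- local_rotation_field(confA, confB)
  part <- partition_domains(field, min_domain = 20, cluster_radius = 4)
  expect_equal(length(part$moving_domains), 2)  # fixed + two moving = 3
})

test_that("hinge parameters recover planted angles across amplitudes", {
  for (amp in c(5, 12, 25)) {
    rec <- recover_hinge(amp, noise_sigma = 0)
    expect_lt(abs(rec$angle - amp), 0.5)
    expect_lte(abs(rec$pivot - rec$spec$pivot_residue), 2)
  }
})

test_that("hinge parameters tolerate thermal jitter", {
  for (amp in c(5, 12, 25)) {
    rec <- recover_hinge(amp, noise_sigma = 0.3, seed = 19)
    expect_lt(abs(rec$angle - amp), 1.5)
  }
  rec25 <- recover_hinge(25, noise_sigma = 0.3, seed = 7)
  expect_lte(abs(rec25$pivot - rec25$spec$pivot_residue), 2)
})

test_that("the planted 25.6-degree hinge is recovered within half a
           degree", {
  rec <- recover_hinge(25.6, noise_sigma = 0)
  expect_lt(abs(rec$angle - 25.6), 0.5)
})

test_that("closure distinguishes pure closure from pure twist", {
  fx <- make_hinge_pair(20)
  field <- local_rotation_field(fx$confA, fx$confB)
  part <- partition_domains(field, cluster_radius = 8)
  mov_idx <- which(seq_len(180) %in% part$moving_domains[[1]])
  fix_idx <- which(seq_len(180) %in% part$fixed_domain)
  g_fix <- colMeans(fx$confA[fix_idx, ])
  g_mov <- colMeans(fx$confA[mov_idx, ])
  dhat <- (g_mov - g_fix); dhat <- dhat / sqrt(sum(dhat^2))
  pivot <- fx$confA[fx$spec$pivot_residue, ]
  # pure closure: rotate the moving lobe about an axis perpendicular to
  # the interdomain line through the pivot
  perp <- trajscope:::.cross3(dhat, c(0, 0, 1))
  perp <- perp / sqrt(sum(perp^2))
  confC <- fx$confA
  rc <- rotation_about(perp, 20)
  confC[mov_idx, ] <- sweep(sweep(confC[mov_idx, , drop = FALSE], 2,
                                  pivot) %*% t(rc), 2, pivot, "+")
  hp_close <- hinge_parameters(fx$confA, confC, part, 1)
  expect_gt(hp_close$closure, 95)
  # pure twist: rotate about the centroid line itself
  confT <- fx$confA
  rt <- rotation_about(dhat, 20)
  confT[mov_idx, ] <- sweep(sweep(confT[mov_idx, , drop = FALSE], 2,
                                  g_mov) %*% t(rt), 2, g_mov, "+")
  hp_twist <- hinge_parameters(fx$confA, confT, part, 1)
  expect_lt(hp_twist$closure, 5)
  expect_lt(abs(hp_close$closure + hp_twist$closure - 100), 5)
  expect_true(hp_close$closure >= 0 && hp_close$closure <= 100)
  # degenerate rotation reports closure as missing
  hp0 <- hinge_parameters(fx$confA, fx$confA, part, 1)
  expect_lt(hp0$rotation_angle, 0.1)
  expect_true(is.na(hp0$closure))
})

test_that("screw translation along the axis is recovered", {
  fx <- make_hinge_pair(15)
  field <- local_rotation_field(fx$confA, fx$confB)
  part <- partition_domains(field, cluster_radius = 6)
  mov_idx <- which(seq_len(180) %in% part$moving_domains[[1]])
  pivot <- fx$confA[fx$spec$pivot_residue, ]
  confS <- fx$confA
  rs <- rotation_about(c(0, 0, 1), 15)
  confS[mov_idx, ] <- sweep(sweep(confS[mov_idx, , drop = FALSE], 2,
                                  pivot) %*% t(rs), 2, pivot, "+")
  confS[mov_idx, 3] <- confS[mov_idx, 3] + 2.5   # screw along +z
  hp <- hinge_parameters(fx$confA, confS, part, 1)
  expect_equal(abs(hp$translation), 2.5, tolerance = 0.05)
  expect_equal(hp$rotation_angle, 15, tolerance = 0.2)
})

test_that("partition and hinge parameters are invariant to a global rigid
           transform", {
  fx <- make_hinge_pair(25)
  field <- local_rotation_field(fx$confA, fx$confB)
  part <- partition_domains(field)
  hp <- hinge_parameters(fx$confA, fx$confB, part, 1)
  set.seed(35)
  rt <- random_rigid()
  confA2 <- apply_rigid(fx$confA, rt)
  confB2 <- apply_rigid(fx$confB, rt)
  field2 <- local_rotation_field(confA2, confB2)
  part2 <- partition_domains(field2)
  expect_equal(part2$fixed_domain, part$fixed_domain)
  expect_equal(part2$moving_domains, part$moving_domains)
  hp2 <- hinge_parameters(confA2, confB2, part2, 1)
  expect_equal(hp2$rotation_angle, hp$rotation_angle, tolerance = 1e-6)
  expect_equal(hp2$closure, hp$closure, tolerance = 1e-4)
  expect_equal(hp2$translation, hp$translation, tolerance = 1e-6)
})
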
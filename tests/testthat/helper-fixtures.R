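# Shared fixture builders: tiny topologies and trajectories constructed in
# code (no binary fixtures on disk).

# bare C-alpha chain topology, one atom per residue
ca_topology <- function(n, chain = "A", molecule = "protein") {
  topology(data.frame(serial = seq_len(n), name = "CA", resname = "ALA",
                      resid = seq_len(n), chain = chain, element = "C",
                      molecule = molecule, mass = 12.011))
}

# random 3-D blob trajectory around a fixed base structure
blob_trajectory <- function(n_atoms, n_frames, sigma = 0, seed = 1) {
  set.seed(seed)
  base <- matrix(rnorm(3 * n_atoms, sd = 4), n_atoms, 3)
  xyz <- t(vapply(seq_len(n_frames), function(f)
    as.numeric(t(base + matrix(rnorm(3 * n_atoms, sd = sigma),
                               n_atoms, 3))),
    numeric(3 * n_atoms)))
  trajectory(ca_topology(n_atoms), xyz)
}

# fully parameterized point-charge topology
charged_topology <- function(q, sigma = 3.4, eps = 0.1, rho = 1.7,
                             rvdw = 1.7, mass = 12.011,
                             molecule = "protein") {
  n <- length(q)
  topology(data.frame(serial = seq_len(n), name = "DU", resname = "DUM",
                      resid = seq_len(n), chain = "A", element = "C",
                      molecule = molecule, charge = q, lj_sigma = sigma,
                      lj_epsilon = eps, born_radius = rho,
                      vdw_radius = rvdw, mass = mass))
}

one_frame <- function(top, coords) {
  trajectory(top, matrix(as.numeric(t(coords)), 1), times = 0)
}

rotation_about <- function(axis, angle_deg) {
  trajscope:::.rotation_matrix(axis, angle_deg)
}

random_rigid <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(r = rotation_about(ax, runif(1, 0, 360)), t = rnorm(3, sd = 10))
}

apply_rigid <- function(coords, rt) {
  sweep(coords %*% t(rt$r), 2, rt$t, "+")
}

# apply one rigid transform to every frame of a trajectory
transform_trajectory <- function(traj, rt) {
  m <- n_frames(traj)
  xyz <- t(vapply(seq_len(m), function(f)
    as.numeric(t(apply_rigid(frame_coords(traj, f), rt))),
    numeric(ncol(traj$xyz))))
  if (m == 1) xyz <- matrix(xyz, nrow = 1)
  trajectory(traj$top, xyz, times = traj$times)
}

# standard hinge-recovery helper used by unit and acceptance tests
recover_hinge <- function(amplitude, noise_sigma, seed = 7, window = 5,
                          cluster_radius = max(2, amplitude / 2),
                          average = if (noise_sigma > 0) 10 else 1,
                          n_frames = 200) {
  spec <- hinge_spec(amplitude = amplitude, noise_sigma = noise_sigma,
                     n_frames = n_frames, seed = seed)
  chain <- make_two_domain_chain(spec)
  traj <- make_hinge_trajectory(chain, spec)
  model <- build_covariance(traj, equilibration_drop = 0)
  ser <- project(traj, model, 1)
  ext <- extreme_conformers(ser, traj, model, 1, average = average)
  field <- local_rotation_field(ext$min_structure, ext$max_structure,
                                window = window)
  part <- partition_domains(field, cluster_radius = cluster_radius)
  big <- which.max(vapply(part$moving_domains, length, numeric(1)))
  hp <- hinge_parameters(ext$min_structure, ext$max_structure, part, big)
  list(angle = hp$rotation_angle,
       pivot = stats::median(part$hinge_residues[[big]]),
       partition = part, hinge = hp, spec = spec)
}
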
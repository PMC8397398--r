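test_that("Coulomb pair energies follow u q_i q_j / r with open boundaries", {
  cfg_pp <- sim_config(charge_sequence(c(1, 1)), u = 1, bond_model = "harmonic",
                       pair_on = FALSE)
  e <- compute_energy(rbind(c(0, 0, 0), c(2, 0, 0)), cfg_pp)
  expect_equal(e$coulomb, 0.5)
  cfg_pm <- sim_config(charge_sequence(c(1, -1)), u = 2, bond_model = "harmonic",
                       pair_on = FALSE)
  expect_equal(compute_energy(rbind(c(0, 0, 0), c(1, 0, 0)), cfg_pm)$coulomb, -2)
  # neutral chain has exactly zero Coulomb energy
  cfg_n <- sim_config(charge_sequence(integer(10)), u = 1)
  fr <- initial_conformation(10, seed = 3)
  expect_identical(compute_energy(fr, cfg_n)$coulomb, 0)
  # overlapping charged beads are singular
  cfg_ov <- sim_config(charge_sequence(c(1, 1)), u = 1, bond_model = "harmonic")
  expect_error(compute_energy(rbind(c(0, 0, 0), c(1e-9, 0, 0)), cfg_ov),
               "singular")
})

test_that("analytic forces match the numerical energy gradient", {
  set.seed(4)
  sq <- generate_sequence(markov_spec(12, 1, 0.5, seed = 6))
  for (bm in c("fene", "harmonic")) {
    cfg <- sim_config(sq, u = 1.5, bond_model = bm)
    fr <- initial_conformation(12, seed = 8)
    f_ana <- compute_forces(fr, cfg)
    f_num <- numerical_forces(fr, cfg)
    expect_lt(max(abs(f_ana - f_num)) / max(abs(f_ana)), 1e-5)
  }
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  sq <- generate_sequence(markov_spec(24, 1, 0, seed = 10))
  cfg <- sim_config(sq, u = 1, n_steps = 2000, n_equil = 500, save_every = 500,
                    seed = 33)
  t1 <- suppressWarnings(run_langevin(cfg))
  t2 <- suppressWarnings(run_langevin(cfg))
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$energies, t2$energies)
  cfg2 <- sim_config(sq, u = 1, n_steps = 2000, n_equil = 500, save_every = 500,
                     seed = 34)
  t3 <- suppressWarnings(run_langevin(cfg2))
  expect_false(identical(t1$frames[[1]], t3$frames[[1]]))
})

test_that("the timestep stability bound is enforced", {
  sq <- charge_sequence(integer(8))
  expect_error(sim_config(sq, timestep = 0.05), "stability bound")
  expect_silent(sim_config(sq, timestep = 0.05, timestep_max = 0.05))
})

test_that("harmonic dimer reproduces the Boltzmann bond statistics", {
  cfg <- sim_config(charge_sequence(c(0, 0)), u = 0, bond_model = "harmonic",
                    bond_k = 3, bond_r0 = 0, pair_on = FALSE,
                    n_steps = 4e5, n_equil = 2e4, save_every = 200, seed = 11)
  tr <- suppressWarnings(run_langevin(cfg))
  b2 <- vapply(tr$frames, function(fr) sum((fr[2, ] - fr[1, ])^2), 0)
  # <b^2> = 3 kT / k = 1
  expect_lt(abs(mean(b2) - 1), 3 * sd(b2) / sqrt(length(b2) / 2))
})

test_that("kinetic energy equipartitions to kT/2 per degree of freedom", {
  sq <- generate_sequence(markov_spec(32, 1, 0, seed = 14))
  cfg <- sim_config(sq, u = 1, n_steps = 1e5, n_equil = 1e4, save_every = 100,
                    seed = 15)
  tr <- suppressWarnings(run_langevin(cfg))
  ke_per_dof <- mean(tr$energies$kinetic) / (3 * 32)
  expect_lt(abs(ke_per_dof - 0.5) / 0.5, 0.02)
})

test_that("collapsed alternating chains grow slower than ideal coils", {
  # alternating polyampholytes form globules: Rg ~ N^(1/3) << N^(1/2)
  rg <- vapply(c(32, 64, 128), function(N) {
    sq <- generate_sequence(markov_spec(N, 1, -1, seed = N))
    cfg <- sim_config(sq, u = 1, n_steps = 30000, n_equil = 30000,
                      save_every = 1000, seed = N + 1)
    mean(suppressWarnings(run_langevin(cfg))$rg)
  }, 0)
  exponents <- diff(log(rg)) / diff(log(c(32, 64, 128)))
  expect_true(all(exponents < 0.5))
})

test_that("XYZ and PDB writers round-trip coordinates and charges", {
  sq <- generate_sequence(markov_spec(16, 1, 0, seed = 20))
  cfg <- sim_config(sq, u = 1, n_steps = 1000, n_equil = 0, save_every = 500,
                    seed = 21)
  tr <- suppressWarnings(run_langevin(cfg))
  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, xyz)
  back <- read_xyz(xyz)
  expect_length(back, length(tr$frames))
  expect_equal(back[[1]], tr$frames[[1]], tolerance = 1e-7)
  expect_equal(attr(back, "charges"), as.integer(sq))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr$frames[[1]], pdb, charges = as.integer(sq))
  lines <- readLines(pdb)
  expect_length(grep("^ATOM", lines), 16)
})
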
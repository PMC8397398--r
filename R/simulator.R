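#' Configuration of a coarse-grained Langevin simulation
#'
#' Bead-spring model of a single polyampholyte in reduced units (monomer
#' size a = 1, k_B T = 1, charge e = 1), with unscreened Coulomb
#' interactions `u q_i q_j / r_ij` between charged beads summed over all
#' pairs with open boundaries.  The default force field is Kremer-Grest
#' style: FENE bonds (k = 30, R0 = 1.5) plus a Lennard-Jones pair potential
#' (cutoff 2.5) with a near-Theta well depth `lj_eps = 0.34`, so that
#' uncharged chains are close to ideal.
#'
#' @param sequence A `charge_sequence` providing N and the bead charges.
#' @param u Dimensionless Bjerrum length (default 1).
#' @param bond_model `"fene"` or `"harmonic"`.
#' @param bond_k Bond stiffness (FENE k, or harmonic spring constant; a
#'   harmonic bond with `bond_k = 3`, `bond_r0 = 0` gives an ideal Gaussian
#'   chain with unit mean-square bond length).
#' @param bond_r0 Harmonic rest length.
#' @param fene_R0 FENE maximum extension.
#' @param lj_eps,lj_cut Lennard-Jones well depth and cutoff (sigma = 1);
#'   the potential is energy-shifted to vanish at the cutoff.
#' @param pair_on Logical: include the excluded-volume pair potential.
#' @param timestep Integration timestep (reduced time), capped at
#'   `timestep_max`.
#' @param n_steps Production steps.
#' @param n_equil Equilibration steps discarded from averages.
#' @param friction Langevin friction coefficient.
#' @param seed Integer RNG seed (thermostat noise and initial velocities,
#'   and the initial conformation).
#' @param save_every Frame stride.
#' @param timestep_max Stability bound on the timestep (default 0.01).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sequence, u = 1, bond_model = c("fene", "harmonic"),
                       bond_k = NULL, bond_r0 = 0, fene_R0 = 1.5,
                       lj_eps = 0.34, lj_cut = 2.5, pair_on = TRUE,
                       timestep = 0.01, n_steps = 10000, n_equil = 5000,
                       friction = 1, seed = 1, save_every = 100,
                       timestep_max = 0.01) {
  stopifnot(inherits(sequence, "charge_sequence"))
  bond_model <- match.arg(bond_model)
  if (is.null(bond_k)) bond_k <- if (bond_model == "fene") 30 else 3
  if (timestep > timestep_max)
    stop("timestep ", timestep, " exceeds the stability bound ", timestep_max,
         " (reduced units)", call. = FALSE)
  stopifnot(n_steps >= 1, n_equil >= 0, friction > 0, save_every >= 1)
  structure(list(sequence = sequence, u = u, bond_model = bond_model,
                 bond_k = bond_k, bond_r0 = bond_r0, fene_R0 = fene_R0,
                 lj_eps = lj_eps, lj_cut = lj_cut, pair_on = pair_on,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 n_equil = as.integer(n_equil), friction = friction,
                 seed = as.integer(seed), save_every = as.integer(save_every)),
            class = "sim_config")
}

ff_list <- function(config) {
  list(bond_type = if (config$bond_model == "fene") 1L else 0L,
       bond_k = config$bond_k, bond_r0 = config$bond_r0,
       fene_R0 = config$fene_R0, lj_eps = config$lj_eps,
       lj_cut = config$lj_cut, lj_on = config$pair_on, u = config$u)
}

#' Potential energy components of a configuration
#'
#' Bonded, excluded-volume (Lennard-Jones), and Coulomb energies of a
#' single frame, in k_B T.  The Coulomb term sums `u q_i q_j / r_ij` over
#' all charged pairs with open boundaries.
#'
#' @param frame N x 3 coordinate matrix (units of a).
#' @param config A [sim_config()].
#' @return Named list `bonded`, `excluded_volume`, `coulomb`, `total`.
#' @export
#' @examples
#' seq2 <- charge_sequence(c(1, 1))
#' cfg <- sim_config(seq2, u = 1, bond_model = "harmonic")
#' frame <- rbind(c(0, 0, 0), c(2, 0, 0))
#' compute_energy(frame, cfg)$coulomb  # u q^2 / r = 0.5
compute_energy <- function(frame, config) {
  check_frame(frame, config)
  res <- cpp_energy(frame, as.integer(config$sequence), ff_list(config))
  res[c("bonded", "excluded_volume", "coulomb", "total")]
}

#' Forces on every bead
#'
#' Analytic negative gradient of [compute_energy()].
#'
#' @inheritParams compute_energy
#' @return N x 3 matrix of forces (k_B T / a).
#' @export
compute_forces <- function(frame, config) {
  check_frame(frame, config)
  cpp_energy(frame, as.integer(config$sequence), ff_list(config))$forces
}

check_frame <- function(frame, config) {
  if (!is.matrix(frame) || ncol(frame) != 3)
    stop("frame must be an N x 3 coordinate matrix", call. = FALSE)
  if (nrow(frame) != length(config$sequence))
    stop("frame has ", nrow(frame), " beads but the sequence has ",
         length(config$sequence), call. = FALSE)
  if (any(!is.finite(frame)))
    stop("frame contains non-finite coordinates", call. = FALSE)
  invisible(TRUE)
}

#' Self-avoiding-walk initial conformation
#'
#' Random walk with unit steps that retries any step placing the new bead
#' within `min_dist` of an existing one; used to start simulations from an
#' expanded, overlap-free state.
#'
#' @param N Number of beads.
#' @param seed RNG seed.
#' @param min_dist Minimum allowed distance to previous beads (default 0.9).
#' @return N x 3 coordinate matrix.
#' @export
initial_conformation <- function(N, seed = NULL, min_dist = 0.9) {
  with_seed(seed, {
    x <- matrix(0, N, 3)
    for (i in seq_len(N - 1)) {
      for (attempt in 1:200) {
        step <- stats::rnorm(3)
        step <- step / sqrt(sum(step^2))
        cand <- x[i, ] + step
        d2 <- rowSums((x[seq_len(i), , drop = FALSE] -
                         matrix(cand, i, 3, byrow = TRUE))^2)
        if (all(d2 > min_dist^2)) break
      }
      x[i + 1, ] <- cand
    }
    x
  })
}

#' Run Langevin dynamics
#'
#' Integrates the chain with the BAOAB Langevin scheme for
#' `n_equil + n_steps` steps, starting (unless `start` is given) from a
#' self-avoiding random walk.  Trajectories are bit-reproducible for a
#' given config and seed.  Equilibration is checked on the gyration-radius
#' series: over the last third of the equilibration window, the running
#' mean of Rg must drift by less than `equil_tol` (relative); otherwise a
#' warning flags the trajectory as possibly unequilibrated.
#'
#' @param config A [sim_config()].
#' @param start Optional N x 3 starting coordinates.
#' @param equil_tol Relative drift tolerance for the equilibration check.
#' @return A `trajectory`: list with `frames` (production frames only),
#'   `times`, `rg`, `energies` (data.frame incl. kinetic energy), `config`,
#'   `equilibrated`, and the discarded equilibration Rg series `rg_equil`.
#' @export
run_langevin <- function(config, start = NULL, equil_tol = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  N <- length(config$sequence)
  if (is.null(start)) start <- initial_conformation(N, seed = config$seed)
  check_frame(start, config)
  total_steps <- config$n_equil + config$n_steps
  res <- cpp_run_langevin(start, as.integer(config$sequence), ff_list(config),
                          config$timestep, total_steps, config$friction,
                          config$seed, config$save_every)
  n_equil_frames <- config$n_equil %/% config$save_every
  idx_prod <- seq.int(n_equil_frames + 1L, length(res$times))
  rg_equil <- res$rg[seq_len(n_equil_frames)]
  equilibrated <- TRUE
  if (n_equil_frames >= 6) {
    tail3 <- rg_equil[seq.int(floor(2 * n_equil_frames / 3) + 1L,
                              n_equil_frames)]
    h <- length(tail3) %/% 2
    m1 <- mean(tail3[seq_len(h)])
    m2 <- mean(tail3[seq.int(h + 1L, length(tail3))])
    equilibrated <- abs(m2 - m1) / ((m1 + m2) / 2) < equil_tol
    if (!equilibrated)
      warning("Rg still drifting over the last third of the equilibration ",
              "window; consider increasing n_equil", call. = FALSE)
  }
  structure(list(
    frames = res$frames[idx_prod],
    times = res$times[idx_prod],
    rg = res$rg[idx_prod],
    rg_equil = rg_equil,
    energies = data.frame(time = res$times[idx_prod],
                          bonded = res$e_bond[idx_prod],
                          excluded_volume = res$e_pair[idx_prod],
                          coulomb = res$e_coul[idx_prod],
                          kinetic = res$e_kin[idx_prod]),
    final = res$final,
    config = config,
    equilibrated = equilibrated), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d production frames of %d beads, t = %.4g..%.4g\n",
              length(x$frames), nrow(x$frames[[1]]),
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  <Rg> = %.4g a, equilibrated: %s\n",
              mean(x$rg), x$equilibrated))
  invisible(x)
}

#' Write a trajectory (or single frame) in XYZ format
#'
#' Element symbols encode the bead charge: `N` (+1), `O` (-1), `C` (0).
#'
#' @param traj A `trajectory`, a list of N x 3 matrices, or one matrix.
#' @param path Output path.
#' @param charges Charges used for element labels (taken from the config
#'   when `traj` is a `trajectory`).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, charges = NULL) {
  frames <- if (inherits(traj, "trajectory")) traj$frames
            else if (is.matrix(traj)) list(traj) else traj
  if (is.null(charges) && inherits(traj, "trajectory"))
    charges <- as.integer(traj$config$sequence)
  if (is.null(charges)) charges <- integer(nrow(frames[[1]]))
  elem <- c("O", "C", "N")[charges + 2L]
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c(as.character(nrow(fr)), "polyample frame"), con)
    writeLines(sprintf("%s %.8f %.8f %.8f", elem, fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by [write_xyz()]
#'
#' @param path XYZ file path.
#' @return List of N x 3 coordinate matrices with attribute `"charges"`
#'   (recovered from the element labels).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  charges <- NULL
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    block <- lines[seq.int(i + 2L, i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    coords <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(charges))
      charges <- c(N = 1L, C = 0L, O = -1L)[vapply(parts, `[[`, "", 1L)]
    frames[[length(frames) + 1L]] <- coords
    i <- i + 2L + n
  }
  attr(frames, "charges") <- unname(charges)
  frames
}

#' Write a single frame as PDB, with charges in the B-factor column
#'
#' @param frame N x 3 coordinate matrix.
#' @param path Output path.
#' @param charges Integer charges stored in the B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(frame, path, charges = integer(nrow(frame))) {
  stopifnot(is.matrix(frame), ncol(frame) == 3,
            length(charges) == nrow(frame))
  n <- nrow(frame)
  recs <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(n), seq_len(n), frame[, 1], frame[, 2], frame[, 3],
    as.numeric(charges))
  conect <- sprintf("CONECT%5d%5d", seq_len(n - 1), seq_len(n - 1) + 1L)
  writeLines(c(recs, conect, "END"), path)
  invisible(path)
}
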
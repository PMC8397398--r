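# Independent oracles used across the suite.

# Exhaustive enumeration of Var(Q) for n Markov +/-1 signs: sums Q^2 over
# all 2^n sign sequences weighted by the Markov path probability.
enumerate_var_q <- function(lam, n) {
  p_same <- (1 + lam) / 2
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  if (n == 1) return(1)
  same <- signs[, -1, drop = FALSE] * signs[, -n, drop = FALSE] == 1
  prob <- 0.5 * apply(ifelse(same, p_same, 1 - p_same), 1, prod)
  sum(prob * rowSums(signs)^2)
}

# Closed-form mean-square gyration radius of an ideal (Gaussian) chain of
# N beads with mean-square bond length b2.
gaussian_rg2 <- function(N, b2 = 1) b2 * (N^2 - 1) / (6 * N)

# Brute-force pairwise-sum gyration radius: Rg^2 = (1/2N^2) sum_ij r_ij^2.
rg_pairwise <- function(frame) {
  n <- nrow(frame)
  d2 <- as.matrix(stats::dist(frame))^2
  sqrt(sum(d2) / (2 * n^2))
}

# Central-difference gradient of the total potential energy.
numerical_forces <- function(frame, config, h = 1e-6) {
  g <- matrix(0, nrow(frame), 3)
  for (i in seq_len(nrow(frame))) {
    for (d in 1:3) {
      fp <- frame; fp[i, d] <- fp[i, d] + h
      fm <- frame; fm[i, d] <- fm[i, d] - h
      g[i, d] <- -(compute_energy(fp, config)$total -
                     compute_energy(fm, config)$total) / (2 * h)
    }
  }
  g
}

# Random rigid motion (rotation + translation) of a frame.
rigid_motion <- function(frame, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  sweep(frame %*% q, 2, rnorm(3, sd = 5), `+`)
}

# Minimal trajectory object for analysis tests that need no dynamics.
fake_trajectory <- function(frames, rg = vapply(frames, radius_of_gyration, 0)) {
  structure(list(frames = frames, times = seq_along(frames),
                 rg = rg, equilibrated = TRUE), class = "trajectory")
}
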
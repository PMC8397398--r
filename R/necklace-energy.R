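#' Necklace free energy for a given bead count and charge partition
#'
#' Scaling-level free energy (in `k_B T`, unit prefactors) of a necklace of
#' `n_beads` beads joined by `n_beads` strings, carrying the chain's
#' characteristic charge `Q = sqrt(f N Lambda)` split between beads and
#' strings by `q_str_frac`:
#' per bead, the Coulomb self-energy `u Q_bead^2 / D_bead` and surface
#' energy `(D_bead / xi)^2`; per string, the surface/stretching energy
#' `l_str / xi`, the string Coulomb self-energy `u Q_str^2 / l_str`, and
#' (between neighboring beads) the bead-bead repulsion
#' `u Q_bead^2 / l_str`.  The bead interior has the globule density `phi`
#' of [globule_density()] (`xi = 1/phi`, `D_bead = (m_bead/phi)^(1/3)`); the
#' string is one concentration blob thick, so `m_str = l_str * xi`.
#' Monomers are conserved: `n_beads * (m_bead + m_str) = N`.
#'
#' Charge placement respects the quenched sequence statistics: a string can
#' carry at most one uncompensated block, `Q_str <= Lambda`, and no more
#' charge than it has ionic monomers, `Q_str <= f m_str` (likewise
#' `Q_bead <= f m_bead`).  When `m_str` is not supplied it is optimized
#' internally on a log grid with local refinement.
#'
#' @param params A [scaling_params()].
#' @param n_beads Number of beads (and strings), integer `>= 1`.
#' @param q_str_frac Fraction of the net charge residing in strings, in
#'   [0, 1].
#' @param m_str Monomers per string; `NULL` (default) minimizes over it.
#' @return List of class `necklace_free_energy` with components
#'   `F_coul_bead`, `F_surf`, `F_el`, `F_coul_rep`, `F_coul_str`, `total`,
#'   the geometry used (`m_bead`, `m_str`, `D_bead`, `l_str`), and a
#'   `feasible` flag (`total = Inf` when the partition violates the charge
#'   caps).
#' @export
necklace_free_energy <- function(params, n_beads, q_str_frac, m_str = NULL) {
  stopifnot(inherits(params, "scaling_params"))
  stopifnot(n_beads >= 1, n_beads == round(n_beads))
  stopifnot(q_str_frac >= 0, q_str_frac <= 1)
  u <- params$u; f <- params$f; N <- params$N
  phi <- suppressWarnings(globule_density(params))
  xi <- 1 / phi
  Q <- characteristic_charge(f, N, Lambda = params$Lambda)
  Q_bead <- (1 - q_str_frac) * Q / n_beads
  Q_str <- q_str_frac * Q / n_beads

  eval_at <- function(ms) {
    mb <- N / n_beads - ms
    if (mb <= 0) return(NULL)
    D <- (mb / phi)^(1 / 3)
    ls <- ms / xi
    feas <- Q_str <= params$Lambda + 1e-12 &&
      Q_str <= f * ms + 1e-12 && Q_bead <= f * mb + 1e-12
    F_coul_bead <- n_beads * u * Q_bead^2 / D
    F_surf <- n_beads * (D / xi)^2 + n_beads * ls / xi
    F_el <- n_beads * ls / xi  # same scaling as the string surface term
    F_coul_rep <- if (n_beads >= 2 && ls > 0)
      (n_beads - 1) * u * Q_bead^2 / ls else
      if (n_beads >= 2) Inf else 0
    F_coul_str <- if (Q_str > 0) {
      if (ls > 0) n_beads * u * Q_str^2 / ls else Inf
    } else 0
    total <- if (feas) F_coul_bead + F_surf + F_coul_rep + F_coul_str else Inf
    list(F_coul_bead = F_coul_bead, F_surf = F_surf, F_el = F_el,
         F_coul_rep = F_coul_rep, F_coul_str = F_coul_str, total = total,
         m_bead = mb, m_str = ms, D_bead = D, l_str = ls,
         phi = phi, Q_bead = Q_bead, Q_str = Q_str, n_beads = n_beads,
         feasible = feas)
  }

  if (!is.null(m_str)) {
    res <- eval_at(m_str)
    if (is.null(res))
      stop("infeasible partition: m_bead = N/n_beads - m_str is not positive",
           call. = FALSE)
    return(structure(res, class = "necklace_free_energy"))
  }

  # minimize over m_str: coarse log grid, then golden-section refinement
  ms_max <- N / n_beads * (1 - 1e-6)
  ms_min <- max(Q_str / f, xi^2 * 1e-6, ms_max * 1e-9)
  grid <- if (q_str_frac == 0 && n_beads == 1) {
    0  # single-bead globule limit: no string
  } else {
    exp(seq(log(max(ms_min, 1e-12)), log(ms_max), length.out = 200))
  }
  best <- NULL
  if (identical(grid, 0)) {
    best <- eval_at(1e-12)  # vanishing string
    best$m_str <- 0; best$l_str <- 0
    best$F_surf <- best$n_beads * (best$D_bead / xi)^2
    best$F_el <- 0; best$F_coul_str <- 0; best$F_coul_rep <- 0
    best$total <- if (best$feasible) best$F_coul_bead + best$F_surf else Inf
  } else {
    vals <- lapply(grid, eval_at)
    tot <- vapply(vals, function(v) if (is.null(v)) Inf else v$total, 0)
    k <- which.min(tot)
    best <- vals[[k]]
    if (is.finite(tot[k])) {
      lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
      opt <- stats::optimize(function(ms) {
        v <- eval_at(ms); if (is.null(v)) Inf else v$total
      }, lower = lo, upper = hi)
      cand <- eval_at(opt$minimum)
      if (!is.null(cand) && cand$total <= best$total) best <- cand
    }
  }
  structure(best, class = "necklace_free_energy")
}

#' @export
print.necklace_free_energy <- function(x, ...) {
  cat(sprintf(
    "Necklace free energy: total = %.4g kT (%d beads, Q_str = %.3g e/string)\n",
    x$total, x$n_beads, x$Q_str))
  cat(sprintf("  coul bead %.4g | surface %.4g | bead-bead %.4g | coul str %.4g\n",
              x$F_coul_bead, x$F_surf, x$F_coul_rep, x$F_coul_str))
  cat(sprintf("  m_bead %.4g  m_str %.4g  D_bead %.4g a  l_str %.4g a\n",
              x$m_bead, x$m_str, x$D_bead, x$l_str))
  invisible(x)
}

#' Minimize the necklace free energy over bead count and charge partition
#'
#' Dense grid search over `n_beads` (log-spaced integers up to `n_max`) and
#' `q_str_frac` (uniform grid), each cell minimized over the string mass by
#' [necklace_free_energy()].
#'
#' @param params A [scaling_params()].
#' @param n_max Largest bead count scanned (default: generous multiple of
#'   the predicted bead count).
#' @param qf_grid Grid of string-charge fractions (default 0 to 1 in steps
#'   of 0.025).
#' @return List with the optimal `n_beads`, `q_str_frac`, the minimizing
#'   `necklace_free_energy`, and the full `grid` data.frame.
#' @export
minimize_necklace <- function(params, n_max = NULL, qf_grid = seq(0, 1, 0.025)) {
  stopifnot(inherits(params, "scaling_params"))
  if (is.null(n_max)) {
    pred <- suppressWarnings(predict_conformation(params))
    n_max <- max(8, ceiling(4 * max(1, pred$N_bead)))
  }
  n_grid <- unique(pmax(1L, round(exp(seq(0, log(n_max), length.out = 40)))))
  cells <- expand.grid(n = n_grid, qf = qf_grid)
  res <- mapply(function(n, qf) {
    v <- necklace_free_energy(params, n, qf)
    v$total
  }, cells$n, cells$qf)
  k <- which.min(res)
  best <- necklace_free_energy(params, cells$n[k], cells$qf[k])
  list(n_beads = cells$n[k], q_str_frac = cells$qf[k], energy = best,
       grid = cbind(cells, total = res))
}

#' Locate the bead-to-string charge-migration crossover numerically
#'
#' For each `Lambda` on a grid, minimizes the necklace free energy and
#' records the optimal string-charge fraction; returns the `Lambda` at
#' which it first exceeds 1/2, for comparison with the closed-form boundary
#' `Lambda_b/s` of [regime_boundaries()].
#'
#' @param u,f,N Scaling parameters.
#' @param Lambda_grid Increasing grid of blockiness values to scan.
#' @return List with `Lambda_cross` (geometric midpoint of the bracketing
#'   grid points, `NA` if no crossing), `L_bs` (closed form), and the scan
#'   `table`.
#' @export
charge_migration_crossing <- function(u, f, N,
                                      Lambda_grid = NULL) {
  b <- regime_boundaries(scaling_params(u, f, N, Lambda = 1))
  if (is.null(Lambda_grid))
    Lambda_grid <- exp(seq(log(b$L_bs / 10), log(b$L_bs * 10),
                           length.out = 25))
  qf <- vapply(Lambda_grid, function(L) {
    m <- minimize_necklace(suppressWarnings(scaling_params(u, f, N, Lambda = L)))
    m$q_str_frac
  }, 0)
  tab <- data.frame(Lambda = Lambda_grid, q_str_frac = qf)
  above <- qf > 0.5
  Lambda_cross <- NA_real_
  if (any(above) && any(!above)) {
    k <- which(above)[1L]
    if (k > 1L) Lambda_cross <- sqrt(Lambda_grid[k - 1L] * Lambda_grid[k])
    else Lambda_cross <- Lambda_grid[1L]
  } else if (all(above)) Lambda_cross <- Lambda_grid[1L]
  list(Lambda_cross = Lambda_cross, L_bs = b$L_bs, table = tab)
}
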
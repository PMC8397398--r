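#' Scaling parameters for a Markov polyampholyte
#'
#' Bundle of the dimensionless control parameters of the scaling theory:
#' reduced Bjerrum length `u = l_B / a`, ionic fraction `f`, chain length
#' `N`, and charge blockiness `Lambda` (or the correlation parameter `lam`
#' from which it follows).  All lengths produced downstream are in units of
#' the monomer size `a`, all energies in `k_B T`, all charges in `e`.
#'
#' @param u Dimensionless Bjerrum length, `u > 0`.
#' @param f Ionic fraction in (0, 1].
#' @param N Chain length in monomers.
#' @param Lambda Blockiness, `Lambda >= 0`; overrides `lam` if given.
#' @param lam Correlation parameter in [-1, 1), used when `Lambda` missing.
#' @return An object of class `scaling_params`.
#' @export
#' @examples
#' scaling_params(u = 1, f = 1/16, N = 1e4, Lambda = 1)
scaling_params <- function(u, f, N, Lambda = NULL, lam = NULL) {
  stopifnot(is.numeric(u), length(u) == 1L, u > 0)
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1)
  if (is.null(Lambda)) {
    if (is.null(lam)) stop("supply either 'Lambda' or 'lam'", call. = FALSE)
    Lambda <- blockiness_quiet(lam)
  }
  stopifnot(is.numeric(Lambda), length(Lambda) == 1L, Lambda >= 0)
  if (is.finite(Lambda) && Lambda > f * N)
    warning("Lambda > f*N: mean block longer than the chain (regime V)",
            call. = FALSE)
  structure(list(u = u, f = f, N = N, Lambda = Lambda),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("Scaling parameters: u = %g, f = %g, N = %g, Lambda = %g\n",
              x$u, x$f, x$N, x$Lambda))
  invisible(x)
}

#' Blob sizes of the globule interior
#'
#' Concentration-blob sizes in the three sequence classes (units of `a`):
#' alternating `xi_a = u^-2 f^-3/2`, essentially random `xi_r = 1/(u f
#' Lambda)`, and highly blocky `xi_hb = (u f^2)^-1/3`, the last coinciding
#' with the electrostatic blob `xi_e`.  Also returns the monomers per
#' electrostatic blob `g_e = (u f^2)^-2/3` and its charge `q_e = f g_e`.
#'
#' @param params A [scaling_params()].
#' @return List with `xi_a`, `xi_r`, `xi_hb`, `xi_e`, `g_e`, `q_e`.
#' @export
blob_set <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  u <- params$u; f <- params$f; L <- params$Lambda
  xi_hb <- (u * f^2)^(-1 / 3)
  list(xi_a = u^-2 * f^(-3 / 2),
       xi_r = if (L > 0) 1 / (u * f * L) else Inf,
       xi_hb = xi_hb,
       xi_e = xi_hb,
       g_e = (u * f^2)^(-2 / 3),
       q_e = f * (u * f^2)^(-2 / 3))
}

#' Equilibrium density of the polyampholyte globule
#'
#' Piecewise (in `Lambda`) monomer volume fraction of the globule interior,
#' with unit prefactors: `u^2 f^(3/2)` for nearly alternating sequences,
#' `u f Lambda` for essentially random ones, and the `Lambda`-independent
#' `(u f^2)^(1/3)` for highly blocky sequences.  The branches intersect
#' exactly at the crossovers `Lambda_a/r` and `Lambda_r/hb`, so the density
#' is continuous by construction:
#' `phi = max(phi_a, min(phi_r, phi_hb))`.  Values above 1 are capped with
#' a warning (dense limit outside the theory).
#'
#' @param params A [scaling_params()].
#' @return Volume fraction `phi` in (0, 1].
#' @export
globule_density <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  u <- params$u; f <- params$f; L <- params$Lambda
  phi_a <- u^2 * f^(3 / 2)
  phi_r <- u * f * L
  phi_hb <- (u * f^2)^(1 / 3)
  phi <- max(phi_a, min(phi_r, phi_hb))
  if (phi > 1) {
    warning("globule density exceeds 1; capping (theory leaves the dense ",
            "limit open)", call. = FALSE)
    phi <- 1
  }
  phi
}

#' Crossover blockiness values between conformational regimes
#'
#' The four boundaries on the `Lambda` axis, with unit prefactors:
#' \describe{
#'   \item{`L_ar = u f^(1/2)`}{alternating / substantially random (where the
#'     alternating and random density branches meet).}
#'   \item{`L_rhb = u^(-2/3) f^(-1/3)`}{random / highly blocky; equals the
#'     electrostatic-blob charge `q_e`.}
#'   \item{`L_bs = u^(-4/9) f^(1/9) N^(1/3)`}{charge in beads / charge in
#'     strings: where bead charge, block charge, and ionic monomers per
#'     string are all equal.}
#'   \item{`L_pe = f N`}{crossover to the stretched polyelectrolyte, where
#'     the mean block spans the chain.}
#' }
#'
#' @param params A [scaling_params()] (`Lambda` itself is not used).
#' @return List of class `regime_boundaries` with `L_ar`, `L_rhb`, `L_bs`,
#'   `L_pe`.
#' @export
regime_boundaries <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  u <- params$u; f <- params$f; N <- params$N
  structure(list(L_ar = u * sqrt(f),
                 L_rhb = u^(-2 / 3) * f^(-1 / 3),
                 L_bs = u^(-4 / 9) * f^(1 / 9) * N^(1 / 3),
                 L_pe = f * N),
            class = "regime_boundaries")
}

#' @export
print.regime_boundaries <- function(x, ...) {
  cat(sprintf(
    "Regime boundaries (Lambda): a/r %.4g | r/hb %.4g | b/s %.4g | PE %.4g\n",
    x$L_ar, x$L_rhb, x$L_bs, x$L_pe))
  invisible(x)
}

#' Rayleigh destabilization ratio of the spherical globule
#'
#' Ratio `I` of the Coulomb energy of the chain's characteristic excess
#' charge, `u Q^2 / R`, to the globule surface energy, `(R / xi)^2`, with
#' `Q = sqrt(f N Lambda)`, `R = (N / phi)^(1/3)` and `xi = 1 / phi`.  With
#' unit prefactors this reduces to `I = u f Lambda / phi`:  `I << 1` for
#' nearly alternating sequences (stable globule), `I = 1` throughout the
#' random regime, and `I >> 1` for highly blocky sequences, where a
#' many-bead necklace forms.
#'
#' @param params A [scaling_params()].
#' @return The dimensionless ratio `I`.
#' @export
rayleigh_ratio <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  phi <- suppressWarnings(globule_density(params))
  params$u * params$f * params$Lambda / phi
}

#' Classify the conformational regime
#'
#' Assigns one of the five regimes by the position of `Lambda` among the
#' boundaries of [regime_boundaries()], on left-closed half-open intervals:
#' I spherical globule, II necklace with charge in beads and about one bead,
#' III many-bead necklace with charge in beads, IV necklace with charge in
#' strings, V stretched polyelectrolyte.
#'
#' @param params A [scaling_params()].
#' @return Character regime label, one of `"I"` ... `"V"`.
#' @export
classify_regime <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  b <- regime_boundaries(params)
  cuts <- c(b$L_ar, b$L_rhb, b$L_bs, b$L_pe)
  if (is.unsorted(cuts)) {
    warning("regime boundaries are not ordered (L_ar < L_rhb < L_bs < L_pe ",
            "fails): scaling separation breaks down for these u, f, N",
            call. = FALSE)
    cuts <- cummax(cuts)  # collapsed boundaries: later regimes take over
  }
  L <- params$Lambda
  c("I", "II", "III", "IV", "V")[findInterval(L, cuts, left.open = FALSE) + 1L]
}

#' Predict the full set of conformational observables
#'
#' Evaluates the scaling laws for the chain size `R`, bead count `N_bead`,
#' monomers per bead and string `m_bead`, `m_str`, bead diameter `D_bead`,
#' string length `l_str`, necklace length `L_nec`, globule/bead density
#' `phi`, bead and string charges `Q_bead`, `Q_str`, and the Rayleigh ratio
#' `I_rayleigh`, in the regime selected by [classify_regime()].  All
#' prefactors are unity, which makes every observable that the theory
#' matches at a boundary exactly continuous there; the bead charge drops
#' discontinuously by a factor `(N / g_e)^(1/9)` at the III/IV boundary.
#'
#' In regime II the ensemble is bimodal (spheres and necklaces coexist);
#' the necklace branch is reported since it dominates the ensemble-average
#' dimensions.
#'
#' @param params A [scaling_params()].
#' @return A list of class `conformation_prediction`.
#' @export
#' @examples
#' predict_conformation(scaling_params(u = 1, f = 1/16, N = 1e4, Lambda = 1))
predict_conformation <- function(params) {
  stopifnot(inherits(params, "scaling_params"))
  u <- params$u; f <- params$f; N <- params$N; L <- params$Lambda
  regime <- classify_regime(params)
  phi <- suppressWarnings(globule_density(params))
  Q <- characteristic_charge(f, N, Lambda = L)
  out <- switch(regime,
    "I" = {
      R <- N^(1 / 3) / (u^(2 / 3) * sqrt(f))
      list(R = R, N_bead = 1, m_bead = N, m_str = 0, D_bead = R, l_str = 0,
           L_nec = R, Q_bead = Q, Q_str = 0)
    },
    "II" = {
      # m_str << m_bead is marginal near the lower edge of II; cap at N
      list(R = sqrt(N), N_bead = 1, m_bead = N,
           m_str = min(sqrt(N) / (u * f * L), N),
           D_bead = (N / (u * f * L))^(1 / 3),
           l_str = sqrt(N), L_nec = sqrt(N),
           Q_bead = Q, Q_str = min(L, Q))
    },
    "III" = {
      n_bead <- u^(2 / 3) * f^(1 / 3) * L
      list(R = u^(1 / 3) * f^(1 / 6) * sqrt(N * L),
           N_bead = n_bead, m_bead = N / n_bead,
           m_str = sqrt(N) / (u^(2 / 3) * f^(5 / 6) * sqrt(L)),
           D_bead = (N / (u * f * L))^(1 / 3),
           l_str = sqrt(N) / (u^(1 / 3) * f^(1 / 6) * sqrt(L)),
           L_nec = u^(1 / 3) * f^(1 / 6) * sqrt(N * L),
           Q_bead = Q / n_bead, Q_str = L)
    },
    "IV" = {
      n_bead <- sqrt(f * N / L)
      list(R = u^(1 / 3) * f^(1 / 6) * sqrt(N * L),
           N_bead = n_bead, m_bead = sqrt(N * L / f), m_str = L / f,
           D_bead = (N * L)^(1 / 6) / (u^(1 / 9) * f^(7 / 18)),
           l_str = (u / f)^(1 / 3) * L,
           L_nec = u^(1 / 3) * f^(1 / 6) * sqrt(N * L),
           Q_bead = (N * L)^(1 / 6) * u^(-4 / 9) * f^(-1 / 18),
           Q_str = L)
    },
    "V" = {
      R <- u^(1 / 3) * f^(2 / 3) * N
      list(R = R, N_bead = 0, m_bead = 0, m_str = N, D_bead = 0,
           l_str = R, L_nec = R, Q_bead = 0, Q_str = Q)
    })
  structure(c(list(regime = regime), out,
              list(phi = phi, I_rayleigh = rayleigh_ratio(params),
                   Q = Q, params = params)),
            class = "conformation_prediction")
}

#' @export
print.conformation_prediction <- function(x, ...) {
  cat(sprintf("Conformation prediction (regime %s)\n", x$regime))
  cat(sprintf("  R = %.4g a   L_nec = %.4g a   phi = %.4g   I = %.4g\n",
              x$R, x$L_nec, x$phi, x$I_rayleigh))
  cat(sprintf("  N_bead = %.4g   m_bead = %.4g   D_bead = %.4g a\n",
              x$N_bead, x$m_bead, x$D_bead))
  cat(sprintf("  m_str = %.4g   l_str = %.4g a\n", x$m_str, x$l_str))
  cat(sprintf("  Q = %.4g e   Q_bead = %.4g e   Q_str = %.4g e\n",
              x$Q, x$Q_bead, x$Q_str))
  invisible(x)
}

#' Convert a prediction's lengths to physical units
#'
#' Multiplies every length observable (`R`, `D_bead`, `l_str`, `L_nec`) by
#' the monomer size `a`; counts, charges and densities are unchanged.
#'
#' @param pred A `conformation_prediction`.
#' @param a Monomer size in the desired unit.
#' @return The prediction with lengths rescaled (attribute `"a"` records it).
#' @export
to_physical <- function(pred, a) {
  stopifnot(inherits(pred, "conformation_prediction"), a > 0)
  for (fld in c("R", "D_bead", "l_str", "L_nec")) pred[[fld]] <- pred[[fld]] * a
  attr(pred, "a") <- a
  pred
}

#' Conformational phase diagram over a blockiness grid
#'
#' Evaluates [predict_conformation()] over a grid of `Lambda` values at
#' fixed `u`, `f`, `N`, returning one row per grid point.  The bead count
#' is non-monotonic along the grid: it rises linearly through regime III and
#' falls as `Lambda^(-1/2)` through regime IV, with its maximum at the
#' bead-to-string charge-migration boundary `Lambda_b/s`.
#'
#' @param u,f,N Scaling parameters.
#' @param Lambda Monotone increasing numeric grid of blockiness values.
#' @return A data.frame with columns `Lambda`, `regime`, and the observables
#'   of [predict_conformation()].
#' @export
phase_diagram <- function(u, f, N, Lambda) {
  stopifnot(is.numeric(Lambda), length(Lambda) >= 1, !is.unsorted(Lambda))
  rows <- lapply(Lambda, function(L) {
    p <- suppressWarnings(predict_conformation(scaling_params(u, f, N, Lambda = L)))
    data.frame(Lambda = L, regime = p$regime, R = p$R, N_bead = p$N_bead,
               m_bead = p$m_bead, m_str = p$m_str, D_bead = p$D_bead,
               l_str = p$l_str, L_nec = p$L_nec, phi = p$phi,
               Q_bead = p$Q_bead, Q_str = p$Q_str,
               I_rayleigh = p$I_rayleigh)
  })
  do.call(rbind, rows)
}
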
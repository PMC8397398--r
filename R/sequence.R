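#' Markov charge-sequence specification
#'
#' Defines the quenched charge sequence of a polyampholyte: a chain of `N`
#' monomers of which a fraction `f` is ionic (charge +1 or -1 in units of e),
#' with the signs of successive ionic monomers following a first-order Markov
#' process with correlation parameter `lam`.  `lam = -1` gives a strictly
#' alternating sequence, `lam = 0` independent random signs, and `lam = 1` the
#' degenerate single-sign limit (a stoichiometric mixture of polyanions and
#' polycations at the ensemble level).
#'
#' Ionic monomers are placed equidistantly along the backbone, at positions
#' `ceiling((k - 1/2) / f)` for `k = 1, ..., N*f`; the remaining monomers are
#' neutral.  `N * f` must therefore be an integer.
#'
#' @param N Chain length in monomers (positive integer).
#' @param f Ionic fraction in (0, 1]; `N * f` must be an integer.
#' @param lam Correlation parameter in [-1, 1].
#' @param seed Optional integer RNG seed; sequences are reproducible given it.
#' @return An object of class `markov_spec`.
#' @seealso [generate_sequence()], [blockiness()]
#' @export
#' @examples
#' spec <- markov_spec(N = 64, f = 1, lam = 0.5, seed = 1)
#' seq <- generate_sequence(spec)
markov_spec <- function(N, f = 1, lam = 0, seed = NULL) {
  stopifnot(is.numeric(N), length(N) == 1L, N >= 1, N == round(N))
  stopifnot(is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  if (!is.numeric(lam) || length(lam) != 1L || lam < -1 || lam > 1)
    stop("correlation parameter 'lam' must lie in [-1, 1]", call. = FALSE)
  n_ion <- N * f
  if (abs(n_ion - round(n_ion)) > 1e-9)
    stop("N * f = ", n_ion, " is not an integer: cannot place ionic monomers",
         call. = FALSE)
  structure(
    list(N = as.integer(N), f = f, lam = lam,
         seed = if (!is.null(seed)) as.integer(seed) else NULL,
         n_ionic = as.integer(round(n_ion))),
    class = "markov_spec")
}

#' @export
print.markov_spec <- function(x, ...) {
  cat(sprintf("Markov sequence spec: N = %d, f = %g, lambda = %g (Lambda = %g)",
              x$N, x$f, x$lam, blockiness_quiet(x$lam)))
  if (!is.null(x$seed)) cat(sprintf(", seed = %d", x$seed))
  cat("\n")
  invisible(x)
}

#' Sign-transition probabilities of the Markov charge process
#'
#' Returns the 2x2 table of conditional probabilities `p(i|j)` that an ionic
#' monomer of sign `i` follows one of sign `j`.  Statistical neutrality
#' requires `p(+|+) = p(-|-) = (1 + lam)/2`, and the correlation parameter
#' `lam` is the second eigenvalue of the table.
#'
#' @param lam Correlation parameter in [-1, 1].
#' @return A 2x2 matrix with rows = current sign (`"+"`, `"-"`), columns =
#'   next sign; each row sums to 1.
#' @export
#' @examples
#' transition_probabilities(0)    # all entries 1/2: independent signs
#' transition_probabilities(-1)   # strict alternation
transition_probabilities <- function(lam) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < -1 || lam > 1)
    stop("correlation parameter 'lam' must lie in [-1, 1]", call. = FALSE)
  p_same <- (1 + lam) / 2
  matrix(c(p_same, 1 - p_same, 1 - p_same, p_same), nrow = 2, byrow = TRUE,
         dimnames = list(from = c("+", "-"), to = c("+", "-")))
}

#' Charge blockiness of a Markov polyampholyte
#'
#' The mean net charge of a block (run) of consecutive like charges is
#' `1 + Lambda` with `Lambda = (1 + lam) / (1 - lam)`: 0 for alternating
#' sequences (`lam = -1`), 1 for ideally random ones (`lam = 0`), and
#' diverging as `lam -> 1` where each chain carries a single sign.
#'
#' @param lam Correlation parameter in [-1, 1).  `lam = 1` returns `Inf`
#'   with a warning (degenerate single-sign limit).
#' @return The blockiness `Lambda >= 0` (vectorized over `lam`).
#' @export
#' @examples
#' blockiness(c(-1, 0, 0.5))  # 0, 1, 3
blockiness <- function(lam) {
  if (!is.numeric(lam) || any(is.na(lam)) || any(lam < -1) || any(lam > 1))
    stop("correlation parameter 'lam' must lie in [-1, 1]", call. = FALSE)
  if (any(lam == 1))
    warning("Lambda diverges at lam = 1 (single-sign chains); returning Inf",
            call. = FALSE)
  (1 + lam) / (1 - lam)
}

blockiness_quiet <- function(lam) suppressWarnings(blockiness(lam))

#' Correlation parameter from blockiness
#'
#' Inverse of [blockiness()]: `lam = (Lambda - 1) / (Lambda + 1)`.
#'
#' @param Lambda Blockiness, `Lambda >= 0` (may be `Inf`).
#' @return Correlation parameter in [-1, 1].
#' @export
lambda_from_blockiness <- function(Lambda) {
  stopifnot(is.numeric(Lambda), all(Lambda >= 0))
  ifelse(is.infinite(Lambda), 1, (Lambda - 1) / (Lambda + 1))
}

## Run RNG-dependent code under a local, restorable seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

## Draw n correlated +/-1 signs of the Markov process (vectorized).
draw_signs <- function(n, lam) {
  if (n == 0L) return(integer(0))
  s1 <- sample(c(1L, -1L), 1L)
  if (n == 1L) return(s1)
  if (lam == 1) return(rep(s1, n))  # degenerate: single-sign chain
  keep <- stats::runif(n - 1L) < (1 + lam) / 2
  cumprod(c(s1, ifelse(keep, 1L, -1L)))
}

#' Generate a quenched Markov charge sequence
#'
#' Draws one realization of the charge sequence defined by a [markov_spec()]:
#' the first ionic sign from the stationary distribution (1/2, 1/2), each
#' subsequent ionic sign from the transition table of
#' [transition_probabilities()], and neutral monomers interleaved so ionic
#' monomers sit equidistantly.
#'
#' @param spec A [markov_spec()].
#' @return A `charge_sequence`: integer vector of per-monomer charges in
#'   \{-1, 0, +1\} with the originating spec attached as attribute `"spec"`.
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  signs <- with_seed(spec$seed, draw_signs(spec$n_ionic, spec$lam))
  charges <- integer(spec$N)
  charges[ionic_positions(spec$N, spec$f)] <- signs
  charge_sequence(charges, spec = spec)
}

## Equidistant ionic positions: ceiling((k - 1/2)/f), k = 1..N*f.
ionic_positions <- function(N, f) {
  n_ion <- as.integer(round(N * f))
  as.integer(ceiling((seq_len(n_ion) - 0.5) / f))
}

#' Construct a charge sequence
#'
#' @param charges Integer vector with entries in \{-1, 0, +1\}.
#' @param spec Optional originating [markov_spec()].
#' @return An object of class `charge_sequence`.
#' @export
charge_sequence <- function(charges, spec = NULL) {
  charges <- as.integer(charges)
  if (!all(charges %in% c(-1L, 0L, 1L)))
    stop("charges must be -1, 0 or +1", call. = FALSE)
  structure(charges, spec = spec, class = "charge_sequence")
}

#' @export
print.charge_sequence <- function(x, ...) {
  n <- length(x)
  cat(sprintf("Charge sequence: N = %d, ionic = %d, net charge Q = %d\n",
              n, sum(x != 0L), sum(x)))
  s <- paste(c("-", "0", "+")[unclass(x) + 2L], collapse = "")
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat(" ", s, "\n")
  invisible(x)
}

#' Net charge of a sequence
#' @param seq A `charge_sequence` (or plain charge vector).
#' @return Integer net charge Q (units of e).
#' @export
net_charge <- function(seq) sum(as.integer(seq))

#' Decompose a charge sequence into blocks of like charges
#'
#' Run-length encodes the ionic subsequence (neutral monomers are skipped):
#' a block is a maximal run of consecutive ionic monomers of equal sign.
#' Block lengths are counted in ionic monomers, so they equal the block
#' net-charge magnitude.
#'
#' @param seq A `charge_sequence`.
#' @return A list of class `block_decomposition` with `block_lengths` and
#'   alternating `block_signs`.
#' @export
#' @examples
#' decompose_blocks(charge_sequence(c(1, 1, -1, -1, -1)))
decompose_blocks <- function(seq) {
  charges <- as.integer(seq)
  ionic <- charges[charges != 0L]
  if (length(ionic) == 0L)
    stop("sequence has no ionic monomers: empty block decomposition",
         call. = FALSE)
  r <- rle(ionic)
  structure(list(block_lengths = r$lengths, block_signs = r$values),
            class = "block_decomposition")
}

#' Exact moments of the global net charge
#'
#' Closed-form mean and variance of `Q = sum of fN Markov-correlated +/-1
#' signs`.  With `n = f N` and sign autocovariance `lam^|i-j|`,
#' `Var(Q) = n (1 + lam)/(1 - lam) - 2 lam (1 - lam^n)/(1 - lam)^2`,
#' valid for any `lam` in [-1, 1) (at `lam = 1`, `Var(Q) = n^2`).
#' Asymptotically `Var(Q)/(f N) -> Lambda`, so the characteristic chain
#' charge is `sqrt(f N Lambda)`.
#'
#' @param lam Correlation parameter in [-1, 1].
#' @param f Ionic fraction.
#' @param N Chain length; `f * N` must be an integer.
#' @return List with `mean` (0 by neutrality), `var`, and `n_ionic`.
#' @export
net_charge_moments <- function(lam, f, N) {
  spec <- markov_spec(N, f, lam)  # reuse validation
  n <- spec$n_ionic
  v <- if (lam == 1) {
    as.numeric(n)^2
  } else {
    n * (1 + lam) / (1 - lam) - 2 * lam * (1 - lam^n) / (1 - lam)^2
  }
  list(mean = 0, var = v, n_ionic = n)
}

#' Characteristic global charge of a statistically neutral Markov chain
#'
#' The typical magnitude of the net charge over sequence realizations,
#' `sqrt(f N Lambda)`: zero for alternating sequences, `sqrt(f N)` for random
#' ones, and approaching the maximal charge `f N` when the block length
#' `Lambda / f` is comparable to the chain length.  Values are capped at
#' `f N`, the largest charge a chain can carry.
#'
#' @param f Ionic fraction.
#' @param N Chain length.
#' @param lam Correlation parameter (used if `Lambda` missing).
#' @param Lambda Blockiness; overrides `lam` if given.
#' @return Characteristic charge in units of e.
#' @export
#' @examples
#' characteristic_charge(f = 1, N = 100, lam = 0)  # sqrt(N) = 10
characteristic_charge <- function(f, N, lam = NULL, Lambda = NULL) {
  if (is.null(Lambda)) {
    if (is.null(lam)) stop("supply either 'lam' or 'Lambda'", call. = FALSE)
    Lambda <- blockiness_quiet(lam)
  }
  stopifnot(all(Lambda >= 0))
  pmin(sqrt(f * N * Lambda), f * N)
}

#' Estimate the correlation parameter from a sequence
#'
#' Maximum-likelihood estimate from the transition counts of the ionic
#' subsequence: `lam_hat = (n_same - n_diff) / (n_same + n_diff)`, with a
#' binomial standard error.  A sequence with a single block (no sign change)
#' gives the degenerate estimate `lam_hat = 1`, flagged with a warning.
#'
#' @param seq A `charge_sequence` with at least 2 ionic monomers.
#' @return List with `lam_hat`, `se`, counts, and `degenerate` flag.
#' @export
estimate_lambda <- function(seq) {
  charges <- as.integer(seq)
  ionic <- charges[charges != 0L]
  if (length(ionic) < 2L)
    stop("need at least 2 ionic monomers to estimate lambda", call. = FALSE)
  same <- ionic[-1L] == ionic[-length(ionic)]
  n_same <- sum(same)
  n_diff <- sum(!same)
  n <- n_same + n_diff
  lam_hat <- (n_same - n_diff) / n
  p_hat <- n_same / n
  se <- 2 * sqrt(p_hat * (1 - p_hat) / n)
  degenerate <- n_diff == 0L
  if (degenerate)
    warning("single-block sequence: lam_hat = 1 is a degenerate estimate",
            call. = FALSE)
  list(lam_hat = lam_hat, se = se, n_same = n_same, n_diff = n_diff,
       degenerate = degenerate)
}

#' Sample sequences conditioned on an exact net charge
#'
#' Plain rejection sampling from the unconditioned Markov ensemble: draw
#' sequences from `spec` and keep those whose net charge equals `Q_target`
#' exactly.  Rejection keeps the quenched ensemble exactly equal to the
#' conditional Markov measure.  Feasibility requires `|Q_target| <= f N`
#' with the parity of `f N`.
#'
#' @param spec A [markov_spec()]; its `seed` (if any) seeds the whole draw.
#' @param Q_target Target integer net charge.
#' @param n_chains Number of conditioned sequences to return.
#' @param acceptance_floor Abort if the running acceptance rate falls below
#'   this value (default `1e-6`) with no accepted draws.
#' @return List of `charge_sequence` objects with attribute
#'   `"acceptance_rate"`.
#' @export
conditioned_ensemble <- function(spec, Q_target, n_chains,
                                 acceptance_floor = 1e-6) {
  stopifnot(inherits(spec, "markov_spec"))
  n_ion <- spec$n_ionic
  Q_target <- as.integer(Q_target)
  if (abs(Q_target) > n_ion)
    stop("|Q_target| exceeds the number of ionic monomers", call. = FALSE)
  if ((Q_target - n_ion) %% 2L != 0L)
    stop("Q_target = ", Q_target, " has wrong parity for f*N = ", n_ion,
         " ionic monomers (Q and f*N must have equal parity)", call. = FALSE)
  pos <- ionic_positions(spec$N, spec$f)
  out <- vector("list", n_chains)
  got <- 0L
  tries <- 0L
  with_seed(spec$seed, {
    while (got < n_chains) {
      signs <- draw_signs(n_ion, spec$lam)
      tries <- tries + 1L
      if (sum(signs) == Q_target) {
        charges <- integer(spec$N)
        charges[pos] <- signs
        got <- got + 1L
        out[[got]] <- charge_sequence(charges, spec = spec)
      } else if (got == 0L && tries >= max(1e4, 10 / acceptance_floor)) {
        stop("acceptance rate below ", acceptance_floor,
             ": check parity and feasibility of Q_target", call. = FALSE)
      }
    }
  })
  attr(out, "acceptance_rate") <- n_chains / tries
  out
}
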
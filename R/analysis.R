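#' Radius of gyration of a frame
#'
#' Root-mean-square distance of the beads from their centroid (equal
#' masses), in units of a.
#'
#' @param frame N x 3 coordinate matrix.
#' @return Rg (scalar).
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # 0.5
radius_of_gyration <- function(frame) {
  stopifnot(is.matrix(frame), ncol(frame) == 3, nrow(frame) >= 2)
  centered <- sweep(frame, 2, colMeans(frame))
  sqrt(sum(centered^2) / nrow(frame))
}

#' Detect necklace beads (pearls) in a conformation
#'
#' Builds the monomer contact graph (an edge wherever `r_ij <
#' contact_cutoff`, excluding bonded neighbors by default so a taut string
#' does not register as a one-dimensional cluster) and takes its connected
#' components.  Components with at least `min_bead_size` monomers are
#' beads; all remaining monomers are strings.  Deterministic for fixed
#' inputs and invariant under rigid motions of the frame.
#'
#' The defaults reflect the theory's length scales: `contact_cutoff = 1.5`
#' is the first-neighbor shell of a dense melt, and a bead must exceed one
#' electrostatic blob, so a good `min_bead_size` is `max(4, g_e)` with
#' `g_e` from [blob_set()] (strings are one blob thick).
#'
#' @param frame N x 3 coordinate matrix.
#' @param contact_cutoff Contact distance (units of a).
#' @param min_bead_size Minimum monomers for a component to count as a bead.
#' @param exclude_bonded Drop edges between backbone neighbors.
#' @param seq Optional `charge_sequence` for the charge bookkeeping fields.
#' @return A `necklace_descriptor`: `n_beads`, `bead_members` (list of
#'   index vectors), `string_members`, `bead_charges`, `string_charge`,
#'   `bead_radii`, `rg_chain`.
#' @export
detect_beads <- function(frame, contact_cutoff = 1.5, min_bead_size = 4,
                         exclude_bonded = TRUE, seq = NULL) {
  stopifnot(is.matrix(frame), ncol(frame) == 3)
  n <- nrow(frame)
  if (!is.null(seq) && length(seq) != n)
    stop("sequence length does not match the frame", call. = FALSE)
  d <- as.matrix(stats::dist(frame))
  adj <- d < contact_cutoff
  diag(adj) <- FALSE
  if (exclude_bonded && n > 1) {
    idx <- cbind(seq_len(n - 1), seq_len(n - 1) + 1L)
    adj[idx] <- FALSE
    adj[idx[, 2:1, drop = FALSE]] <- FALSE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(seq_len(n), comp$membership)
  is_bead <- lengths(members) >= min_bead_size
  bead_members <- unname(members[is_bead])
  # order beads along the backbone by their first monomer
  if (length(bead_members) > 1)
    bead_members <- bead_members[order(vapply(bead_members, min, 0L))]
  string_members <- sort(unlist(members[!is_bead], use.names = FALSE))
  charges <- if (!is.null(seq)) as.integer(seq) else integer(n)
  descriptor <- structure(list(
    n_beads = length(bead_members),
    bead_members = bead_members,
    string_members = string_members,
    bead_charges = vapply(bead_members, function(m) sum(charges[m]), 0L),
    string_charge = sum(charges[string_members]),
    bead_radii = vapply(bead_members, function(m) {
      if (length(m) >= 2)
        radius_of_gyration(frame[m, , drop = FALSE]) else 0
    }, 0),
    rg_chain = if (n >= 2) radius_of_gyration(frame) else 0,
    n_monomers = n), class = "necklace_descriptor")
  stopifnot(length(unlist(descriptor$bead_members)) +
              length(descriptor$string_members) == n)
  descriptor
}

#' @export
print.necklace_descriptor <- function(x, ...) {
  cat(sprintf("Necklace: %d bead(s), %d string monomers, Rg = %.4g a\n",
              x$n_beads, length(x$string_members), x$rg_chain))
  if (x$n_beads > 0)
    cat(sprintf("  bead masses: %s; bead charges: %s; string charge: %d\n",
                paste(lengths(x$bead_members), collapse = ", "),
                paste(x$bead_charges, collapse = ", "), x$string_charge))
  invisible(x)
}

#' Partition the chain's net charge between beads and strings
#'
#' Exact integer bookkeeping: the summed bead charge and the string charge
#' of a [detect_beads()] descriptor, verified to add up to the chain net
#' charge.
#'
#' @param descriptor A `necklace_descriptor`.
#' @param seq A `charge_sequence` of matching length.
#' @return List `Q_bead_total`, `Q_str`, `Q` and the string charge
#'   fraction `f_str` (`NA` for a neutral chain).
#' @export
charge_partition <- function(descriptor, seq) {
  stopifnot(inherits(descriptor, "necklace_descriptor"))
  charges <- as.integer(seq)
  if (length(charges) != descriptor$n_monomers)
    stop("sequence length (", length(charges),
         ") does not match the descriptor (", descriptor$n_monomers, ")",
         call. = FALSE)
  qb <- vapply(descriptor$bead_members, function(m) sum(charges[m]), 0L)
  qs <- sum(charges[descriptor$string_members])
  Q <- sum(charges)
  stopifnot(sum(qb) + qs == Q)
  list(Q_bead_total = sum(qb), Q_str = qs, Q = Q,
       f_str = if (Q != 0) abs(qs) / abs(Q) else NA_real_)
}

## Integrated autocorrelation time (in frames) of a scalar series.
autocorrelation_time <- function(x, c_stop = 0.05) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(1)
  rho <- stats::acf(x, lag.max = min(n - 1, floor(n / 3)), plot = FALSE,
                    demean = TRUE)$acf[-1]
  keep <- which(rho < c_stop)
  m <- if (length(keep)) keep[1] - 1L else length(rho)
  max(1, 1 + 2 * sum(rho[seq_len(m)]))
}

#' Ensemble averages with block-averaged standard errors
#'
#' Averages gyration radius, bead count, and string-charge fraction over a
#' set of independent trajectories of the same condition.  Within each
#' trajectory, frames are grouped into blocks of about twice the integrated
#' autocorrelation time of the Rg series (capped at half the shortest run,
#' so every run contributes at least two blocks), and the standard error is
#' taken
#' over all block means (blocks from independent runs are independent by
#' construction).
#'
#' @param trajectories List of `trajectory` objects (>= 2) for the same
#'   condition.
#' @param seqs List of `charge_sequence`s matching the trajectories (or a
#'   single sequence recycled).
#' @param contact_cutoff,min_bead_size Passed to [detect_beads()].
#' @return One-row data.frame: `rg_mean`, `rg_se`, `n_beads_mean`,
#'   `n_beads_se`, `f_str_mean` (mean string charge fraction, `NA` for
#'   neutral chains), `n_traj`, `n_frames`, `block_size`.
#' @export
ensemble_report <- function(trajectories, seqs, contact_cutoff = 1.5,
                            min_bead_size = 4) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) < 2)
    stop("need >= 2 independent trajectories for ensemble averages",
         call. = FALSE)
  if (inherits(seqs, "charge_sequence"))
    seqs <- rep(list(seqs), length(trajectories))
  stopifnot(length(seqs) == length(trajectories))

  tau <- max(vapply(trajectories, function(tr) autocorrelation_time(tr$rg), 0))
  n_min <- min(vapply(trajectories, function(tr) length(tr$frames), 0L))
  if (n_min < 4 && stats::sd(unlist(lapply(trajectories, `[[`, "rg"))) > 0)
    stop("too few frames (", n_min, ") for block averaging: lengthen the ",
         "runs or save more frames", call. = FALSE)
  # every run contributes at least two blocks; runs are independent anyway
  block <- max(1L, min(ceiling(2 * tau), n_min %/% 2L))

  per_block <- function(values) {
    unlist(lapply(values, function(v) {
      nb <- length(v) %/% block
      if (nb < 1) return(mean(v))
      vapply(seq_len(nb), function(b)
        mean(v[seq.int((b - 1L) * block + 1L, b * block)]), 0)
    }))
  }
  rg_vals <- lapply(trajectories, `[[`, "rg")
  stats_of <- function(blocks) {
    m <- mean(blocks)
    se <- if (length(blocks) > 1) stats::sd(blocks) / sqrt(length(blocks)) else 0
    c(m, se)
  }
  rg_b <- stats_of(per_block(rg_vals))

  nb_vals <- vector("list", length(trajectories))
  fs_vals <- vector("list", length(trajectories))
  for (i in seq_along(trajectories)) {
    descs <- lapply(trajectories[[i]]$frames, detect_beads,
                    contact_cutoff = contact_cutoff,
                    min_bead_size = min_bead_size, seq = seqs[[i]])
    nb_vals[[i]] <- vapply(descs, `[[`, 0L, "n_beads")
    fs_vals[[i]] <- vapply(descs, function(d)
      charge_partition(d, seqs[[i]])$f_str, 0)
  }
  nb_b <- stats_of(per_block(nb_vals))
  fs_all <- unlist(fs_vals)
  f_str_mean <- if (all(is.na(fs_all))) NA_real_ else mean(fs_all, na.rm = TRUE)

  data.frame(rg_mean = rg_b[1], rg_se = rg_b[2],
             n_beads_mean = nb_b[1], n_beads_se = nb_b[2],
             f_str_mean = f_str_mean,
             n_traj = length(trajectories),
             n_frames = sum(lengths(rg_vals)),
             block_size = block)
}
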
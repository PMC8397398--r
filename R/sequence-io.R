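#' Write charge sequences to a plain-text file
#'
#' FASTA-like format: a header line `>id N=.. f=.. lambda=.. seed=..`
#' followed by the charge string over the alphabet `+`, `-`, `0`, wrapped at
#' 60 characters per line.  [read_sequences()] round-trips bit-exactly.
#'
#' @param seqs A `charge_sequence` or list of them.
#' @param path Output file path.
#' @param ids Optional character vector of record ids (default `seq_1`, ...).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, ids = NULL) {
  if (inherits(seqs, "charge_sequence")) seqs <- list(seqs)
  if (is.null(ids)) ids <- sprintf("seq_%d", seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  lines <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    spec <- attr(s, "spec")
    hdr <- paste0(">", ids[[i]])
    if (!is.null(spec)) {
      hdr <- sprintf("%s N=%d f=%s lambda=%s", hdr, spec$N,
                     format(spec$f, digits = 15),
                     format(spec$lam, digits = 15))
      if (!is.null(spec$seed)) hdr <- sprintf("%s seed=%d", hdr, spec$seed)
    }
    body <- paste(c("-", "0", "+")[as.integer(s) + 2L], collapse = "")
    lines <- c(lines, hdr,
               substring(body, seq(1, nchar(body), 60),
                         pmin(seq(1, nchar(body), 60) + 59, nchar(body))))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read charge sequences written by [write_sequences()]
#'
#' @param path File path.
#' @return Named list of `charge_sequence` objects; headers carrying
#'   `N= f= lambda= seed=` fields are restored into each sequence's spec.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop("no sequence records in ", path, call. = FALSE)
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr_idx))
  ids <- character(length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    hdr <- sub("^>", "", lines[hdr_idx[i]])
    fields <- strsplit(hdr, "\\s+")[[1L]]
    ids[i] <- fields[1L]
    body <- paste(lines[seq(hdr_idx[i] + 1L, ends[i])], collapse = "")
    chars <- strsplit(body, "")[[1L]]
    if (!all(chars %in% c("+", "-", "0")))
      stop("record '", ids[i], "' contains characters outside {+,-,0}",
           call. = FALSE)
    charges <- c("-" = -1L, "0" = 0L, "+" = 1L)[chars]
    kv <- fields[grepl("=", fields, fixed = TRUE)]
    spec <- NULL
    if (length(kv)) {
      vals <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
      if (all(c("N", "f", "lambda") %in% names(vals))) {
        spec <- markov_spec(as.integer(vals[["N"]]), as.numeric(vals[["f"]]),
                            as.numeric(vals[["lambda"]]),
                            seed = if ("seed" %in% names(vals))
                              as.integer(vals[["seed"]]) else NULL)
      }
    }
    out[[i]] <- charge_sequence(unname(charges), spec = spec)
  }
  stats::setNames(out, ids)
}

#' Map a protein sequence to backbone charges
#'
#' Coarse charge assignment at neutral pH: lysine (K) and arginine (R) map
#' to +1, aspartate (D) and glutamate (E) to -1, all other residues to 0.
#' Histidine's partial protonation can be approximated by `his` (0 by
#' default; set to +1 to treat it as charged).
#'
#' @param aa Character string (or vector of single letters) of one-letter
#'   amino-acid codes.
#' @param his Charge assigned to histidine (0 or 1).
#' @return A `charge_sequence` of the residue charges.
#' @export
#' @examples
#' charges_from_protein("MKKDDE")
charges_from_protein <- function(aa, his = 0) {
  stopifnot(his %in% c(0, 1))
  if (length(aa) == 1L && nchar(aa) > 1L) aa <- strsplit(aa, "")[[1L]]
  aa <- toupper(aa)
  charges <- integer(length(aa))
  charges[aa %in% c("K", "R")] <- 1L
  charges[aa %in% c("D", "E")] <- -1L
  charges[aa == "H"] <- as.integer(his)
  charge_sequence(charges)
}

#' Read a protein FASTA file as charge sequences
#'
#' Reads standard FASTA and maps residues to charges via
#' [charges_from_protein()].
#'
#' @param path FASTA file path.
#' @param his Charge assigned to histidine.
#' @return Named list of `charge_sequence` objects.
#' @export
read_protein_fasta <- function(path, his = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr_idx <- grep("^>", lines)
  if (length(hdr_idx) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(hdr_idx[-1L] - 1L, length(lines))
  out <- vector("list", length(hdr_idx))
  ids <- character(length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    ids[i] <- strsplit(sub("^>", "", lines[hdr_idx[i]]), "\\s+")[[1L]][1L]
    body <- paste(lines[seq(hdr_idx[i] + 1L, ends[i])], collapse = "")
    out[[i]] <- charges_from_protein(body, his = his)
  }
  stats::setNames(out, ids)
}
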
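#' Exact density of states of an HP chain
#'
#' Exhaustively enumerates every self-avoiding conformation of the chain on
#' the simple cubic lattice and tallies conformation counts by energy.
#' Counting follows the convention in which the first bond is fixed to +x:
#' a purely linear structure then contributes 1, a planar structure 4, and a
#' three-dimensional structure 8, so a sequence has a unique native structure
#' exactly when the ground-state count is 8.
#'
#' Two traversal modes are available and must agree exactly: `"fixed"`
#' enumerates every walk whose first step is +x; `"symmetry"` enumerates one
#' representative per point-group orbit (first step +x, first non-x step +y,
#' first out-of-plane step +z) and weights it by its orbit size under the
#' fixed-first-step convention (1, 4 or 8).  The symmetry mode is roughly
#' eight times faster and is the default.
#'
#' @param seq an [hp_sequence()] (or string).
#' @param params an [hp_params()] energy triple.
#' @param mode `"symmetry"` or `"fixed"` (see Details).
#' @return an object of class `hp_dos`: a data frame with columns `energy`
#'   (increasing, all <= 0 for attractive parameters) and `count` (exact
#'   conformation counts; integers stored as doubles, all below 2^53).
#' @examples
#' enumerate_dos("HHHH")    # 4 U-shapes with one H-H contact, 21 open walks
#' @export
enumerate_dos <- function(seq, params = hp_params(), mode = c("symmetry", "fixed")) {
  seq <- hp_sequence(seq)
  mode <- match.arg(mode)
  if (length(seq) > 20L)
    stop("exhaustive enumeration is limited to chains of at most 20 beads",
         call. = FALSE)
  res <- .enum_dos_cpp(hp_types(seq), hp_eps(params),
                       if (mode == "fixed") 0L else 1L)
  out <- data.frame(energy = res$energy, count = res$count)
  out <- out[order(out$energy), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hp_dos", "data.frame"),
            sequence = as.character(seq), params = hp_eps(params),
            n = length(seq), mode = mode)
}

#' @export
print.hp_dos <- function(x, ...) {
  cat(sprintf("<hp_dos> %s  (N = %d, %s mode)\n", attr(x, "sequence"),
              attr(x, "n"), attr(x, "mode")))
  cat(sprintf("  E0 = %d, n(E0) = %.0f, %d energy levels, %.0f conformations\n",
              min(x$energy), x$count[which.min(x$energy)], nrow(x),
              sum(x$count)))
  invisible(x)
}

#' Partition polynomial of a density of states
#'
#' With integer contact energies the partition function is a polynomial in
#' `x = exp(1/kT)`: `Z(x) = sum_E n(E) x^(-E)`, so the coefficient of `x^m`
#' is the number of conformations with energy `-m` and the degree `M = -E0`.
#'
#' @param dos an `hp_dos` from [enumerate_dos()].
#' @return an object of class `hp_polynomial`: a list with `coef` (ascending
#'   powers, `coef[m+1]` multiplying `x^m`), `degree`, and the originating
#'   sequence/parameters.
#' @export
build_polynomial <- function(dos) {
  if (!inherits(dos, "hp_dos")) stop("expected an 'hp_dos' object", call. = FALSE)
  if (!nrow(dos)) stop("empty density of states", call. = FALSE)
  if (any(dos$energy > 0L))
    stop("positive energies present; the polynomial form requires attractive contacts",
         call. = FALSE)
  M <- -min(dos$energy)
  coef <- numeric(M + 1L)
  coef[-dos$energy + 1L] <- dos$count
  structure(list(coef = coef, degree = M,
                 sequence = attr(dos, "sequence"),
                 params = attr(dos, "params"), n = attr(dos, "n")),
            class = "hp_polynomial")
}

#' @export
print.hp_polynomial <- function(x, ...) {
  cat(sprintf("<hp_polynomial> degree %d, leading coefficient %.0f (%s)\n",
              x$degree, x$coef[x$degree + 1L],
              if (is.null(x$sequence)) "manual" else x$sequence))
  invisible(x)
}

# build an hp_polynomial directly from coefficients (toy polynomials, tests)
as_hp_polynomial <- function(coef) {
  coef <- as.numeric(coef)
  while (length(coef) > 1L && coef[length(coef)] == 0) coef <- coef[-length(coef)]
  structure(list(coef = coef, degree = length(coef) - 1L,
                 sequence = NULL, params = NULL, n = NULL),
            class = "hp_polynomial")
}

#' Ground-state analysis of an HP sequence
#'
#' Enumerates the chain, reports the ground-state energy `E0` and its
#' degeneracy `n(E0)`, keeps one minimum-energy conformation as a
#' representative native structure, and flags uniqueness.  Under the
#' fixed-first-step counting convention a unique (three-dimensional) native
#' structure has degeneracy exactly 8.
#'
#' @inheritParams enumerate_dos
#' @return an object of class `hp_ground_state` with elements `e0`, `n_e0`,
#'   `unique`, `conformation`, `sequence`.
#' @export
ground_state <- function(seq, params = hp_params()) {
  seq <- hp_sequence(seq)
  dos <- enumerate_dos(seq, params)
  e0 <- min(dos$energy)
  n_e0 <- dos$count[which.min(dos$energy)]
  dirs <- .gs_conformation_cpp(hp_types(seq), hp_eps(params))
  conf <- hp_conformation(paste(.hp_dir_chars[dirs + 1L], collapse = ""))
  stopifnot(hp_energy(conf, seq, params) == e0)
  structure(list(e0 = as.integer(e0), n_e0 = n_e0, unique = (n_e0 == 8),
                 conformation = conf, sequence = as.character(seq),
                 params = hp_eps(params)),
            class = "hp_ground_state")
}

#' @export
print.hp_ground_state <- function(x, ...) {
  cat(sprintf("<hp_ground_state> %s: E0 = %d, n(E0) = %.0f (%s)\n",
              x$sequence, x$e0, x$n_e0,
              if (x$unique) "unique native structure" else "degenerate"))
  invisible(x)
}

#' Screen the full sequence space for unique-ground-state sequences
#'
#' Evaluates all `2^n` HP sequences of length `n` and keeps those whose
#' ground state is unique (`n(E0) = 8`).  The conformation set is
#' sequence-independent, so a single enumeration pass aggregates
#' conformation counts keyed by their contact-pair set; each sequence is then
#' scored against the distinct contact signatures, which is orders of
#' magnitude cheaper than re-enumerating per sequence.
#'
#' @param n chain length (at most 20; the signature key is limited to 64
#'   admissible contact pairs).
#' @param params an [hp_params()] triple.
#' @param checkpoint optional path to a TSV sidecar; a completed run is
#'   written there and, with `resume = TRUE`, reloaded instead of recomputed.
#' @param resume reuse the checkpoint file if it is complete.
#' @return a data frame with columns `sequence`, `e0`, `n_e0`, sorted
#'   lexicographically, holding only the candidate sequences.  Attributes
#'   `n_total` (2^n) and `n_signatures` record the scale of the pass.
#' @seealso [screen_sequences_direct()] for the slow per-sequence fallback.
#' @export
screen_sequences <- function(n, params = hp_params(), checkpoint = NULL,
                             resume = FALSE) {
  n <- as.integer(n)
  if (n < 3L || n > 20L) stop("screen supports 3 <= n <= 20", call. = FALSE)
  if (resume && !is.null(checkpoint) && file.exists(checkpoint)) {
    prev <- read_screen(checkpoint)
    if (isTRUE(attr(prev, "complete"))) return(prev)
  }
  res <- .screen_cpp(n, hp_eps(params))
  keep <- which(res$ne0 == 8)
  seqs <- vapply(keep - 1L, function(s) {
    bits <- bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L)
    paste(ifelse(bits == 1L, "H", "P"), collapse = "")
  }, "")
  out <- data.frame(sequence = seqs, e0 = res$e0[keep], n_e0 = res$ne0[keep])
  out <- out[order(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total") <- 2^n
  attr(out, "n_signatures") <- res$n_signatures
  attr(out, "complete") <- TRUE
  if (!is.null(checkpoint)) write_screen(out, checkpoint)
  out
}

#' Per-sequence screening fallback
#'
#' Re-enumerates each given sequence independently, checkpointing results
#' every `every` sequences so interrupted runs can resume.  Intended for
#' subsets; [screen_sequences()] is the production path for a full length.
#'
#' @param sequences character vector of HP strings (all the same length).
#' @param params an [hp_params()] triple.
#' @param checkpoint optional TSV path written incrementally.
#' @param every checkpoint granularity in sequences.
#' @return data frame with `sequence`, `e0`, `n_e0` for every input sequence.
#' @export
screen_sequences_direct <- function(sequences, params = hp_params(),
                                    checkpoint = NULL, every = 1024L) {
  done <- data.frame(sequence = character(0), e0 = integer(0), n_e0 = numeric(0))
  if (!is.null(checkpoint) && file.exists(checkpoint))
    done <- read_screen(checkpoint)
  todo <- setdiff(sequences, done$sequence)
  rows <- done[done$sequence %in% sequences, , drop = FALSE]
  since <- 0L
  for (s in todo) {
    d <- enumerate_dos(s, params)
    rows <- rbind(rows, data.frame(sequence = s, e0 = min(d$energy),
                                   n_e0 = d$count[which.min(d$energy)]))
    since <- since + 1L
    if (!is.null(checkpoint) && since %% every == 0L)
      write_screen(rows, checkpoint, complete = FALSE)
  }
  rows <- rows[order(rows$sequence), , drop = FALSE]
  rownames(rows) <- NULL
  if (!is.null(checkpoint)) write_screen(rows, checkpoint)
  rows
}
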
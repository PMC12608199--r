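#' Naive reference enumerator
#'
#' A deliberately unoptimised density-of-states enumerator kept as an
#' independent cross-check of the compiled production enumerator: it grows
#' walks recursively in plain R under the fixed-first-step convention and
#' computes every conformation's energy from scratch through [contacts()],
#' with no incremental bookkeeping and no symmetry weighting.  Practical for
#' chains of up to about 8 beads.
#'
#' @inheritParams enumerate_dos
#' @return an `hp_dos` data frame identical in layout to [enumerate_dos()].
#' @export
reference_dos <- function(seq, params = hp_params()) {
  seq <- hp_sequence(seq)
  n <- length(seq)
  if (n > 9L) stop("the reference enumerator is limited to 9 beads", call. = FALSE)
  eps <- hp_eps(params)
  types <- hp_types(seq)
  steps <- .hp_dir_steps
  tally <- new.env(parent = emptyenv())

  grow <- function(coords, occupied) {
    k <- nrow(coords)
    if (k == n) {
      e <- hp_energy(hp_conformation(coords, canonicalize = FALSE), seq, params)
      key <- as.character(e)
      assign(key, (if (exists(key, tally)) get(key, tally) else 0) + 1, tally)
      return(invisible())
    }
    for (d in seq_len(6)) {
      nxt <- coords[k, ] + steps[d, ]
      key <- paste(nxt, collapse = ",")
      if (key %in% occupied) next
      grow(rbind(coords, nxt), c(occupied, key))
    }
  }
  start <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))
  grow(start, c("0,0,0", "1,0,0"))

  energies <- sort(as.integer(ls(tally)))
  out <- data.frame(energy = energies,
                    count = vapply(as.character(energies), get, 0, envir = tally))
  rownames(out) <- NULL
  structure(out, class = c("hp_dos", "data.frame"),
            sequence = as.character(seq), params = eps, n = n,
            mode = "reference")
}
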
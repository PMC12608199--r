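#' Lattice conformations
#'
#' A conformation of an N-bead chain on the simple cubic lattice is a
#' self-avoiding walk: an ordered list of integer coordinates in which
#' consecutive beads sit on adjacent sites and no site is visited twice.
#' Conformations are stored in a canonical frame that starts at the origin
#' with the first bond along +x; an equivalent compact representation is a
#' direction string over `R, L, U, D, F, B` (+x, -x, +y, -y, +z, -z).
#'
#' @param x an integer matrix with one row per bead and columns x, y, z, or
#'   a direction string such as `"RRUL"`.
#' @param canonicalize translate/rotate the walk into the canonical frame
#'   (origin start, first bond +x).  Rotation preserves contacts and energy.
#' @return an object of class `hp_conformation`: the coordinate matrix with
#'   the direction string attached as attribute `dirs`.
#' @examples
#' u <- hp_conformation("RUL")        # the 4-bead U shape
#' contacts(u)
#' @export
hp_conformation <- function(x, canonicalize = TRUE) {
  if (inherits(x, "hp_conformation")) return(x)
  coords <- if (is.character(x)) dirs_to_coords(x) else {
    m <- as.matrix(x)
    storage.mode(m) <- "integer"
    m
  }
  if (ncol(coords) != 3L || nrow(coords) < 2L)
    stop("a conformation needs an n x 3 integer coordinate matrix (n >= 2)",
         call. = FALSE)
  validate_walk(coords)
  if (canonicalize) coords <- canonical_frame(coords)
  structure(coords, dirs = coords_to_dirs(coords), class = "hp_conformation")
}

# consecutive unit steps and self-avoidance; errors name the first bad bead
validate_walk <- function(coords) {
  steps <- diff(coords)
  bad <- which(rowSums(abs(steps)) != 1L)
  if (length(bad))
    stop(sprintf("broken bond: beads %d and %d are not lattice neighbours",
                 bad[1], bad[1] + 1L), call. = FALSE)
  key <- paste(coords[, 1], coords[, 2], coords[, 3])
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("overlap: bead %d revisits an occupied site", dup[1]),
         call. = FALSE)
  invisible(coords)
}

# translate bead 1 to the origin and map the first bond onto +x with a fixed
# signed permutation (the remaining axes keep their order and sign)
canonical_frame <- function(coords) {
  coords <- sweep(coords, 2, coords[1, ])
  s <- coords[2, ]
  a <- which(s != 0L)
  if (!(a == 1L && s[1L] == 1L)) {
    others <- setdiff(1:3, a)
    rot <- matrix(0L, 3, 3)
    rot[1, a] <- as.integer(sign(s[a]))
    rot[2, others[1]] <- 1L
    rot[3, others[2]] <- 1L
    coords <- coords %*% t(rot)
  }
  storage.mode(coords) <- "integer"
  coords
}

dirs_to_coords <- function(dirs) {
  ch <- strsplit(toupper(dirs), "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% .hp_dir_chars)
  if (length(bad))
    stop(sprintf("invalid direction '%s' at step %d (alphabet is R,L,U,D,F,B)",
                 ch[bad[1]], bad[1]), call. = FALSE)
  steps <- .hp_dir_steps[ch, , drop = FALSE]
  coords <- rbind(c(0L, 0L, 0L), apply(steps, 2, cumsum))
  storage.mode(coords) <- "integer"
  coords
}

coords_to_dirs <- function(coords) {
  steps <- diff(coords)
  idx <- match(paste(steps[, 1], steps[, 2], steps[, 3]),
               paste(.hp_dir_steps[, 1], .hp_dir_steps[, 2], .hp_dir_steps[, 3]))
  paste(.hp_dir_chars[idx], collapse = "")
}

#' @export
print.hp_conformation <- function(x, ...) {
  cat(sprintf("<hp_conformation> %d beads, dirs = %s\n", nrow(x), attr(x, "dirs")))
  invisible(x)
}

#' The straight chain
#'
#' @param n number of beads.
#' @return an `hp_conformation` lying along +x.
#' @export
straight_chain <- function(n) {
  hp_conformation(cbind(0L:(as.integer(n) - 1L), 0L, 0L))
}

#' Nonconsecutive nearest-neighbour contacts
#'
#' Returns every bead pair (i, j) with j > i + 1 whose positions are at unit
#' Euclidean distance, in sorted order.  Bead indices are 1-based.
#'
#' @param conf an [hp_conformation()].
#' @return a two-column integer matrix of contact pairs (possibly 0 rows).
#' @export
contacts <- function(conf) {
  conf <- hp_conformation(conf)
  n <- nrow(conf)
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  # contacts need opposite sublattice parity, so j - i is odd and >= 3
  for (i in seq_len(n - 3L)) {
    j <- seq.int(i + 3L, n, by = 2L)
    if (!length(j)) next
    d <- abs(conf[j, 1] - conf[i, 1]) + abs(conf[j, 2] - conf[i, 2]) +
      abs(conf[j, 3] - conf[i, 3])
    hit <- j[d == 1L]
    if (length(hit)) out <- rbind(out, cbind(i = i, j = hit))
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Contact energy of a conformation
#'
#' The energy is the sum over all nonconsecutive nearest-neighbour contacts
#' of the contact energy for the two residue types involved.
#'
#' @param conf an [hp_conformation()].
#' @param seq an [hp_sequence()] of the same length.
#' @param params an [hp_params()] triple.
#' @return an integer energy (0 when there are no contacts).
#' @examples
#' hp_energy(hp_conformation("RUL"), hp_sequence("HHHH"), hp_params())
#' @export
hp_energy <- function(conf, seq, params = hp_params()) {
  conf <- hp_conformation(conf)
  seq <- hp_sequence(seq)
  if (length(seq) != nrow(conf))
    stop(sprintf("sequence length (%d) does not match bead count (%d)",
                 length(seq), nrow(conf)), call. = FALSE)
  eps <- hp_eps(params)
  cp <- contacts(conf)
  if (!nrow(cp)) return(0L)
  ti <- hp_types(seq)[cp[, 1]]
  tj <- hp_types(seq)[cp[, 2]]
  # type code 0 = H, 1 = P: ti+tj indexes (HH, HP, PP)
  sum(eps[ti + tj + 1L])
}

#' Lattice point-group operations
#'
#' The 48 signed permutation matrices (rotations and reflections of the
#' cube).  Conformation energies are invariant under all of them and under
#' translation, which the tests exercise.
#'
#' @return a list of 48 integer 3x3 matrices.
#' @export
lattice_symmetries <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- expand.grid(s1 = c(1L, -1L), s2 = c(1L, -1L), s3 = c(1L, -1L))
  out <- vector("list", 48L)
  k <- 0L
  for (p in perms) for (r in seq_len(nrow(signs))) {
    m <- matrix(0L, 3, 3)
    for (a in 1:3) m[a, p[a]] <- as.integer(signs[r, a])
    k <- k + 1L
    out[[k]] <- m
  }
  out
}
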
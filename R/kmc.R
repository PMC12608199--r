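#' Legal single-bead moves of a conformation
#'
#' The physical move set contains corner flips (an interior bead whose two
#' bonds are perpendicular hops to the free diagonal site) and 90-degree end
#' flips (a terminal bead hops to a free site adjacent to its bonded
#' neighbour and perpendicular to the terminal bond).  The straight-back
#' 180-degree end reversal is never generated.  Every move displaces one
#' bead by a lattice diagonal and carries a Metropolis rate
#' `W = min(1, exp(-dE/T))`.
#'
#' @param conf an [hp_conformation()].
#' @param seq the matching [hp_sequence()].
#' @param params an [hp_params()] triple.
#' @param temperature reduced temperature (`k_B = 1`), `> 0`.
#' @return a data frame of class `hp_move_catalog` with columns `kind`
#'   (`"corner"`/`"end"`), `bead` (1-based), target coordinates `tx, ty,
#'   tz`, `d_e` and `w`; attributes `w_total`, `energy` (current), and the
#'   inputs.
#' @export
legal_moves <- function(conf, seq, params = hp_params(), temperature = 1) {
  conf <- hp_conformation(conf)
  seq <- hp_sequence(seq)
  if (length(seq) != nrow(conf))
    stop("sequence length does not match bead count", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  cat_df <- .kmc_catalog_cpp(unclass_coords(conf), hp_types(seq), hp_eps(params),
                             temperature)
  structure(as.data.frame(cat_df),
            class = c("hp_move_catalog", "data.frame"),
            w_total = sum(cat_df$w), energy = attr(cat_df, "energy"),
            conformation = conf, sequence = as.character(seq),
            params = hp_eps(params), temperature = temperature)
}

unclass_coords <- function(conf) {
  m <- matrix(as.integer(conf), ncol = 3)
  m
}

#' One Gillespie event
#'
#' Draws a waiting time `-log(xi) / W_T` (exponential with rate `W_T`) and a
#' move with probability `W_i / W_T`, applies the move, and returns the new
#' conformation (re-canonicalised) together with the chosen row and the
#' waiting time.  Randomness comes from R's RNG, so `set.seed()` makes the
#' step reproducible.
#'
#' @param catalog an `hp_move_catalog` from [legal_moves()].
#' @return list with `conformation`, `move` (the selected catalog row),
#'   `dt`, and `d_e`.
#' @export
gillespie_step <- function(catalog) {
  if (!inherits(catalog, "hp_move_catalog")) stop("expected an 'hp_move_catalog'", call. = FALSE)
  if (!nrow(catalog))
    stop("trapped state: no legal moves available", call. = FALSE)
  wt <- attr(catalog, "w_total")
  i <- findInterval(stats::runif(1) * wt, cumsum(catalog$w),
                    rightmost.closed = TRUE) + 1L
  i <- min(i, nrow(catalog))
  dt <- -log(stats::runif(1)) / wt
  conf <- attr(catalog, "conformation")
  coords <- unclass_coords(conf)
  coords[catalog$bead[i], ] <- c(catalog$tx[i], catalog$ty[i], catalog$tz[i])
  list(conformation = hp_conformation(coords), move = catalog[i, , drop = FALSE],
       dt = dt, d_e = catalog$d_e[i])
}

#' First-passage time to the native state
#'
#' Runs a Gillespie kinetic Monte Carlo trajectory from the straight chain
#' until the chain energy first equals the ground-state energy, and records
#' the accumulated continuous time.  The sequence must have a unique ground
#' state (`n(E0) = 8`): energy equality is then equivalent to reaching the
#' native structure, because the minimum-energy conformation is unique up to
#' lattice symmetry and energy is symmetry-invariant.
#'
#' @param seq an [hp_sequence()].
#' @param params an [hp_params()] triple.
#' @param temperature reduced temperature, `> 0`.
#' @param seed RNG seed; identical seed and parameters reproduce the
#'   trajectory bit for bit.
#' @param max_events censoring cap on the number of executed moves.
#' @param ground optional [ground_state()] result, to avoid re-enumerating
#'   the chain on every call.
#' @return list of class `hp_kmc_result`: `fpt` (NA when censored),
#'   `events`, `reached`, `censored`, `seed`, `temperature`.
#' @export
first_passage <- function(seq, params = hp_params(), temperature = 1,
                          seed = 1, max_events = 1e8, ground = NULL) {
  seq <- hp_sequence(seq)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (is.null(ground)) ground <- ground_state(seq, params)
  if (!isTRUE(ground$unique))
    stop("first-passage analysis requires a unique ground state (n(E0) = 8); ",
         sprintf("this sequence has n(E0) = %.0f", ground$n_e0), call. = FALSE)
  res <- .kmc_run_cpp(hp_types(seq), hp_eps(params), temperature,
                      ground$e0, max_events, seed, 0, 0)
  if (isTRUE(res$trapped))
    stop("trapped state encountered: no legal moves remain", call. = FALSE)
  structure(list(fpt = res$fpt, events = res$events, reached = res$reached,
                 censored = res$censored, seed = seed,
                 temperature = temperature, e0 = ground$e0),
            class = "hp_kmc_result")
}

#' @export
print.hp_kmc_result <- function(x, ...) {
  cat(sprintf("<hp_kmc_result> T = %g: %s after %.0f events%s\n",
              x$temperature,
              if (x$reached) sprintf("reached E0 = %d at t = %.4g", x$e0, x$fpt)
              else "censored",
              x$events, if (x$censored) " (cap hit)" else ""))
  invisible(x)
}

#' Mean first-passage-time curve over a temperature grid
#'
#' Repeats [first_passage()] `runs` times per temperature with independent,
#' reproducible RNG streams derived from `(seed, temperature index, run
#' index)`, and summarises the mean and standard error of the uncensored
#' first-passage times.  The mean-FPT curve of a foldable sequence is
#' U-shaped: entropy slows folding at high temperature, metastable traps at
#' low temperature.
#'
#' @param seq an [hp_sequence()].
#' @param params an [hp_params()] triple.
#' @param temperatures numeric vector of reduced temperatures.
#' @param runs trajectories per temperature.
#' @param seed base RNG seed.
#' @param max_events per-trajectory censoring cap.
#' @param detail keep the per-run table as attribute `runs`.
#' @return data frame of class `hp_fpt_curve` with columns `temperature`,
#'   `mean_fpt`, `sem`, `n_runs`, `n_censored`.  `mean_fpt` is `NA` where
#'   every run was censored.
#' @export
mean_fpt_curve <- function(seq, params = hp_params(),
                           temperatures = seq(3, 7, by = 0.5), runs = 1000,
                           seed = 1, max_events = 1e8, detail = FALSE) {
  seq <- hp_sequence(seq)
  ground <- ground_state(seq, params)
  if (!isTRUE(ground$unique))
    stop("mean_fpt_curve requires a unique-ground-state sequence", call. = FALSE)
  rows <- vector("list", length(temperatures))
  per_run <- if (detail) vector("list", length(temperatures)) else NULL
  for (ti in seq_along(temperatures)) {
    res <- .kmc_many_cpp(hp_types(seq), hp_eps(params), temperatures[ti],
                         ground$e0, as.integer(runs), max_events, seed, ti - 1)
    ok <- res$reached
    fpts <- res$fpt[ok]
    rows[[ti]] <- data.frame(
      temperature = temperatures[ti],
      mean_fpt = if (length(fpts)) mean(fpts) else NA_real_,
      sem = if (length(fpts) > 1) stats::sd(fpts) / sqrt(length(fpts)) else NA_real_,
      n_runs = as.integer(runs),
      n_censored = sum(!ok))
    if (detail)
      per_run[[ti]] <- data.frame(temperature = temperatures[ti],
                                  run = seq_len(runs), fpt = res$fpt,
                                  events = res$events, censored = !res$reached)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("hp_fpt_curve", "data.frame"),
            sequence = as.character(seq), params = hp_eps(params),
            seed = seed, max_events = max_events, e0 = ground$e0,
            runs = if (detail) do.call(rbind, per_run) else NULL)
}

#' @export
print.hp_fpt_curve <- function(x, ...) {
  cat(sprintf("<hp_fpt_curve> %s (E0 = %d, %d temperatures, %d runs each)\n",
              attr(x, "sequence"), attr(x, "e0"), nrow(x), x$n_runs[1]))
  print.data.frame(x, digits = 4)
  invisible(x)
}
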
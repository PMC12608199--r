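#' Partition-function zeros
#'
#' Computes all complex roots of the partition polynomial `Z(x)` in the
#' complex plane of `x = exp(1/kT)`.  Initial estimates from a
#' companion-matrix solver ([polyroot()]) are polished by Newton iteration in
#' compiled double-double arithmetic (about 31 significant digits) on the
#' exact integer coefficients; conjugate symmetry is then enforced by pairing
#' and averaging.  Every root must pass a relative residual bound of
#' `10^(-precision/2)` or the function aborts with advice to lower the
#' requested precision.
#'
#' Because the coefficients are positive counts, `Z(x) > 0` for all real
#' `x > 0`: no zero can lie on the positive real axis, and the few real
#' zeros sit on the negative axis.
#'
#' @param poly an `hp_polynomial` from [build_polynomial()].
#' @param precision target precision in decimal digits (<= 30, the working
#'   precision of the double-double kernel; default 30).
#' @return an object of class `hp_zeros`: a data frame with columns `re`,
#'   `im`, `modulus`, `arg`, `residual` and a `band` column filled by
#'   [band_zeros()].  Low-order root parts are kept in attributes for exact
#'   reconstruction checks.
#' @export
find_zeros <- function(poly, precision = 30) {
  if (!inherits(poly, "hp_polynomial")) stop("expected an 'hp_polynomial'", call. = FALSE)
  if (poly$degree < 1L) stop("polynomial degree must be >= 1", call. = FALSE)
  if (precision > 30)
    stop("requested precision exceeds the 30-digit working precision of the ",
         "double-double root kernel; use precision <= 30", call. = FALSE)

  z0 <- polyroot(poly$coef)
  pol <- .dd_polish_cpp(poly$coef, Re(z0), Im(z0))
  re <- pol$re; im <- pol$im
  re_lo <- pol$re_lo; im_lo <- pol$im_lo

  # classify real roots, then enforce exact conjugate symmetry by averaging
  mod <- sqrt(re^2 + im^2)
  is_real <- abs(im) < 1e-12 * pmax(mod, 1)
  im[is_real] <- 0; im_lo[is_real] <- 0
  pos <- which(!is_real & im > 0)
  neg <- which(!is_real & im < 0)
  if (length(pos) != length(neg))
    stop("failed to pair conjugate roots; increase precision", call. = FALSE)
  used <- logical(length(neg))
  for (k in pos) {
    d2 <- (re[neg] - re[k])^2 + (im[neg] + im[k])^2
    d2[used] <- Inf
    j <- neg[which.min(d2)]
    used[which.min(d2)] <- TRUE
    mre <- (re[k] + re[j]) / 2; mim <- (im[k] - im[j]) / 2
    re[c(k, j)] <- mre; im[k] <- mim; im[j] <- -mim
    re_lo[c(k, j)] <- (re_lo[k] + re_lo[j]) / 2
    mlo <- (im_lo[k] - im_lo[j]) / 2
    im_lo[k] <- mlo; im_lo[j] <- -mlo
  }

  tol <- 10^(-precision / 2)
  if (any(pol$residual > tol))
    stop(sprintf(paste0("root polishing left %d residual(s) above %.1e; the ",
                        "requested precision was not reached -- retry with a ",
                        "lower 'precision'"),
                 sum(pol$residual > tol), tol), call. = FALSE)
  if (any(im == 0 & re > 0))
    stop("a zero was found on the positive real axis; the coefficients are not all positive",
         call. = FALSE)

  ord <- order(sqrt(re^2 + im^2), atan2(im, re))
  out <- data.frame(re = re[ord], im = im[ord],
                    modulus = sqrt(re^2 + im^2)[ord],
                    arg = atan2(im, re)[ord],
                    residual = pol$residual[ord],
                    band = NA_character_)
  structure(out, class = c("hp_zeros", "data.frame"),
            re_lo = re_lo[ord], im_lo = im_lo[ord],
            poly = poly, precision = precision, gap_factor = NA_real_)
}

#' @export
print.hp_zeros <- function(x, ...) {
  cat(sprintf("<hp_zeros> %d roots, max residual %.2e, precision %d digits\n",
              nrow(x), max(x$residual), attr(x, "precision")))
  if (!all(is.na(x$band)))
    cat(sprintf("  bands: %s (gap factor %.3f)\n",
                paste(names(table(x$band)), table(x$band), collapse = ", "),
                attr(x, "gap_factor")))
  invisible(x)
}

# dd reconstruction and Vieta aggregates for an hp_zeros object
zeros_verify <- function(zeros) {
  poly <- attr(zeros, "poly")
  .dd_verify_cpp(poly$coef, zeros$re, attr(zeros, "re_lo"),
                 zeros$im, attr(zeros, "im_lo"))
}

#' Heat capacity from the partition polynomial
#'
#' Evaluates `C_V(x) = x (ln x)^2 d/dx [ x d/dx ln Z(x) ]` directly from the
#' polynomial and its exact derivatives; no roots are involved.  To stay
#' well-scaled at low temperature (large `x`) the ratio `Z'/Z` is formed on
#' the reversed polynomial in `y = 1/x`.  With `k_B = 1` the temperature is
#' `T = 1/ln x`, so `x > 1` corresponds to `T > 0`.
#'
#' @param poly an `hp_polynomial`.
#' @param x numeric vector, all `> 1`.
#' @return the heat capacity at each `x` (nonnegative).
#' @export
heat_capacity <- function(poly, x) {
  if (!inherits(poly, "hp_polynomial")) stop("expected an 'hp_polynomial'", call. = FALSE)
  if (any(x <= 1)) stop("heat_capacity requires x > 1 (physical T > 0)", call. = FALSE)
  M <- poly$degree
  b <- rev(poly$coef)            # Q(y) = sum b_j y^j with b_j = a_{M-j}
  y <- 1 / x
  Q <- outer(y, 0:M, `^`) %*% b
  Qp <- if (M >= 1) outer(y, 0:(M - 1), `^`) %*% (b[-1] * seq_len(M)) else 0 * y
  Qpp <- if (M >= 2) outer(y, 0:(M - 2), `^`) %*% (b[-(1:2)] * seq_len(M - 1) * (2:M)) else 0 * y
  r1 <- Qp / Q
  bracket <- r1 + y * (Qpp / Q - r1^2)
  as.numeric(x * log(x)^2 * y^2 * bracket)
}

# internal energy U(T) = -d ln Z / d beta = -(x d/dx ln Z); used by the
# finite-difference consistency tests
internal_energy <- function(poly, x) {
  M <- poly$degree
  b <- rev(poly$coef)
  y <- 1 / x
  Q <- outer(y, 0:M, `^`) %*% b
  Qp <- if (M >= 1) outer(y, 0:(M - 1), `^`) %*% (b[-1] * seq_len(M)) else 0 * y
  as.numeric(y * Qp / Q - M)
}

#' Heat-capacity component of a single zero
#'
#' Each zero `x_k` contributes
#' `C_{V,k}(x) = -x (ln x)^2 Re[x_k / (x - x_k)^2]`, evaluated through its
#' closed real form.  A complex-conjugate pair contributes twice the same
#' real function, so with `paired = TRUE` (the value plotted for a pair) the
#' result is doubled; real zeros on the negative axis appear singly and use
#' `paired = FALSE`.  Components may be negative away from their peaks; the
#' negative parts cancel in the total.
#'
#' @param zero a complex scalar (one member of the pair).
#' @param x numeric vector, all `> 1`.
#' @param paired is the component the doubled conjugate-pair value?
#' @return numeric vector of component values.
#' @export
cv_component <- function(zero, x, paired = TRUE) {
  if (any(x <= 1)) stop("cv_component requires x > 1", call. = FALSE)
  a <- Re(zero); m2 <- Re(zero)^2 + Im(zero)^2
  den <- (m2 - 2 * a * x + x^2)
  if (any(den == 0)) stop("evaluation point coincides with a real zero", call. = FALSE)
  base <- -x * log(x)^2 * (a * m2 - 2 * m2 * x + a * x^2) / den^2
  if (paired) 2 * base else base
}

#' Decompose the heat capacity into per-zero components
#'
#' Profiles one component per conjugate pair (doubled) and per lone real
#' zero.  Peaks are located on a geometric temperature grid and refined by
#' bracketed scalar maximisation to a relative tolerance of 1e-9; a
#' component whose maximum sits on the boundary of the search range is
#' flagged `peakless` rather than treated as a transition.
#'
#' @param zeros an `hp_zeros` object.
#' @param t_range temperature search range (reduced units, `k_B = 1`).
#' @param grid_points number of coarse bracketing points.
#' @return an object of class `hp_components`: a data frame with one row per
#'   component (`re`, `im` of the generating zero with `im >= 0`, `paired`,
#'   `peak_T`, `peak_height`, `peakless`).
#' @export
decompose <- function(zeros, t_range = c(0.05, 50), grid_points = 400L) {
  if (!inherits(zeros, "hp_zeros")) stop("expected an 'hp_zeros' object", call. = FALSE)
  gen <- zeros[zeros$im >= 0, , drop = FALSE]   # one generator per pair
  gen <- gen[order(gen$modulus, abs(gen$arg)), , drop = FALSE]
  tg <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = grid_points))
  xg <- exp(1 / tg)
  rows <- lapply(seq_len(nrow(gen)), function(i) {
    z <- complex(real = gen$re[i], imaginary = gen$im[i])
    paired <- gen$im[i] > 0
    f <- function(tt) cv_component(z, exp(1 / tt), paired = paired)
    v <- f(tg)
    j <- which.max(v)
    if (j == 1L || j == grid_points) {
      data.frame(re = gen$re[i], im = gen$im[i], paired = paired,
                 peak_T = NA_real_, peak_height = v[j], peakless = TRUE)
    } else {
      opt <- stats::optimize(f, lower = tg[j - 1L], upper = tg[j + 1L],
                             maximum = TRUE, tol = 1e-9 * tg[j])
      data.frame(re = gen$re[i], im = gen$im[i], paired = paired,
                 peak_T = opt$maximum, peak_height = opt$objective,
                 peakless = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("hp_components", "data.frame"),
            t_range = t_range, grid_points = grid_points,
            poly = attr(zeros, "poly"))
}

#' Partition zeros into modulus bands
#'
#' The zeros of protein-like sequences arrange into rings: an inner ring
#' (small modulus, high temperature) for the collapse transition, an outer
#' ring for the folding transition, and sometimes an intermediate ring of
#' crossover zeros.  Bands are found by splitting the sorted moduli at up to
#' the two largest multiplicative gaps exceeding `gap_factor`.
#'
#' @param zeros an `hp_zeros` object.
#' @param gap_factor minimum ratio of consecutive moduli that counts as a
#'   band gap (default 1.05; recorded in the result).  The default is the
#'   largest value that separates the diffuse folding zeros from the
#'   collapse ring across the full bundled reference set.
#' @return the `hp_zeros` object with its `band` column filled with
#'   `"collapse"`, `"intermediate"` or `"folding"`.
#' @export
band_zeros <- function(zeros, gap_factor = 1.05) {
  if (!inherits(zeros, "hp_zeros")) stop("expected an 'hp_zeros' object", call. = FALSE)
  if (nrow(zeros) < 2L) {
    zeros$band <- "collapse"
    attr(zeros, "gap_factor") <- gap_factor
    return(zeros)
  }
  mods <- sort(unique(zeros$modulus))
  ratios <- mods[-1] / mods[-length(mods)]
  gaps <- which(ratios > gap_factor)
  if (length(gaps) > 2L) gaps <- gaps[order(ratios[gaps], decreasing = TRUE)[1:2]]
  cuts <- sort(mods[gaps] * sqrt(ratios[gaps]))   # geometric midpoints
  idx <- findInterval(zeros$modulus, cuts) + 1L   # 1..(#bands)
  nb <- length(cuts) + 1L
  labels <- if (nb == 1L) "collapse"
            else if (nb == 2L) c("collapse", "folding")
            else c("collapse", "intermediate", "folding")
  zeros$band <- labels[idx]
  attr(zeros, "gap_factor") <- gap_factor
  attr(zeros, "n_bands") <- nb
  zeros
}

#' Transition temperatures from first zeros
#'
#' A *first zero* is the zero that provides the leading contribution to the
#' heat capacity of its transition.  For the collapse transition the inner
#' (small-modulus) ring of zeros hugs the positive real axis, and the first
#' zero is the inner-band root with minimal `|arg(x_k)|`; the collapse
#' temperature `T_theta` is the peak position of its component.  The folding
#' zeros are diffuse and often accompanied by intermediate crossover rings,
#' so angular proximity alone can point at a subdominant root; the folding
#' first zero is therefore identified as the zero outside the inner band
#' whose heat-capacity component has the largest peak height, and `T_f` is
#' that component's peak position.  The foldability measure
#' `sigma = (T_theta - T_f) / T_theta` is reported alongside.  A single-band
#' spectrum has no folding transition and reports `T_f = NA`.
#'
#' @param zeros an `hp_zeros` object with bands assigned ([band_zeros()]).
#' @param components the matching [decompose()] output.
#' @return an object of class `hp_transitions`: a list with `t_theta`,
#'   `t_f`, `sigma`, the two first zeros, band/gap metadata and the
#'   component table (used by [classify_foldability()]).
#' @export
transition_temperatures <- function(zeros, components) {
  if (all(is.na(zeros$band)))
    stop("assign bands with band_zeros() first", call. = FALSE)
  if (!inherits(components, "hp_components"))
    stop("expected an 'hp_components' object", call. = FALSE)

  comp_for <- function(fz) {
    if (is.null(fz)) return(NULL)
    i <- which(abs(components$re - fz$re) <= 1e-9 * pmax(1, abs(fz$re)) &
               abs(components$im - fz$im) <= 1e-9 * pmax(1, abs(fz$im)))
    if (!length(i)) return(NULL)
    components[i[1], , drop = FALSE]
  }

  # collapse: inner-band root closest to the positive real axis
  zz <- zeros[zeros$band == "collapse" & zeros$im >= 0, , drop = FALSE]
  cz <- if (nrow(zz)) zz[which.min(abs(zz$arg)), , drop = FALSE] else NULL
  cc <- comp_for(cz)

  # folding: dominant component among the zeros outside the inner band
  inner_max <- max(zeros$modulus[zeros$band == "collapse"])
  cmod <- sqrt(components$re^2 + components$im^2)
  outer <- components[cmod > inner_max * (1 + 1e-12) & !components$peakless, ,
                      drop = FALSE]
  fc <- if (nrow(outer)) outer[which.max(outer$peak_height), , drop = FALSE] else NULL
  fzb <- if (is.null(fc)) NULL else {
    i <- which(abs(zeros$re - fc$re) < 1e-9 & abs(zeros$im - fc$im) < 1e-9)
    zeros[i[1], , drop = FALSE]
  }
  t_theta <- if (!is.null(cc) && !cc$peakless) cc$peak_T else NA_real_
  t_f <- if (!is.null(fc) && !fc$peakless) fc$peak_T else NA_real_
  structure(list(
    t_theta = t_theta,
    t_f = t_f,
    sigma = if (is.na(t_theta) || is.na(t_f)) NA_real_ else (t_theta - t_f) / t_theta,
    collapse_zero = if (is.null(cz)) NULL else complex(real = cz$re, imaginary = cz$im),
    folding_zero = if (is.null(fzb)) NULL else complex(real = fzb$re, imaginary = fzb$im),
    collapse_peak_height = if (is.null(cc)) NA_real_ else cc$peak_height,
    folding_peak_height = if (is.null(fc)) NA_real_ else fc$peak_height,
    n_bands = attr(zeros, "n_bands"),
    gap_factor = attr(zeros, "gap_factor"),
    precision = attr(zeros, "precision"),
    components = components,
    sequence = attr(zeros, "poly")$sequence),
    class = "hp_transitions")
}

#' @export
print.hp_transitions <- function(x, ...) {
  cat(sprintf("<hp_transitions> %s\n", if (is.null(x$sequence)) "" else x$sequence))
  cat(sprintf("  T_theta = %.6f   T_f = %s   sigma = %s   bands = %s\n",
              x$t_theta,
              if (is.na(x$t_f)) "NA" else sprintf("%.6f", x$t_f),
              if (is.na(x$sigma)) "NA" else sprintf("%.4f", x$sigma),
              x$n_bands))
  if (!is.null(x$group))
    cat(sprintf("  crossover score S = %.4f -> group %d (threshold %.2f)\n",
                x$crossover_score, x$group, x$threshold))
  invisible(x)
}

#' Classify foldability from intermediate crossover peaks
#'
#' Slow folders show significant heat-capacity component peaks between the
#' folding and collapse temperatures, attributed to metastable compact
#' globules that compete with the native state.  The continuous crossover
#' score `S` is the largest peak height among components peaking strictly
#' inside `(T_f, T_theta)` (excluding the two first-zero components),
#' measured relative to the folding-component peak height.  A sequence is
#' labelled group 2 (slow folder) when `S >= threshold`; the score itself is
#' the primary output, the label is a convenience.
#'
#' @param report an `hp_transitions` object with both temperatures defined.
#' @param threshold significance threshold on `S` (default 0.5).
#' @return the report with `crossover_score`, `group` and `threshold` added.
#' @export
classify_foldability <- function(report, threshold = 0.5) {
  if (!inherits(report, "hp_transitions")) stop("expected 'hp_transitions'", call. = FALSE)
  if (is.na(report$t_theta) || is.na(report$t_f))
    stop("both T_theta and T_f must be defined to classify", call. = FALSE)
  comp <- report$components
  is_first <- (abs(comp$re - Re(report$collapse_zero)) < 1e-9 &
                 abs(comp$im - Im(report$collapse_zero)) < 1e-9) |
              (abs(comp$re - Re(report$folding_zero)) < 1e-9 &
                 abs(comp$im - Im(report$folding_zero)) < 1e-9)
  mid <- !is_first & !comp$peakless &
    comp$peak_T > report$t_f & comp$peak_T < report$t_theta
  s <- if (any(mid)) max(comp$peak_height[mid]) / report$folding_peak_height else 0
  report$crossover_score <- s
  report$group <- if (s >= threshold) 2L else 1L
  report$threshold <- threshold
  report
}
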
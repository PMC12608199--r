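# partition-function zeros, heat capacity, per-zero decomposition

# the binomial polynomial 4 x^10 + 21 has closed-form roots:
# modulus (21/4)^(1/10), angles pi (2k+1)/10
toy_poly <- function() hpfold:::as_hp_polynomial(c(21, rep(0, 9), 4))

test_that("roots of a binomial polynomial match the closed form", {
  z <- find_zeros(toy_poly())
  expect_equal(nrow(z), 10L)
  expect_equal(z$modulus, rep((21 / 4)^(1 / 10), 10), tolerance = 1e-14)
  expect_equal(sort(abs(z$arg)), rep(pi * c(1, 3, 5, 7, 9) / 10, each = 2),
               tolerance = 1e-12)
  expect_lt(max(z$residual), 1e-15)
})

test_that("conjugate closure and absence of positive real roots hold", {
  for (poly in list(toy_poly(),
                    build_polynomial(enumerate_dos("HPPHPHPP")))) {
    z <- find_zeros(poly)
    expect_equal(nrow(z), poly$degree)
    roots <- complex(real = z$re, imaginary = z$im)
    nonreal <- roots[Im(roots) != 0]
    for (r in nonreal)
      expect_true(any(abs(Conj(r) - nonreal) == 0))
    expect_false(any(Im(roots) == 0 & Re(roots) > 0))
  }
  z2 <- find_zeros(hpfold:::as_hp_polynomial(c(1, 0, 1)))   # x^2 + 1
  expect_equal(sort(z2$im), c(-1, 1), tolerance = 1e-15)
  expect_equal(z2$re, c(0, 0), tolerance = 1e-15)
})

test_that("root reconstruction and Vieta identities hold at working precision", {
  for (poly in list(toy_poly(),
                    build_polynomial(enumerate_dos("HHPPHPHH")))) {
    z <- find_zeros(poly)
    v <- hpfold:::zeros_verify(z)
    expect_lt(v$recon_rel_max, 1e-15)
    M <- poly$degree
    a <- poly$coef
    expect_equal(Re(v$root_sum), -a[M] / a[M + 1], tolerance = 1e-12)
    expect_equal(Re(v$root_prod), (-1)^M * a[1] / a[M + 1], tolerance = 1e-12)
    expect_lt(abs(Im(v$root_sum)), 1e-12)
  }
})

test_that("precision contract is enforced", {
  expect_error(find_zeros(toy_poly(), precision = 60), "precision <= 30")
  expect_error(find_zeros(hpfold:::as_hp_polynomial(5)), "degree")
})

test_that("heat capacity matches a finite-difference derivative of U(T)", {
  for (poly in list(toy_poly(),
                    build_polynomial(enumerate_dos("HPHHPHP")))) {
    expect_error(heat_capacity(poly, 0.9), "x > 1")
    expect_equal(heat_capacity(hpfold:::as_hp_polynomial(5), c(1.5, 3)), c(0, 0))
    tt <- c(0.3, 0.7, 1.3, 2.9, 6.1)
    h <- 1e-5
    cv_fd <- vapply(tt, function(T) {
      (hpfold:::internal_energy(poly, exp(1 / (T + h))) -
         hpfold:::internal_energy(poly, exp(1 / (T - h)))) / (2 * h)
    }, 0)
    cv <- heat_capacity(poly, exp(1 / tt))
    expect_equal(cv, cv_fd, tolerance = 1e-5)
    # vanishing limit at infinite temperature (x -> 1+) and positivity
    expect_lt(heat_capacity(poly, 1 + 1e-8), 1e-6)
    xg <- exp(1 / exp(seq(log(0.05), log(50), length.out = 200)))
    expect_true(all(heat_capacity(poly, xg) >= 0))
  }
})

test_that("component closed form equals direct complex arithmetic", {
  z <- find_zeros(toy_poly())
  x <- exp(1 / seq(0.2, 8, length.out = 40))
  for (k in which(z$im > 0)) {
    zk <- complex(real = z$re[k], imaginary = z$im[k])
    direct <- -x * log(x)^2 *
      Re(zk / (x - zk)^2 + Conj(zk) / (x - Conj(zk))^2)
    expect_equal(cv_component(zk, x, paired = TRUE), direct, tolerance = 1e-10)
  }
  # a lone real root is not doubled
  zr <- -2
  single <- -x * log(x)^2 * zr / (x - zr)^2
  expect_equal(cv_component(zr, x, paired = FALSE), single, tolerance = 1e-12)
})

test_that("components sum to the heat capacity (toy polynomials)", {
  for (poly in list(toy_poly(),
                    build_polynomial(enumerate_dos("HHPHPPHH")))) {
    z <- find_zeros(poly)
    xg <- exp(seq(log(1 + 1e-6), 2, length.out = 250))   # x in (1, e^2]
    total <- heat_capacity(poly, xg)
    comp_sum <- rep(0, length(xg))
    for (k in seq_len(nrow(z))) {
      zk <- complex(real = z$re[k], imaginary = z$im[k])
      comp_sum <- comp_sum + cv_component(zk, xg, paired = FALSE)
    }
    expect_lt(max(abs(comp_sum - total) / pmax(1, abs(total))), 1e-6)
  }
})

test_that("decomposition profiles one component per pair and per real root", {
  # (x^2+5x+6) = (x+2)(x+3): two lone negative real roots
  poly <- hpfold:::as_hp_polynomial(c(6, 5, 1))
  z <- find_zeros(poly)
  expect_equal(sort(z$re), c(-3, -2), tolerance = 1e-14)
  comps <- decompose(z)
  expect_equal(nrow(comps), 2L)
  expect_true(all(!comps$paired))
  zt <- find_zeros(toy_poly())
  ct <- decompose(zt)
  expect_equal(nrow(ct), 5L)
  expect_true(all(ct$paired))
  expect_true(all(!ct$peakless))
  # the pair closest to the positive real axis dominates the total CV peak
  dom <- ct[which.min(abs(atan2(ct$im, ct$re))), ]
  expect_equal(max(ct$peak_height), dom$peak_height)
})

test_that("banding splits synthetic two-ring spectra and binomials stay single-band", {
  zt <- band_zeros(find_zeros(toy_poly()))
  expect_true(all(zt$band == "collapse"))
  expect_equal(attr(zt, "n_bands"), 1L)
  # two rings of moduli 1.2 and 1.6: (x^6 + 1.2^6)(x^8 + 1.6^8)
  p1 <- c(1.2^6, rep(0, 5), 1)
  p2 <- c(1.6^8, rep(0, 7), 1)
  coefs <- rep(0, 15)
  for (i in seq_along(p1)) for (j in seq_along(p2))
    coefs[i + j - 1] <- coefs[i + j - 1] + p1[i] * p2[j]
  zb <- band_zeros(find_zeros(hpfold:::as_hp_polynomial(coefs)))
  expect_equal(attr(zb, "n_bands"), 2L)
  expect_equal(sort(unique(zb$band)), c("collapse", "folding"))
  expect_true(all(zb$band[zb$modulus < 1.4] == "collapse"))
  expect_true(all(zb$band[zb$modulus > 1.4] == "folding"))
})

test_that("transition temperatures come from the first-zero components", {
  # synthetic two-ring spectrum: collapse from the inner ring, folding from
  # the dominant outer component
  p1 <- c(1.15^6, rep(0, 5), 1)
  p2 <- c(1.7^4, rep(0, 3), 1)
  coefs <- rep(0, 11)
  for (i in seq_along(p1)) for (j in seq_along(p2))
    coefs[i + j - 1] <- coefs[i + j - 1] + p1[i] * p2[j]
  poly <- hpfold:::as_hp_polynomial(coefs)
  z <- band_zeros(find_zeros(poly))
  comps <- decompose(z)
  tr <- transition_temperatures(z, comps)
  expect_equal(tr$n_bands, 2L)
  expect_gt(tr$t_theta, tr$t_f)
  expect_equal(tr$sigma, (tr$t_theta - tr$t_f) / tr$t_theta)
  # collapse zero is the inner-ring root closest to the positive real axis
  inner <- z[z$band == "collapse" & z$im >= 0, ]
  expect_equal(Re(tr$collapse_zero), inner$re[which.min(abs(inner$arg))])
  # single-band spectrum: folding undefined
  zs <- band_zeros(find_zeros(toy_poly()))
  trs <- transition_temperatures(zs, decompose(zs))
  expect_true(is.na(trs$t_f))
  expect_false(is.na(trs$t_theta))
})

test_that("a single-pair spectrum has crossover score 0 and group 1", {
  p1 <- c(1.15^2, 0, 1)          # one conjugate pair (inner)
  p2 <- c(1.8^2, 0, 1)           # one conjugate pair (outer)
  coefs <- rep(0, 5)
  for (i in 1:3) for (j in 1:3)
    coefs[i + j - 1] <- coefs[i + j - 1] + p1[i] * p2[j]
  z <- band_zeros(find_zeros(hpfold:::as_hp_polynomial(coefs)))
  tr <- transition_temperatures(z, decompose(z))
  cl <- classify_foldability(tr)
  expect_equal(cl$crossover_score, 0)
  expect_equal(cl$group, 1L)
})
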
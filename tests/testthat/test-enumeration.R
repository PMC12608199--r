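# exact enumeration: densities of states, partition polynomials,
# ground states, and the sequence screen

test_that("tiny chains reproduce hand-countable densities of states", {
  # 3 beads: one rod + four bends under the fixed-first-step convention
  for (s in c("HHH", "HPH", "PPP"))
    expect_equal(dos_as_map(enumerate_dos(s)), c("0" = 5))
  # 4 beads: 25 walks; the four U-shapes have one H-H contact
  expect_equal(dos_as_map(enumerate_dos("HHHH")), c("-10" = 4, "0" = 21))
  expect_equal(dos_as_map(enumerate_dos("HHHH", mode = "fixed")),
               c("-10" = 4, "0" = 21))
  expect_equal(dos_as_map(enumerate_dos("HPPH")), c("-10" = 4, "0" = 21))
  expect_equal(dos_as_map(enumerate_dos("PPPP")), c("-3" = 4, "0" = 21))
})

test_that("production enumerator matches the naive reference enumerator", {
  set.seed(7)
  for (s in c("HPHPH", "PPHHPP", random_hp_string(6), random_hp_string(7))) {
    ref <- reference_dos(s)
    expect_equal(dos_as_map(enumerate_dos(s, mode = "fixed")), dos_as_map(ref))
    expect_equal(dos_as_map(enumerate_dos(s, mode = "symmetry")), dos_as_map(ref))
  }
})

test_that("fixed-first-step and symmetry-weighted modes agree exactly", {
  set.seed(11)
  for (n in c(8, 9, 10)) {
    s <- random_hp_string(n)
    expect_equal(dos_as_map(enumerate_dos(s, mode = "fixed")),
                 dos_as_map(enumerate_dos(s, mode = "symmetry")),
                 info = s)
  }
})

test_that("total conformation count is sequence-independent", {
  set.seed(13)
  # known fixed-first-step walk counts c_{N-1}/6 for the cubic lattice
  walks <- c("4" = 25, "6" = 589, "8" = 13565)
  for (n in c(4, 6, 8)) {
    t1 <- sum(enumerate_dos(random_hp_string(n))$count)
    t2 <- sum(enumerate_dos(random_hp_string(n))$count)
    expect_equal(t1, t2)
    expect_equal(t1, unname(walks[as.character(n)]))
  }
})

test_that("polynomial transcription preserves counts and degree", {
  p <- build_polynomial(enumerate_dos("HHH"))
  expect_equal(p$coef, 5)
  expect_equal(p$degree, 0L)
  p <- build_polynomial(enumerate_dos("HHHH"))
  expect_equal(p$coef, c(21, rep(0, 9), 4))   # 4 x^10 + 21
  expect_equal(p$degree, 10L)
  # a hand-made DoS with a positive energy must be rejected
  fake <- structure(data.frame(energy = c(-1L, 2L), count = c(1, 1)),
                    class = c("hp_dos", "data.frame"))
  expect_error(build_polynomial(fake), "positive energies")
})

test_that("ground-state reports are consistent and homopolymers are degenerate", {
  gs <- ground_state("HPPHPHPP")
  expect_s3_class(gs$conformation, "hp_conformation")
  expect_equal(hp_energy(gs$conformation, "HPPHPHPP"), gs$e0)
  d <- enumerate_dos("HPPHPHPP")
  expect_equal(gs$e0, min(d$energy))
  expect_equal(gs$n_e0, d$count[which.min(d$energy)])
  # homopolymers can realise their maximal contact count in many shapes
  for (s in c("HHHHHHH", "PPPPPPPP")) {
    gs <- ground_state(s)
    expect_false(gs$unique)
    expect_gt(gs$n_e0, 8)
  }
})

test_that("screen agrees with per-sequence enumeration at small n", {
  n <- 6L
  sc <- screen_sequences(n)
  expect_equal(attr(sc, "n_total"), 64)
  expect_true(all(sc$n_e0 == 8))
  expect_false(is.unsorted(sc$sequence))
  expect_false(paste(rep("H", n), collapse = "") %in% sc$sequence)
  expect_false(paste(rep("P", n), collapse = "") %in% sc$sequence)
  # full cross-check of candidates against independent enumeration
  all_seqs <- vapply(0:(2^n - 1), function(s) {
    bits <- bitwAnd(bitwShiftR(s, 0:(n - 1L)), 1L)
    paste(ifelse(bits == 1L, "H", "P"), collapse = "")
  }, "")
  expected <- Filter(function(s) {
    d <- enumerate_dos(s)
    d$count[which.min(d$energy)] == 8
  }, all_seqs)
  expect_setequal(sc$sequence, expected)
})

test_that("screen checkpoints are written and resumed", {
  ck <- tempfile(fileext = ".tsv")
  sc <- screen_sequences(5, checkpoint = ck)
  expect_true(file.exists(ck))
  again <- screen_sequences(5, checkpoint = ck, resume = TRUE)
  expect_equal(again$sequence, sc$sequence)
  expect_equal(again$e0, sc$e0)
})

test_that("per-sequence fallback matches the signature screen", {
  sc <- screen_sequences(5)
  direct <- screen_sequences_direct(sc$sequence)
  expect_equal(direct$sequence, sc$sequence)
  expect_equal(direct$e0, sc$e0)
  expect_equal(direct$n_e0, sc$n_e0)
})
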
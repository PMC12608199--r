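# lattice geometry, sequences, conformations, contact energy

test_that("sequence validation catches bad residues and short chains", {
  expect_error(hp_sequence("HPX"), "position 3")
  expect_error(hp_sequence("HXPH"), "'X' at position 2")
  expect_error(hp_sequence("HP"), "at least 3")
  expect_error(hp_sequence(c("HPH", "PPH")), "single character string")
  s <- hp_sequence("hpPH")   # case-insensitive input
  expect_equal(as.character(s), "HPPH")
  expect_equal(length(s), 4L)
  expect_identical(hp_sequence(s), s)
})

test_that("interaction parameters enforce the HP inequalities", {
  p <- hp_params()
  expect_equal(c(p$eHH, p$eHP, p$ePP), c(-10L, -6L, -3L))
  expect_error(hp_params(-6, -10, -3), "eHH < eHP < ePP")
  expect_error(hp_params(-30, -10, 0), "negative")
  # demixing condition: eHH + ePP < 2 eHP
  expect_error(hp_params(-10, -7, -3), "2\\*eHP")
  expect_error(hp_params(-10.5, -6, -3), "integer")
})

test_that("direction strings and coordinates are a bijection", {
  dirs <- c("RRR", "RUL", "RUFDL", "RULDR")  # last one revisits the origin
  expect_error(hp_conformation("RULD"), "overlap: bead 5")
  for (d in dirs[1:3]) {
    conf <- hp_conformation(d)
    expect_equal(attr(conf, "dirs"), d)
    expect_equal(unname(conf[1, ]), c(0L, 0L, 0L))
    expect_equal(unname(conf[2, ]), c(1L, 0L, 0L))
  }
  expect_error(hp_conformation("RQX"), "invalid direction 'Q' at step 2")
})

test_that("invalid coordinate walks name the first offending bead", {
  broken <- rbind(c(0,0,0), c(1,0,0), c(3,0,0))
  expect_error(hp_conformation(broken), "broken bond: beads 2 and 3")
  overlap <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0), c(0,0,0))
  expect_error(hp_conformation(overlap), "overlap: bead 5")
})

test_that("canonicalisation maps any start onto origin/+x without changing geometry", {
  conf <- random_saw(8)
  for (op in sample(lattice_symmetries(), 8)) {
    moved <- sweep(unclass(conf) %*% t(op), 2, c(-3L, 5L, 2L), `+`)
    canon <- hp_conformation(moved)
    expect_equal(unname(canon[1, ]), c(0L, 0L, 0L))
    expect_equal(unname(canon[2, ]), c(1L, 0L, 0L))
    expect_equal(nrow(contacts(canon)), nrow(contacts(conf)))
  }
})

test_that("contacts finds exactly the nonconsecutive unit-distance pairs", {
  expect_equal(nrow(contacts(straight_chain(10))), 0L)
  u <- hp_conformation(rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)))
  expect_equal(unname(contacts(u)), matrix(c(1L, 4L), 1))
  l <- hp_conformation(rbind(c(0,0,0), c(1,0,0), c(2,0,0), c(2,1,0), c(2,2,0)))
  expect_equal(nrow(contacts(l)), 0L)
  # deterministic sorted order on a denser walk
  cp <- contacts(hp_conformation("RULLDDRR"))
  expect_true(all(diff(order(cp[, 1], cp[, 2])) == 1))
  expect_true(all(cp[, 2] > cp[, 1] + 1))
})

test_that("energy sums typed contact energies", {
  expect_equal(hp_energy(straight_chain(6), "HHHHHH"), 0L)
  u <- hp_conformation("RUL")
  expect_equal(hp_energy(u, "HHHH"), -10L)
  expect_equal(hp_energy(u, "HPPH"), -10L)
  expect_equal(hp_energy(u, "PPPH"), -6L)
  expect_equal(hp_energy(u, "PPPP"), -3L)
  expect_error(hp_energy(u, "HHHHH"), "does not match")
})

test_that("energy is invariant under the 48 lattice symmetries and translation", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    conf <- random_saw(n)
    seq <- hp_sequence(random_hp_string(n))
    e <- hp_energy(conf, seq)
    for (op in sample(lattice_symmetries(), 6)) {
      moved <- sweep(unclass(conf) %*% t(op), 2, sample(-5:5, 3), `+`)
      expect_equal(hp_energy(hp_conformation(moved), seq), e)
    }
  }
})
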
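# Gillespie kinetic Monte Carlo: move catalog, sampling laws, trajectories

test_that("the straight 16-rod has exactly 8 end flips with unit rates", {
  cat16 <- legal_moves(straight_chain(16), SEQ_A, temperature = 4)
  expect_equal(nrow(cat16), 8L)
  expect_true(all(cat16$kind == "end"))
  expect_true(all(cat16$bead %in% c(1L, 16L)))
  expect_true(all(cat16$d_e == 0L))
  expect_true(all(cat16$w == 1))
  expect_equal(attr(cat16, "w_total"), 8)
  expect_equal(attr(cat16, "energy"), 0)
})

test_that("corner flips require perpendicular bonds and a free diagonal site", {
  # open zig-zag: both interior beads can flip across their squares
  zig <- hp_conformation("RUR")
  catz <- legal_moves(zig, "HHHH", temperature = 2)
  corner2 <- catz[catz$kind == "corner" & catz$bead == 2L, ]
  expect_equal(nrow(corner2), 1L)
  expect_equal(unname(unlist(corner2[, c("tx", "ty", "tz")])), c(0L, 1L, 0L))
  expect_equal(corner2$d_e, 0L)
  expect_equal(corner2$w, 1)
  # closed U: each interior bead's diagonal target is occupied by the chain
  u <- hp_conformation("RUL")
  catu <- legal_moves(u, "HHHH", temperature = 2)
  expect_false(any(catu$kind == "corner"))
  # collinear interior beads have no corner flip at all
  rod <- legal_moves(straight_chain(6), "HHHHHH", temperature = 2)
  expect_false(any(rod$kind == "corner"))
})

test_that("every cataloged move keeps the walk self-avoiding and bonded", {
  set.seed(99)
  for (rep in 1:6) {
    conf <- random_saw(10)
    cat_df <- legal_moves(conf, random_hp_string(10), temperature = 1.5)
    for (i in seq_len(nrow(cat_df))) {
      coords <- matrix(as.integer(conf), ncol = 3)
      coords[cat_df$bead[i], ] <- c(cat_df$tx[i], cat_df$ty[i], cat_df$tz[i])
      expect_silent(hp_conformation(coords))   # validates bonds + overlap
    }
  }
})

test_that("forward and reverse move rates obey detailed balance", {
  set.seed(123)
  temperature <- 1.7
  for (rep in 1:5) {
    n <- 9
    conf <- random_saw(n)
    seq <- hp_sequence(random_hp_string(n))
    cat_fwd <- legal_moves(conf, seq, temperature = temperature)
    for (i in seq_len(nrow(cat_fwd))) {
      old <- matrix(as.integer(conf), ncol = 3)
      coords <- old
      coords[cat_fwd$bead[i], ] <- c(cat_fwd$tx[i], cat_fwd$ty[i], cat_fwd$tz[i])
      cat_rev <- legal_moves(hp_conformation(coords, canonicalize = FALSE),
                             seq, temperature = temperature)
      j <- which(cat_rev$bead == cat_fwd$bead[i] &
                 cat_rev$tx == old[cat_fwd$bead[i], 1] &
                 cat_rev$ty == old[cat_fwd$bead[i], 2] &
                 cat_rev$tz == old[cat_fwd$bead[i], 3])
      expect_length(j, 1L)
      expect_equal(cat_rev$d_e[j], -cat_fwd$d_e[i])
      expect_equal(cat_fwd$w[i] / cat_rev$w[j],
                   exp(-cat_fwd$d_e[i] / temperature), tolerance = 1e-12)
    }
  }
})

test_that("waiting times are exponential with rate W_T and <-log xi> = 1", {
  draws <- hpfold:::.kmc_draw_wait_cpp(8, 1e5, 42)
  ks <- suppressWarnings(stats::ks.test(draws, "pexp", rate = 8))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(draws), 1 / 8, tolerance = 0.02)
  # <-log xi> = 1 (unit total rate)
  expect_equal(mean(hpfold:::.kmc_draw_wait_cpp(1, 1e5, 7)), 1, tolerance = 0.02)
})

test_that("move selection frequencies follow W_i / W_T", {
  w <- c(1, 1, exp(-10 / 4.5), exp(-6 / 4.5), 0.5)
  counts <- hpfold:::.kmc_draw_select_cpp(w, 2e5, 11)
  chi <- stats::chisq.test(counts, p = w / sum(w))
  expect_gt(chi$p.value, 0.001)
})

test_that("incremental energy bookkeeping matches recomputation along trajectories", {
  for (s in list(SEQ_A, "HPPHPHPP")) {
    audit <- hpfold:::.kmc_energy_audit_cpp(hpfold:::hp_types(hp_sequence(s)),
                                            c(-10L, -6L, -3L), 2.0, 1e4, 3)
    expect_equal(audit$mismatches, 0L)
    expect_equal(audit$events, 1e4)
  }
})

test_that("trajectories are bitwise reproducible under a fixed seed", {
  gs <- cached("gs8", ground_state("HPPHPHPP"))
  r1 <- first_passage("HPPHPHPP", temperature = 2, seed = 5, ground = gs)
  r2 <- first_passage("HPPHPHPP", temperature = 2, seed = 5, ground = gs)
  expect_identical(r1$fpt, r2$fpt)
  expect_identical(r1$events, r2$events)
  r3 <- first_passage("HPPHPHPP", temperature = 2, seed = 6, ground = gs)
  expect_false(identical(r1$fpt, r3$fpt))
  expect_true(r1$reached)
})

test_that("first passage reports censoring, refuses degenerate sequences, and is 0 at the native state", {
  gs <- cached("gs8", ground_state("HPPHPHPP"))
  censored <- first_passage("HPPHPHPP", temperature = 0.5, seed = 1,
                            max_events = 10, ground = gs)
  expect_false(censored$reached)
  expect_true(censored$censored)
  expect_true(is.na(censored$fpt))
  expect_error(first_passage("HHHHHHH", temperature = 2),
               "unique ground state")
  # starting at the native conformation the first-passage time is zero
  native <- matrix(as.integer(gs$conformation), ncol = 3)
  res <- hpfold:::.kmc_run_cpp(hpfold:::hp_types(hp_sequence("HPPHPHPP")),
                               c(-10L, -6L, -3L), 2.0, gs$e0, 1e6, 1, 0, 0,
                               start = native)
  expect_true(res$reached)
  expect_equal(res$fpt, 0)
  expect_equal(res$events, 0)
})

test_that("gillespie_step applies a cataloged move and advances time", {
  set.seed(1)
  conf <- straight_chain(8)
  cat_df <- legal_moves(conf, "HPPHPHPP", temperature = 2)
  st <- gillespie_step(cat_df)
  expect_s3_class(st$conformation, "hp_conformation")
  expect_gt(st$dt, 0)
  expect_equal(nrow(st$conformation), 8L)
  # reached energy consistent with the applied move
  expect_equal(hp_energy(st$conformation, "HPPHPHPP"), 0L + st$d_e)
})

test_that("mean-FPT curves summarise runs, SEM and censoring correctly", {
  curve <- mean_fpt_curve("HPPHPHPP", temperatures = c(1.5, 2.5), runs = 40,
                          seed = 3, detail = TRUE)
  expect_equal(nrow(curve), 2L)
  expect_true(all(curve$n_runs == 40L))
  expect_true(all(curve$n_censored == 0L))
  runs <- attr(curve, "runs")
  expect_equal(nrow(runs), 80L)
  for (k in 1:2) {
    fpts <- runs$fpt[runs$temperature == curve$temperature[k]]
    expect_equal(curve$mean_fpt[k], mean(fpts))
    expect_equal(curve$sem[k], sd(fpts) / sqrt(length(fpts)))
  }
  # an impossible event cap censors everything and the mean becomes NA
  capped <- mean_fpt_curve("HPPHPHPP", temperatures = 2, runs = 5, seed = 3,
                           max_events = 5)
  expect_true(is.na(capped$mean_fpt))
  expect_equal(capped$n_censored, 5L)
})
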
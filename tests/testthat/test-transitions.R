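params2 <- probeam_params(n_colors = 2, n_cycles = 4)

test_that("detachment branches carry p_d and absorb dark states", {
  s <- pb_state(c(2, 1), c(1, 1), "")
  tr <- detach_step(s, params2)
  expect_equal(sum(tr$prob), 1, tolerance = 1e-12)
  df <- transitions_as_df(tr)
  expect_equal(df$p[df$key == state_key(detach(s))], 0.05)
  expect_equal(df$p[df$key == state_key(s)], 0.95)

  dark <- pb_state(c(2, 1), c(0, 0), "0")
  trd <- detach_step(dark, params2)
  expect_length(trd$states, 1)
  expect_equal(trd$prob, 1)
})

test_that("dye miss follows the per-color binomial product", {
  p1 <- probeam_params(n_colors = 1, n_cycles = 0)
  expect_equal(dye_miss_prob(0L, 1L, p1), 0.07)
  expect_equal(dye_miss_prob(c(2L, 1L), c(2L, 1L), params2), (1 - 0.07)^3)
  expect_error(dye_miss_prob(2L, 1L, p1), "K <= N")
  # normalization over the whole K lattice
  N <- c(2L, 3L)
  kgrid <- expand.grid(0:2, 0:3)
  tot <- sum(apply(kgrid, 1, function(K)
    dye_miss_prob(as.integer(K), N, params2)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("dye loss enumerates K' <= K with binomial mass", {
  p1 <- probeam_params(n_colors = 1, n_cycles = 0)
  s <- pb_state(2, 1, "0")
  tr <- dye_loss_step(s, params = p1)
  df <- transitions_as_df(tr)
  expect_equal(sum(df$p), 1, tolerance = 1e-12)
  expect_equal(df$p[df$key == state_key(s)], 0.95)
  expect_equal(df$p[df$key == state_key(pb_state(2, 0, "0"))], 0.05)

  # unpruned mass is conserved for larger K too
  s2 <- pb_state(c(3, 2), c(3, 2), "")
  expect_equal(sum(dye_loss_step(s2, params = params2)$prob), 1,
               tolerance = 1e-12)

  # an observation close to the current counts prunes distant successors
  x <- s2$K * params2$mu
  trp <- dye_loss_step(s2, x_t = x, params = params2)
  expect_true(trp$pruned)
  expect_true(sum(trp$prob) < 1)
  kept <- vapply(trp$states, function(st) all(st$K >= s2$K - 1), logical(1))
  expect_true(all(kept))

  dark <- pb_state(c(1, 1), c(0, 0), "")
  expect_equal(dye_loss_step(dark, params = params2)$prob, 1)
})

test_that("dye attachment probability is the count fraction", {
  s <- pb_state(c(3, 0, 2), c(1, 0, 1), "")
  expect_equal(p_dye_attached(s, 0), 1 / 3)
  expect_equal(p_dye_attached(pb_state(2, 2, ""), 0), 1)
  expect_equal(p_dye_attached(pb_state(2, 0, ""), 0), 0)
  expect_error(p_dye_attached(s, 1), "N_i >= 1")
})

test_that("removal probabilities renormalize the prior over eta", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database(c("DCK", "CDK"), sch) # "01" and "10", equal priors
  s <- pb_state(c(1, 1), c(1, 1), "")
  pr <- p_removal(db, s)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  expect_equal(unname(pr[c("0", "1")]), c(1 / 2, 1 / 2))
  expect_equal(p_removal(db, s, "."), 0)

  # single-sequence eta: deterministic next symbol
  s2 <- pb_state(c(0, 1), c(0, 1), "0")
  expect_equal(p_removal(db, s2, "1"), 1)
})

test_that("Edman degradation composes failure, dot and color removals", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database(c("ADCK", "GCK"), sch) # ".01" and ".1"
  # eta = {".01"}: next symbol is "." with certainty
  s <- pb_state(c(1, 1), c(1, 1), "")
  tr <- edman_step(db, s, params2)
  df <- transitions_as_df(tr)
  expect_equal(sum(df$p), 1, tolerance = 1e-12)
  expect_equal(df$p[df$key == state_key(s)], 0.06)
  expect_equal(df$p[df$key == state_key(append_removed(s, "."))], 0.94)

  # K = N: a color removal always decrements both K and N (dye surely attached)
  s2 <- pb_state(c(1, 1), c(1, 1), ".")
  tr2 <- transitions_as_df(edman_step(db, s2, params2))
  succ <- dec_K(dec_N(append_removed(s2, "0"), 0), 0)
  expect_equal(tr2$p[tr2$key == state_key(succ)], 0.94)
  expect_equal(sum(tr2$p), 1, tolerance = 1e-12)
})

test_that("degenerate rates leave a single pure-removal successor", {
  p0 <- probeam_params(n_colors = 2, n_cycles = 4, e = 0, l = 0, p_d = 0)
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database("DCK", sch) # "01"
  s <- pb_state(c(1, 1), c(1, 1), "")
  tr <- one_cycle_transitions(db, s, params = p0)
  expect_length(tr$states, 1)
  expect_equal(tr$prob, 1)
  expect_identical(state_key(tr$states[[1]]),
                   state_key(dec_K(dec_N(append_removed(s, "0"), 0), 0)))
})

test_that("every phase and the composition conserve probability", {
  set.seed(21)
  for (seed in 1:6) {
    db <- small_db(8, seed = seed)
    for (rep in 1:8) {
      s <- random_state(db)
      expect_equal(sum(detach_step(s, params2)$prob), 1, tolerance = 1e-12)
      expect_equal(sum(dye_loss_step(s, params = params2)$prob), 1,
                   tolerance = 1e-12)
      expect_equal(sum(edman_step(db, s, params2)$prob), 1, tolerance = 1e-12)
      expect_equal(sum(one_cycle_transitions(db, s, params = params2)$prob), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("the one-cycle composition matches brute-force enumeration", {
  set.seed(31)
  for (seed in 1:5) {
    db <- small_db(8, seed = seed)
    for (rep in 1:6) {
      s <- random_state(db)
      x <- if (rep %% 2 == 0) rnorm(2, s$K * params2$mu, 0.2) else NULL
      got <- transitions_as_df(one_cycle_transitions(db, s, x, params2))
      want <- bf_transitions(db, s, params2, x)
      got <- got[order(got$key), ]
      want <- want[order(want$key), ]
      expect_equal(got$key, want$key)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("dark states are absorbing through the full cycle", {
  db <- small_db(6, seed = 2)
  d <- db$dye_seqs$dye_seq[1]
  s <- pb_state(dye_count(d, 2), c(0, 0), "")
  tr <- one_cycle_transitions(db, s, params = params2)
  expect_length(tr$states, 1)
  expect_equal(tr$prob, 1)
  expect_identical(state_key(tr$states[[1]]), state_key(s))
})
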
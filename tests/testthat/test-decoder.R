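params2 <- probeam_params(n_colors = 2, n_cycles = 4)

test_that("beam steps stay normalized and merge duplicate successors", {
  db <- small_db(10, seed = 8)
  set.seed(18)
  rd <- simulate_reads(db, params2, 10)
  for (r in seq_len(5)) {
    x <- rd$intensities[r, , ]
    beam <- greedy_initial_beam(db, x[, 1], params2)
    for (t in 1:4) {
      beam <- beam_step(db, beam, x[, t + 1], params2)
      expect_equal(lse(beam$logw), 0, tolerance = 1e-10)
      keys <- vapply(beam$states, state_key, character(1))
      expect_false(anyDuplicated(keys) > 0)
      expect_true(length(beam$states) <= params2$n_beam)
    }
  }
})

test_that("deterministic degenerate parameters follow a single trajectory", {
  p0 <- probeam_params(n_colors = 2, n_cycles = 3, e = 0, l = 0, m = 0,
                       p_d = 0, sigma = 1e-4, sigma_b = 1e-5, n_beam = 50)
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database(c("DCK", "CDK", "DCC"), sch) # "01", "10", "011"
  # noiseless staircase for "01": K [1,1] -> [0,1] -> [0,0] -> [0,0]
  x <- cbind(c(1, 1), c(0, 1), c(0, 0), c(0, 0))
  res <- decode_read(db, x, p0)
  expect_equal(res$sequence, "DCK")
  expect_equal(res$posterior, 1, tolerance = 1e-9)
})

test_that("a single-peptide database always decodes to it with posterior 1", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database("DCK", sch)
  set.seed(9)
  rd <- simulate_reads(db, params2, 20)
  res <- decode_batch(db, rd, params2)
  ok <- !res$undecodable
  expect_true(all(res$predicted_peptide_id[ok] == 1))
  expect_equal(res$posterior[ok], rep(1, sum(ok)), tolerance = 1e-12)
})

test_that("peptide posteriors sum to one across the database", {
  db <- small_db(10, seed = 12)
  set.seed(22)
  rd <- simulate_reads(db, params2, 25)
  res <- decode_batch(db, rd, params2)
  post <- attr(res, "posterior")
  ok <- !res$undecodable
  expect_equal(rowSums(post[ok, , drop = FALSE]),
               rep(1, sum(ok)), tolerance = 1e-10)
})

test_that("wide-beam decoding reproduces the exact posterior", {
  db <- small_db(12, seed = 13)
  pinf <- probeam_params(n_colors = 2, n_cycles = 4, n_beam = 1e9, h = Inf)
  set.seed(23)
  rd <- simulate_reads(db, pinf, 60)
  res <- decode_batch(db, rd, pinf)
  ex <- decode_map_exact_batch(db, rd, pinf)
  expect_false(any(res$pruned))
  expect_equal(attr(res, "posterior"), attr(ex, "posterior"),
               tolerance = 1e-9)
  # with the default pruning threshold the posterior barely moves
  res5 <- decode_batch(db, rd, probeam_params(n_colors = 2, n_cycles = 4,
                                              n_beam = 1e9))
  expect_equal(attr(res5, "posterior"), attr(ex, "posterior"),
               tolerance = 1e-4)
})

test_that("the beam posterior converges to the exact posterior as N_B grows", {
  db <- small_db(12, seed = 14)
  set.seed(24)
  rd <- simulate_reads(db, params2, 400)
  exact <- attr(decode_map_exact_batch(db, rd, params2), "posterior")
  err <- vapply(c(1, 5, 20, 100), function(nb) {
    p <- probeam_params(n_colors = 2, n_cycles = 4, n_beam = nb)
    post <- attr(decode_batch(db, rd, p), "posterior")
    mean(abs(post - exact), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-6))
  expect_lt(err[4], 1e-3)
})

test_that("pathological observations are flagged, not force-predicted", {
  db <- small_db(6, seed = 15)
  # x around 0.12 is outside the pruning window of every integer count
  x <- matrix(0.12, 2, 5)
  x[, 1] <- c(1, 1)
  res <- decode_read(db, x, params2)
  expect_true(res$undecodable)
  expect_true(is.na(res$peptide_id))

  # batch decoding carries the flag through without aborting
  rd <- structure(list(intensities = array(rep(x, each = 2), c(2, 2, 5)),
                       true_peptide = c(1L, 1L), read_id = 1:2,
                       n_dropped = 0L), class = "pb_reads")
  resb <- decode_batch(db, rd, params2)
  expect_true(all(resb$undecodable))
  expect_true(all(is.na(resb$predicted_peptide_id)))
})

test_that("batch decoding is deterministic and order-preserving", {
  db <- small_db(8, seed = 16)
  set.seed(26)
  rd <- simulate_reads(db, params2, 30)
  r1 <- decode_batch(db, rd, params2)
  r2 <- decode_batch(db, rd, params2)
  expect_identical(r1, r2)
  expect_identical(r1$read_id, rd$read_id)

  # single-read decoding agrees with the batch row
  one <- decode_read(db, rd$intensities[7, , ], params2)
  expect_identical(one$peptide_id, r1$predicted_peptide_id[7])
  expect_equal(one$posterior, r1$posterior[7], tolerance = 1e-12)

  # empty batch decodes to an empty result
  rd0 <- simulate_reads(db, params2, 0)
  expect_equal(nrow(decode_batch(db, rd0, params2)), 0L)
})
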
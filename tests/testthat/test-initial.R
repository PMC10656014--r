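params2 <- probeam_params(n_colors = 2, n_cycles = 4)

test_that("ideal states group dye sequences by count vector", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database(c("DCK", "CDK"), sch) # "01", "10": same counts
  ideal <- ideal_states(db)
  expect_equal(nrow(ideal), 1L)
  expect_equal(ideal$N[[1]], c(1L, 1L))
  expect_equal(ideal$prob, 1)

  for (seed in 1:4) {
    db <- small_db(10, seed = seed)
    ideal <- ideal_states(db)
    expect_equal(sum(ideal$prob), 1, tolerance = 1e-12)
    # probabilities are the summed priors of the matching dye sequences
    for (r in seq_len(nrow(ideal))) {
      match_prior <- sum(db$dye_seqs$prior[vapply(db$dye_seqs$dye_seq,
        function(d) identical(dye_count(d, 2), ideal$N[[r]]), logical(1))])
      expect_equal(ideal$prob[r], match_prior, tolerance = 1e-12)
    }
  }
})

test_that("the initial joint is the ideal-state times dye-miss product", {
  db <- small_db(8, seed = 3)
  ideal <- ideal_states(db)
  for (r in seq_len(nrow(ideal))) {
    N <- ideal$N[[r]]
    expect_equal(initial_joint_logprob(db, pb_state(N, N, ""), params2),
                 log(ideal$prob[r]) + log((1 - 0.07)^sum(N)),
                 tolerance = 1e-12)
    # summing over all K <= N recovers the ideal-state probability
    kgrid <- expand.grid(lapply(N, function(n) 0:n))
    tot <- sum(apply(kgrid, 1, function(K)
      exp(initial_joint_logprob(db, pb_state(N, as.integer(K), ""), params2))))
    expect_equal(tot, ideal$prob[r], tolerance = 1e-12)
  }
})

test_that("p_upper bounds p_alpha and tightens at K = N for small m", {
  db <- small_db(8, seed = 4)
  set.seed(14)
  x0 <- runif(2, 0, 3)
  for (rep in 1:20) {
    s <- pb_state(
      N <- dye_count(sample(db$dye_seqs$dye_seq, 1), 2),
      vapply(N, function(n) sample(0:n, 1), integer(1)), "")
    pa <- p_alpha(db, s, x0, params2)
    pu <- p_upper(db, s, x0, params2)
    expect_true(pu >= pa)
    expect_equal(pu - pa, -log(dye_miss_prob(s$K, s$N, params2)),
                 tolerance = 1e-10)
  }
})

test_that("the greedy initial search equals exhaustive enumeration", {
  set.seed(41)
  for (rep in 1:20) {
    db <- small_db(sample(4:12, 1), seed = 500 + rep)
    p <- probeam_params(n_colors = 2, n_cycles = 4,
                        n_beam = sample(c(1, 3, 8, 25), 1))
    x0 <- runif(2, -0.5, 4)
    beam <- greedy_initial_beam(db, x0, p)
    got <- vapply(beam$states, state_key, character(1))
    expect_setequal(got, exhaustive_initial_keys(db, x0, p))
    # weights are the normalized scores
    expect_equal(lse(beam$logw), 0, tolerance = 1e-10)
    expect_equal(beam$logw, beam$log_palpha - lse(beam$log_palpha),
                 tolerance = 1e-10)
  }
})

test_that("a beam wide enough returns every initial state", {
  db <- small_db(6, seed = 6)
  p <- probeam_params(n_colors = 2, n_cycles = 4, n_beam = 1e9)
  ideal <- ideal_states(db)
  total <- sum(vapply(ideal$N, function(N) prod(N + 1), numeric(1)))
  beam <- greedy_initial_beam(db, c(1, 1), p)
  expect_length(beam$states, total)
})

test_that("an exact observation with a dominant prior ranks first", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  # nine peptides share "01"; one maps to "0011"
  db <- build_database(c("DCK", "DCA", "DCG", "DCT", "DCS",
                         "DCW", "DCV", "DCM", "DCF", "DDCCAA"), sch)
  p <- probeam_params(n_colors = 2, n_cycles = 4, n_beam = 3)
  beam <- greedy_initial_beam(db, c(1, 1), p)
  expect_equal(beam$states[[1]]$N, c(1L, 1L))
  expect_equal(beam$states[[1]]$K, c(1L, 1L))
})
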
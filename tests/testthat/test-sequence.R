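test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_equal(digest_trypsin("AAKAA"), c("AAK", "AA"))
  expect_equal(digest_trypsin("AAA"), "AAA")
  expect_equal(digest_trypsin("AKPA"), "AKPA")
  expect_equal(digest_trypsin("KRK"), c("K", "R", "K"))
  expect_equal(digest_trypsin("MKRPGR"), c("MK", "RPGR"))
  expect_error(digest_trypsin(""), "empty")

  set.seed(7)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    prot <- paste(sample(aa, sample(5:60, 1), replace = TRUE), collapse = "")
    frags <- digest_trypsin(prot)
    expect_identical(paste(frags, collapse = ""), prot)
    # internal cleavage sites are exhausted: no K/R inside a fragment except
    # at its end or when followed by P
    for (f in frags) {
      inner <- substr(f, 1, nchar(f) - 1)
      hits <- gregexpr("[KR](?!P)", inner, perl = TRUE)[[1]]
      expect_true(hits[1] == -1 || all(hits == nchar(inner)))
    }
  }
})

test_that("dye-sequence construction substitutes colors and trims dots", {
  expect_identical(to_dye_sequence("DAREICIKS", scheme_tbl2()), "2..0.0.1")
  expect_identical(to_dye_sequence("AAAA", scheme_tbl2()), "")
  expect_identical(to_dye_sequence("KD", label_scheme(list("X", "K", "D"))), "12")
  expect_identical(to_dye_sequence("DAA", scheme2()), "0")
})

test_that("dye counting and prefix tests match hand counts", {
  expect_equal(dye_count("1.02..0.0.2", 3), c(3L, 1L, 2L))
  expect_equal(dye_count("", 3), c(0L, 0L, 0L))
  expect_equal(dye_count("2..0.0.1", 3), c(2L, 1L, 1L))
  expect_equal(dseq_starts_with("2.", "2..0.0.1"), 1L)
  expect_equal(dseq_starts_with("", "2..0.0.1"), 1L)
  expect_equal(dseq_starts_with("1", "2..0.0.1"), 0L)
})

test_that("dye counts equal labelable residue counts and survive trimming", {
  set.seed(11)
  sch <- scheme3()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:50) {
    pep <- paste(sample(aa, sample(3:15, 1), replace = TRUE), collapse = "")
    d <- to_dye_sequence(pep, sch)
    cnt <- dye_count(d, 3)
    chars <- strsplit(pep, "")[[1]]
    for (i in 0:2) {
      expect_identical(cnt[i + 1], sum(chars %in% names(sch)[sch == i]))
    }
    # trimming never changes the counts
    expect_identical(cnt, dye_count(paste0(d, "..."), 3))
  }
})

test_that("database priors follow the uniform peptide prior", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  expect_message(db <- build_database(c("ACDK", "ACEK", "GCK", "GGK"), sch),
                 "GGK")
  expect_identical(db$dropped, "GGK")
  expect_equal(sum(db$prior_p), 1, tolerance = 1e-12)
  expect_equal(sum(db$dye_seqs$prior), 1, tolerance = 1e-12)
  # ACDK and ACEK share a dye sequence: prior 2/3 of the 3 kept peptides
  shared <- db$dye_seqs$prior[db$dye_seqs$dye_seq ==
                                to_dye_sequence("ACDK", sch)]
  expect_equal(shared, 2 / 3)

  db1 <- build_database("ACDK", sch)
  expect_equal(db1$prior_p, 1)
  expect_equal(db1$dye_seqs$prior, 1)

  expect_error(suppressMessages(build_database(c("GGG", "AAA"), sch)),
               "labelable")
})

test_that("dye-sequence priors are the grouped peptide priors", {
  for (seed in 1:5) {
    db <- small_db(12, seed = seed)
    grouped <- tapply(db$prior_p[db$peptides$id], db$peptides$dseq_id, sum)
    expect_equal(as.numeric(grouped[as.character(db$dye_seqs$id)]),
                 db$dye_seqs$prior, tolerance = 1e-12)
    expect_equal(sum(db$prior_p), 1, tolerance = 1e-12)
    expect_equal(sum(db$dye_seqs$prior), 1, tolerance = 1e-12)
  }
})

test_that("duplicate peptides collapse and proteins are digested first", {
  sch <- label_scheme(list(c("D", "E"), "C"))
  db <- build_database(c("ACDK", "ACDK", "AEEK"), sch)
  expect_equal(nrow(db$peptides), 2L)
  dbp <- suppressMessages(build_database("ACDKAEEK", sch, type = "proteins"))
  expect_setequal(dbp$peptides$sequence, c("ACDK", "AEEK"))
})

test_that("label schemes validate their invariants", {
  expect_error(label_scheme(list(c("D", "E"), "D")), "at most one color")
  expect_error(label_scheme(list(character(0))), "at least one")
  expect_error(label_scheme(list("DE")), "single uppercase")
  sch <- label_scheme(list(c("D", "E"), "C"))
  expect_error(to_dye_sequence("ACD", sch, n_colors = 1), "n_colors")
})
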
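test_that("a minimal well-formed session validates and reports its shape", {
  feats <- list(A = matrix(rnorm(300), 3), V = matrix(rnorm(3 * 2048), 3),
                T = matrix(rnorm(3 * 768), 3))
  s <- session_sample("s1", feats, 12.0, "PHQ8")
  expect_s3_class(s, "mignn_session")
  expect_equal(s$n_utterances, 3L)
  cohort <- as_cohort(list(s))
  expect_length(cohort, 1L)
})

test_that("row-count mismatch across modalities is rejected, naming the counts", {
  feats <- list(A = matrix(0, 3, 10), V = matrix(0, 4, 10))
  expect_error(session_sample("s1", feats, 5, "PHQ8"), "3 vs 4")
})

test_that("labels outside the scale range and degenerate inputs are rejected", {
  m <- matrix(0, 2, 3)
  expect_error(session_sample("s", list(A = m), 30, "PHQ8"), "range")
  expect_error(session_sample("s", list(A = m), -1, "BDI"), "range")
  expect_silent(session_sample("s", list(A = m), 63, "BDI"))
  expect_error(session_sample("s", list(), 5, "PHQ8"), "at least one modality")
  expect_error(session_sample("s", list(A = matrix(NA_real_, 2, 3)), 5, "PHQ8"),
               "non-finite")
})

test_that("cohort-level validation enforces uniform modalities, dims, scale and ids", {
  a <- session_sample("a", list(A = matrix(0, 2, 3)), 5, "PHQ8")
  b_dup <- session_sample("a", list(A = matrix(0, 3, 3)), 6, "PHQ8")
  b_mods <- session_sample("b", list(A = matrix(0, 2, 3), T = matrix(0, 2, 2)), 6, "PHQ8")
  b_dims <- session_sample("b", list(A = matrix(0, 2, 4)), 6, "PHQ8")
  b_scale <- session_sample("b", list(A = matrix(0, 2, 3)), 6, "BDI")
  expect_error(as_cohort(list(a, b_dup)), "duplicate")
  expect_error(as_cohort(list(a, b_mods)), "modality set")
  expect_error(as_cohort(list(a, b_dims)), "dimension")
  expect_error(as_cohort(list(a, b_scale)), "scales")
})

test_that("an empty cohort writes a manifest with no matrix files", {
  d <- withr::local_tempdir()
  write_cohort(list(), d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  expect_length(list.files(d, pattern = "csv$"), 0L)
  expect_length(read_cohort(file.path(d, "manifest.json")), 0L)
})

test_that("two 3-modality sessions produce 2 manifest entries and 6 matrix files", {
  cohort <- tiny_cohort(2, seed = 4)
  d <- withr::local_tempdir()
  mf <- write_cohort(cohort, d)
  expect_length(jsonlite::read_json(mf)$entries, 2L)
  expect_length(list.files(d, pattern = "csv$"), 6L)
})

test_that("cohorts round-trip losslessly and in order through write/read", {
  for (seed in 1:3) {
    cohort <- tiny_cohort(3, seed = seed)
    d <- withr::local_tempdir()
    mf <- write_cohort(cohort, d)
    back <- read_cohort(mf)
    expect_equal(cohort_ids(back), cohort_ids(cohort))
    for (i in seq_along(cohort)) {
      expect_equal(back[[i]]$label, cohort[[i]]$label)
      expect_equal(back[[i]]$scale, cohort[[i]]$scale)
      for (m in names(cohort[[i]]$features))
        expect_equal(back[[i]]$features[[m]], cohort[[i]]$features[[m]],
                     tolerance = 1e-9)
    }
  }
})

test_that("loading preserves utterance order (file row i is utterance i)", {
  m <- matrix(seq_len(12), 4, 3)             # distinguishable rows
  s <- session_sample("ord", list(A = m), 3, "PHQ8")
  d <- withr::local_tempdir()
  back <- read_cohort(write_cohort(list(s), d))
  expect_equal(back[[1]]$features$A, m)
})

test_that("write -> read -> write produces byte-identical manifests", {
  cohort <- tiny_cohort(2, seed = 9)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_cohort(cohort, d1)
  m2 <- write_cohort(read_cohort(m1), d2)
  expect_identical(readLines(m1, warn = FALSE), readLines(m2, warn = FALSE))
})

test_that("missing feature files are reported with the session id", {
  cohort <- tiny_cohort(1, seed = 2)
  d <- withr::local_tempdir()
  mf <- write_cohort(cohort, d)
  file.remove(file.path(d, sprintf("%s.A.csv", cohort_ids(cohort)[1])))
  expect_error(read_cohort(mf), "syn0001")
})

test_that("duplicate session ids abort write_cohort before any file is written", {
  s <- session_sample("dup", list(A = matrix(0, 2, 3)), 5, "PHQ8")
  d <- withr::local_tempdir()
  expect_error(write_cohort(list(s, s), d), "duplicate")
  expect_length(list.files(d), 0L)
})
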
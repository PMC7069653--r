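test_that("write/read round-trips the dataset and is byte-stable", {
  d <- simulate_trial(small_design(), seed = 8)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_challenge_dataset(d, f1)
  back <- read_challenge_dataset(f1)
  expect_equal(names(back), names(d))
  expect_equal(nrow(back), nrow(d))
  expect_equal(back$DV, d$DV, tolerance = 1e-5)
  expect_identical(back$ID, as.integer(d$ID))
  expect_identical(back$STUDY, d$STUDY)
  # identical content twice -> identical bytes
  write_challenge_dataset(d, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # no locale-dependent decimal marks
  expect_false(any(grepl(",5", readLines(f1)[2], fixed = TRUE)))
})

test_that("an empty dataset writes a header-only file", {
  d <- simulate_trial(small_design(), seed = 8)[0, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_challenge_dataset(d, f)
  expect_length(readLines(f), 1L)
})

test_that("validation reports offending rows", {
  d <- simulate_trial(small_design(), seed = 8)
  bad <- d
  i <- which(bad$EVID == 0L)[4]
  bad$DVID[i] <- 4L
  expect_error(validate_challenge_dataset(bad), "unknown DVID")
  expect_error(validate_challenge_dataset(bad), paste0("row ", i))

  bad2 <- d
  j <- which(bad2$EVID == 0L)[1]
  bad2$DV[j] <- -5
  expect_error(validate_challenge_dataset(bad2), "DV >= 0")

  bad3 <- d[!(d$EVID == 1L & d$ID == 1L), ]
  expect_error(validate_challenge_dataset(bad3),
               "treatment occasion without exactly one dose row")

  bad4 <- d
  bad4$CBG[which(bad4$ID == 2L)[1]] <- 99
  expect_error(validate_challenge_dataset(bad4), "CBG varies")

  expect_error(read_challenge_dataset(file.path(tempdir(), "nope.csv")),
               "No such file")
})

test_that("the simulator's output always passes validation", {
  for (s in 1:3) {
    expect_silent(validate_challenge_dataset(
      simulate_trial(small_design(), seed = s)))
  }
})
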
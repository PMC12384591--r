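test_that("trial construction enforces ratings and baseline bounds", {
  d <- matrix(0, 2, 10)
  expect_error(eeg_trial(d, n_baseline = 12, arousal = 5, valence = 5), "n_baseline")
  expect_error(eeg_trial(d, n_baseline = 4, arousal = 0.5, valence = 5), "\\[1, 9\\]")
  tr <- eeg_trial(d, n_baseline = 4, arousal = 5, valence = 9)
  expect_s3_class(tr, "eeg_trial")
})

test_that("rating thresholds follow the low <= 5 < high rule exactly", {
  mk <- function(a, v) eeg_trial(matrix(0, 2, 4), 2, arousal = a, valence = v)
  expect_equal(as.character(label_trial(mk(5.0, 1), label_scheme("arousal"))), "LA")
  expect_equal(as.character(label_trial(mk(5.01, 1), label_scheme("arousal"))), "HA")
  expect_equal(as.character(label_trial(mk(5.0, 9), label_scheme("quaternary"))), "LAHV")
  expect_equal(as.character(label_trial(mk(6, 5), label_scheme("valence"))), "LV")
})

test_that("quaternary labels partition the rating grid and refine the binary tasks", {
  grid <- expand.grid(a = seq(1, 9, by = 0.5), v = seq(1, 9, by = 0.5))
  for (i in seq_len(nrow(grid))) {
    tr <- eeg_trial(matrix(0, 2, 4), 2, arousal = grid$a[i], valence = grid$v[i])
    q <- as.character(label_trial(tr, label_scheme("quaternary")))
    a <- as.character(label_trial(tr, label_scheme("arousal")))
    v <- as.character(label_trial(tr, label_scheme("valence")))
    expect_true(q %in% c("LALV", "HALV", "LAHV", "HAHV"))
    expect_equal(substr(q, 1, 2), a)
    expect_equal(substr(q, 3, 4), v)
  }
})

test_that("the packaged montage lists 32 unique names with the documented anchors", {
  nm <- montage_names()
  expect_length(nm, 32L)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(nm[c(20, 22)], c("F4", "FC6"))
  expect_equal(nm[1], "Fp1")
})

test_that("the DEAP-layout subject container round-trips and validates", {
  set.seed(4)
  data <- array(rnorm(40 * 40 * 8064), dim = c(40, 40, 8064))
  labels <- cbind(valence = runif(40, 1, 9), arousal = runif(40, 1, 9),
                  dominance = runif(40, 1, 9), liking = runif(40, 1, 9))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path), add = TRUE)
  write_deap_subject(data, labels, path)
  trials <- read_deap_subject(path)
  expect_length(trials, 40L)
  expect_identical(dim(trials[[1]]$data), c(32L, 8064L))
  expect_identical(trials[[1]]$n_baseline, 384L)
  expect_equal(trials[[7]]$arousal, unname(labels[7, "arousal"]))
  expect_equal(trials[[7]]$valence, unname(labels[7, "valence"]))
  expect_equal(trials[[3]]$data[5, ], data[3, 5, ])

  # directory form (raw float64 written in C order + ratings CSV)
  dirp <- tempfile()
  dir.create(dirp)
  on.exit(unlink(dirp, recursive = TRUE), add = TRUE)
  # C order from a (trial, channel, sample) array = sample fastest
  writeBin(as.vector(aperm(data, c(3, 2, 1))), file.path(dirp, "eeg.bin"),
           size = 8, endian = "little")
  utils::write.csv(as.data.frame(labels), file.path(dirp, "ratings.csv"),
                   row.names = FALSE)
  trials2 <- read_deap_subject(dirp)
  expect_equal(trials2[[3]]$data[5, ], data[3, 5, ])
  expect_equal(trials2[[7]]$arousal, unname(labels[7, "arousal"]))

  # malformed containers fail with the offending dimension named
  expect_error({
    write_deap_subject(data[1:39, , ], labels, path); read_deap_subject(path)
  }, "trial dimension")
  expect_error({
    write_deap_subject(data[, , 1:100], labels, path); read_deap_subject(path)
  }, "sample dimension")
  bad <- labels; bad[2, "valence"] <- 0.5
  expect_error({
    write_deap_subject(data, bad, path); read_deap_subject(path)
  }, "outside \\[1,9\\]")
})

test_that("the generic dataset container restores its contents bit-exactly", {
  ds <- generate_dataset(plant_spec(seed = 6), 1)
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  write_dataset(ds, path)
  expect_identical(read_dataset(path), ds)
})

test_that("contribution CSVs round-trip at full float precision", {
  set.seed(8)
  scores <- matrix(runif(32 * 4), 32, 4,
                   dimnames = list(NULL, c("LALV", "HALV", "LAHV", "HAHV")))
  scores[1, 1] <- 1 / 3  # not representable in decimal shorthand
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_contributions(scores, montage_names(), path)
  back <- read_contributions(path)
  expect_identical(unname(back), unname(scores))
  expect_equal(colnames(back), colnames(scores))
  expect_equal(rownames(back), montage_names())

  write_contributions(rep(0, 32), montage_names(), path)
  z <- read_contributions(path)
  expect_true(all(z == 0) && nrow(z) == 32)

  expect_error(write_contributions(scores[1:10, ], montage_names(), path),
               "length 32")
  expect_error(write_contributions(scores, montage_names()[1:5], path),
               "mismatch")
})
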
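test_that("HashtagCounts validates its invariants", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("d1", "d2")))
  expect_s3_class(HashtagCounts(m), "HashtagCounts")
  expect_error(HashtagCounts(m[1, , drop = FALSE]), "2 HTOs")
  m2 <- m; m2[1] <- -3L
  expect_error(HashtagCounts(m2), "negative")
  m3 <- matrix(c(1.5, 1, 2, 3), 2, 2, dimnames = dimnames(m))
  expect_error(HashtagCounts(m3), "integers")
  m4 <- m; rownames(m4) <- c("a", "a")
  expect_error(HashtagCounts(m4), "unique")
})

test_that("MTX and CSV round trips are bit-exact, including zero columns", {
  sim <- simulate_experiment(sim_config(n_samples = 8, droplets = 1000,
                                        seed = 4))
  x <- sim$counts
  x[, 5] <- 0L  # an empty droplet must survive as an explicit zero column
  d <- withr::local_tempdir()
  write_counts(x, file.path(d, "mtx"), "mtx")
  y <- read_counts(file.path(d, "mtx"))
  expect_identical(unclass(x), unclass(y))

  write_counts(x, file.path(d, "x.csv"), "csv")
  z <- read_counts(file.path(d, "x.csv"))
  expect_identical(unclass(x), unclass(z))
})

test_that("round-trip identity holds across many random matrices", {
  d <- withr::local_tempdir()
  set.seed(99)
  for (i in 1:25) {
    x <- random_counts(sample(2:6, 1), sample(1:40, 1), lambda = 5)
    write_counts(x, file.path(d, "m"), "mtx")
    expect_identical(unclass(read_counts(file.path(d, "m"))), unclass(x))
    write_counts(x, file.path(d, "m.csv"), "csv")
    expect_identical(unclass(read_counts(file.path(d, "m.csv"))), unclass(x))
  }
})

test_that("on-disk orientation is normalized from the sidecars", {
  x <- random_counts(3, 12, seed = 8)
  d <- withr::local_tempdir()
  dir.create(file.path(d, "t"))
  Matrix::writeMM(Matrix::Matrix(t(unclass(x)), sparse = TRUE),
                  file.path(d, "t", "matrix.mtx"))
  writeLines(rownames(x), file.path(d, "t", "features.tsv"))
  writeLines(colnames(x), file.path(d, "t", "barcodes.tsv"))
  y <- read_counts(file.path(d, "t"))
  expect_identical(unclass(y), unclass(x))
})

test_that("missing sidecars and negative entries are rejected", {
  x <- random_counts(3, 5, seed = 1)
  d <- withr::local_tempdir()
  dir.create(file.path(d, "m"))
  Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE),
                  file.path(d, "m", "matrix.mtx"))
  expect_error(read_counts(file.path(d, "m")), "sidecar")

  writeLines(rownames(x), file.path(d, "m", "features.tsv"))
  writeLines(colnames(x), file.path(d, "m", "barcodes.tsv"))
  mtx <- readLines(file.path(d, "m", "matrix.mtx"))
  mtx[length(mtx)] <- sub("[0-9]+$", "-3", mtx[length(mtx)])
  writeLines(mtx, file.path(d, "m", "matrix.mtx"))
  expect_error(read_counts(file.path(d, "m")), "negative")
})

test_that("truth tables map tokens case-insensitively and round trip", {
  d <- withr::local_tempdir()
  p <- file.path(d, "truth.tsv")
  writeLines(c("barcode\tlabel", "b1\tBAL A", "b2\tDoublet",
               "b3\tunassigned", "b4\tNEGATIVE"), p)
  tr <- read_truth(p)
  expect_equal(as.character(tr$category),
               c("singlet", "doublet", "negative", "negative"))
  expect_equal(tr$identity, c("BAL A", NA, NA, NA))

  write_truth(tr, file.path(d, "rt.tsv"))
  tr2 <- read_truth(file.path(d, "rt.tsv"))
  expect_equal(as.character(tr2$category), as.character(tr$category))
  expect_equal(tr2$identity, tr$identity)

  ## unknown tokens are rejected with the offending line
  expect_error(read_truth(p, samples = c("BAL B")), "line.*2")
})

test_that("assignments round trip and keep one result per method", {
  r <- make_result(c("singlet", "doublet", "negative", "singlet", "singlet"),
                   c("H1", NA, NA, "H2", "H1"), method = "toy")
  d <- withr::local_tempdir()
  write_assignments(r, file.path(d, "a.tsv"))
  back <- read_assignments(file.path(d, "a.tsv"))
  expect_named(back, "toy")
  expect_same_calls(back$toy, r)
})

test_that("truth barcodes absent from a result are kept until comparison", {
  r <- make_result(rep("singlet", 3), "H1",
                   barcodes = c("b1", "b2", "b3"))
  tr <- GroundTruth(c("b2", "b3", "b999"), rep("singlet", 3), "H1")
  fs <- f_scores(r, tr, mapping = identity_mapping("H1"))
  ## only the 2 shared barcodes are compared
  expect_equal(fs$table$TP, 2)
  expect_equal(fs$table$FN, 0)
})

test_that("sample-HTO mapping I/O is strict about one-to-one pairing", {
  d <- withr::local_tempdir()
  mp <- data.frame(sample = c("BAL A", "BAL B"), hto = c("BAL 1", "BAL 2"))
  write_mapping(mp, file.path(d, "map.tsv"))
  expect_equal(read_mapping(file.path(d, "map.tsv")), mp)
  expect_error(write_mapping(data.frame(sample = c("a", "a"),
                                        hto = c("x", "y")), file.path(d, "bad.tsv")),
               "one-to-one")
})
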
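test_that("F-score follows the harmonic-mean formula on hand counts", {
  ## TP=8, FP=1, FN=3 -> F = 8 / (8 + 2) = 0.8
  category <- c(rep("singlet", 9), rep("negative", 3), rep("singlet", 3))
  identity <- c(rep("H1", 9), rep(NA, 3), rep("H2", 3))
  truth_cat <- c(rep("singlet", 8), "doublet", rep("singlet", 3),
                 rep("singlet", 3))
  truth_id <- c(rep("H1", 8), NA, rep("H1", 3), rep("H2", 3))
  r <- make_result(category, identity, method = "hand")
  tr <- GroundTruth(r$calls$barcode, truth_cat, truth_id)
  fs <- f_scores(r, tr, mapping = identity_mapping(c("H1", "H2")))
  row <- fs$table[fs$table$label == "H1", ]
  expect_equal(c(row$TP, row$FP, row$FN), c(8, 1, 3))
  expect_identical(row$F, 0.8)
})

test_that("perfect agreement gives F = 1 everywhere; F = 1 iff no errors", {
  sim <- clean_sim(droplets = 300, seed = 2)
  truth <- sim$truth
  mapping <- attr(truth, "mapping")
  ## oracle result copied from the truth itself
  id <- mapping$hto[match(truth$identity, mapping$sample)]
  r <- make_result(as.character(truth$category), id,
                   barcodes = truth$barcode)
  fs <- f_scores(r, truth)
  expect_true(all(fs$table$F == 1))
  expect_equal(fs$mean_F, 1)
  expect_true(all(fs$table$FP == 0 & fs$table$FN == 0 & fs$table$TP > 0))
})

test_that("f_scores equals the brute-force confusion tally on random fixtures", {
  set.seed(123)
  htos <- c("A", "B", "C")
  for (i in 1:40) {
    n <- sample(20:60, 1)
    cat_r <- sample(c("singlet", "doublet", "negative"), n, replace = TRUE)
    id_r <- ifelse(cat_r == "singlet", sample(htos, n, replace = TRUE), NA)
    cat_t <- sample(c("singlet", "doublet", "negative"), n, replace = TRUE)
    id_t <- ifelse(cat_t == "singlet", sample(htos, n, replace = TRUE), NA)
    bcs <- sprintf("BC%03d", seq_len(n))
    r <- make_result(cat_r, id_r, barcodes = bcs)
    tr <- GroundTruth(bcs, cat_t, id_t)
    got <- f_scores(r, tr, mapping = identity_mapping(htos))$table
    want <- brute_force_f(r, tr, identity_mapping(htos))
    expect_equal(got[, c("TP", "FP", "FN", "F")],
                 want[, c("TP", "FP", "FN", "F")],
                 ignore_attr = TRUE)
  }
})

test_that("category proportions and doublet breakdown count correctly", {
  r <- make_result(c("singlet", "singlet", "doublet", "negative"),
                   c("H1", "H2", NA, NA))
  expect_equal(unname(category_proportions(r)), c(0.5, 0.25, 0.25))

  allS <- make_result(rep("singlet", 4), "H1")
  expect_equal(unname(category_proportions(allS)), c(1, 0, 0))

  ## 10 truth doublets: 6 called doublet, 3 singlet, 1 negative
  calls <- c(rep("doublet", 6), rep("singlet", 3), "negative")
  r2 <- make_result(calls, ifelse(calls == "singlet", "H1", NA))
  tr <- GroundTruth(r2$calls$barcode, rep("doublet", 10))
  expect_equal(unname(doublet_breakdown(r2, tr)), c(0.6, 0.3, 0.1))

  ## order invariance
  perm <- sample(10)
  tr_perm <- GroundTruth(r2$calls$barcode[perm], rep("doublet", 10))
  expect_equal(doublet_breakdown(r2, tr_perm), doublet_breakdown(r2, tr))
  expect_error(doublet_breakdown(r2, GroundTruth("BC0001", "singlet", "H1")),
               "doublet")
})

test_that("proportions sum to one on random results", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    cat_r <- sample(c("singlet", "doublet", "negative"), n, replace = TRUE)
    r <- make_result(cat_r, ifelse(cat_r == "singlet", "H1", NA))
    expect_equal(sum(category_proportions(r)), 1, tolerance = 1e-12)
  }
})

test_that("reports order methods by mean F and survive the JSON round trip", {
  sim <- clean_sim(droplets = 200, seed = 6)
  truth <- sim$truth
  mapping <- attr(truth, "mapping")
  id <- mapping$hto[match(truth$identity, mapping$sample)]
  good <- make_result(as.character(truth$category), id,
                      barcodes = truth$barcode, method = "good")
  ## a worse method: every fourth call blanked to negative
  cat2 <- as.character(truth$category)
  id2 <- id
  blank <- seq(1, length(cat2), by = 4)
  cat2[blank] <- "negative"; id2[blank] <- NA
  bad <- make_result(cat2, id2, barcodes = truth$barcode, method = "bad")

  rep <- benchmark_report(list(bad, good), truth)
  expect_equal(vapply(rep$methods, `[[`, character(1), "method"),
               c("good", "bad"))
  ## mean_F is the mean of the per-label table
  for (m in rep$methods) expect_equal(m$mean_F, mean(m$f_scores$F),
                                      tolerance = 1e-12)

  d <- withr::local_tempdir()
  write_report(rep, file.path(d, "r.json"))
  back <- read_report(file.path(d, "r.json"))
  expect_equal(length(back$methods), 2)
  expect_equal(back$methods[[1]]$mean_F, rep$methods[[1]]$mean_F)
  expect_equal(back$methods[[2]]$f_scores$F, rep$methods[[2]]$f_scores$F)
})

test_that("removing a correctly-called singlet never increases that label's F", {
  set.seed(77)
  n <- 40
  cat_r <- sample(c("singlet", "doublet", "negative"), n, replace = TRUE,
                  prob = c(0.7, 0.2, 0.1))
  id_r <- ifelse(cat_r == "singlet", sample(c("A", "B"), n, TRUE), NA)
  bcs <- sprintf("BC%03d", 1:n)
  cat_t <- sample(c("singlet", "doublet"), n, TRUE, prob = c(0.8, 0.2))
  id_t <- ifelse(cat_t == "singlet", sample(c("A", "B"), n, TRUE), NA)
  r <- make_result(cat_r, id_r, barcodes = bcs)
  tr <- GroundTruth(bcs, cat_t, id_t)
  mp <- identity_mapping(c("A", "B"))
  base <- f_scores(r, tr, mapping = mp)$table
  correct <- which(cat_r == "singlet" & cat_t == "singlet" & id_r == id_t &
                     id_r == "A")
  for (drop in correct) {
    keep <- setdiff(seq_len(n), drop)
    r2 <- make_result(cat_r[keep], id_r[keep], barcodes = bcs[keep])
    f2 <- f_scores(r2, tr, mapping = mp)$table
    expect_lte(f2$F[f2$label == "A"], base$F[base$label == "A"])
  }
})

test_that("undefined F (no calls, no truth) is zero and flagged", {
  r <- make_result(rep("negative", 5))
  tr <- GroundTruth(r$calls$barcode, rep("doublet", 5))
  fs <- f_scores(r, tr, mapping = identity_mapping("H9"))
  expect_identical(fs$table$F, 0)
  expect_true(fs$table$undefined)
})
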
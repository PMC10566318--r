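## Engine behaviour on constructed fixtures and clean simulations.

test_that("hashedDrops: zero droplets are negative; hand-built LFCs classify", {
  zero <- HashtagCounts(matrix(0L, 3, 4,
                               dimnames = list(paste0("H", 1:3),
                                               paste0("b", 1:4))))
  r <- suppressWarnings(run_hasheddrops(zero))
  expect_true(all(r$calls$category == "negative"))
  expect_match(r$warnings, "zero", all = FALSE)

  ## 200 clean singlets with uniform ambient, plus one marked droplet
  set.seed(42)
  n <- 200
  m <- matrix(rpois(3 * n, 2), 3, n)
  for (j in seq_len(n)) m[(j %% 3) + 1, j] <- m[(j %% 3) + 1, j] + 100L
  m[, 1] <- c(100L, 2L, 2L)
  m[, 2] <- c(100L, 100L, 2L)
  counts <- HashtagCounts(m, paste0("H", 1:3), sprintf("b%03d", 1:n))
  amb <- rep(1 / 3, 3)
  r1 <- run_hasheddrops(counts, confident_min = 0.5, ambient = amb)
  expect_equal(as.character(r1$calls$category[1]), "singlet")
  expect_equal(r1$calls$identity[1], "H1")
  r2 <- run_hasheddrops(counts, doublet_min = 1, ambient = amb)
  expect_equal(as.character(r2$calls$category[2]), "doublet")
})

test_that("hashedDrops: lowering confident_min never loses singlets", {
  for (seed in 1:3) {
    sim <- simulate_experiment(quality_preset("medium", droplets = 600,
                                              seed = seed))
    loose <- run_hasheddrops(sim$counts, confident_min = 0.5)
    strict <- run_hasheddrops(sim$counts, confident_min = 2.0)
    expect_gte(sum(loose$calls$category == "singlet"),
               sum(strict$calls$category == "singlet"))
  }
})

test_that("HTODemux recovers singlet identities on a clean simulation", {
  sim <- clean_sim(droplets = 1500, seed = 1)
  r <- run_htodemux(sim$counts)
  mapping <- attr(sim$truth, "mapping")
  sing <- sim$truth$category == "singlet"
  want <- mapping$hto[match(sim$truth$identity[sing], mapping$sample)]
  got <- r$calls$identity[sing]
  expect_gte(mean(!is.na(got) & got == want), 0.90)
  expect_same_calls(run_htodemux(sim$counts), r)  # deterministic
})

test_that("HTODemux calls a constructed double-positive a doublet", {
  sim <- clean_sim(droplets = 500, seed = 3)
  m <- unclass(sim$counts)
  m[1, 1] <- 5000L; m[2, 1] <- 5000L  # far above any background quantile
  r <- run_htodemux(HashtagCounts(m))
  expect_equal(as.character(r$calls$category[1]), "doublet")
})

test_that("GMM-Demux: confidence threshold is monotone in positives", {
  sim <- clean_sim(droplets = 800, seed = 2)
  r80 <- run_gmm_demux(sim$counts, confidence = 0.8)
  r99 <- run_gmm_demux(sim$counts, confidence = 0.99)
  ## number of positive HTOs per droplet never increases with confidence
  n80 <- ifelse(r80$calls$category == "negative", 0,
                ifelse(r80$calls$category == "singlet", 1, 2))
  n99 <- ifelse(r99$calls$category == "negative", 0,
                ifelse(r99$calls$category == "singlet", 1, 2))
  expect_true(all(n99 <= n80 | (n80 == 2 & n99 == 2)))
  fs <- f_scores(r80, sim$truth)
  expect_gte(fs$mean_F, 0.95)
})

test_that("demuxmix recovers a clean simulation and honours the outlier rule", {
  sim <- clean_sim(droplets = 800, seed = 4)
  r <- run_demuxmix(sim$counts)
  expect_gte(f_scores(r, sim$truth)$mean_F, 0.95)

  ## an extreme outlier count is forced positive
  m <- unclass(sim$counts)
  m[3, 7] <- as.integer(100 * max(m[3, ]))
  m[setdiff(1:8, 3), 7] <- 1L
  r2 <- run_demuxmix(HashtagCounts(m))
  expect_equal(as.character(r2$calls$category[7]), "singlet")
  expect_equal(r2$calls$identity[7], rownames(m)[3])
})

test_that("demuxmix yields no positives for an all-background HTO", {
  sim <- clean_sim(droplets = 800, seed = 5, n_samples = 6)
  m <- unclass(sim$counts)
  ## append a pure-ambient HTO no droplet is tagged with
  m <- rbind(m, extra = rpois(ncol(m), 5))
  storage.mode(m) <- "integer"
  r <- suppressWarnings(run_demuxmix(HashtagCounts(m)))
  ## no droplet is singlet for the ambient-only tag
  expect_false(any(r$calls$identity %in% "extra"))
})

test_that("deMULTIplex converges with a monotone negative set and no RNG", {
  sim <- clean_sim(droplets = 1000, seed = 6)
  r <- run_demultiplex(sim$counts)
  expect_lte(r$details$rounds, 3)
  expect_true(all(diff(r$details$negative_trace) >= 0))
  expect_same_calls(run_demultiplex(sim$counts), r)
  fs <- f_scores(r, sim$truth)
  expect_gte(fs$mean_F, 0.90)
})

test_that("BFF raw thresholds a constructed bimodal two-HTO mixture", {
  set.seed(31)
  n <- 600
  ## droplet j positive for HTO (j mod 2): background ~e^0, signal ~e^5
  sig <- as.integer(round(exp(rnorm(n, 5, 0.4))))
  bg1 <- as.integer(round(exp(rnorm(n, 0, 0.4))))
  bg2 <- as.integer(round(exp(rnorm(n, 0, 0.4))))
  m <- matrix(0L, 2, n, dimnames = list(c("A", "B"), sprintf("b%03d", 1:n)))
  odd <- seq(1, n, 2)
  even <- seq(2, n, 2)
  m[1, odd] <- sig[odd];  m[2, odd] <- bg2[odd]
  m[2, even] <- sig[even]; m[1, even] <- bg1[even]
  r <- run_bff(HashtagCounts(m), mode = "raw")
  thr <- r$details$thresholds
  expect_true(all(thr > 1 & thr < 4))
  expect_true(all(r$calls$category == "singlet"))
  expect_equal(r$calls$identity[odd], rep("A", length(odd)))
})

test_that("BFF fails softly on unimodal data in both modes", {
  sim <- simulate_experiment(quality_preset("low", droplets = 600, seed = 3,
                                            quality = 0.05))
  for (mode in c("raw", "cluster")) {
    r <- suppressWarnings(run_bff(sim$counts, mode = mode))
    expect_true(all(r$calls$category == "negative"))
    expect_match(r$warnings, "failed to classify", all = FALSE)
  }
})

test_that("BFF cluster mode agrees with raw mode on a symmetric fixture", {
  set.seed(8)
  n <- 400
  sig <- as.integer(round(exp(rnorm(n, 5, 0.3))))
  bg <- as.integer(round(exp(rnorm(2 * n, 0.5, 0.3))))
  m <- matrix(0L, 2, n, dimnames = list(c("A", "B"), sprintf("b%03d", 1:n)))
  odd <- seq(1, n, 2); even <- seq(2, n, 2)
  m[1, odd] <- sig[odd]; m[2, odd] <- bg[odd]
  m[2, even] <- sig[even]; m[1, even] <- bg[n + even]
  raw <- run_bff(HashtagCounts(m), mode = "raw")
  clu <- run_bff(HashtagCounts(m), mode = "cluster")
  expect_gte(mean(raw$calls$category == clu$calls$category), 0.99)
})

test_that("HashSolo degenerate priors force the corresponding category", {
  sim <- clean_sim(droplets = 300, seed = 9)
  allS <- run_hashsolo(sim$counts, priors = c(1, 0, 0))
  expect_true(all(allS$calls$category == "singlet"))
  allN <- run_hashsolo(sim$counts, priors = c(0, 0, 1))
  expect_true(all(allN$calls$category == "negative"))
  expect_error(run_hashsolo(sim$counts, priors = c(0.5, 0.2, 0.2)), "sum")
})

test_that("HashSolo calls equal brute-force posterior enumeration", {
  ## 10 droplets, hand-set noise/signal densities
  fit <- hashdemux:::new_mixture_fit(
    "gaussian", c(0.8, 0.2), c(mean = 1, scale = 0.5),
    c(mean = 6, scale = 0.8), NA, numeric(0), 0L, TRUE)
  set.seed(12)
  m <- matrix(0L, 3, 10, dimnames = list(c("A", "B", "C"),
                                         sprintf("b%02d", 1:10)))
  m[] <- as.integer(round(exp(runif(30, 0, 7))))
  priors <- c(0.75, 0.20, 0.05)
  r <- run_hashsolo(HashtagCounts(m), priors = priors, fit = fit)
  ## independent enumeration from the density formulas
  for (j in 1:10) {
    x <- unname(sort(log1p(m[, j]), decreasing = TRUE))[1:2]
    f0 <- function(v) dnorm(v, 1, 0.5)
    f1 <- function(v) dnorm(v, 6, 0.8)
    L <- c(singlet = priors[1] * f1(x[1]) * f0(x[2]),
           doublet = priors[2] * f1(x[1]) * f1(x[2]),
           negative = priors[3] * f0(x[1]) * f0(x[2]))
    expect_equal(as.character(r$calls$category[j]), names(which.max(L)))
  }
})

test_that("HashSolo calls are insensitive to plausible prior changes", {
  sim <- clean_sim(droplets = 1000, seed = 1)
  base <- run_hashsolo(sim$counts)
  worst <- 0
  for (pr in list(c(0.70, 0.20, 0.10), c(0.80, 0.10, 0.10),
                  c(0.69, 0.30, 0.01), c(0.60, 0.30, 0.10))) {
    alt <- run_hashsolo(sim$counts, priors = pr / sum(pr))
    worst <- max(worst, mean(as.character(alt$calls$category) !=
                               as.character(base$calls$category)))
  }
  expect_lt(worst, 0.01)
})

test_that("run_all returns nine isolated configurations with echoed params", {
  sim <- clean_sim(droplets = 400, seed = 7)
  res <- run_all(sim$counts)
  expect_length(res, 9)
  expect_setequal(names(res),
                  c("hashedDrops", "hashedDrops_tuned", "HTODemux",
                    "GMM-Demux", "demuxmix", "deMULTIplex", "BFF_raw",
                    "BFF_cluster", "HashSolo"))
  expect_equal(res$hashedDrops$params$confident_min, 2.0)
  expect_equal(res$hashedDrops_tuned$params$confident_min, 0.5)
  expect_equal(res$`GMM-Demux`$params$confidence, 0.8)

  ## a bad parameter fails only its own engine
  res2 <- run_all(sim$counts,
                  config = list("GMM-Demux" = list(nonsense = 1)))
  expect_s3_class(res2$`GMM-Demux`, "demux_error")
  expect_s3_class(res2$demuxmix, "DemuxResult")
})

test_that("every engine is equivariant under droplet permutation", {
  sim <- clean_sim(droplets = 300, seed = 11, n_samples = 4)
  set.seed(1)
  perm <- sample(ncol(sim$counts))
  permuted <- HashtagCounts(unclass(sim$counts)[, perm])
  base <- run_all(sim$counts)
  moved <- run_all(permuted)
  for (nm in names(base)) {
    expect_s3_class(base[[nm]], "DemuxResult")
    expect_equal(as.character(moved[[nm]]$calls$category),
                 as.character(base[[nm]]$calls$category[perm]),
                 label = paste(nm, "categories under permutation"))
    expect_equal(moved[[nm]]$calls$identity,
                 base[[nm]]$calls$identity[perm],
                 label = paste(nm, "identities under permutation"))
  }
})

test_that("permuting HTO order relabels singlet identities consistently", {
  sim <- clean_sim(droplets = 300, seed = 13, n_samples = 4)
  perm <- c(3, 1, 4, 2)
  permuted <- HashtagCounts(unclass(sim$counts)[perm, ])
  for (runner in list(run_hasheddrops, run_gmm_demux, run_demuxmix,
                      run_hashsolo)) {
    base <- runner(sim$counts)
    moved <- runner(permuted)
    ## droplets whose top two counts tie are flagged ambiguous: their
    ## index-based tie-break legitimately depends on HTO order. A droplet
    ## whose score sits exactly at a decision threshold can additionally
    ## flip with the float summation order, so agreement is asserted at
    ## 99.5% rather than bitwise.
    amb <- base$details$ambiguous_top
    ok <- if (is.null(amb)) rep(TRUE, nrow(base$calls)) else !amb
    expect_gte(mean(as.character(moved$calls$category)[ok] ==
                      as.character(base$calls$category)[ok]), 0.995)
    same_id <- moved$calls$identity[ok] == base$calls$identity[ok]
    expect_gte(mean(same_id, na.rm = TRUE), 0.995)
  }
})

test_that("singlet identities always come from the HTO universe", {
  sim <- clean_sim(droplets = 400, seed = 15)
  for (r in run_all(sim$counts)) {
    expect_equal(nrow(r$calls), ncol(sim$counts))
    ids <- r$calls$identity[!is.na(r$calls$identity)]
    expect_true(all(ids %in% rownames(sim$counts)))
  }
})
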
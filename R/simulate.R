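#' Configuration for a synthetic HTO experiment
#'
#' Describes a pooled hashing experiment with one HTO per sample. Each
#' droplet is a singlet (one tag bound), a cross-sample doublet (two tags) or
#' an ambient-only negative (no tag). Counts follow a negative binomial whose
#' mean combines an ambient background, a bound-tag signal scaled by the
#' labelling quality, and a per-droplet size factor:
#' `x_hd ~ NB(mean = s_d * (background_h + quality_h * signal_h * [h in tags]),
#' size = dispersion)`, `s_d ~ LogNormal(0, size_factor_sigma)`.
#'
#' @param n_samples number of pooled samples (= number of HTOs, >= 2).
#' @param droplets number of droplets.
#' @param doublet_rate fraction of droplets that are cross-sample doublets.
#' @param negative_rate fraction of ambient-only droplets.
#' @param signal_mean per-HTO bound-tag mean counts (recycled to n_samples).
#' @param signal_dispersion negative-binomial size parameter; the default 4
#'   gives a log-scale peak width (sd about 0.5) comparable to real hashing
#'   log-count distributions.
#' @param background_mean per-HTO ambient mean counts (recycled).
#' @param size_factor_sigma log-normal sd of per-droplet depth (>= 0).
#' @param quality labelling quality in (0, 1], scalar or per-HTO; multiplies
#'   the signal mean (1 = fully labelled, small values degrade the HTO
#'   towards a unimodal background-only distribution).
#' @param seed integer seed making the experiment reproducible.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_samples = 8L, droplets = 5000L, doublet_rate = 0.10,
                       negative_rate = 0.05, signal_mean = 500,
                       signal_dispersion = 4, background_mean = 5,
                       size_factor_sigma = 0.3, quality = 1, seed = 0L) {
  stopifnot(n_samples >= 2L, droplets >= 1L)
  if (doublet_rate < 0 || negative_rate < 0 ||
      doublet_rate + negative_rate >= 1) {
    stop("doublet_rate + negative_rate must be in [0, 1)", call. = FALSE)
  }
  signal_mean <- rep_len(signal_mean, n_samples)
  background_mean <- rep_len(background_mean, n_samples)
  quality <- rep_len(quality, n_samples)
  if (any(signal_mean <= 0) || any(background_mean <= 0)) {
    stop("signal and background means must be positive", call. = FALSE)
  }
  if (any(quality <= 0) || any(quality > 1)) {
    stop("quality must be in (0, 1]", call. = FALSE)
  }
  if (signal_dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (size_factor_sigma < 0) stop("size_factor_sigma must be >= 0",
                                  call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 droplets = as.integer(droplets),
                 doublet_rate = doublet_rate, negative_rate = negative_rate,
                 signal_mean = signal_mean,
                 signal_dispersion = signal_dispersion,
                 background_mean = background_mean,
                 size_factor_sigma = size_factor_sigma,
                 quality = quality, seed = as.integer(seed)),
            class = "SimConfig")
}

#' Quality presets for simulated hashing experiments
#'
#' Three regimes spanning the range seen in real hashing batches, from
#' cleanly bimodal per-HTO log-count distributions to degraded,
#' near-unimodal ones:
#' \describe{
#'   \item{high}{signal/background mean ratio 100, full labelling quality —
#'     every HTO bimodal and well separated.}
#'   \item{medium}{ratio 20 — separable but compressed.}
#'   \item{low}{ratio 5, with every fourth HTO (25%) degraded to quality
#'     0.2, i.e. near-unimodal.}
#' }
#'
#' @param name `"high"`, `"medium"` or `"low"`.
#' @param n_samples,droplets,seed passed to [sim_config()].
#' @param ... further overrides passed to [sim_config()].
#' @return A `SimConfig`. Pure function: identical inputs give identical
#'   configurations.
#' @export
quality_preset <- function(name = c("high", "medium", "low"), n_samples = 8L,
                           droplets = 5000L, seed = 0L, ...) {
  name <- match.arg(name)
  background <- 5
  spec <- switch(name,
    high = list(signal_mean = 100 * background, quality = 1),
    medium = list(signal_mean = 20 * background, quality = 1),
    low = list(signal_mean = 5 * background,
               quality = ifelse(seq_len(n_samples) %% 4L == 0L, 0.2, 1))
  )
  args <- c(list(n_samples = n_samples, droplets = droplets,
                 background_mean = background, seed = seed), spec, list(...))
  ## later overrides win
  args <- args[!duplicated(names(args), fromLast = TRUE)]
  do.call(sim_config, args)
}

#' Simulate an HTO experiment with known ground truth
#'
#' Draws each droplet's true origin (singlet uniformly over samples with
#' probability `1 - doublet_rate - negative_rate`, cross-sample doublet with
#' probability `doublet_rate` over uniform unordered pairs, ambient-only
#' negative otherwise), then generates negative-binomial counts as described
#' in [sim_config()]. Doublets carry both tags at full signal mean;
#' negatives carry ambient background only (not all-zero). Deterministic
#' given the config seed.
#'
#' @param config a `SimConfig`.
#' @return List with `counts` (a [HashtagCounts]) and `truth`
#'   (a [GroundTruth] whose mapping links "S<i>" samples to "HTO<i>" tags).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$n_samples
  d <- config$droplets
  htos <- sprintf("HTO%02d", seq_len(n))
  samples <- sprintf("S%02d", seq_len(n))
  barcodes <- sprintf("BC%06d", seq_len(d))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  p_sing <- 1 - config$doublet_rate - config$negative_rate
  category <- sample(.CATEGORIES, d, replace = TRUE,
                     prob = c(p_sing, config$doublet_rate,
                              config$negative_rate))
  tagmat <- matrix(0, n, d)  # indicator: tag bound in droplet
  identity <- rep(NA_character_, d)
  pair1 <- rep(NA_character_, d)
  pair2 <- rep(NA_character_, d)
  is_s <- which(category == "singlet")
  if (length(is_s)) {
    k <- sample.int(n, length(is_s), replace = TRUE)
    tagmat[cbind(k, is_s)] <- 1
    identity[is_s] <- samples[k]
  }
  is_d <- which(category == "doublet")
  for (j in is_d) {
    pr <- sort(sample.int(n, 2L))
    tagmat[pr, j] <- 1
    pair1[j] <- samples[pr[1]]
    pair2[j] <- samples[pr[2]]
  }
  s_d <- stats::rlnorm(d, 0, config$size_factor_sigma)
  mu <- (config$background_mean +
           config$quality * config$signal_mean * tagmat) *
    rep(s_d, each = n)
  counts <- matrix(stats::rnbinom(n * d, mu = mu,
                                  size = config$signal_dispersion), n, d)
  list(
    counts = HashtagCounts(counts, hto_names = htos, barcodes = barcodes),
    truth = GroundTruth(barcodes, category, identity, pair1, pair2,
                        mapping = data.frame(sample = samples, hto = htos,
                                             stringsAsFactors = FALSE))
  )
}
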
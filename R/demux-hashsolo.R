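#' Bayesian singlet/doublet/negative demultiplexing
#'
#' Models the pooled `ln(1 + x)` distribution over all matrix entries as a
#' two-component mixture of a noise (ambient) and a signal (bound-tag)
#' log-normal, fitted here as a Gaussian pair on the log scale. For each
#' droplet, the two highest log counts `(v1, v2)` support three hypotheses:
#' negative (`f_noise(v1) f_noise(v2)`), singlet
#' (`f_signal(v1) f_noise(v2)`) and doublet (`f_signal(v1) f_signal(v2)`).
#' Each likelihood is weighted by its prior and the maximum-posterior
#' hypothesis is called; the singlet identity is the top-count HTO and the
#' doublet pair the top two.
#'
#' @param counts a [HashtagCounts].
#' @param priors prior probabilities `(singlet, doublet, negative)` summing
#'   to 1 (default `c(0.75, 0.20, 0.05)`).
#' @param fit optional pre-computed `MixtureFit` on pooled log counts
#'   (advanced; used to inject hand-set densities).
#' @return A [DemuxResult]; `score` is the winning posterior probability.
#' @export
run_hashsolo <- function(counts, priors = c(0.75, 0.20, 0.05), fit = NULL) {
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  priors <- as.numeric(priors)
  if (length(priors) != 3L || any(priors < 0) ||
      abs(sum(priors) - 1) > 1e-9) {
    stop("priors must be 3 non-negative values (singlet, doublet, negative) ",
         "summing to 1", call. = FALSE)
  }
  params <- list(prior_singlet = priors[1], prior_doublet = priors[2],
                 prior_negative = priors[3])
  cw <- with_collected_warnings({
    if (is.null(fit)) fit <- fit_gaussian_mixture2(log1p(as.numeric(m)))
    tt <- top_two(m)
    j <- seq_len(n)
    v1 <- log1p(m[cbind(tt$first, j)])
    v2 <- log1p(m[cbind(tt$second, j)])
    lf0 <- function(v) stats::dnorm(v, fit$params0[["mean"]],
                                    fit$params0[["scale"]], log = TRUE)
    lf1 <- function(v) stats::dnorm(v, fit$params1[["mean"]],
                                    fit$params1[["scale"]], log = TRUE)
    lp <- cbind(singlet = log(priors[1]) + lf1(v1) + lf0(v2),
                doublet = log(priors[2]) + lf1(v1) + lf1(v2),
                negative = log(priors[3]) + lf0(v1) + lf0(v2))
    pick <- max.col(lp, ties.method = "first")
    mx <- lp[cbind(j, pick)]
    post <- 1 / rowSums(exp(lp - mx))
    post[!is.finite(post)] <- NaN
    category <- colnames(lp)[pick]
    list(category = category,
         identity = ifelse(category == "singlet", htos[tt$first],
                           NA_character_),
         pair1 = ifelse(category == "doublet", htos[tt$first], NA_character_),
         pair2 = ifelse(category == "doublet", htos[tt$second],
                        NA_character_),
         score = post, tied = tt$tied)
  })
  r <- cw$value
  DemuxResult("HashSolo", colnames(m), r$category, r$identity, r$pair1,
              r$pair2, score = r$score, params = params,
              warnings = cw$warnings, hto_names = htos,
              details = list(ambiguous_top = r$tied))
}
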
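#' Negative-binomial mixture demultiplexing on raw counts
#'
#' For each HTO the raw counts are split into positive and negative clusters
#' by 1-D k-means (initialization only), extreme counts above the
#' `outlier_quantile` are set aside, and a two-component negative-binomial
#' mixture is fitted to the remainder by EM. A droplet is positive for the
#' HTO when its posterior probability of the upper (signal) component
#' reaches `accept_prob`; outliers are forced positive (posterior 1).
#' Droplets are classified by their number of positive HTOs. HTOs with fewer
#' than 20 nonzero counts are skipped with a warning and never positive.
#'
#' @param counts a [HashtagCounts] with at least 20 droplets.
#' @param accept_prob posterior threshold for positivity (default 0.9).
#' @param outlier_quantile per-HTO count quantile above which droplets are
#'   outliers, excluded from fitting and forced positive (default 0.999).
#' @return A [DemuxResult]; `score` is the posterior supporting the call.
#' @export
run_demuxmix <- function(counts, accept_prob = 0.9, outlier_quantile = 0.999) {
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  if (n < 20L) stop("need at least 20 droplets", call. = FALSE)
  params <- list(accept_prob = accept_prob,
                 outlier_quantile = outlier_quantile)
  cw <- with_collected_warnings({
    post <- matrix(0, nrow(m), n, dimnames = dimnames(m))
    for (h in seq_len(nrow(m))) {
      x <- m[h, ]
      if (sum(x > 0) < 20L) {
        warning("HTO ", htos[h], " has fewer than 20 nonzero counts; skipped")
        next
      }
      cut <- stats::quantile(x, outlier_quantile, type = 7, names = FALSE)
      out <- x > cut
      fit <- tryCatch(fit_negbin_mixture2(x[!out]), error = function(e) NULL)
      if (is.null(fit)) {
        warning("negative-binomial mixture failed for ", htos[h],
                "; skipped")
        next
      }
      ## a collapsed mixture (both means close) means no real signal
      ## component: the HTO yields no positives, outliers included
      if (fit$params1[["mean"]] <= 1.5 * fit$params0[["mean"]]) {
        warning("mixture for ", htos[h], " is degenerate (no signal ",
                "component); no positives for this HTO")
        next
      }
      post[h, !out] <- posterior(fit, x[!out])
      post[h, out] <- 1
    }
    pos <- post >= accept_prob
    cls <- classify_by_positives(pos, rank_score = post)
    maxpost <- apply(post, 2, max)
    score <- ifelse(cls$npos >= 1L, maxpost, 1 - maxpost)
    c(cls, list(score = score))
  })
  r <- cw$value
  DemuxResult("demuxmix", colnames(m), r$category, r$identity, r$pair1,
              r$pair2, score = r$score, params = params,
              warnings = cw$warnings, hto_names = htos)
}
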
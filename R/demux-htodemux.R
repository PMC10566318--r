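#' Clustering-based demultiplexing with negative-binomial thresholds
#'
#' CLR-transformed counts are clustered by k-medoids with
#' `k = N_HTOs + 1` (one cluster per sample plus one for background). For
#' each HTO, the cluster with the lowest mean raw count is taken as that
#' HTO's negative cluster; a single negative binomial is fitted to the HTO's
#' raw counts inside it (moment estimates with a Newton-refined dispersion)
#' and droplets whose raw count exceeds the fitted `positive_quantile` are
#' positive for the HTO. Droplets are then classified by their number of
#' positive HTOs (0 negative, 1 singlet, 2+ doublet).
#'
#' @param counts a [HashtagCounts] with more than `N_HTOs + 1` droplets.
#' @param positive_quantile quantile of the fitted background NB above which
#'   a count is called positive (default 0.99).
#' @param clr_margin CLR centring margin, `"droplet"` or `"hto"`.
#' @param quantile_on `"fit"` (quantile of the fitted NB, default) or
#'   `"empirical"` (quantile of the negative cluster's raw counts).
#' @param seed retained for API stability; clustering is deterministic.
#' @return A [DemuxResult]; `score` is the number of positive HTOs.
#' @export
run_htodemux <- function(counts, positive_quantile = 0.99,
                         clr_margin = c("droplet", "hto"),
                         quantile_on = c("fit", "empirical"), seed = 0L) {
  clr_margin <- match.arg(clr_margin)
  quantile_on <- match.arg(quantile_on)
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  k <- nrow(m) + 1L
  if (n <= k) {
    stop("need more than N_HTOs + 1 droplets (got ", n, ")", call. = FALSE)
  }
  params <- list(positive_quantile = positive_quantile,
                 clr_margin = clr_margin, quantile_on = quantile_on,
                 seed = seed)
  cw <- with_collected_warnings({
    clr <- clr_transform(m, margin = clr_margin)
    cl <- kmedoids(t(clr), k = k, seed = seed)
    pos <- matrix(FALSE, nrow(m), n, dimnames = dimnames(m))
    thresholds <- stats::setNames(numeric(nrow(m)), htos)
    for (h in seq_len(nrow(m))) {
      cl_means <- vapply(seq_len(k), function(c) mean(m[h, cl == c]),
                         numeric(1))
      neg_cluster <- which.min(cl_means)
      neg_counts <- m[h, cl == neg_cluster]
      if (length(neg_counts) < 5L) {
        warning("negative cluster for ", htos[h], " has ",
                length(neg_counts), " droplets; falling back to the ",
                "lowest-count decile for this HTO")
        neg_counts <- m[h, m[h, ] <= stats::quantile(m[h, ], 0.1, type = 7)]
      }
      thr <- if (quantile_on == "empirical") {
        stats::quantile(neg_counts, positive_quantile, type = 7, names = FALSE)
      } else {
        mu <- max(mean(neg_counts), 1e-3)
        theta <- nb_moment_theta(neg_counts, rep(1, length(neg_counts)))
        theta <- nb_theta_newton(neg_counts, mu, rep(1, length(neg_counts)),
                                 theta)
        stats::qnbinom(positive_quantile, mu = mu, size = theta)
      }
      thresholds[h] <- thr
      pos[h, ] <- m[h, ] > thr
    }
    cls <- classify_by_positives(pos, rank_score = m)
    c(cls, list(thresholds = thresholds))
  })
  r <- cw$value
  DemuxResult("HTODemux", colnames(m), r$category, r$identity, r$pair1,
              r$pair2, score = r$npos, params = params,
              warnings = cw$warnings, hto_names = htos,
              details = list(thresholds = r$thresholds))
}
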
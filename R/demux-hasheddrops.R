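#' Threshold-based demultiplexing on ambient-corrected log-fold changes
#'
#' A simple, assumption-light classifier. Counts are corrected for the
#' ambient profile, then each droplet is summarized by two log-fold changes:
#' `lfc1` between its highest and second-highest corrected counts and `lfc2`
#' between the second-highest corrected count and its ambient expectation.
#' Doublets are called first, where `lfc2` exceeds both a hard threshold and
#' a robust outlier bound (median + `doublet_nmads` MADs); remaining droplets
#' are singlets when `lfc1` exceeds the hard `confident_min` threshold and is
#' not a low outlier (median - `confident_nmads` MADs); everything else is
#' negative.
#'
#' Ambient correction: with ambient proportions `a`, each droplet's ambient
#' scale is `s_d = mean(x_hd / a_h)` over all HTOs except its top two (0 if
#' none is positive); corrected counts are `max(x - s_d a, 0)` and the
#' log-fold changes use the pseudocount
#' `max(1, median_d(s_d * min_h a_h))`.
#'
#' @param counts a [HashtagCounts].
#' @param confident_min hard lower bound on `lfc1` for singlets (default 2;
#'   lowering it recovers more singlets at the cost of doublet leakage).
#' @param confident_nmads MADs below the median tolerated for `lfc1`.
#' @param doublet_min hard lower bound on `lfc2` for doublets.
#' @param doublet_nmads MADs above the median required for `lfc2`.
#' @param ambient optional ambient proportion vector over HTOs; estimated
#'   with [estimate_ambient()] when missing.
#' @return A [DemuxResult]; `score` is `lfc1` (log2 scale).
#' @export
run_hasheddrops <- function(counts, confident_min = 2.0, confident_nmads = 3,
                            doublet_min = 2.0, doublet_nmads = 3,
                            ambient = NULL) {
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  params <- list(confident_min = confident_min,
                 confident_nmads = confident_nmads,
                 doublet_min = doublet_min, doublet_nmads = doublet_nmads,
                 ambient = !is.null(ambient))
  cw <- with_collected_warnings({
    if (all(m == 0)) {
      warning("all counts are zero; every droplet is negative")
      list(category = rep("negative", n), identity = rep(NA_character_, n),
           pair1 = NA_character_, pair2 = NA_character_, score = NaN,
           tied = logical(n))
    } else {
      if (is.null(ambient)) ambient <- estimate_ambient(m)
      a <- rep_len(as.numeric(ambient), nrow(m))
      a <- a / sum(a)
      tt <- top_two(m)
      s_d <- vapply(seq_len(n), function(j) {
        rest <- setdiff(seq_len(nrow(m)), c(tt$first[j], tt$second[j]))
        if (!length(rest) || all(m[rest, j] == 0)) return(0)
        mean(m[rest, j] / a[rest])
      }, numeric(1))
      y <- pmax(m - outer(a, s_d), 0)
      p <- max(1, stats::median(s_d * min(a)))
      j <- seq_len(n)
      y1 <- y[cbind(tt$first, j)]
      y2 <- y[cbind(tt$second, j)]
      amb2 <- s_d * a[tt$second]
      lfc1 <- log2((y1 + p) / (y2 + p))
      lfc2 <- log2((y2 + p) / (amb2 + p))
      is_doub <- lfc2 > stats::median(lfc2) + doublet_nmads * stats::mad(lfc2) &
        lfc2 > doublet_min
      is_sing <- !is_doub & lfc1 > confident_min &
        lfc1 >= stats::median(lfc1) - confident_nmads * stats::mad(lfc1)
      category <- ifelse(is_doub, "doublet",
                         ifelse(is_sing, "singlet", "negative"))
      list(category = category,
           identity = ifelse(is_sing, htos[tt$first], NA_character_),
           pair1 = ifelse(is_doub, htos[tt$first], NA_character_),
           pair2 = ifelse(is_doub, htos[tt$second], NA_character_),
           score = lfc1, tied = tt$tied)
    }
  })
  r <- cw$value
  DemuxResult("hashedDrops", colnames(m), r$category, r$identity, r$pair1,
              r$pair2, r$score, params, cw$warnings, hto_names = htos,
              details = list(ambiguous_top = r$tied))
}
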
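#' Gaussian-mixture demultiplexing on CLR counts
#'
#' Fits a two-component Gaussian mixture to each HTO's CLR-transformed
#' counts (background vs signal) and calls a droplet positive for an HTO
#' when its posterior probability of the upper component reaches the
#' confidence threshold. Droplets are classified by their number of positive
#' HTOs; for multiplets the two highest-posterior HTOs are reported as the
#' pair. An HTO whose mixture degenerates (component means closer than 0.1
#' pooled standard deviations) is treated as unimodal and contributes no
#' positives, with a warning.
#'
#' @param counts a [HashtagCounts] with at least 20 droplets.
#' @param confidence posterior threshold for positivity (default 0.8).
#' @param clr_margin CLR centring margin, `"droplet"` or `"hto"`.
#' @param seed retained for API stability; fitting is deterministic.
#' @return A [DemuxResult]; `score` is the maximum posterior among positive
#'   HTOs (or one minus the maximum posterior for negatives).
#' @export
run_gmm_demux <- function(counts, confidence = 0.8,
                          clr_margin = c("droplet", "hto"), seed = 0L) {
  clr_margin <- match.arg(clr_margin)
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  if (n < 20L) stop("need at least 20 droplets", call. = FALSE)
  params <- list(confidence = confidence, clr_margin = clr_margin,
                 seed = seed)
  cw <- with_collected_warnings({
    clr <- clr_transform(m, margin = clr_margin)
    post <- matrix(0, nrow(m), n, dimnames = dimnames(m))
    for (h in seq_len(nrow(m))) {
      v <- clr[h, ]
      ## two deterministic EM starts: the k-means split, and a split at the
      ## expected positive fraction (~1/N of the pool carries this tag);
      ## the better log-likelihood wins. Overlapping components make EM
      ## start-sensitive and the k-means start alone can land on a
      ## balanced background split.
      starts <- list(NULL, as.integer(v > stats::quantile(v, 1 - 1 / nrow(m),
                                                          type = 7)))
      fits <- lapply(starts, function(ini) {
        tryCatch(fit_gaussian_mixture2(v, seed = seed, init_labels = ini),
                 error = function(e) NULL)
      })
      fits <- Filter(Negate(is.null), fits)
      fit <- if (length(fits)) {
        fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
      }
      if (is.null(fit)) {
        warning("mixture fit failed for ", htos[h],
                "; treating the HTO as unimodal (no positives)")
        next
      }
      sep <- fit$params1[["mean"]] - fit$params0[["mean"]]
      if (sep < 0.1 * stats::sd(v)) {
        warning("mixture for ", htos[h], " is degenerate (means within 0.1 ",
                "pooled sd); treating the HTO as unimodal (no positives)")
        next
      }
      ## components fitted to a unimodal HTO split the background instead of
      ## isolating signal; require clear separation (Ashman's D > 2, the
      ## standard bimodality criterion for Gaussian pairs)
      D <- sqrt(2) * sep / sqrt(fit$params0[["scale"]]^2 +
                                  fit$params1[["scale"]]^2)
      if (D <= 2) {
        warning("mixture components for ", htos[h], " are not separable ",
                "(Ashman's D = ", round(D, 2), " <= 2); treating the HTO ",
                "as unimodal (no positives)")
        next
      }
      ## in an N-plex pool only ~1/N of droplets are truly positive for one
      ## HTO; an upper component holding the majority of droplets is
      ## background substructure, not signal (guard inactive for 2-plex,
      ## where half the pool is legitimately positive)
      if (nrow(m) >= 3L && fit$weights[2] > 0.5) {
        warning("upper component for ", htos[h], " spans ",
                round(100 * fit$weights[2]), "% of droplets; treating the ",
                "HTO as unimodal (no positives)")
        next
      }
      post[h, ] <- posterior(fit, v)
    }
    pos <- post >= confidence
    cls <- classify_by_positives(pos, rank_score = post)
    maxpost <- apply(post, 2, max)
    score <- ifelse(cls$npos >= 1L, maxpost, 1 - maxpost)
    c(cls, list(score = score))
  })
  r <- cw$value
  DemuxResult("GMM-Demux", colnames(m), r$category, r$identity, r$pair1,
              r$pair2, score = r$score, params = params,
              warnings = cw$warnings, hto_names = htos)
}
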
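#' Bimodal thresholding demultiplexing (raw and cluster modes)
#'
#' Assumes each HTO's log-count distribution is bimodal. In `"raw"` mode the
#' threshold for an HTO is the density minimum between the two tallest
#' maxima of a kernel density estimate of `ln(1 + x)`; a droplet is positive
#' when its log count exceeds the threshold, and droplets are classified by
#' their number of positive HTOs. `"cluster"` mode adds bimodal quantile
#' normalization: using the raw thresholds, each HTO's sub-threshold values
#' are mapped through their empirical CDF onto the pooled (all-HTO)
#' sub-threshold distribution, supra-threshold values likewise onto the
#' pooled supra-threshold distribution; a single global threshold is then
#' re-estimated on the normalized values with the same two-peak rule.
#'
#' HTOs without two density maxima contribute no positives. If no HTO is
#' bimodal the engine fails softly: every droplet is negative and a
#' "failed to classify" warning is recorded.
#'
#' @param counts a [HashtagCounts] with at least 50 droplets.
#' @param mode `"raw"` or `"cluster"`.
#' @param bandwidth KDE bandwidth, `"auto"` (Silverman) or a number.
#' @return A [DemuxResult]; `score` is the margin of the top log count above
#'   its threshold.
#' @export
run_bff <- function(counts, mode = c("raw", "cluster"), bandwidth = "auto") {
  mode <- match.arg(mode)
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  if (n < 50L) stop("need at least 50 droplets", call. = FALSE)
  params <- list(mode = mode, bandwidth = bandwidth)
  lx <- log1p(m)

  bimodal_threshold <- function(v) {
    bm <- bimodal_modes(v, bandwidth = bandwidth)
    if (is.null(bm)) NULL else bm$threshold
  }

  cw <- with_collected_warnings({
    thr <- lapply(seq_len(nrow(m)), function(h) bimodal_threshold(lx[h, ]))
    has_thr <- !vapply(thr, is.null, logical(1))
    if (!any(has_thr)) {
      warning("failed to classify: no HTO shows a bimodal log-count ",
              "density; all droplets negative")
      list(category = rep("negative", n), identity = rep(NA_character_, n),
           pair1 = rep(NA_character_, n), pair2 = rep(NA_character_, n),
           score = rep(NaN, n))
    } else if (mode == "raw") {
      pos <- matrix(FALSE, nrow(m), n, dimnames = dimnames(m))
      margin <- matrix(-Inf, nrow(m), n, dimnames = dimnames(m))
      for (h in which(has_thr)) {
        pos[h, ] <- lx[h, ] > thr[[h]]
        margin[h, ] <- lx[h, ] - thr[[h]]
      }
      if (any(!has_thr)) {
        warning("no bimodal density for HTO(s): ",
                paste(htos[!has_thr], collapse = ", "), "; never positive")
      }
      cls <- classify_by_positives(pos, rank_score = margin)
      c(cls, list(score = apply(margin, 2, max),
                  thresholds = unlist(ifelse(has_thr, thr, NA))))
    } else {
      ## bimodal quantile normalization onto pooled sub/supra distributions
      lo_pool <- sort(unlist(lapply(which(has_thr),
                                    function(h) lx[h, lx[h, ] <= thr[[h]]])))
      hi_pool <- sort(unlist(lapply(which(has_thr),
                                    function(h) lx[h, lx[h, ] > thr[[h]]])))
      norm <- matrix(NA_real_, nrow(m), n, dimnames = dimnames(m))
      for (h in which(has_thr)) {
        v <- lx[h, ]
        lo <- v <= thr[[h]]
        if (any(lo)) {
          p <- (rank(v[lo], ties.method = "average") - 0.5) / sum(lo)
          norm[h, lo] <- stats::quantile(lo_pool, p, type = 7, names = FALSE)
        }
        if (any(!lo)) {
          p <- (rank(v[!lo], ties.method = "average") - 0.5) / sum(!lo)
          norm[h, !lo] <- stats::quantile(hi_pool, p, type = 7, names = FALSE)
        }
      }
      pooled <- as.numeric(norm[has_thr, , drop = FALSE])
      gthr <- bimodal_threshold(pooled)
      if (is.null(gthr)) {
        warning("failed to classify: normalized values are not bimodal; ",
                "all droplets negative")
        list(category = rep("negative", n), identity = rep(NA_character_, n),
             pair1 = rep(NA_character_, n), pair2 = rep(NA_character_, n),
             score = rep(NaN, n))
      } else {
        pos <- matrix(FALSE, nrow(m), n, dimnames = dimnames(m))
        margin <- matrix(-Inf, nrow(m), n, dimnames = dimnames(m))
        for (h in which(has_thr)) {
          pos[h, ] <- norm[h, ] > gthr
          margin[h, ] <- norm[h, ] - gthr
        }
        if (any(!has_thr)) {
          warning("no bimodal density for HTO(s): ",
                  paste(htos[!has_thr], collapse = ", "), "; never positive")
        }
        cls <- classify_by_positives(pos, rank_score = margin)
        c(cls, list(score = apply(margin, 2, max), global_threshold = gthr))
      }
    }
  })
  r <- cw$value
  method <- if (mode == "raw") "BFF_raw" else "BFF_cluster"
  DemuxResult(method, colnames(m), r$category, r$identity, r$pair1, r$pair2,
              score = r$score, params = params, warnings = cw$warnings,
              hto_names = htos,
              details = r[setdiff(names(r), c("category", "identity",
                                              "pair1", "pair2", "score",
                                              "npos"))])
  }
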
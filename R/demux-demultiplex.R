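#' Iterative quantile-sweep demultiplexing on KDE anchors
#'
#' Each round smooths the log-normalized counts of every HTO with a kernel
#' density estimate and anchors a per-HTO threshold range between the
#' background mode (the tallest density maximum) and the signal peak (by
#' default the tallest of the remaining maxima; `top_anchor = "rightmost"`
#' uses the right-most maximum instead). A single quantile `q` in
#' `(0, 1)` places every HTO's threshold at `bottom + q * (top - bottom)`;
#' the sweep picks the `q` maximizing the fraction of droplets classified as
#' singlets (ties towards smaller `q`). Negative droplets are removed and
#' the procedure repeats until no new negatives appear (or `max_rounds`).
#' HTOs whose density has a single maximum cannot be thresholded and are
#' never positive that round.
#'
#' @param counts a [HashtagCounts] with at least 50 droplets.
#' @param sweep_step grid step of the quantile sweep (default 0.02).
#' @param max_rounds cap on the number of remove-and-refit rounds.
#' @param top_anchor `"tallest"` (default) or `"rightmost"` signal peak.
#' @return A [DemuxResult]; `score` is the selected quantile of the final
#'   round and `details$negative_trace` records the cumulative negative
#'   count after each round.
#' @export
run_demultiplex <- function(counts, sweep_step = 0.02, max_rounds = 50L,
                            top_anchor = c("tallest", "rightmost")) {
  top_anchor <- match.arg(top_anchor)
  m <- assert_counts(counts)
  htos <- rownames(m)
  n <- ncol(m)
  if (n < 50L) stop("need at least 50 droplets", call. = FALSE)
  params <- list(sweep_step = sweep_step, max_rounds = max_rounds,
                 top_anchor = top_anchor)
  qs <- seq(sweep_step, 1 - sweep_step, by = sweep_step)

  cw <- with_collected_warnings({
    active <- seq_len(n)          # droplets still in play
    negative <- integer(0)        # accumulated negatives
    trace <- integer(0)
    final <- NULL
    q_star <- NA_real_
    norm <- log_normalize(m)
    for (round in seq_len(max_rounds)) {
      sub <- norm[, active, drop = FALSE]
      anchors <- lapply(seq_len(nrow(m)), function(h) {
        v <- sub[h, ]
        if (length(unique(v)) < 2L) return(NULL)
        curve <- kde_density(v)
        pk <- find_peaks(curve)
        if (length(pk$maxima) < 2L) return(NULL)
        bottom <- curve$grid[pk$maxima[1]]
        top <- switch(top_anchor,
                      tallest = curve$grid[pk$maxima[2]],
                      rightmost = curve$grid[max(pk$maxima)])
        ## the background mode holds most droplets and must lie below the
        ## signal anchor; an inverted pair marks background substructure
        ## (e.g. a zero-count spike), not a usable signal peak
        if (top <= bottom) return(NULL)
        c(bottom, top)
      })
      unimodal <- vapply(anchors, is.null, logical(1))
      if (any(unimodal)) {
        warning("HTO(s) with a single density maximum this round: ",
                paste(htos[unimodal], collapse = ", "),
                "; never positive")
      }
      if (all(unimodal)) {
        warning("all HTOs unimodal; classifying remaining droplets negative")
        final <- list(category = rep("negative", length(active)),
                      identity = rep(NA_character_, length(active)),
                      pair1 = rep(NA_character_, length(active)),
                      pair2 = rep(NA_character_, length(active)))
        negative <- c(negative, active)
        trace <- c(trace, length(negative))
        active <- integer(0)
        break
      }
      classify_at <- function(q) {
        pos <- matrix(FALSE, nrow(m), length(active))
        for (h in seq_len(nrow(m))) {
          if (unimodal[h]) next
          thr <- anchors[[h]][1] + q * diff(anchors[[h]])
          pos[h, ] <- sub[h, ] > thr
        }
        pos
      }
      singlet_frac <- vapply(qs, function(q) {
        mean(colSums(classify_at(q)) == 1L)
      }, numeric(1))
      q_star <- qs[which.max(singlet_frac)]  # which.max ties -> smaller q
      pos <- classify_at(q_star)
      rownames(pos) <- htos
      cls <- classify_by_positives(pos, rank_score = sub)
      new_neg <- active[cls$category == "negative"]
      final <- cls
      trace <- c(trace, length(negative) + length(new_neg))
      if (!length(new_neg)) break
      negative <- c(negative, new_neg)
      keep <- cls$category != "negative"
      active <- active[keep]
      final <- lapply(cls[c("category", "identity", "pair1", "pair2")],
                      function(v) v[keep])
      if (!length(active)) break
    }
    category <- rep("negative", n)
    identity <- rep(NA_character_, n)
    pair1 <- rep(NA_character_, n)
    pair2 <- rep(NA_character_, n)
    if (length(active)) {
      category[active] <- final$category
      identity[active] <- final$identity
      pair1[active] <- final$pair1
      pair2[active] <- final$pair2
    }
    list(category = category, identity = identity, pair1 = pair1,
         pair2 = pair2, q_star = q_star, trace = trace)
  })
  r <- cw$value
  DemuxResult("deMULTIplex", colnames(m), r$category, r$identity, r$pair1,
              r$pair2, score = r$q_star, params = params,
              warnings = unique(cw$warnings), hto_names = htos,
              details = list(negative_trace = r$trace,
                             rounds = length(r$trace)))
}
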
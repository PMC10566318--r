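#' Per-HTO log-count densities with bimodality calls
#'
#' High-quality hashing shows a bimodal `ln(1 + x)` density for every HTO: a
#' background peak from ambient tags and a signal peak from bound tags. An
#' HTO is called bimodal when [bimodal_modes()] finds a credible
#' background/signal pair (two maxima with the second at least 5% of the
#' tallest, a separating valley at most 80% of the lower peak, and the
#' dominant mode below the signal mode). The fraction of bimodal HTOs is a
#' quick quality summary: values below 1 flag degraded labelling.
#'
#' @param counts a [HashtagCounts] with at least 50 droplets.
#' @param bandwidth KDE bandwidth (`"auto"` = Silverman).
#' @return List with `curves` (named list of `DensityCurve`s, `NULL` for
#'   constant HTOs), `bimodal` (named logical), `bimodal_fraction`.
#' @export
qc_density <- function(counts, bandwidth = "auto") {
  m <- assert_counts(counts)
  if (ncol(m) < 50L) stop("need at least 50 droplets", call. = FALSE)
  htos <- rownames(m)
  curves <- vector("list", nrow(m))
  names(curves) <- htos
  bimodal <- stats::setNames(logical(nrow(m)), htos)
  for (h in seq_len(nrow(m))) {
    v <- log1p(m[h, ])
    if (length(unique(v)) < 2L) {
      warning("HTO ", htos[h], " is constant; flagged unimodal")
      next
    }
    bm <- bimodal_modes(v, bandwidth = bandwidth)
    if (!is.null(bm)) {
      curves[[h]] <- bm$curve
      bimodal[h] <- TRUE
    } else {
      curves[[h]] <- kde_density(v)
    }
  }
  list(curves = curves, bimodal = bimodal,
       bimodal_fraction = mean(bimodal))
}

#' Two-dimensional embedding of normalized HTO counts
#'
#' Log-normalizes the counts, projects droplets by PCA, and optionally runs
#' tSNE on the principal-component scores. In well-labelled data, droplets
#' form one tight cluster per sample plus smaller doublet/negative clusters.
#'
#' @param counts a [HashtagCounts] with at least 10 droplets.
#' @param method `"pca"` or `"tsne"` (tSNE requires the Rtsne package).
#' @param seed seed for the stochastic tSNE layout.
#' @param perplexity tSNE perplexity (reduced automatically for small n).
#' @return `N_droplets` x 2 matrix of finite coordinates, rownames barcodes.
#' @export
qc_embedding <- function(counts, method = c("pca", "tsne"), seed = 0L,
                         perplexity = 30) {
  method <- match.arg(method)
  m <- assert_counts(counts)
  if (ncol(m) < 10L) stop("need at least 10 droplets", call. = FALSE)
  x <- t(log_normalize(m))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x
  if (method == "pca") {
    out <- scores[, 1:2, drop = FALSE]
    if (ncol(scores) < 2L) out <- cbind(scores[, 1], 0)
  } else {
    if (!requireNamespace("Rtsne", quietly = TRUE)) {
      stop("method = 'tsne' requires the Rtsne package", call. = FALSE)
    }
    perplexity <- min(perplexity, floor((nrow(x) - 1) / 3))
    set.seed(seed)
    ts <- Rtsne::Rtsne(scores, dims = 2, perplexity = perplexity,
                       pca = FALSE, check_duplicates = FALSE)
    out <- ts$Y
  }
  out[!is.finite(out)] <- 0
  dimnames(out) <- list(colnames(m), c("dim1", "dim2"))
  out
}
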
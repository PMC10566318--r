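#' Centred log-ratio transform of HTO counts
#'
#' `clr_hd = ln(x_hd + p) - mean(ln(x_.d + p))`, centred per droplet across
#' HTOs by default so each droplet's transformed values sum to zero. The
#' alternative margin centres each HTO across droplets, as some pipelines do.
#'
#' @param counts a [HashtagCounts] (or plain count matrix, HTOs as rows).
#' @param pseudocount positive offset inside the log (default 1).
#' @param margin `"droplet"` (centre within each droplet) or `"hto"`.
#' @return A numeric matrix with the same dimensions and dimnames.
#' @export
clr_transform <- function(counts, pseudocount = 1, margin = c("droplet", "hto")) {
  margin <- match.arg(margin)
  stopifnot(pseudocount > 0)
  lx <- log(as_plain_matrix(counts) + pseudocount)
  if (margin == "droplet") {
    sweep(lx, 2, colMeans(lx), "-")
  } else {
    sweep(lx, 1, rowMeans(lx), "-")
  }
}

#' Log-normalize HTO counts
#'
#' `l_hd = ln(1 + scale * x_hd / total_d)` where `total_d` is the droplet's
#' total HTO count. Droplets with zero total map to all zeros.
#'
#' @param counts count matrix, HTOs as rows.
#' @param scale positive scale factor (default 1e4).
#' @return A numeric matrix with the same dimensions and dimnames.
#' @export
log_normalize <- function(counts, scale = 1e4) {
  stopifnot(scale > 0)
  m <- as_plain_matrix(counts)
  totals <- colSums(m)
  denom <- ifelse(totals > 0, totals, 1)
  log1p(scale * sweep(m, 2, denom, "/"))
}

#' Estimate the ambient HTO profile
#'
#' The ambient profile is the mean count profile of the droplets in the
#' lowest tail of total counts (at or below the `low_quantile` of totals),
#' made strictly positive with a pseudocount of 0.5 per HTO and renormalized
#' to sum to one. These low-count droplets are dominated by unbound tags, so
#' their profile approximates the ambient contamination present everywhere.
#'
#' @param counts count matrix, HTOs as rows.
#' @param low_quantile quantile of per-droplet totals defining "low" (0.1).
#' @return Named proportion vector over HTOs summing to 1.
#' @export
estimate_ambient <- function(counts, low_quantile = 0.1) {
  m <- as_plain_matrix(counts)
  totals <- colSums(m)
  thr <- stats::quantile(totals, low_quantile, type = 7, names = FALSE)
  low <- totals <= thr
  if (sum(low) < 10L) {
    stop("only ", sum(low), " droplets at or below the ", low_quantile,
         " total-count quantile; need >= 10. Lower the quantile or supply ",
         "an explicit ambient profile.", call. = FALSE)
  }
  prof <- rowMeans(m[, low, drop = FALSE]) + 0.5
  prof / sum(prof)
}

#' Kernel density estimate of a 1-D sample
#'
#' Gaussian-kernel KDE evaluated on an even grid spanning
#' `[min - 3h, max + 3h]` where `h` is the bandwidth; `"auto"` uses
#' Silverman's rule of thumb.
#'
#' @param values numeric vector (>= 2 finite values, not all equal).
#' @param bandwidth positive bandwidth or `"auto"`.
#' @param grid_size number of grid points (>= 16, default 512).
#' @return A `DensityCurve`: list with `grid`, `density`, `bandwidth`.
#' @export
kde_density <- function(values, bandwidth = "auto", grid_size = 512L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least 2 finite values for a KDE", call. = FALSE)
  }
  if (grid_size < 16L) stop("grid_size must be >= 16", call. = FALSE)
  if (identical(bandwidth, "auto")) {
    if (length(unique(values)) < 2L) {
      stop("constant input: bandwidth is zero; jitter the values or pass an ",
           "explicit bandwidth", call. = FALSE)
    }
    bandwidth <- stats::bw.nrd0(values)
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      n = grid_size, from = min(values) - 3 * bandwidth,
                      to = max(values) + 3 * bandwidth)
  structure(list(grid = d$x, density = d$y, bandwidth = bandwidth),
            class = "DensityCurve")
}

#' Locate interior extrema of a density curve
#'
#' Returns strict interior local maxima and minima; flat plateaus collapse to
#' their midpoint grid index. Maxima are sorted by density, tallest first;
#' minima are in grid order.
#'
#' @param curve a `DensityCurve` from [kde_density()], or any list with
#'   `grid` and `density`.
#' @return List with integer vectors `maxima` and `minima` (grid indices).
#' @export
find_peaks <- function(curve) {
  y <- curve$density
  n <- length(y)
  r <- rle(y)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- as.integer(floor((starts + ends) / 2))
  maxima <- integer(0)
  minima <- integer(0)
  if (k >= 3L) {
    for (i in 2:(k - 1L)) {
      v <- r$values[i]
      if (v > r$values[i - 1L] && v > r$values[i + 1L]) {
        maxima <- c(maxima, mids[i])
      } else if (v < r$values[i - 1L] && v < r$values[i + 1L]) {
        minima <- c(minima, mids[i])
      }
    }
  }
  maxima <- maxima[order(y[maxima], decreasing = TRUE)]
  list(maxima = maxima, minima = minima)
}

#' Detect a background/signal bimodal structure in a 1-D sample
#'
#' Searches for two genuine modes in the kernel density of `values`. With
#' `bandwidth = "auto"` the bandwidth grows progressively from Silverman's
#' rule (a critical-bandwidth search) until a curve with exactly two maxima
#' appears; raw log-counts are near-discrete at low values, so the base
#' bandwidth alone often shows spurious atom-level peaks. A candidate pair
#' of modes is accepted only if (i) the second peak reaches 5% of the
#' tallest, (ii) the separating valley dips to at most 80% of the lower
#' peak, and (iii) the taller mode is the lower one — in a multiplexed pool
#' most droplets are negative for any given HTO, so the background mode
#' dominates and sits below the signal; a taller upper mode marks
#' background substructure (e.g. a zero-count spike), not signal.
#'
#' @param values numeric vector.
#' @param bandwidth `"auto"` (progressive search) or a fixed bandwidth.
#' @return `NULL` when no credible bimodal structure exists, else a list
#'   with `curve` (the accepted `DensityCurve`), `modes` (grid locations,
#'   lower first) and `threshold` (grid location of the valley between
#'   them).
#' @export
bimodal_modes <- function(values, bandwidth = "auto") {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L) return(NULL)
  curve_at <- function(bw) tryCatch(kde_density(v, bandwidth = bw),
                                    error = function(e) NULL)
  accept <- function(curve) {
    if (is.null(curve)) return(NULL)
    pk <- find_peaks(curve)
    if (length(pk$maxima) < 2L) return(NULL)
    hts <- curve$density[pk$maxima]
    if (hts[2] < 0.05 * hts[1]) return(NULL)
    if (pk$maxima[1] > pk$maxima[2]) return(NULL)  # taller mode must be lower
    two <- sort(pk$maxima[1:2])
    between <- pk$minima[pk$minima > two[1] & pk$minima < two[2]]
    if (!length(between)) return(NULL)
    valley <- between[which.min(curve$density[between])]
    if (curve$density[valley] > 0.8 * min(curve$density[two])) return(NULL)
    list(curve = curve, modes = curve$grid[two],
         threshold = curve$grid[valley])
  }
  if (!identical(bandwidth, "auto")) {
    return(accept(curve_at(bandwidth)))
  }
  bw0 <- stats::bw.nrd0(v)
  if (!is.finite(bw0) || bw0 <= 0) return(NULL)
  for (bw in bw0 * 1.25^(0:20)) {
    cu <- curve_at(bw)
    if (is.null(cu)) return(NULL)
    nmax <- length(find_peaks(cu)$maxima)
    if (nmax < 2L) return(NULL)  # smoothed to unimodality
    if (nmax == 2L) {
      hit <- accept(cu)
      if (!is.null(hit)) return(hit)
      ## two maxima but not credible signal/background: keep smoothing
    }
  }
  NULL
}
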
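#' Per-label F-scores of a demultiplexing result against ground truth
#'
#' Comparison is restricted to the intersection of barcodes. For each HTO
#' label `h` mapped to sample `s`:
#' TP = droplets called singlet `h` whose truth is singlet `s`;
#' FP = droplets called singlet `h` with any other truth (truth doublets and
#' negatives count as false positives); FN = truth-singlet-`s` droplets not
#' called singlet `h`. Then `F = TP / (TP + (FP + FN) / 2)`, the harmonic
#' mean of precision and recall, defined as 0 (and flagged `undefined`) when
#' TP = FP = FN = 0.
#'
#' @param result a [DemuxResult].
#' @param truth a [GroundTruth].
#' @param mapping data.frame with columns `sample`, `hto`; taken from the
#'   truth's `mapping` attribute when missing, or inferred by exact name
#'   match between truth identities and called identities as a last resort.
#' @param average `"label"` (unweighted mean over labels, default) or
#'   `"cell"` (weighted by the number of truth singlets per label).
#' @return List with `table` (data.frame label, sample, TP, FP, FN, F,
#'   undefined) and `mean_F`.
#' @export
f_scores <- function(result, truth, mapping = NULL,
                     average = c("label", "cell")) {
  average <- match.arg(average)
  stopifnot(inherits(result, "DemuxResult"))
  mapping <- resolve_mapping(result, truth, mapping)
  calls <- result$calls
  common <- intersect(calls$barcode, truth$barcode)
  if (!length(common)) stop("no barcodes shared between result and truth",
                            call. = FALSE)
  calls <- calls[match(common, calls$barcode), ]
  tr <- truth[match(common, truth$barcode), ]
  called_singlet <- calls$category == "singlet"
  truth_singlet <- tr$category == "singlet"
  tab <- do.call(rbind, lapply(seq_len(nrow(mapping)), function(i) {
    h <- mapping$hto[i]; s <- mapping$sample[i]
    call_h <- called_singlet & calls$identity == h
    true_s <- truth_singlet & !is.na(tr$identity) & tr$identity == s
    TP <- sum(call_h & true_s)
    FP <- sum(call_h & !true_s)
    FN <- sum(true_s & !call_h)
    denom <- TP + 0.5 * (FP + FN)
    data.frame(label = h, sample = s, TP = TP, FP = FP, FN = FN,
               F = if (denom > 0) TP / denom else 0,
               undefined = denom == 0, stringsAsFactors = FALSE)
  }))
  w <- if (average == "label") rep(1, nrow(tab)) else (tab$TP + tab$FN)
  mean_F <- if (sum(w) > 0) sum(w * tab$F) / sum(w) else 0
  list(table = tab, mean_F = mean_F)
}

resolve_mapping <- function(result, truth, mapping) {
  if (is.null(mapping)) mapping <- attr(truth, "mapping")
  if (is.null(mapping)) {
    truth_labels <- sort(unique(stats::na.omit(truth$identity)))
    call_labels <- sort(unique(stats::na.omit(result$calls$identity)))
    ## exact name match only; positional pairing would silently mislabel
    if (!length(truth_labels) || !all(truth_labels %in% call_labels)) {
      stop("no sample<->HTO mapping supplied and truth sample names do not ",
           "match called HTO names exactly; supply a mapping (missing: ",
           paste(setdiff(truth_labels, call_labels), collapse = ", "), ")",
           call. = FALSE)
    }
    mapping <- data.frame(sample = truth_labels, hto = truth_labels,
                          stringsAsFactors = FALSE)
  }
  validate_mapping(mapping)
}

#' Fractions of calls in each broad category
#'
#' @param result a [DemuxResult].
#' @return Named numeric `(singlet, doublet, negative)` summing to 1.
#' @export
category_proportions <- function(result) {
  stopifnot(inherits(result, "DemuxResult"), nrow(result$calls) >= 1L)
  tab <- table(factor(result$calls$category, levels = .CATEGORIES))
  as.numeric(tab) / nrow(result$calls) -> p
  stats::setNames(p, .CATEGORIES)
}

#' How truth doublets were called
#'
#' Over the droplets that are doublets in the ground truth (restricted to
#' the barcode intersection), the fractions called doublet, singlet and
#' negative. A method that minimizes the singlet fraction here rarely
#' promotes true doublets to singlets.
#'
#' @param result a [DemuxResult].
#' @param truth a [GroundTruth] containing at least one doublet in the
#'   intersection.
#' @return Named numeric `(doublet, singlet, negative)` summing to 1.
#' @export
doublet_breakdown <- function(result, truth) {
  stopifnot(inherits(result, "DemuxResult"))
  calls <- result$calls
  common <- intersect(calls$barcode, truth$barcode)
  tr <- truth[match(common, truth$barcode), ]
  dd <- common[tr$category == "doublet"]
  if (!length(dd)) stop("no truth doublets in the barcode intersection",
                        call. = FALSE)
  got <- calls$category[match(dd, calls$barcode)]
  tab <- table(factor(got, levels = .CATEGORIES))
  p <- as.numeric(tab[c("doublet", "singlet", "negative")]) / length(dd)
  stats::setNames(p, c("doublet", "singlet", "negative"))
}

#' Aggregate benchmark report over several results
#'
#' Combines per-label F-scores, category proportions and the doublet
#' breakdown for each method, ordered by descending mean F-score. Failed
#' engine slots (from [run_all()]) are reported with their error message.
#'
#' @param results list of [DemuxResult]s (and/or `demux_error` records).
#' @param truth a [GroundTruth].
#' @param mapping optional sample-to-HTO mapping (see [f_scores()]).
#' @param average F-score averaging mode (see [f_scores()]).
#' @return A `BenchmarkReport`: list with `methods` (ordered summaries) and
#'   `errors`.
#' @export
benchmark_report <- function(results, truth, mapping = NULL,
                             average = c("label", "cell")) {
  average <- match.arg(average)
  if (inherits(results, "DemuxResult")) results <- list(results)
  if (!length(results)) stop("need at least one result", call. = FALSE)
  ok <- vapply(results, inherits, logical(1), "DemuxResult")
  errors <- lapply(results[!ok], function(e) {
    list(method = e$method, error = e$error)
  })
  has_doublets <- any(truth$category == "doublet")
  methods <- lapply(results[ok], function(r) {
    fs <- f_scores(r, truth, mapping = mapping, average = average)
    list(method = r$method,
         f_scores = fs$table,
         mean_F = fs$mean_F,
         category_proportions = as.list(category_proportions(r)),
         doublet_breakdown = if (has_doublets) {
           as.list(doublet_breakdown(r, truth))
         },
         params = r$params,
         warnings = r$warnings)
  })
  ord <- order(vapply(methods, `[[`, numeric(1), "mean_F"),
               decreasing = TRUE)
  structure(list(methods = methods[ord], errors = errors),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat("BenchmarkReport:", length(x$methods), "methods\n")
  for (m in x$methods) {
    cat(sprintf("  %-20s mean F = %.3f  (singlet %.2f, doublet %.2f, negative %.2f)\n",
                m$method, m$mean_F, m$category_proportions$singlet,
                m$category_proportions$doublet,
                m$category_proportions$negative))
  }
  for (e in x$errors) cat("  [failed]", e$method, "-", e$error, "\n")
  invisible(x)
}

#' Write / read a benchmark report as JSON
#'
#' The JSON round trip is lossless for the report's numeric content.
#'
#' @param report a `BenchmarkReport`.
#' @param path output JSON file.
#' @return The path (write) or a `BenchmarkReport` (read).
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "BenchmarkReport"))
  dir_create(dirname(path))
  payload <- list(methods = lapply(report$methods, function(m) {
    m$f_scores <- as.list(m$f_scores)
    m
  }), errors = report$errors)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  methods <- lapply(x$methods, function(m) {
    m$f_scores <- as.data.frame(m$f_scores, stringsAsFactors = FALSE)
    m$category_proportions <- lapply(m$category_proportions, as.numeric)
    if (!is.null(m$doublet_breakdown)) {
      m$doublet_breakdown <- lapply(m$doublet_breakdown, as.numeric)
    }
    m
  })
  structure(list(methods = methods, errors = x$errors),
            class = "BenchmarkReport")
}
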
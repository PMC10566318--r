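#' HashtagCounts: an HTO-by-droplet count matrix
#'
#' Container for hashtag-oligo (HTO) read counts. Rows are HTOs, columns are
#' droplet barcodes. Counts must be non-negative integers; row and column
#' names must be unique and non-empty, with at least two HTOs and one droplet.
#'
#' @param counts numeric matrix of non-negative integer counts, HTOs as rows.
#' @param hto_names optional character vector overriding `rownames(counts)`.
#' @param barcodes optional character vector overriding `colnames(counts)`.
#'
#' @return An integer matrix of class `HashtagCounts` with rownames (HTOs)
#'   and colnames (barcodes).
#' @examples
#' m <- matrix(c(10L, 0L, 0L, 12L), 2, 2,
#'             dimnames = list(c("HTO1", "HTO2"), c("bc1", "bc2")))
#' HashtagCounts(m)
#' @export
HashtagCounts <- function(counts, hto_names = NULL, barcodes = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (!is.null(hto_names)) rownames(counts) <- hto_names
  if (!is.null(barcodes)) colnames(counts) <- barcodes
  validate_hashtag_counts(counts)
  storage.mode(counts) <- "integer"
  class(counts) <- c("HashtagCounts", "matrix", "array")
  counts
}

validate_hashtag_counts <- function(counts) {
  if (!is.numeric(counts)) {
    stop("counts must be numeric", call. = FALSE)
  }
  if (nrow(counts) < 2L) {
    stop("at least 2 HTOs are required (got ", nrow(counts), ")", call. = FALSE)
  }
  if (ncol(counts) < 1L) {
    stop("at least 1 droplet is required", call. = FALSE)
  }
  if (anyNA(counts)) {
    stop("counts contain NA values", call. = FALSE)
  }
  if (any(counts < 0)) {
    stop("counts must be non-negative; found ", sum(counts < 0),
         " negative entries", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integers; found non-integral entries", call. = FALSE)
  }
  check_unique_names(rownames(counts), "HTO names")
  check_unique_names(colnames(counts), "barcodes")
  invisible(counts)
}

check_unique_names <- function(nm, what) {
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm))) {
    stop(what, " must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(what, " must be unique; duplicated: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  invisible(nm)
}

#' @export
print.HashtagCounts <- function(x, ...) {
  cat("HashtagCounts: ", nrow(x), " HTOs x ", ncol(x), " droplets\n", sep = "")
  cat("HTOs: ", paste(utils::head(rownames(x), 8), collapse = ", "),
      if (nrow(x) > 8) ", ..." else "", "\n", sep = "")
  cat("total counts: ", sum(as.numeric(x)), "\n", sep = "")
  invisible(x)
}

#' @rdname HashtagCounts
#' @param x object to test.
#' @export
is_hashtag_counts <- function(x) inherits(x, "HashtagCounts")

as_plain_matrix <- function(x) {
  class(x) <- NULL
  x
}
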
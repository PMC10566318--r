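#' Read an HTO count matrix
#'
#' Reads counts from MatrixMarket (a `matrix.mtx` with adjacent
#' `features.tsv` and `barcodes.tsv` sidecars, the CellRanger convention) or
#' from a dense CSV with HTO names in the first column and barcodes in the
#' header. Matrix orientation is normalized to HTOs-as-rows regardless of the
#' on-disk orientation, detected from the sidecar lengths (MTX) or assumed
#' HTOs-as-rows (CSV).
#'
#' @param path for `format = "mtx"`, the directory containing the triplet or
#'   the `.mtx` file itself; for `"csv"`, the CSV file.
#' @param format `"auto"` (from the path), `"mtx"` or `"csv"`.
#' @return A [HashtagCounts] matrix.
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "mtx"
  }
  if (format == "csv") {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    return(HashtagCounts(m))
  }
  ## MTX triplet
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
  } else {
    mtx <- path
    path <- dirname(path)
  }
  feat <- file.path(path, "features.tsv")
  bcs <- file.path(path, "barcodes.tsv")
  if (!file.exists(mtx)) stop("missing matrix file: ", mtx, call. = FALSE)
  missing <- c(feat, bcs)[!file.exists(c(feat, bcs))]
  if (length(missing)) {
    stop("missing MTX sidecar file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(mtx))
  hto_names <- readLines(feat)
  barcodes <- readLines(bcs)
  if (nrow(m) == length(hto_names) && ncol(m) == length(barcodes)) {
    ## HTOs already on rows
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(hto_names)) {
    m <- t(m)
  } else {
    stop("matrix dimensions ", nrow(m), "x", ncol(m),
         " match neither sidecar orientation (", length(hto_names),
         " features, ", length(barcodes), " barcodes)", call. = FALSE)
  }
  HashtagCounts(m, hto_names = hto_names, barcodes = barcodes)
}

#' Write an HTO count matrix
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x))` reproduces `x`
#' bit-exactly. MTX output is MatrixMarket coordinate integer with 1-based
#' indices and CellRanger-style sidecars.
#'
#' @param counts a [HashtagCounts] matrix.
#' @param path output directory (mtx) or file (csv).
#' @param format `"mtx"` or `"csv"`.
#' @return The path written, invisibly.
#' @export
write_counts <- function(counts, path, format = c("mtx", "csv")) {
  format <- match.arg(format)
  validate_hashtag_counts(counts)
  if (format == "csv") {
    dir_create(dirname(path))
    utils::write.csv(as.data.frame(as_plain_matrix(counts)), path)
    return(invisible(path))
  }
  dir_create(path)
  sp <- methods::as(methods::as(Matrix::Matrix(as_plain_matrix(counts),
                                               sparse = TRUE), "generalMatrix"),
                    "CsparseMatrix")
  Matrix::writeMM(sp, file.path(path, "matrix.mtx"))
  writeLines(rownames(counts), file.path(path, "features.tsv"))
  writeLines(colnames(counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

dir_create <- function(path) {
  if (nzchar(path) && !dir.exists(path)) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
  }
  if (nzchar(path) && !dir.exists(path)) {
    stop("cannot create directory: ", path, call. = FALSE)
  }
  invisible(path)
}

.SPECIAL_TOKENS <- c(doublet = "doublet", negative = "negative",
                     unassigned = "negative")

#' Read a ground-truth table
#'
#' Reads a TSV with columns `barcode` and `label`, where `label` is a sample
#' name or one of the case-insensitive tokens `"doublet"`, `"negative"`,
#' `"unassigned"` (the latter maps to negative). This is the shape of a
#' genetic demultiplexing (donor-assignment) output used as ground truth.
#'
#' @param path TSV file.
#' @param samples optional vector of valid sample names; any label outside
#'   `samples` and the special tokens raises an error naming the line.
#' @param mapping optional sample-to-HTO mapping (data.frame or TSV path with
#'   columns `sample`, `hto`), attached to the result.
#' @return A [GroundTruth] data.frame.
#' @export
read_truth <- function(path, samples = NULL, mapping = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(df))) {
    stop("truth file needs columns 'barcode' and 'label'", call. = FALSE)
  }
  lab <- as.character(df$label)
  low <- tolower(lab)
  special <- low %in% names(.SPECIAL_TOKENS)
  bad <- is.na(lab) | !nzchar(lab)
  if (!is.null(samples)) {
    bad <- bad | (!special & !(lab %in% samples))
  }
  if (any(bad)) {
    lines <- which(bad) + 1L  # account for header line
    stop("unknown label token(s) in ", path, " at line(s) ",
         paste(utils::head(lines, 10), collapse = ", "), ": ",
         paste(utils::head(unique(lab[bad]), 10), collapse = ", "),
         call. = FALSE)
  }
  category <- ifelse(special, .SPECIAL_TOKENS[low], "singlet")
  identity <- ifelse(special, NA_character_, lab)
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- read_mapping(mapping)
  }
  GroundTruth(df$barcode, category, identity, mapping = mapping)
}

#' Write a ground-truth table
#'
#' @param truth a [GroundTruth].
#' @param path output TSV.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  label <- ifelse(truth$category == "singlet", truth$identity,
                  as.character(truth$category))
  dir_create(dirname(path))
  utils::write.table(data.frame(barcode = truth$barcode, label = label),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-to-HTO mapping
#'
#' Two-column TSV (`sample`, `hto`). Supplying a mapping explicitly avoids
#' silent positional pairing when sample labels (e.g. "BAL A") differ from
#' HTO labels (e.g. "BAL 1").
#'
#' @param path TSV file.
#' @return data.frame with columns `sample` and `hto`.
#' @export
read_mapping <- function(path) {
  validate_mapping(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_mapping
#' @param mapping data.frame with columns `sample`, `hto`.
#' @export
write_mapping <- function(mapping, path) {
  mapping <- validate_mapping(mapping)
  dir_create(dirname(path))
  utils::write.table(mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write demultiplexing assignments
#'
#' Writes one or several [DemuxResult]s as a TSV with columns
#' `barcode`, `method`, `category`, `identity`, `score`.
#'
#' @param results a `DemuxResult` or list of them.
#' @param path output TSV.
#' @return The path, invisibly.
#' @export
write_assignments <- function(results, path) {
  if (inherits(results, "DemuxResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    if (!inherits(r, "DemuxResult")) {
      return(NULL)  # failed engine slots are skipped
    }
    data.frame(barcode = r$calls$barcode, method = r$method,
               category = as.character(r$calls$category),
               identity = r$calls$identity, score = r$calls$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  dir_create(dirname(path))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read demultiplexing assignments
#'
#' Inverse of [write_assignments()]; returns one [DemuxResult] per method
#' found in the file (parameters are not stored in the TSV and are recorded
#' as `list(source = path)`).
#'
#' @param path assignments TSV.
#' @return Named list of [DemuxResult]s.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("barcode", "method", "category", "identity", "score")
  if (!all(need %in% names(df))) {
    stop("assignments file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$method), function(d) {
    DemuxResult(d$method[1], d$barcode, d$category, d$identity,
                score = d$score, params = list(source = path))
  })
  out[unique(df$method)]
}
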
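#' @name demux-classes
#' @title Assignment containers: DemuxResult and GroundTruth
#'
#' @description
#' A per-droplet call is one of three categories: `"singlet"` (with the
#' identity of the positive HTO), `"doublet"` (optionally with the pair of
#' most likely HTOs) or `"negative"` (no positive HTO). `DemuxResult` holds
#' the calls of one demultiplexing run together with per-droplet scores and
#' the parameters actually used; `GroundTruth` holds the true origin of each
#' droplet (identities are *sample* names, linked to HTO names through a
#' sample-to-HTO mapping).
NULL

.CATEGORIES <- c("singlet", "doublet", "negative")

as_category <- function(x) {
  x <- tolower(as.character(x))
  bad <- setdiff(unique(x), .CATEGORIES)
  if (length(bad)) {
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = .CATEGORIES)
}

#' Construct a DemuxResult
#'
#' @param method name of the demultiplexing engine.
#' @param barcodes droplet barcodes.
#' @param category per-droplet category in `c("singlet","doublet","negative")`.
#' @param identity HTO identity per droplet (`NA` unless singlet).
#' @param pair1,pair2 optional HTO pair for doublets (`NA` elsewhere).
#' @param score per-droplet method-specific confidence (`NaN` allowed).
#' @param params named list of parameters actually used (non-empty).
#' @param warnings character vector of engine warnings.
#' @param hto_names HTO universe the identities must belong to.
#' @param details optional engine-specific diagnostics (list).
#'
#' @return A `DemuxResult`: list with `method`, `calls` (data.frame with
#'   columns barcode, category, identity, pair1, pair2, score), `params`,
#'   `warnings` and `details`.
#' @export
DemuxResult <- function(method, barcodes, category, identity = NA_character_,
                        pair1 = NA_character_, pair2 = NA_character_,
                        score = NaN, params = list(), warnings = character(),
                        hto_names = NULL, details = list()) {
  n <- length(barcodes)
  stopifnot(nzchar(method), n >= 1L)
  category <- as_category(category)
  identity <- rep_len(as.character(identity), n)
  pair1 <- rep_len(as.character(pair1), n)
  pair2 <- rep_len(as.character(pair2), n)
  score <- rep_len(as.numeric(score), n)
  if (length(category) != n) stop("category length mismatch", call. = FALSE)
  if (!length(params)) stop("params must record the effective parameters",
                            call. = FALSE)
  sing <- category == "singlet"
  if (any(sing & is.na(identity))) {
    stop("singlet calls require an HTO identity", call. = FALSE)
  }
  if (any(!sing & !is.na(identity))) {
    stop("identity must be NA for non-singlet calls", call. = FALSE)
  }
  if (!is.null(hto_names)) {
    bad <- setdiff(stats::na.omit(unique(c(identity, pair1, pair2))), hto_names)
    if (length(bad)) {
      stop("identities not in hto_names: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  both <- !is.na(pair1) & !is.na(pair2)
  if (any(both & pair1 == pair2)) {
    stop("doublet pair members must be distinct", call. = FALSE)
  }
  structure(list(
    method = method,
    calls = data.frame(barcode = as.character(barcodes), category = category,
                       identity = identity, pair1 = pair1, pair2 = pair2,
                       score = score, stringsAsFactors = FALSE),
    params = params,
    warnings = as.character(warnings),
    details = details
  ), class = "DemuxResult")
}

#' @export
print.DemuxResult <- function(x, ...) {
  tab <- table(x$calls$category)
  cat("DemuxResult <", x$method, ">: ", nrow(x$calls), " droplets (",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), ")\n",
      sep = "")
  if (length(x$warnings)) {
    cat("warnings: ", paste(x$warnings, collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

#' Construct a GroundTruth table
#'
#' @param barcodes droplet barcodes.
#' @param category per-droplet true category.
#' @param identity true sample of origin (`NA` unless singlet).
#' @param pair1,pair2 optional sample pair for doublets.
#' @param mapping optional data.frame with columns `sample`, `hto` linking
#'   sample names to HTO names.
#'
#' @return A data.frame of class `GroundTruth` with columns barcode,
#'   category, identity, pair1, pair2 and a `mapping` attribute.
#' @export
GroundTruth <- function(barcodes, category, identity = NA_character_,
                        pair1 = NA_character_, pair2 = NA_character_,
                        mapping = NULL) {
  n <- length(barcodes)
  category <- as_category(category)
  out <- data.frame(barcode = as.character(barcodes), category = category,
                    identity = rep_len(as.character(identity), n),
                    pair1 = rep_len(as.character(pair1), n),
                    pair2 = rep_len(as.character(pair2), n),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$barcode)) {
    stop("truth barcodes must be unique", call. = FALSE)
  }
  if (any(out$category == "singlet" & is.na(out$identity))) {
    stop("singlet truth rows require a sample identity", call. = FALSE)
  }
  if (!is.null(mapping)) mapping <- validate_mapping(mapping)
  structure(out, mapping = mapping, class = c("GroundTruth", "data.frame"))
}

validate_mapping <- function(mapping) {
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  if (!all(c("sample", "hto") %in% names(mapping))) {
    stop("mapping needs columns 'sample' and 'hto'", call. = FALSE)
  }
  mapping$sample <- as.character(mapping$sample)
  mapping$hto <- as.character(mapping$hto)
  if (anyDuplicated(mapping$sample) || anyDuplicated(mapping$hto)) {
    stop("sample<->HTO mapping must be one-to-one", call. = FALSE)
  }
  mapping[, c("sample", "hto")]
}
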
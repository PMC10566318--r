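## Shared fixtures, all generated in code.

## small random count matrix with unique names
random_counts <- function(n_htos = 4, n_droplets = 30, lambda = 20,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_htos * n_droplets, lambda), n_htos, n_droplets)
  HashtagCounts(m,
                hto_names = sprintf("HTO%02d", seq_len(n_htos)),
                barcodes = sprintf("BC%04d", seq_len(n_droplets)))
}

## a clean, well-separated experiment used by several engine tests
clean_sim <- function(droplets = 1500, n_samples = 8, seed = 1, ...) {
  simulate_experiment(quality_preset("high", n_samples = n_samples,
                                     droplets = droplets, seed = seed, ...))
}

## identity sample<->HTO mapping for hand-built results
identity_mapping <- function(htos) {
  data.frame(sample = htos, hto = htos, stringsAsFactors = FALSE)
}

## build a DemuxResult from category/identity vectors with minimal ceremony
make_result <- function(category, identity = NA_character_,
                        barcodes = sprintf("BC%04d", seq_along(category)),
                        method = "toy", score = NaN, hto_names = NULL) {
  DemuxResult(method, barcodes, category, identity, score = score,
              params = list(fixture = TRUE), hto_names = hto_names)
}

## naive O(N*K) confusion tally, the independent oracle for f_scores
brute_force_f <- function(result, truth, mapping) {
  calls <- result$calls
  common <- intersect(calls$barcode, truth$barcode)
  out <- lapply(seq_len(nrow(mapping)), function(i) {
    h <- mapping$hto[i]; s <- mapping$sample[i]
    TP <- FP <- FN <- 0L
    for (b in common) {
      cl <- calls[calls$barcode == b, ]
      tr <- truth[truth$barcode == b, ]
      called_h <- cl$category == "singlet" && !is.na(cl$identity) &&
        cl$identity == h
      true_s <- tr$category == "singlet" && !is.na(tr$identity) &&
        tr$identity == s
      if (called_h && true_s) TP <- TP + 1L
      if (called_h && !true_s) FP <- FP + 1L
      if (!called_h && true_s) FN <- FN + 1L
    }
    denom <- TP + 0.5 * (FP + FN)
    data.frame(label = h, TP = TP, FP = FP, FN = FN,
               F = if (denom > 0) TP / denom else 0)
  })
  do.call(rbind, out)
}

expect_same_calls <- function(a, b) {
  expect_equal(as.character(a$calls$category), as.character(b$calls$category))
  expect_equal(a$calls$identity, b$calls$identity)
}
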
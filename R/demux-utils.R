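## Shared plumbing for the demultiplexing engines.

## Classify droplets from an HTO x droplet positivity matrix. For doublets the
## reported pair is the two positive HTOs ranked by `rank_score` (a matrix of
## the same shape; larger = stronger evidence), falling back to the positive
## order. Returns the components of a DemuxResult's calls.
classify_by_positives <- function(pos, rank_score = NULL) {
  htos <- rownames(pos)
  npos <- colSums(pos)
  category <- ifelse(npos == 0L, "negative",
                     ifelse(npos == 1L, "singlet", "doublet"))
  n <- ncol(pos)
  identity <- rep(NA_character_, n)
  pair1 <- rep(NA_character_, n)
  pair2 <- rep(NA_character_, n)
  for (j in which(npos >= 1L)) {
    idx <- which(pos[, j])
    if (length(idx) == 1L) {
      identity[j] <- htos[idx]
    } else {
      if (!is.null(rank_score)) idx <- idx[order(rank_score[idx, j],
                                                 decreasing = TRUE)]
      pair1[j] <- htos[idx[1]]
      pair2[j] <- htos[idx[2]]
    }
  }
  list(category = category, identity = identity, pair1 = pair1, pair2 = pair2,
       npos = npos)
}

## Indices of the two largest counts per droplet; ties broken by HTO index
## (lower index first). Flags droplets whose top two are exactly tied.
top_two <- function(m) {
  n <- ncol(m)
  i1 <- integer(n); i2 <- integer(n); tied <- logical(n)
  for (j in seq_len(n)) {
    x <- m[, j]
    o <- order(x, seq_along(x), decreasing = c(TRUE, FALSE), method = "radix")
    i1[j] <- o[1]; i2[j] <- o[2]
    tied[j] <- x[o[1]] == x[o[2]]
  }
  list(first = i1, second = i2, tied = tied)
}

## Collect warnings raised by an engine body without losing its value.
with_collected_warnings <- function(expr) {
  warns <- character()
  val <- withCallingHandlers(expr, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = warns)
}

assert_counts <- function(counts) {
  validate_hashtag_counts(counts)
  as_plain_matrix(counts)
}
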
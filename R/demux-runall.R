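.ENGINES <- c("hashedDrops", "hashedDrops_tuned", "HTODemux", "GMM-Demux",
              "demuxmix", "deMULTIplex", "BFF_raw", "BFF_cluster", "HashSolo")

#' Run every demultiplexing engine
#'
#' Runs the full panel of nine configurations: hashedDrops at both the
#' default (`confident_min = 2`) and tuned (`confident_min = 0.5`)
#' thresholds, HTODemux, GMM-Demux, demuxmix, deMULTIplex, BFF in raw and
#' cluster modes, and HashSolo. An engine failure never aborts the panel:
#' the failing slot carries an `error` entry and the others are unaffected.
#'
#' @param counts a [HashtagCounts].
#' @param config optional named list of per-engine parameter overrides, one
#'   block per engine name (e.g. `list("GMM-Demux" = list(confidence =
#'   0.9))`). Unknown engine names or parameter keys make that engine fail.
#' @param seed seed recorded for engines that accept one.
#' @return Named list with one [DemuxResult] (or an error record of class
#'   `demux_error`) per engine configuration.
#' @export
run_all <- function(counts, config = list(), seed = 0L) {
  runners <- list(
    "hashedDrops" = function(...) run_hasheddrops(counts, ...),
    "hashedDrops_tuned" = function(...) {
      args <- list(...)
      if (is.null(args$confident_min)) args$confident_min <- 0.5
      do.call(run_hasheddrops, c(list(counts), args))
    },
    "HTODemux" = function(...) run_htodemux(counts, seed = seed, ...),
    "GMM-Demux" = function(...) run_gmm_demux(counts, seed = seed, ...),
    "demuxmix" = function(...) run_demuxmix(counts, ...),
    "deMULTIplex" = function(...) run_demultiplex(counts, ...),
    "BFF_raw" = function(...) run_bff(counts, mode = "raw", ...),
    "BFF_cluster" = function(...) run_bff(counts, mode = "cluster", ...),
    "HashSolo" = function(...) run_hashsolo(counts, ...)
  )
  bad_cfg <- setdiff(names(config), names(runners))
  if (length(bad_cfg)) {
    stop("unknown engine(s) in config: ", paste(bad_cfg, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(names(runners), function(nm) {
    args <- config[[nm]]
    if (is.null(args)) args <- list()
    r <- tryCatch(do.call(runners[[nm]], args), error = function(e) {
      structure(list(method = nm, error = conditionMessage(e)),
                class = "demux_error")
    })
    ## slot names distinguish configurations sharing an engine
    if (inherits(r, "DemuxResult")) r$method <- nm
    r
  })
  names(out) <- names(runners)
  out
}
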
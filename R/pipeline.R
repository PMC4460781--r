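# End-to-end search: predictions -> SSD -> matches -> filter -> chains.

#' Run the full motif search
#'
#' Wires the pipeline end to end: decompose the reference's local folding
#' windows into an SSD, scan the target for pairing-compatible matches,
#' filter weak matches, and chain the survivors.
#'
#' @param reference Reference `seq_record`.
#' @param target Target `seq_record`.
#' @param windows List of `fold_window` objects for the reference (e.g. from
#'   [parse_fold_predictions()]), or `NULL` if `ssd` is supplied.
#' @param mode `"S1"` or `"Sk"` (ignored when `ssd` is supplied).
#' @param params [score_params()].
#' @param ssd Optional pre-built `ssd`, bypassing extraction.
#' @param min_pairs,min_len NBS size filter for extraction.
#' @return List with `ssd`, `matches` (filtered), `result` (`chain_result`),
#'   `n_raw_matches`.
#' @export
run_search <- function(reference, target, windows = NULL,
                       mode = c("S1", "Sk"), params = score_params(),
                       ssd = NULL, min_pairs = 2L, min_len = 6L) {
  mode <- match.arg(mode)
  if (is.null(ssd)) {
    if (is.null(windows)) stop("either windows or a pre-built ssd is required")
    ssd <- build_ssd(windows, reference, mode = mode,
                     min_pairs = min_pairs, min_len = min_len)
  }
  raw <- find_matches(ssd, target, min_identity = params$min_identity)
  flt <- filter_matches(raw, target, ssd, tau = params$tau)
  res <- chain_matches(flt, ssd, params)
  list(ssd = ssd, matches = flt, result = res, n_raw_matches = nrow(raw))
}
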
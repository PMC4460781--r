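# Decomposition of local folding windows into non-branching structures and
# assembly of the SSD in unique-structure (S1) or alternative-structures (Sk)
# mode.

#' Decompose a folding window into non-branching structures
#'
#' Each hairpin loop of the window seeds one NBS: starting from its closing
#' pair, the helix is extended outward through stacked pairs, bulges and
#' internal loops until a branching (multiloop) or the unpaired exterior is
#' reached. Helices that close multiloops belong to no NBS. Flanking
#' unpaired positions of the window are never part of an NBS, which always
#' starts and ends on a paired position.
#'
#' @param w A `fold_window`.
#' @param ref The reference `seq_record` the window was predicted on.
#' @param min_pairs Minimum number of base pairs an NBS must retain
#'   (default 2; single-pair stems match almost anywhere).
#' @param min_len Minimum NBS length in nt (default 6).
#' @return List of NBS descriptors: `start` (absolute, 1-based), `length`,
#'   `structure`, `energy` (inherited from the window), `window_id`.
#' @export
decompose_window <- function(w, ref, min_pairs = 2L, min_len = 6L) {
  pt <- parse_dotbracket(w$structure)
  n <- length(pt)
  if (w$start + n - 1L > nchar(ref$seq)) {
    stop(sprintf("window [%d, %d] exceeds reference '%s' length %d",
                 w$start, w$start + n - 1L, ref$id, nchar(ref$seq)))
  }
  chars <- strsplit(w$structure, "", fixed = TRUE)[[1]]
  # parent pair and direct child-helix count for every opening position
  parent <- rep(NA_integer_, n)
  nchild <- rep(0L, n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      if (length(open)) {
        top <- open[length(open)]
        parent[i] <- top
        nchild[top] <- nchild[top] + 1L
      }
      open <- c(open, i)
    } else if (chars[i] == ")") {
      open <- open[-length(open)]
    }
  }
  opens <- which(!is.na(pt) & pt > seq_along(pt))
  hairpin <- opens[vapply(opens, function(i) {
    j <- pt[i]
    j == i + 1L || all(is.na(pt[(i + 1L):(j - 1L)]))
  }, logical(1))]
  out <- list()
  for (h in hairpin) {
    p <- h
    while (!is.na(parent[p]) && nchild[parent[p]] == 1L) p <- parent[p]
    i0 <- p
    j0 <- pt[p]
    len <- j0 - i0 + 1L
    npairs <- sum(!is.na(pt[i0:j0])) %/% 2L
    if (npairs < min_pairs || len < min_len) next
    out[[length(out) + 1L]] <- list(
      start = w$start + i0 - 1L,
      length = len,
      structure = substr(w$structure, i0, j0),
      energy = w$energy,
      window_id = w$window_id
    )
  }
  out
}

#' Build the secondary structure descriptor from folding windows
#'
#' All windows are decomposed into NBSs (see [decompose_window()]) and
#' deduplicated on `(start, length, structure)`, keeping the most stable
#' (lowest-energy) provenance. In mode `Sk` every distinct NBS is retained.
#' In mode `S1` a unique structure is selected greedily: candidates are
#' visited by increasing window energy (most stable first; ties by start
#' ascending, then length descending) and accepted iff interval-disjoint
#' from everything already accepted. The result is sorted by start (ties by
#' length, then structure) and each NBS is paired with its reference
#' subsequence to form an RSSP.
#'
#' @param windows List of `fold_window` objects.
#' @param ref Reference `seq_record`.
#' @param mode `"S1"` (unique prediction) or `"Sk"` (alternatives allowed).
#' @param min_pairs,min_len NBS size filter, see [decompose_window()].
#' @return An `ssd`.
#' @export
build_ssd <- function(windows, ref, mode = c("S1", "Sk"),
                      min_pairs = 2L, min_len = 6L) {
  mode <- match.arg(mode)
  nbs <- do.call(rbind, lapply(windows, function(w) {
    parts <- decompose_window(w, ref, min_pairs = min_pairs, min_len = min_len)
    if (!length(parts)) return(NULL)
    do.call(rbind, lapply(parts, as.data.frame))
  }))
  if (is.null(nbs) || nrow(nbs) == 0L) {
    return(ssd(data.frame(start = integer(0), length = integer(0),
                          structure = character(0), subseq = character(0),
                          energy = numeric(0)),
               mode = mode, source_id = ref$id))
  }
  # dedupe identical NBSs, keeping the most stable provenance
  nbs <- nbs[order(nbs$energy, nbs$start), , drop = FALSE]
  nbs <- nbs[!duplicated(paste(nbs$start, nbs$length, nbs$structure)), ,
             drop = FALSE]
  if (mode == "S1") {
    cand <- nbs[order(nbs$energy, nbs$start, -nbs$length), , drop = FALSE]
    kept <- logical(nrow(cand))
    starts <- integer(0)
    ends <- integer(0) # exclusive
    for (i in seq_len(nrow(cand))) {
      s <- cand$start[i]
      e <- s + cand$length[i]
      if (!length(starts) || all(e <= starts | ends <= s)) {
        kept[i] <- TRUE
        starts <- c(starts, s)
        ends <- c(ends, e)
      }
    }
    nbs <- cand[kept, , drop = FALSE]
  }
  nbs <- nbs[order(nbs$start, nbs$length, nbs$structure), , drop = FALSE]
  nbs$subseq <- substr(rep(ref$seq, nrow(nbs)), nbs$start,
                       nbs$start + nbs$length - 1L)
  out <- ssd(nbs[, c("start", "length", "structure", "subseq", "energy")],
             mode = mode, source_id = ref$id, validate = FALSE)
  # internal-consistency gate: the reference must be able to form its own
  # predicted pairs; a violation indicates corrupt predictions
  validate_ssd(out)
  out
}
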
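# Shuffle-based significance and family-ranking evaluation.

#' Shuffle a sequence preserving composition
#'
#' `mono` is an exact permutation of the nucleotides (mononucleotide counts
#' preserved). `di` preserves all dinucleotide counts using the
#' Eulerian-path (Altschul-Erikson) method: the sequence is a walk on the
#' graph whose edges are its adjacent pairs, and a random new walk with the
#' same edge multiset, first and last vertex is drawn. Both are
#' deterministic under a fixed RNG state.
#'
#' @param seq Character string (length >= 2; >= 3 for `di`).
#' @param mode `"mono"` or `"di"`.
#' @return Shuffled string. If no distinct dinucleotide shuffle can be
#'   drawn, the input is returned with attribute `degenerate = TRUE`.
#' @export
shuffle_sequence <- function(seq, mode = c("mono", "di")) {
  mode <- match.arg(mode)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (mode == "mono") {
    if (n < 2L) stop("sequence too short to shuffle")
    return(paste(sample(chars), collapse = ""))
  }
  if (n < 3L) stop("dinucleotide shuffle needs at least 3 nt")
  verts <- unique(chars)
  from <- chars[-n]
  to <- chars[-1]
  last <- chars[n]
  out_edges <- split(to, factor(from, levels = verts))
  # Altschul-Erikson: pick one terminal (last-used) edge per vertex except
  # the final one so that terminal edges form a tree into the final vertex;
  # rejection-sample the terminal choice (alphabet <= 5, cheap).
  non_last <- setdiff(verts, last)
  term <- NULL
  for (attempt in seq_len(200L)) {
    cand <- vapply(non_last, function(v) {
      e <- out_edges[[v]]
      e[sample.int(length(e), 1L)]
    }, "")
    names(cand) <- non_last
    ok <- all(vapply(non_last, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || !v %in% names(cand)) return(FALSE)
        seen <- c(seen, v)
        v <- cand[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok) {
      term <- cand
      break
    }
  }
  if (is.null(term)) {
    out <- seq
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  queues <- lapply(verts, function(v) {
    e <- out_edges[[v]]
    if (v %in% names(term)) {
      i <- match(term[[v]], e)
      rest <- e[-i]
      c(if (length(rest)) rest[sample.int(length(rest))], term[[v]])
    } else {
      if (length(e)) e[sample.int(length(e))] else character(0)
    }
  })
  names(queues) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  walk <- character(n)
  walk[1] <- chars[1]
  v <- chars[1]
  for (i in seq_len(n - 1L)) {
    used[v] <- used[v] + 1L
    nxt <- queues[[v]][used[[v]]]
    walk[i + 1L] <- nxt
    v <- nxt
  }
  paste(walk, collapse = "")
}

#' Best chain found in one target
#'
#' Runs the full search (match, filter, chain) of an SSD against one target
#' and returns the top-scoring chain. The score of an empty result is 0.
#'
#' @param ssd An `ssd`.
#' @param target Target `seq_record`.
#' @param params [score_params()].
#' @return List with `score`, `length`, `chain` (`NULL` if no match
#'   survived), and the `chain_result` as `result`.
#' @export
best_chain <- function(ssd, target, params = score_params()) {
  m <- find_matches(ssd, target, min_identity = params$min_identity)
  m <- filter_matches(m, target, ssd, tau = params$tau)
  res <- chain_matches(m, ssd, params)
  if (!length(res$chains)) {
    return(list(score = 0, length = 0L, chain = NULL, result = res))
  }
  top <- res$chains[[1]]
  list(score = top$score, length = top$length, chain = top, result = res)
}

#' Shuffle-based significance of a reference/target comparison
#'
#' The observed best-chain score is compared with the null distribution of
#' best-chain scores over composition-preserving shuffles of the target:
#' `zscore = (observed - mean) / sd`, with the empirical p-value
#' `(1 + #\{null >= observed\}) / (n_shuffles + 1)` (so p = 0 is never
#' reported). If the null is degenerate (`sd = 0`), the z-score is `Inf`
#' when the observed score exceeds the null mean and 0 otherwise.
#'
#' @param ssd Reference `ssd`.
#' @param target Target `seq_record`.
#' @param n_shuffles Number of shuffles (>= 20).
#' @param mode Shuffle mode, `"mono"` (default) or `"di"`.
#' @param seed Optional integer seed recorded in the result.
#' @param params [score_params()].
#' @return Object of class `significance_result`.
#' @export
significance <- function(ssd, target, n_shuffles = 1000L,
                         mode = c("mono", "di"), seed = NULL,
                         params = score_params()) {
  mode <- match.arg(mode)
  stopifnot(n_shuffles >= 20L)
  if (!is.null(seed)) set.seed(seed)
  observed <- best_chain(ssd, target, params)$score
  null <- vapply(seq_len(n_shuffles), function(i) {
    sh <- seq_record(target$id, shuffle_sequence(target$seq, mode))
    best_chain(ssd, sh, params)$score
  }, 0)
  mu <- mean(null)
  sdv <- stats::sd(null)
  z <- if (sdv > 0) (observed - mu) / sdv else if (observed > mu) Inf else 0
  structure(list(observed_score = observed, null_mean = mu, null_sd = sdv,
                 zscore = z,
                 p_empirical = (1 + sum(null >= observed)) / (n_shuffles + 1),
                 n_shuffles = as.integer(n_shuffles),
                 shuffle_mode = mode,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 null_scores = null),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf(
    "<significance> observed=%.4f null mean=%.4f sd=%.4f z=%.3f p=%.4g (%d %s shuffles)\n",
    x$observed_score, x$null_mean, x$null_sd, x$zscore, x$p_empirical,
    x$n_shuffles, x$shuffle_mode))
  invisible(x)
}

#' Rank targets by best-chain score
#'
#' Scores every target against the reference SSD and sorts them in
#' decreasing score order (ties keep input order, ranks are 1-based). The
#' detection fraction is the share of designated positives scoring strictly
#' above the best-scoring non-positive; when every score ties, it is 0 by
#' this convention.
#'
#' @param ssd Reference `ssd`.
#' @param targets List of `seq_record` objects (>= 2).
#' @param positives Character vector of target ids forming the positive set.
#' @param params [score_params()].
#' @return Object of class `ranking_result`: `table` (id, score, rank,
#'   positive flag, sorted), `detection_fraction`, `positive_ranks`.
#' @export
rank_targets <- function(ssd, targets, positives = character(0),
                         params = score_params()) {
  stopifnot(length(targets) >= 2L)
  ids <- vapply(targets, `[[`, "", "id")
  unknown <- setdiff(positives, ids)
  if (length(unknown)) stop("unknown positive id: ", unknown[1])
  score <- vapply(targets, function(t) best_chain(ssd, t, params)$score, 0)
  o <- order(-score) # stable: ties keep input order
  tab <- data.frame(target_id = ids[o], score = score[o],
                    rank = seq_along(o),
                    positive = ids[o] %in% positives)
  rownames(tab) <- NULL
  det <- NA_real_
  if (length(positives)) {
    neg <- score[!ids %in% positives]
    best_neg <- if (length(neg)) max(neg) else -Inf
    det <- mean(score[ids %in% positives] > best_neg)
  }
  structure(list(table = tab, detection_fraction = det,
                 positive_ranks = tab$rank[tab$positive]),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking> %d targets; detection fraction %s\n",
              nrow(x$table),
              ifelse(is.na(x$detection_fraction), "NA",
                     sprintf("%.3f", x$detection_fraction))))
  print(utils::head(x$table, 10))
  invisible(x)
}
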
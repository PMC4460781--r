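# Dynamic-programming chaining of matches. A chain is scored as
#   sc(C) = sum_i P(m_i) + sum_i Q(m_i, m_{i+1})
# where P rewards the size of each match and Q rewards target spacings
# consistent with the reference, damped by the structural distance d(f,g)
# between the two NBS indices involved.

# Greedy max-index distance scan shared by distance_d() and the DP.
# st/le are the SSD start/length vectors; returns 1 + number of selected
# intermediate non-overlapping NBSs.
.dist_greedy <- function(f, g, st, le) {
  cnt <- 0L
  l <- f
  if (f - g >= 2L) {
    end_g <- st[g] + le[g]
    for (k in seq.int(f - 1L, g + 1L)) {
      if (st[k] + le[k] <= st[l] && end_g <= st[k]) {
        cnt <- cnt + 1L
        l <- k
      }
    }
  }
  1L + cnt
}

# Exact maximum set of mutually non-overlapping NBSs fitting strictly
# between s_g and s_f (classic interval scheduling by earliest end).
.dist_exact <- function(f, g, st, le) {
  if (f - g < 2L) return(1L)
  ks <- seq.int(g + 1L, f - 1L)
  end_g <- st[g] + le[g]
  ks <- ks[st[ks] >= end_g & st[ks] + le[ks] <= st[f]]
  if (!length(ks)) return(1L)
  ks <- ks[order(st[ks] + le[ks], st[ks])]
  cnt <- 0L
  cur <- end_g
  for (k in ks) {
    if (st[k] >= cur) {
      cnt <- cnt + 1L
      cur <- st[k] + le[k]
    }
  }
  1L + cnt
}

#' Structural distance between two NBS indices
#'
#' `d(f, g)` is defined as 1 plus the maximum number of mutually
#' non-overlapping NBSs lying strictly between `s_g` and `s_f` that fit in
#' the interval between them. If no such NBS exists, `d(f, g) = 1`. In a
#' fully non-overlapping (`S1`) descriptor `d(f, g) = f - g`.
#'
#' The default `"greedy"` method is the iterative algorithm that repeatedly
#' selects the maximum eligible index and anchors the next search on it; the
#' `"exact"` method computes the true maximum independent set of intervals
#' (interval scheduling). The greedy pick never exceeds the exact one.
#'
#' @param f,g NBS indices with `1 <= g < f <= |SSD|`.
#' @param ssd An `ssd`.
#' @param method `"greedy"` (default) or `"exact"`.
#' @return Integer distance `>= 1`.
#' @export
distance_d <- function(f, g, ssd, method = c("greedy", "exact")) {
  method <- match.arg(method)
  n <- nrow(ssd$rssps)
  if (g < 1L || f > n || g >= f) {
    stop("distance_d requires 1 <= g < f <= number of RSSPs")
  }
  st <- ssd$rssps$start
  le <- ssd$rssps$length
  if (method == "greedy") .dist_greedy(f, g, st, le) else .dist_exact(f, g, st, le)
}

#' Per-match score P
#'
#' `P(m) = w_p * len(m)`: the individual relevance of a match is its number
#' of bases.
#'
#' @param m One match (list or one-row data frame with a `length` field).
#' @param params [score_params()].
#' @return Numeric score.
#' @export
score_P <- function(m, params = score_params()) {
  params$w_p * as.numeric(m$length)
}

#' Pairwise consistency score Q
#'
#' For consecutive chain members `m_i` (NBS index `g`) and `m_j` (NBS index
#' `f`, with `g < f`), let `gap_R` be the reference gap between `s_g` and
#' `s_f` and `gap_T` the target gap between the two matches. With the
#' normalized gap discrepancy
#' `delta = |gap_T - gap_R| / max(gap_R, gap_T, 1)`,
#' `Q = (w_q / d(f, g)) * exp(-delta / lambda)`, which lies in `(0, w_q]`
#' and is maximal when the target reproduces the reference spacing between
#' consecutive NBSs.
#'
#' @param mi,mj Consecutive matches (lists or one-row data frames with
#'   `nbs_index`, `target_pos`, `length`) satisfying the chain conditions.
#' @param ssd An `ssd`.
#' @param params [score_params()].
#' @return Numeric score.
#' @export
score_Q <- function(mi, mj, ssd, params = score_params()) {
  g <- as.integer(mi$nbs_index)
  f <- as.integer(mj$nbs_index)
  if (g >= f) stop("chain condition (i) violated: need ind(mi) < ind(mj)")
  if (mi$target_pos + mi$length > mj$target_pos) {
    stop("chain condition (ii) violated: target intervals overlap")
  }
  st <- ssd$rssps$start
  le <- ssd$rssps$length
  d <- if (ssd$mode == "S1") f - g
       else if (params$d_method == "exact") .dist_exact(f, g, st, le)
       else .dist_greedy(f, g, st, le)
  gap_r <- st[f] - (st[g] + le[g])
  gap_t <- mj$target_pos - (mi$target_pos + mi$length)
  delta <- abs(gap_t - gap_r) / max(gap_r, gap_t, 1)
  (params$w_q / d) * exp(-delta / params$lambda)
}

#' Recompute the score of a chain from its matches
#'
#' Evaluates `sum P + sum Q` over the chain; used as the independent check
#' that the DP-reported score is exact.
#'
#' @param matches Chain matches in order (`data.frame`).
#' @param ssd An `ssd`.
#' @param params [score_params()].
#' @return Numeric score.
#' @export
chain_score <- function(matches, ssd, params = score_params()) {
  n <- nrow(matches)
  if (!n) return(0)
  s <- sum(params$w_p * matches$length)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      s <- s + score_Q(matches[i, ], matches[i + 1L, ], ssd, params)
    }
  }
  s
}

#' Chain matches by dynamic programming
#'
#' Computes, for every match `m_i`, the best score of a chain ending at
#' `m_i`:
#' `best(i) = P(m_i) + max(0, max_j best(j) + Q(m_j, m_i))`
#' over predecessors `j` with strictly smaller NBS index and a
#' non-overlapping, earlier target interval. Chains may start at any match
#' (local chaining). The top `params$top_k` chains by score are returned
#' (ties: earlier first target position, then shorter target span);
#' traceback ties pick the smallest predecessor index. Each returned chain
#' is re-validated against the chain conditions and its score re-evaluated
#' to within 1e-9.
#'
#' Instrumentation: `q_calls` counts the Q evaluations of the run; `d_steps`
#' accumulates the work of the distance computations (1 per call in `S1`
#' mode where `d` is closed-form, `f - g` per call in `Sk` mode).
#'
#' @param matches Matches sorted by target position, e.g. from
#'   [find_matches()]/[filter_matches()].
#' @param ssd The `ssd` the matches refer to.
#' @param params [score_params()].
#' @return Object of class `chain_result`: list with `chains` (each a list
#'   of `matches`, `score`, `length`), `q_calls`, `d_steps`.
#' @export
chain_matches <- function(matches, ssd, params = score_params()) {
  m <- nrow(matches)
  if (m > 1L && is.unsorted(matches$target_pos)) {
    stop("matches must be sorted by increasing target position")
  }
  st <- ssd$rssps$start
  le <- ssd$rssps$length
  s1 <- ssd$mode == "S1"
  exact <- params$d_method == "exact"
  pos <- matches$target_pos
  len <- matches$length
  ind <- matches$nbs_index
  best <- numeric(m)
  pred <- integer(m)
  q_calls <- 0L
  d_steps <- 0
  for (i in seq_len(m)) {
    bscore <- 0
    bj <- 0L
    ii <- ind[i]
    for (j in seq_len(i - 1L)) {
      if (ind[j] < ii && pos[j] + len[j] <= pos[i]) {
        f <- ii
        g <- ind[j]
        if (s1) {
          d <- f - g
          d_steps <- d_steps + 1
        } else {
          d <- if (exact) .dist_exact(f, g, st, le) else .dist_greedy(f, g, st, le)
          d_steps <- d_steps + (f - g)
        }
        gap_r <- st[f] - (st[g] + le[g])
        gap_t <- pos[i] - (pos[j] + len[j])
        delta <- abs(gap_t - gap_r) / max(gap_r, gap_t, 1)
        q <- (params$w_q / d) * exp(-delta / params$lambda)
        q_calls <- q_calls + 1L
        cand <- best[j] + q
        if (cand > bscore) {
          bscore <- cand
          bj <- j
        }
      }
    }
    best[i] <- params$w_p * len[i] + max(0, bscore)
    pred[i] <- if (bscore > 0) bj else 0L
  }
  chains <- list()
  if (m > 0L) {
    trace <- function(i) {
      path <- integer(0)
      while (i > 0L) {
        path <- c(i, path)
        i <- pred[i]
      }
      path
    }
    paths <- lapply(seq_len(m), trace)
    first <- vapply(paths, function(p) pos[p[1]], 0)
    span <- vapply(paths, function(p) {
      pl <- p[length(p)]
      pos[pl] + len[pl] - pos[p[1]]
    }, 0)
    o <- order(-best, first, span)
    o <- o[seq_len(min(params$top_k, m))]
    chains <- lapply(o, function(i) {
      p <- paths[[i]]
      ch <- matches[p, , drop = FALSE]
      rownames(ch) <- NULL
      validate_chain(ch, ssd)
      sc <- chain_score(ch, ssd, params)
      if (abs(sc - best[i]) > 1e-9) {
        stop("internal error: DP score does not re-evaluate to the chain score")
      }
      list(matches = ch, score = best[i], length = length(p))
    })
  }
  structure(list(chains = chains, q_calls = q_calls, d_steps = d_steps,
                 params = params),
            class = "chain_result")
}

#' Number of Q evaluations in a chaining run
#'
#' @param x A `chain_result`.
#' @return Integer count of Q-function calls.
#' @export
q_call_count <- function(x) {
  stopifnot(inherits(x, "chain_result"))
  x$q_calls
}

#' Accumulated distance-computation work in a chaining run
#'
#' One unit per Q call in `S1` mode (constant-time distance); `f - g` units
#' per call in `Sk` mode (the distance scan walks the intermediate indices).
#'
#' @param x A `chain_result`.
#' @return Numeric work count.
#' @export
d_step_count <- function(x) {
  stopifnot(inherits(x, "chain_result"))
  x$d_steps
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result> %d chain(s); Q calls: %d; distance work: %g\n",
              length(x$chains), x$q_calls, x$d_steps))
  for (i in seq_along(x$chains)) {
    ch <- x$chains[[i]]
    cat(sprintf("  #%d score=%.4f length=%d at target %d..%d\n", i, ch$score,
                ch$length, ch$matches$target_pos[1],
                ch$matches$target_pos[ch$length] + ch$matches$length[ch$length] - 1L))
  }
  invisible(x)
}
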
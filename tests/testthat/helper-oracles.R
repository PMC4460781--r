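# Independent oracles and randomized-instance generators shared by the
# tests. Oracles are deliberately naive (string scans, exhaustive
# enumeration) and never reuse the code paths they check.

# Random pseudoknot-free dot-bracket string of length n (recursive grammar).
random_nested_db <- function(n) {
  if (n <= 0L) return("")
  if (n == 1L) return(".")
  if (stats::runif(1) < 0.4) {
    k <- sample.int(n - 1L, 1L) - 1L # inside the new pair
    paste0("(", random_nested_db(k), ")", random_nested_db(n - 2L - k))
  } else {
    paste0(".", random_nested_db(n - 1L))
  }
}

# Hairpin count by string scan: each innermost "( ... )" run is one hairpin.
oracle_count_hairpins <- function(db) {
  length(gregexpr("\\(\\.*\\)", db)[[1]]) *
    (gregexpr("\\(\\.*\\)", db)[[1]][1] != -1)
}

# Best chain score by exhaustive enumeration of every ordered match subset
# satisfying the chain conditions; uses the exported P/Q scorers so float
# agreement with the DP is exact.
oracle_best_chain_score <- function(matches, ssd, params) {
  m <- nrow(matches)
  if (!m) return(0)
  best <- 0
  extend <- function(last, acc) {
    if (acc > best) best <<- acc
    for (nx in seq_len(m)) {
      if (matches$nbs_index[nx] > matches$nbs_index[last] &&
          matches$target_pos[last] + matches$length[last] <=
            matches$target_pos[nx]) {
        # grouping (acc + Q) + P mirrors the DP recurrence, so agreement is
        # exact in floating point, not merely within tolerance
        extend(nx, acc + score_Q(matches[last, ], matches[nx, ], ssd, params) +
                 score_P(matches[nx, ], params))
      }
    }
  }
  for (s in seq_len(m)) extend(s, score_P(matches[s, ], params))
  best
}

# Maximum number of mutually disjoint intervals strictly between s_g and
# s_f that fit in the gap, by subset enumeration (small instances only).
oracle_max_disjoint_between <- function(f, g, st, le) {
  ks <- seq_len(length(st))
  ks <- ks[ks > g & ks < f & st[ks] >= st[g] + le[g] &
             st[ks] + le[ks] <= st[f]]
  if (!length(ks)) return(0L)
  best <- 0L
  for (mask in seq_len(2^length(ks)) - 1L) {
    sel <- ks[bitwAnd(mask, 2^(seq_along(ks) - 1L)) > 0]
    if (length(sel) <= best) next
    o <- order(st[sel])
    sel <- sel[o]
    if (length(sel) < 2L ||
        all(st[sel][-1] >= (st[sel] + le[sel])[-length(sel)])) {
      best <- length(sel)
    }
  }
  best
}

# A structurally valid RSSP row of a given length (>= 6): two outer GC
# pairs, unpaired interior.
stub_rssp <- function(start, len) {
  stopifnot(len >= 6L)
  data.frame(start = start, length = len,
             structure = paste0("((", strrep(".", len - 4L), "))"),
             subseq = paste0("GG", strrep("A", len - 4L), "CC"),
             energy = NA_real_)
}

# Random SSD with n RSSPs; mode Sk allows overlaps, S1 draws disjoint
# intervals.
random_ssd <- function(n, mode = "Sk", span = 120L) {
  if (mode == "S1") {
    start <- integer(n)
    len <- integer(n)
    cur <- 1L
    for (i in seq_len(n)) {
      cur <- cur + sample.int(6L, 1L) - 1L
      len[i] <- sample(6:14, 1L)
      start[i] <- cur
      cur <- cur + len[i]
    }
  } else {
    start <- sort(sample.int(span, n, replace = TRUE))
    len <- sample(6:14, n, replace = TRUE)
  }
  rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    stub_rssp(start[i], len[i])
  }))
  rows <- rows[order(rows$start, rows$length, rows$structure), ]
  ssd(rows, mode = mode, source_id = "synthetic")
}

# Random match list for an SSD: positions sorted, lengths tied to the
# matched RSSP (the Match invariant).
random_matches <- function(ssd, m, span = 200L) {
  n <- nrow(ssd$rssps)
  idx <- sample.int(n, m, replace = TRUE)
  pos <- sample.int(span, m, replace = TRUE)
  df <- data.frame(nbs_index = idx, target_pos = pos,
                   length = ssd$rssps$length[idx],
                   filter_score = 1)
  df <- df[order(df$target_pos, df$nbs_index), ]
  rownames(df) <- NULL
  df
}

random_rna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Dinucleotide count table used to check the di shuffle.
dinuc_counts <- function(x) {
  table(substring(x, 1:(nchar(x) - 1L), 2:nchar(x)))
}
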
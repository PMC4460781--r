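# Scanning matcher: all positions of the target where each RSSP can occur
# under the base pairing rules, plus the fold-propensity match filter.

#' Find pairing-compatible matches of an SSD in a target sequence
#'
#' For every RSSP and every target offset, the pattern matches iff each
#' paired position `(i, j)` of its structure maps to an allowed pair
#' (AU, UA, CG, GC, GU, UG) in the target. Unpaired pattern positions are
#' unconstrained. All matches are reported, including overlapping ones,
#' sorted by target position (ties by NBS index).
#'
#' @param ssd An `ssd`.
#' @param target Target `seq_record`.
#' @param min_identity Optional minimum fraction of identical bases between
#'   the RSSP subsequence and the target window; 0 (default) disables the
#'   sequence-identity requirement.
#' @return `data.frame` with columns `nbs_index`, `target_pos` (1-based),
#'   `length`, `filter_score` (`NA` until [filter_matches()] is applied).
#' @export
find_matches <- function(ssd, target, min_identity = 0) {
  stopifnot(min_identity >= 0, min_identity <= 1)
  tchars <- strsplit(target$seq, "", fixed = TRUE)[[1]]
  codes <- match(tchars, .BASES)
  nt <- length(codes)
  r <- ssd$rssps
  res <- vector("list", nrow(r))
  for (i in seq_len(nrow(r))) {
    L <- r$length[i]
    n_off <- nt - L + 1L
    if (n_off < 1L) next
    pt <- parse_dotbracket(r$structure[i])
    op <- which(!is.na(pt) & pt > seq_along(pt))
    p <- seq_len(n_off)
    ok <- rep(TRUE, n_off)
    for (k in op) {
      ok <- ok & .PAIR_OK[cbind(codes[p + k - 1L], codes[p + pt[k] - 1L])]
      if (!any(ok)) break
    }
    if (min_identity > 0 && any(ok)) {
      sub <- strsplit(r$subseq[i], "", fixed = TRUE)[[1]]
      ident <- integer(n_off)
      for (k in seq_len(L)) ident <- ident + (tchars[p + k - 1L] == sub[k])
      ok <- ok & (ident / L >= min_identity)
    }
    hit <- which(ok)
    if (length(hit)) {
      res[[i]] <- data.frame(nbs_index = i, target_pos = hit, length = L)
    }
  }
  m <- do.call(rbind, res)
  if (is.null(m)) {
    m <- data.frame(nbs_index = integer(0), target_pos = integer(0),
                    length = integer(0))
  }
  m <- m[order(m$target_pos, m$nbs_index), , drop = FALSE]
  m$filter_score <- rep(NA_real_, nrow(m))
  rownames(m) <- NULL
  m
}

#' Fold-propensity score of matches
#'
#' A deterministic surrogate for the probability that the target window folds
#' into the pattern's structure: `PS = (3 nGC + 2 nAU + nGU) / (3 n_pairs)`,
#' where the counts classify the pairs the target would form. `PS` lies in
#' `(0, 1]`; an all-GC stem scores 1, an all-wobble stem 1/3.
#'
#' @param matches Output of [find_matches()].
#' @param target Target `seq_record`.
#' @param ssd The `ssd` the matches refer to.
#' @return Numeric vector of scores, one per match.
#' @export
fold_propensity <- function(matches, target, ssd) {
  codes <- match(strsplit(target$seq, "", fixed = TRUE)[[1]], .BASES)
  ps <- numeric(nrow(matches))
  if (!nrow(matches)) return(ps)
  pts <- lapply(ssd$rssps$structure, parse_dotbracket)
  for (i in seq_len(nrow(matches))) {
    pt <- pts[[matches$nbs_index[i]]]
    op <- which(!is.na(pt) & pt > seq_along(pt))
    p0 <- matches$target_pos[i] - 1L
    w <- .PAIR_WEIGHT[cbind(codes[p0 + op], codes[p0 + pt[op]])]
    ps[i] <- sum(w) / (3 * length(op))
  }
  ps
}

#' Filter weak matches by fold propensity
#'
#' Annotates each match with its fold-propensity score (see
#' [fold_propensity()], or a user-supplied engine) and removes matches
#' scoring below `tau`. Order is preserved; raising `tau` never adds
#' matches.
#'
#' @param matches Output of [find_matches()].
#' @param target Target `seq_record`.
#' @param ssd The `ssd` the matches refer to.
#' @param tau Threshold in `(0, 1]`.
#' @param engine Optional function `(subsequence, structure) -> [0, 1]`
#'   replacing the built-in propensity, e.g. a thermodynamic adapter
#'   returning the probability of the constrained structure.
#' @return Filtered `data.frame` with `filter_score` filled in.
#' @export
filter_matches <- function(matches, target, ssd, tau = 0.5, engine = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]")
  }
  if (!nrow(matches)) return(matches)
  if (is.null(engine)) {
    ps <- fold_propensity(matches, target, ssd)
  } else {
    ps <- vapply(seq_len(nrow(matches)), function(i) {
      sub <- substr(target$seq, matches$target_pos[i],
                    matches$target_pos[i] + matches$length[i] - 1L)
      engine(sub, ssd$rssps$structure[matches$nbs_index[i]])
    }, 0)
  }
  matches$filter_score <- ps
  out <- matches[ps >= tau, , drop = FALSE]
  rownames(out) <- NULL
  out
}
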
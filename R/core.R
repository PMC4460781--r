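# Domain model: sequences, dot-bracket structures, SSDs, matches, chains.
# Coordinates are 1-based inclusive everywhere (R convention); an interval
# [start, start+length-1] is disjoint from a later one iff start+length <= start'.

.BASES <- c("A", "C", "G", "U", "N")

# Allowed pairs: Watson-Crick plus GU wobble. N never pairs.
.PAIR_OK <- local({
  m <- matrix(FALSE, 5, 5, dimnames = list(.BASES, .BASES))
  for (p in list(c("A", "U"), c("U", "A"), c("C", "G"), c("G", "C"),
                 c("G", "U"), c("U", "G"))) {
    m[p[1], p[2]] <- TRUE
  }
  m
})

# Nussinov-style pair strengths used by the match filter: GC=3, AU=2, GU=1.
.PAIR_WEIGHT <- local({
  m <- matrix(0, 5, 5, dimnames = list(.BASES, .BASES))
  m["G", "C"] <- m["C", "G"] <- 3
  m["A", "U"] <- m["U", "A"] <- 2
  m["G", "U"] <- m["U", "G"] <- 1
  m
})

.enc <- function(seq) {
  code <- match(strsplit(seq, "", fixed = TRUE)[[1]], .BASES)
  stopifnot(!anyNA(code))
  code
}

#' Create an RNA sequence record
#'
#' Normalizes the alphabet (uppercase, DNA `T` converted to `U`) and rejects
#' characters outside `A`, `C`, `G`, `U`, `N`. `N` is a legal placeholder that
#' never forms a base pair.
#'
#' @param id Record identifier (non-empty string).
#' @param seq Nucleotide sequence.
#' @return An object of class `seq_record` with fields `id` and `seq`.
#' @export
#' @examples
#' seq_record("x", "acgt")$seq # "ACGU"
seq_record <- function(id, seq) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("sequence id must be a non-empty string")
  }
  seq <- chartr("t", "u", tolower(seq))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("sequence '", id, "' is empty")
  bad <- regmatches(seq, regexpr("[^ACGUN]", seq))
  if (length(bad) && nzchar(bad)) {
    stop("sequence '", id, "' contains illegal character '", bad, "'")
  }
  structure(list(id = id, seq = seq), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d nt)\n", x$id, nchar(x$seq)))
  invisible(x)
}

#' Parse dot-bracket notation into a pair table
#'
#' The pair table is an integer vector of the same length as the structure;
#' entry `i` holds the 1-based partner of position `i`, or `NA` if unpaired.
#' Only pseudoknot-free (nested) structures over the alphabet `.`, `(`, `)`
#' are accepted.
#'
#' @param db Dot-bracket string.
#' @return Integer vector of class `pair_table`.
#' @export
#' @examples
#' parse_dotbracket("((...))")
parse_dotbracket <- function(db) {
  stopifnot(is.character(db), length(db) == 1L)
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad)) {
    stop(sprintf("illegal structure character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  open <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      open <- c(open, i)
    } else if (chars[i] == ")") {
      if (!length(open)) {
        stop(sprintf("unbalanced structure: unmatched ')' at position %d", i))
      }
      j <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(open)) {
    stop(sprintf("unbalanced structure: unmatched '(' at position %d", open[1]))
  }
  structure(partner, class = "pair_table")
}

#' Render a pair table back to dot-bracket notation
#'
#' Inverse of [parse_dotbracket()]: `render_dotbracket(parse_dotbracket(db))`
#' is the identity on every valid dot-bracket string.
#'
#' @param pt A `pair_table`.
#' @return Dot-bracket string.
#' @export
render_dotbracket <- function(pt) {
  idx <- seq_along(pt)
  paste(ifelse(is.na(pt), ".", ifelse(pt > idx, "(", ")")), collapse = "")
}

#' Count hairpin loops in a pair table
#'
#' A hairpin loop is a pair enclosing no further pairs. A non-branching
#' structure contains exactly one.
#'
#' @param pt A `pair_table` (or dot-bracket string, parsed on the fly).
#' @return Integer count.
#' @export
count_hairpins <- function(pt) {
  if (is.character(pt)) pt <- parse_dotbracket(pt)
  cnt <- 0L
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (!is.na(j) && j > i &&
        (j == i + 1L || all(is.na(pt[(i + 1L):(j - 1L)])))) {
      cnt <- cnt + 1L
    }
  }
  cnt
}

#' Test whether a structure is non-branching
#'
#' A non-branching structure (NBS) is a single stem-loop: one hairpin loop
#' closed by a helix that may be interrupted by bulges and internal loops,
#' but no multiloop. For nested structures this is equivalent to containing
#' exactly one hairpin loop (a multiloop implies at least two).
#'
#' @param db Dot-bracket string.
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' is_non_branching("((..((...))..))") # TRUE: internal loop, one hairpin
#' is_non_branching("(((...)(...)))")  # FALSE: multiloop
is_non_branching <- function(db) {
  count_hairpins(parse_dotbracket(db)) == 1L
}

#' Scoring and search parameters
#'
#' @param w_p Weight per matched base in the per-match term P (>= 0).
#' @param w_q Scale of the pairwise consistency term Q (>= 0).
#' @param lambda Decay of the gap-consistency penalty (> 0, unitless).
#' @param tau Match-filter threshold on the fold-propensity score, in (0, 1].
#' @param top_k Number of chains to report.
#' @param min_identity Minimum sequence identity between pattern subsequence
#'   and target window, in `[0, 1]`; 0 disables the identity requirement
#'   (pure structure-compatibility matching).
#' @param d_method How the structural distance d(f,g) is computed in the
#'   overlapping (`Sk`) mode: `"greedy"` (iterative max-index algorithm) or
#'   `"exact"` (maximum set of mutually non-overlapping intervals).
#' @return List of class `score_params`.
#' @export
score_params <- function(w_p = 1, w_q = 1, lambda = 0.5, tau = 0.5,
                         top_k = 10L, min_identity = 0,
                         d_method = c("greedy", "exact")) {
  d_method <- match.arg(d_method)
  stopifnot(w_p >= 0, w_q >= 0, lambda > 0, tau > 0, tau <= 1,
            top_k >= 1, min_identity >= 0, min_identity <= 1)
  structure(list(w_p = w_p, w_q = w_q, lambda = lambda, tau = tau,
                 top_k = as.integer(top_k), min_identity = min_identity,
                 d_method = d_method),
            class = "score_params")
}

#' Construct a secondary structure descriptor (SSD)
#'
#' An SSD is the ordered list of RNA sequence-structure patterns (RSSPs)
#' describing the local stem-loops of a reference RNA. In mode `S1` the
#' patterns are mutually non-overlapping (a unique structure prediction); in
#' mode `Sk` overlapping patterns encoding alternative predictions are kept.
#'
#' @param rssps `data.frame` with columns `start` (1-based), `length`,
#'   `structure` (dot-bracket), `subseq` (reference subsequence) and
#'   optionally `energy` (kcal/mol, `NA` allowed).
#' @param mode `"S1"` or `"Sk"`.
#' @param source_id Identifier of the reference sequence.
#' @param validate Check invariants (sortedness, pairing compatibility,
#'   non-branching structures, S1 disjointness).
#' @return Object of class `ssd`.
#' @export
ssd <- function(rssps, mode = c("S1", "Sk"), source_id = NA_character_,
                validate = TRUE) {
  mode <- match.arg(mode)
  rssps <- as.data.frame(rssps)
  if (is.null(rssps$energy)) rssps$energy <- NA_real_
  n <- nrow(rssps)
  rssps <- rssps[, c("start", "length", "structure", "subseq", "energy")]
  rssps$index <- seq_len(n)
  rssps <- rssps[, c("index", "start", "length", "structure", "subseq", "energy")]
  rownames(rssps) <- NULL
  obj <- structure(list(rssps = rssps, mode = mode, source_id = source_id),
                   class = "ssd")
  if (validate && n > 0L) validate_ssd(obj)
  obj
}

#' Validate SSD invariants
#'
#' Checks that RSSPs are sorted by increasing start (ties by length, then
#' structure), that structure and subsequence lengths agree with the declared
#' length, that every paired position is an allowed pair in the subsequence,
#' that every structure is non-branching, and (mode `S1`) that consecutive
#' patterns do not overlap.
#'
#' @param x An `ssd`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_ssd <- function(x) {
  r <- x$rssps
  n <- nrow(r)
  if (n == 0L) return(invisible(TRUE))
  if (any(nchar(r$structure) != r$length)) {
    stop("SSD invariant violated: structure length != declared length")
  }
  if (any(nchar(r$subseq) != r$length)) {
    stop("SSD invariant violated: subsequence length != declared length")
  }
  o <- order(r$start, r$length, r$structure)
  if (!identical(o, seq_len(n))) stop("SSD entries are not sorted by start")
  if (x$mode == "S1" && n > 1L) {
    if (any(r$start[-1] < (r$start + r$length)[-n])) {
      stop("S1 SSD contains overlapping RSSPs")
    }
  }
  for (i in seq_len(n)) {
    pt <- parse_dotbracket(r$structure[i])
    if (count_hairpins(pt) != 1L) {
      stop("RSSP ", i, " is not a non-branching structure")
    }
    code <- .enc(r$subseq[i])
    op <- which(!is.na(pt) & pt > seq_along(pt))
    if (length(op) && !all(.PAIR_OK[cbind(code[op], code[pt[op]])])) {
      stop("RSSP ", i, " subsequence cannot form its own predicted pairs")
    }
  }
  invisible(TRUE)
}

#' @export
print.ssd <- function(x, ...) {
  cat(sprintf("<ssd> mode=%s source=%s rssps=%d\n",
              x$mode, x$source_id, nrow(x$rssps)))
  if (nrow(x$rssps)) print(utils::head(x$rssps, 10))
  invisible(x)
}

#' Validate chain conditions
#'
#' A chain is an ordered list of matches with (i) strictly increasing NBS
#' indices and (ii) non-overlapping, increasing target intervals
#' (`pos + len <= pos'` for consecutive matches). Used as the postcondition
#' gate of the chainer.
#'
#' @param matches `data.frame` with columns `nbs_index`, `target_pos`,
#'   `length`, in chain order.
#' @param ssd The SSD the matches refer to.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_chain <- function(matches, ssd) {
  n <- nrow(matches)
  if (n == 0L) return(invisible(TRUE))
  if (any(matches$nbs_index < 1L) || any(matches$nbs_index > nrow(ssd$rssps))) {
    stop("chain refers to NBS indices outside the SSD")
  }
  if (any(matches$length != ssd$rssps$length[matches$nbs_index])) {
    stop("chain match length differs from its NBS length")
  }
  if (n > 1L) {
    if (any(diff(matches$nbs_index) <= 0L)) {
      stop("chain condition (i) violated: NBS indices not strictly increasing")
    }
    ends <- matches$target_pos + matches$length
    if (any(matches$target_pos[-1] < ends[-n])) {
      stop("chain condition (ii) violated: overlapping target intervals")
    }
  }
  invisible(TRUE)
}
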
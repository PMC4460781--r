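# Synthetic planted-motif generator: references carrying a known stem-loop
# architecture and targets carrying pairing-compatible, optionally noisy
# copies, so every pipeline stage is testable without external data.

.sample_bases <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  if (n <= 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a random hairpin fragment
#'
#' Builds a single stem-loop: `stem_pairs` base pairs (sampled from
#' configurable GC/AU/GU class weights, orientation uniform), a loop of
#' `loop_len` random bases, and optionally single-nucleotide bulges inserted
#' between stacked pairs on a random strand. By construction the fragment
#' can fold into the returned non-branching dot-bracket under the pairing
#' rules.
#'
#' @param stem_pairs Number of base pairs (>= 2).
#' @param loop_len Hairpin loop length (>= 3).
#' @param bulges Number of 1-nt bulges (0 to `stem_pairs - 1`).
#' @param pair_weights Named weights for pair classes `GC`, `AU`, `GU`.
#'   The default is GC-enriched with occasional wobbles, as in stable
#'   natural helices.
#' @return List with `seq` and `structure` (equal length).
#' @export
make_hairpin <- function(stem_pairs, loop_len, bulges = 0,
                         pair_weights = c(GC = 2, AU = 1, GU = 0.25)) {
  stopifnot(stem_pairs >= 2L, loop_len >= 3L,
            bulges >= 0L, bulges <= stem_pairs - 1L)
  classes <- c("GC", "CG", "AU", "UA", "GU", "UG")
  w <- rep(pair_weights[c("GC", "AU", "GU")] / 2, each = 2)
  picks <- sample(classes, stem_pairs, replace = TRUE, prob = w)
  left5 <- substr(picks, 1, 1)   # 5' strand, outside-in
  right3 <- substr(picks, 2, 2)  # 3' strand, outside-in
  bulge_at <- if (bulges > 0L) {
    sort(sample.int(stem_pairs - 1L, bulges))
  } else integer(0)
  bulge_side <- sample(c("L", "R"), length(bulge_at), replace = TRUE)
  lseq <- ldb <- rseq <- rdb <- character(0) # right built outside-in, reversed later
  for (k in seq_len(stem_pairs)) {
    lseq <- c(lseq, left5[k])
    ldb <- c(ldb, "(")
    rseq <- c(rseq, right3[k])
    rdb <- c(rdb, ")")
    bi <- match(k, bulge_at)
    if (!is.na(bi)) {
      if (bulge_side[bi] == "L") {
        lseq <- c(lseq, .sample_bases(1))
        ldb <- c(ldb, ".")
      } else {
        rseq <- c(rseq, .sample_bases(1))
        rdb <- c(rdb, ".")
      }
    }
  }
  loop <- .sample_bases(loop_len)
  seq <- paste(c(lseq, loop, rev(rseq)), collapse = "")
  db <- paste(c(ldb, rep(".", loop_len), rev(rdb)), collapse = "")
  stopifnot(nchar(seq) == nchar(db))
  list(seq = seq, structure = db)
}

#' Plant a shared stem-loop architecture in a reference/target pair
#'
#' The reference is a random background carrying `k_motifs` hairpins at
#' regular spacings; one folding window per motif (with a stability
#' proportional to its stem size) makes the planted structures available to
#' the extractor without any external folding engine. The target carries
#' pairing-compatible copies of the motifs, in the same order, with the
#' unpaired positions mutated at `mutation_rate` and the gaps jittered by up
#' to `jitter` nt. The truth table records where each copy was planted.
#'
#' @param k_motifs Number of planted hairpins (>= 1).
#' @param spacing Background gap between consecutive motifs, nt.
#' @param jitter Maximum absolute jitter applied to each target gap, nt.
#' @param mutation_rate Per-base substitution rate on unpaired motif
#'   positions of the target copies, in `[0, 1)`.
#' @param bg_len Total reference length, nt; defaults to the motifs plus
#'   `spacing` between and around them. Motifs exceeding `bg_len` is an
#'   error.
#' @param stem_pairs,loop_len,bulges,pair_weights Motif geometry, see
#'   [make_hairpin()].
#' @param bg_probs Background base composition (default uniform ACGU).
#' @return List of class `planted_pair`: `reference`, `windows`, `ssd`
#'   (mode `S1`, built from the windows), `target`, `truth` (`data.frame`
#'   `nbs_index`, `target_pos`, `length`), and the motif list.
#' @export
plant_reference_and_target <- function(k_motifs = 5L, spacing = 20L,
                                       jitter = 0L, mutation_rate = 0,
                                       bg_len = NULL,
                                       stem_pairs = 8L, loop_len = 4L,
                                       bulges = 0L,
                                       pair_weights = c(GC = 2, AU = 1, GU = 0.25),
                                       bg_probs = c(A = 0.25, C = 0.25,
                                                    G = 0.25, U = 0.25)) {
  stopifnot(k_motifs >= 1L, jitter >= 0L, mutation_rate >= 0, mutation_rate < 1)
  motifs <- lapply(seq_len(k_motifs), function(i) {
    make_hairpin(stem_pairs, loop_len, bulges, pair_weights)
  })
  mlen <- vapply(motifs, function(m) nchar(m$seq), 0L)
  need <- sum(mlen) + (k_motifs + 1L) * spacing
  if (is.null(bg_len)) bg_len <- need
  if (sum(mlen) + (k_motifs - 1L) * spacing > bg_len) {
    stop("planted motifs exceed the requested background length")
  }
  pad <- (bg_len - sum(mlen) - (k_motifs - 1L) * spacing) %/% 2L
  build <- function(gaps, lead, frags) {
    pieces <- character(0)
    pos <- integer(k_motifs)
    cur <- 0L
    add_bg <- function(n) paste(.sample_bases(n, bg_probs), collapse = "")
    pieces <- c(pieces, add_bg(lead))
    cur <- lead
    for (i in seq_len(k_motifs)) {
      if (i > 1L) {
        pieces <- c(pieces, add_bg(gaps[i - 1L]))
        cur <- cur + gaps[i - 1L]
      }
      pos[i] <- cur + 1L
      pieces <- c(pieces, frags[i])
      cur <- cur + nchar(frags[i])
    }
    tail_len <- max(bg_len - cur, 0L)
    pieces <- c(pieces, add_bg(tail_len))
    list(seq = paste(pieces, collapse = ""), pos = pos)
  }
  ref_gaps <- rep(spacing, max(k_motifs - 1L, 0L))
  ref <- build(ref_gaps, pad, vapply(motifs, `[[`, "", "seq"))
  reference <- seq_record("ref", ref$seq)
  windows <- lapply(seq_len(k_motifs), function(i) {
    fold_window(motifs[[i]]$structure, energy = -2 * stem_pairs,
                start = ref$pos[i], window_id = i)
  })
  true_ssd <- build_ssd(windows, reference, mode = "S1")

  # target copies: paired positions intact, unpaired positions mutated
  copies <- vapply(seq_len(k_motifs), function(i) {
    ch <- strsplit(motifs[[i]]$seq, "", fixed = TRUE)[[1]]
    un <- which(strsplit(motifs[[i]]$structure, "", fixed = TRUE)[[1]] == ".")
    if (mutation_rate > 0 && length(un)) {
      hit <- un[stats::runif(length(un)) < mutation_rate]
      for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, "")
  tgt_gaps <- if (k_motifs > 1L) {
    pmax(ref_gaps + sample(seq.int(-jitter, jitter), k_motifs - 1L,
                           replace = TRUE), 0L)
  } else integer(0)
  tgt <- build(tgt_gaps, pad, copies)
  target <- seq_record("target", tgt$seq)
  truth <- data.frame(nbs_index = seq_len(k_motifs), target_pos = tgt$pos,
                      length = mlen)
  structure(list(reference = reference, windows = windows, ssd = true_ssd,
                 target = target, truth = truth, motifs = motifs,
                 spacing = spacing, pad = pad, bg_probs = bg_probs),
            class = "planted_pair")
}

#' Draw a fresh target sharing a planted architecture
#'
#' Generates another target carrying pairing-compatible copies of the
#' motifs of an existing [plant_reference_and_target()] result, with its
#' own background, jitter and unpaired-position mutations — a synthetic
#' "family member".
#'
#' @param plant A `planted_pair`.
#' @param jitter,mutation_rate Noise applied to this member.
#' @param id Identifier of the new record.
#' @return List with `target` (`seq_record`) and `truth`.
#' @export
sample_target <- function(plant, jitter = 0L, mutation_rate = 0,
                          id = "member") {
  k <- length(plant$motifs)
  copies <- vapply(seq_len(k), function(i) {
    ch <- strsplit(plant$motifs[[i]]$seq, "", fixed = TRUE)[[1]]
    un <- which(strsplit(plant$motifs[[i]]$structure, "", fixed = TRUE)[[1]] == ".")
    if (mutation_rate > 0 && length(un)) {
      hit <- un[stats::runif(length(un)) < mutation_rate]
      for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, "")
  gaps <- if (k > 1L) {
    pmax(rep(plant$spacing, k - 1L) +
           sample(seq.int(-jitter, jitter), k - 1L, replace = TRUE), 0L)
  } else integer(0)
  pieces <- character(0)
  pos <- integer(k)
  cur <- 0L
  lead <- paste(.sample_bases(plant$pad, plant$bg_probs), collapse = "")
  pieces <- lead
  cur <- nchar(lead)
  for (i in seq_len(k)) {
    if (i > 1L) {
      g <- paste(.sample_bases(gaps[i - 1L], plant$bg_probs), collapse = "")
      pieces <- c(pieces, g)
      cur <- cur + nchar(g)
    }
    pos[i] <- cur + 1L
    pieces <- c(pieces, copies[i])
    cur <- cur + nchar(copies[i])
  }
  pieces <- c(pieces, paste(.sample_bases(plant$pad, plant$bg_probs),
                            collapse = ""))
  list(target = seq_record(id, paste(pieces, collapse = "")),
       truth = data.frame(nbs_index = seq_len(k), target_pos = pos,
                          length = vapply(plant$motifs,
                                          function(m) nchar(m$seq), 0L)))
}

#' Write a planted fixture to disk
#'
#' Emits `reference.fa`, `target.fa`, `predictions.txt` (RNALfold dialect)
#' and `truth.tsv`. The truth table uses the chain-report dialect (the
#' planted chain scored with `params`), so exact recovery is a file-level
#' diff against the search's chain report.
#'
#' @param plant A `planted_pair`.
#' @param dir Output directory (created if needed).
#' @param params [score_params()] used to score the truth chain.
#' @return Invisibly a named list of the written paths.
#' @export
write_fixture <- function(plant, dir, params = score_params()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    target = file.path(dir, "target.fa"),
    predictions = file.path(dir, "predictions.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(list(plant$reference), paths$reference)
  write_fasta(list(plant$target), paths$target)
  write_fold_predictions(plant$windows, paths$predictions)
  truth_chain <- list(matches = plant$truth,
                      score = chain_score(plant$truth, plant$ssd, params))
  write_chain_report(list(truth_chain), paths$truth)
  invisible(paths)
}
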
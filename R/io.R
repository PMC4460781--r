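# Readers/writers: FASTA, RNALfold-style local folding output, SSD pattern
# files, and chain report TSVs.

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Sequences are normalized to the RNA alphabet (uppercase, `T` converted to
#' `U`). Duplicate identifiers and characters outside `A`,`C`,`G`,`U`,`T`,`N`
#' are errors.
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record()] objects in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  lapply(seq_along(set), function(i) seq_record(ids[i], as.character(set[[i]])))
}

#' Write sequence records as FASTA
#'
#' @param records List of `seq_record` objects.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a local folding window
#'
#' One record of a local-folding prediction: a locally stable secondary
#' structure, its free energy, and its 1-based start on the reference.
#'
#' @param structure Dot-bracket string (validated).
#' @param energy Free energy in kcal/mol.
#' @param start 1-based start position on the reference.
#' @param window_id Ordinal provenance id.
#' @return List of class `fold_window`.
#' @export
fold_window <- function(structure, energy, start, window_id = NA_integer_) {
  parse_dotbracket(structure) # validates
  stopifnot(start >= 1)
  structure(list(structure = structure, energy = as.numeric(energy),
                 start = as.integer(start), window_id = as.integer(window_id)),
            class = "fold_window")
}

# One prediction line: dot-bracket, "( energy )", 1-based start.
.FOLD_LINE_RE <- "^([.()]+)\\s+\\(\\s*([-+]?[0-9]+(?:\\.[0-9]+)?)\\s*\\)\\s+([0-9]+)\\s*$"

#' Parse RNALfold-style local folding predictions
#'
#' Each prediction line holds a dot-bracket structure, the free energy in
#' parentheses, and the 1-based start position, e.g.
#' `"((((...)))) ( -5.20)   17"`. Trailing summary lines (a bare sequence
#' and/or a bare total energy in parentheses) are ignored; any other
#' non-empty unparseable line is an error reporting its line number.
#'
#' @param path Path to the prediction text file.
#' @param reference Optional `seq_record`; when supplied, windows extending
#'   past the reference end are errors.
#' @return List of `fold_window` objects in input order.
#' @export
parse_fold_predictions <- function(path, reference = NULL) {
  lines <- readLines(path)
  out <- list()
  wid <- 0L
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) next
    m <- regmatches(line, regexec(.FOLD_LINE_RE, line))[[1]]
    if (length(m) == 4L) {
      wid <- wid + 1L
      w <- fold_window(m[2], as.numeric(m[3]), as.integer(m[4]), wid)
      if (!is.null(reference) &&
          w$start + nchar(w$structure) - 1L > nchar(reference$seq)) {
        stop(sprintf("line %d: window [%d, %d] exceeds reference length %d",
                     ln, w$start, w$start + nchar(w$structure) - 1L,
                     nchar(reference$seq)))
      }
      out[[length(out) + 1L]] <- w
      next
    }
    # trailing summary lines emitted by local folding tools
    if (grepl("^[ACGUTNacgutn]+$", trimws(line))) next
    if (grepl("^\\(\\s*[-+]?[0-9]+(\\.[0-9]+)?\\s*\\)$", trimws(line))) next
    stop(sprintf("line %d: cannot parse folding prediction line: '%s'",
                 ln, line))
  }
  out
}

#' Write an SSD pattern file
#'
#' Layout per RSSP: a header line
#' `>rssp_<index> start=<1-based> len=<L> energy=<E|NA> mode=<S1|Sk>`,
#' the reference subsequence line, then the dot-bracket line. An empty SSD
#' yields an empty file. The format round-trips bit-exactly through
#' [read_ssd()].
#'
#' @param x An `ssd`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_ssd <- function(x, path) {
  r <- x$rssps
  lines <- character(0)
  for (i in seq_len(nrow(r))) {
    en <- if (is.na(r$energy[i])) "NA" else sprintf("%.2f", r$energy[i])
    lines <- c(lines,
               sprintf(">rssp_%d start=%d len=%d energy=%s mode=%s",
                       r$index[i], r$start[i], r$length[i], en, x$mode),
               r$subseq[i],
               r$structure[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an SSD pattern file
#'
#' @param path Path written by [write_ssd()].
#' @param mode Mode assumed for an empty file (non-empty files carry the mode
#'   in their headers).
#' @param source_id Reference id to record on the returned object.
#' @return An `ssd`.
#' @export
read_ssd <- function(path, mode = c("S1", "Sk"), source_id = NA_character_) {
  mode <- match.arg(mode)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(ssd(data.frame(start = integer(0), length = integer(0),
                          structure = character(0), subseq = character(0),
                          energy = numeric(0)),
               mode = mode, source_id = source_id))
  }
  if (length(lines) %% 3L != 0L) {
    stop("malformed SSD file: expected header/sequence/structure triples")
  }
  hre <- "^>rssp_([0-9]+) start=([0-9]+) len=([0-9]+) energy=(NA|[-+]?[0-9.]+) mode=(S1|Sk)$"
  n <- length(lines) %/% 3L
  start <- len <- integer(n)
  en <- numeric(n)
  subseq <- db <- character(n)
  modes <- character(n)
  for (i in seq_len(n)) {
    h <- lines[3L * i - 2L]
    m <- regmatches(h, regexec(hre, h))[[1]]
    if (length(m) != 6L) stop("malformed SSD header: '", h, "'")
    start[i] <- as.integer(m[3])
    len[i] <- as.integer(m[4])
    en[i] <- if (m[5] == "NA") NA_real_ else as.numeric(m[5])
    modes[i] <- m[6]
    subseq[i] <- lines[3L * i - 1L]
    db[i] <- lines[3L * i]
    if (nchar(subseq[i]) != len[i] || nchar(db[i]) != len[i]) {
      stop(sprintf("SSD entry %d: header len=%d but sequence/structure lengths are %d/%d",
                   i, len[i], nchar(subseq[i]), nchar(db[i])))
    }
  }
  if (length(unique(modes)) != 1L) stop("SSD file mixes S1 and Sk headers")
  ssd(data.frame(start = start, length = len, structure = db,
                 subseq = subseq, energy = en),
      mode = modes[1], source_id = source_id)
}

.format_score <- function(x) sprintf("%.4f", x)

#' Write a chain report
#'
#' TSV with columns `chain_rank`, `score`, `n_matches` and `matches`, the
#' latter a comma-separated list of `nbs_index:target_start:length` triples
#' (1-based starts). Chains are ordered by decreasing score; ties are broken
#' by the earlier first target position.
#'
#' @param chains List of chains, each a list with elements `matches`
#'   (`data.frame` with `nbs_index`, `target_pos`, `length`) and `score`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_chain_report <- function(chains, path) {
  header <- "chain_rank\tscore\tn_matches\tmatches"
  if (!length(chains)) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- vapply(chains, `[[`, 0, "score")
  first <- vapply(chains, function(ch) ch$matches$target_pos[1], 0)
  o <- order(-score, first)
  rows <- vapply(seq_along(o), function(r) {
    ch <- chains[[o[r]]]
    trip <- paste(sprintf("%d:%d:%d", ch$matches$nbs_index,
                          ch$matches$target_pos, ch$matches$length),
                  collapse = ",")
    sprintf("%d\t%s\t%d\t%s", r, .format_score(ch$score),
            nrow(ch$matches), trip)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a chain report written by [write_chain_report()]
#'
#' @param path Path to the TSV.
#' @return List of chains (`matches` data frame plus `score` and `rank`).
#' @export
read_chain_report <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "chain_rank\tscore\tn_matches\tmatches") {
    stop("not a chain report: ", path)
  }
  lapply(lines[-1][nzchar(lines[-1])], function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    trip <- do.call(rbind, lapply(strsplit(f[4], ",", fixed = TRUE)[[1]],
                                  function(t) as.integer(strsplit(t, ":", fixed = TRUE)[[1]])))
    list(rank = as.integer(f[1]), score = as.numeric(f[2]),
         matches = data.frame(nbs_index = trip[, 1], target_pos = trip[, 2],
                              length = trip[, 3]))
  })
}

#' Write folding windows in the RNALfold-style dialect
#'
#' Emits the same line layout accepted by [parse_fold_predictions()], so the
#' pair is self-consistent by construction.
#'
#' @param windows List of `fold_window` objects.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_fold_predictions <- function(windows, path) {
  lines <- vapply(windows, function(w) {
    sprintf("%s (%6.2f) %5d", w$structure, w$energy, w$start)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
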
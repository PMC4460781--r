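one_rssp_ssd <- function(subseq = "GGAAACC", db = "((...))", start = 5L) {
  ssd(data.frame(start = start, length = nchar(db), structure = db,
                 subseq = subseq, energy = NA_real_), mode = "S1")
}

test_that("a pattern matches itself and fails where pairing is impossible", {
  s <- one_rssp_ssd()
  m <- find_matches(s, seq_record("t", "GGAAACC"))
  expect_equal(nrow(m), 1)
  expect_equal(m$target_pos, 1L)
  # positions 2 and 6 are G,G: cannot pair
  expect_equal(nrow(find_matches(s, seq_record("t", "GGAAAGG"))), 0)
})

test_that("the scan matcher agrees with a brute-force pairing check", {
  set.seed(41)
  brute <- function(db, target) {
    pt <- parse_dotbracket(db)
    op <- which(!is.na(pt) & pt > seq_along(pt))
    tch <- strsplit(target, "", fixed = TRUE)[[1]]
    pair_ok <- function(a, b) {
      paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
    }
    hits <- integer(0)
    for (p in seq_len(nchar(target) - nchar(db) + 1L)) {
      if (all(vapply(op, function(k) {
        pair_ok(tch[p + k - 1L], tch[p + pt[k] - 1L])
      }, logical(1)))) {
        hits <- c(hits, p)
      }
    }
    hits
  }
  s <- one_rssp_ssd()
  m <- find_matches(s, seq_record("t", "UGAAACAUGAAACA"))
  expect_equal(m$target_pos, brute("((...))", "UGAAACAUGAAACA"))
  for (i in 1:25) {
    h <- make_hairpin(sample(2:5, 1), sample(3:6, 1), bulges = sample(0:1, 1))
    s <- ssd(data.frame(start = 1L, length = nchar(h$seq),
                        structure = h$structure, subseq = h$seq,
                        energy = NA_real_), mode = "S1")
    tgt <- random_rna(sample(50:200, 1))
    m <- find_matches(s, seq_record("t", tgt))
    expect_equal(m$target_pos, brute(h$structure, tgt), info = h$structure)
  }
})

test_that("matches are sorted by target position with overlaps retained", {
  set.seed(40)
  s <- ssd(rbind(stub_rssp(1L, 6L), stub_rssp(10L, 6L)), mode = "S1")
  tgt <- seq_record("t", random_rna(150))
  m <- find_matches(s, tgt)
  expect_gt(nrow(m), 0)
  expect_false(is.unsorted(m$target_pos))
  # ties ordered by nbs_index: both RSSPs share the stub structure, so every
  # hit position appears once per index
  dup <- m[duplicated(m$target_pos) | duplicated(m$target_pos, fromLast = TRUE), ]
  if (nrow(dup)) {
    expect_true(all(tapply(dup$nbs_index, dup$target_pos, function(x) {
      !is.unsorted(x)
    })))
  }
})

test_that("self-match completeness: every RSSP matches its own reference position", {
  set.seed(42)
  for (i in 1:10) {
    plant <- plant_reference_and_target(k_motifs = 4, spacing = 15,
                                        stem_pairs = 5)
    m <- find_matches(plant$ssd, plant$reference)
    for (r in seq_len(nrow(plant$ssd$rssps))) {
      expect_true(any(m$nbs_index == r &
                        m$target_pos == plant$ssd$rssps$start[r]))
    }
  }
})

test_that("the sequence-identity option only restricts the match set", {
  set.seed(43)
  h <- make_hairpin(4, 5)
  s <- ssd(data.frame(start = 1L, length = nchar(h$seq),
                      structure = h$structure, subseq = h$seq,
                      energy = NA_real_), mode = "S1")
  tgt <- seq_record("t", paste0(random_rna(60), h$seq, random_rna(60)))
  m0 <- find_matches(s, tgt)
  m9 <- find_matches(s, tgt, min_identity = 0.9)
  expect_true(all(m9$target_pos %in% m0$target_pos))
  expect_true(61L %in% m9$target_pos) # the exact copy passes any identity
  expect_error(find_matches(s, tgt, min_identity = 1.5))
})

test_that("fold propensity evaluates the declared pair-weight formula", {
  s <- one_rssp_ssd(subseq = "GGAAACC", db = "((...))")
  # all-GC stem: PS = 1
  m <- find_matches(s, seq_record("t", "GGAAACC"))
  f <- filter_matches(m, seq_record("t", "GGAAACC"), s, tau = 1)
  expect_equal(f$filter_score, 1)
  # all-GU stem: PS = (1+1)/(3*2) = 1/3, removed at tau 0.5
  tgt <- seq_record("t", "GGAAAUU")
  m <- find_matches(s, tgt)
  expect_equal(nrow(m), 1)
  expect_equal(fold_propensity(m, tgt, s), 1 / 3)
  expect_equal(nrow(filter_matches(m, tgt, s, tau = 0.5)), 0)
  expect_equal(nrow(filter_matches(m, tgt, s, tau = 1 / 3)), 1)
})

test_that("filtering is monotone in tau and the identity at tau -> 0+", {
  set.seed(44)
  h <- make_hairpin(4, 4, pair_weights = c(GC = 1, AU = 1, GU = 1))
  s <- ssd(data.frame(start = 1L, length = nchar(h$seq),
                      structure = h$structure, subseq = h$seq,
                      energy = NA_real_), mode = "S1")
  tgt <- seq_record("t", random_rna(300))
  m <- find_matches(s, tgt)
  taus <- c(1e-9, 0.4, 0.6, 0.8, 1)
  sizes <- vapply(taus, function(tau) {
    nrow(filter_matches(m, tgt, s, tau = tau))
  }, 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], nrow(m)) # PS > 0 always, so tiny tau keeps all
  expect_error(filter_matches(m, tgt, s, tau = 0), "tau")
  expect_error(filter_matches(m, tgt, s, tau = 1.2), "tau")
})

test_that("an external propensity engine replaces the built-in score", {
  s <- one_rssp_ssd()
  tgt <- seq_record("t", "GGAAACC")
  m <- find_matches(s, tgt)
  f <- filter_matches(m, tgt, s, tau = 0.5,
                      engine = function(sub, db) 0.75)
  expect_equal(f$filter_score, 0.75)
  f2 <- filter_matches(m, tgt, s, tau = 0.5,
                       engine = function(sub, db) 0.1)
  expect_equal(nrow(f2), 0)
})
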
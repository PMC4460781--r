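test_that("distance is 1 when nothing lies between adjacent NBSs", {
  s <- ssd(rbind(stub_rssp(1L, 10L), stub_rssp(13L, 8L)), mode = "S1")
  expect_equal(distance_d(2, 1, s), 1L)
  expect_equal(distance_d(2, 1, s, method = "exact"), 1L)
  expect_error(distance_d(1, 2, s), "g < f")
  expect_error(distance_d(1, 1, s), "g < f")
})

test_that("in an S1 descriptor the distance collapses to f - g", {
  set.seed(51)
  for (rep in 1:100) {
    s <- random_ssd(sample(3:10, 1), mode = "S1")
    n <- nrow(s$rssps)
    f <- sample(2:n, 1)
    g <- sample(seq_len(f - 1L), 1)
    expect_equal(distance_d(f, g, s), f - g)
    expect_equal(distance_d(f, g, s, method = "exact"), f - g)
  }
})

test_that("mutually overlapping intermediates count once", {
  # s2 and s3 overlap each other, both fit between s1 and s4
  rows <- rbind(stub_rssp(1L, 8L),
                stub_rssp(10L, 8L),
                stub_rssp(14L, 8L),
                stub_rssp(30L, 8L))
  s <- ssd(rows, mode = "Sk")
  expect_equal(distance_d(4, 1, s), 2L)
  expect_equal(distance_d(4, 1, s, method = "exact"), 2L)
})

test_that("the exact distance matches subset enumeration and bounds the greedy one", {
  set.seed(52)
  diverged <- 0L
  for (rep in 1:200) {
    s <- random_ssd(sample(4:9, 1), mode = "Sk")
    n <- nrow(s$rssps)
    f <- sample(3:n, 1)
    g <- sample(seq_len(f - 2L), 1)
    st <- s$rssps$start
    le <- s$rssps$length
    exact <- distance_d(f, g, s, method = "exact")
    greedy <- distance_d(f, g, s, method = "greedy")
    expect_equal(exact, 1L + oracle_max_disjoint_between(f, g, st, le))
    expect_lte(greedy, exact)
    if (greedy != exact) diverged <- diverged + 1L
  }
  expect_lt(diverged / 200, 0.5) # divergence is the exception, not the rule
})

test_that("P and Q evaluate to their stated closed forms", {
  p <- score_params(w_p = 1, w_q = 1, lambda = 1)
  expect_equal(score_P(list(length = 7L), p), 7)
  expect_equal(score_P(list(length = 7L), score_params(w_p = 0)), 0)
  expect_equal(score_P(list(length = 12L), score_params(w_p = 0.5)), 6)

  # two adjacent NBSs, gap_R = 2
  s <- ssd(rbind(stub_rssp(1L, 10L), stub_rssp(13L, 8L)), mode = "S1")
  mi <- list(nbs_index = 1L, target_pos = 1L, length = 10L)
  # gap_T = gap_R = 2, d = 1 -> Q = w_q
  mj <- list(nbs_index = 2L, target_pos = 13L, length = 8L)
  expect_equal(score_Q(mi, mj, s, p), 1)
  # gap_R = 10 vs gap_T = 20 at lambda 1: delta = 0.5
  s2 <- ssd(rbind(stub_rssp(1L, 10L), stub_rssp(21L, 8L)), mode = "S1")
  mj2 <- list(nbs_index = 2L, target_pos = 31L, length = 8L)
  expect_equal(score_Q(mi, mj2, s2, p), exp(-0.5))
  # d = 2 halves Q: insert an intermediate NBS, keep gaps consistent
  s3 <- ssd(rbind(stub_rssp(1L, 10L), stub_rssp(13L, 6L),
                  stub_rssp(21L, 8L)), mode = "S1")
  mj3 <- list(nbs_index = 3L, target_pos = 21L, length = 8L)
  expect_equal(score_Q(mi, mj3, s3, p), 0.5) # gap_T = gap_R = 10, d = 2
  expect_error(score_Q(mj, mi, s, p), "condition \\(i\\)")
  expect_error(score_Q(mi, list(nbs_index = 2L, target_pos = 5L, length = 8L),
                       s, p), "condition \\(ii\\)")
})

test_that("single and forced two-match chains score as P and P1+P2+Q", {
  s <- ssd(rbind(stub_rssp(1L, 10L), stub_rssp(13L, 8L)), mode = "S1")
  p <- score_params()
  one <- data.frame(nbs_index = 1L, target_pos = 4L, length = 10L)
  res <- chain_matches(one, s, p)
  expect_length(res$chains, 1)
  expect_equal(res$chains[[1]]$score, 10)
  expect_equal(res$chains[[1]]$length, 1L)
  expect_equal(q_call_count(res), 0L)

  two <- data.frame(nbs_index = c(1L, 2L), target_pos = c(1L, 13L),
                    length = c(10L, 8L))
  res2 <- chain_matches(two, s, p)
  expect_equal(res2$chains[[1]]$score, 10 + 8 + 1) # delta = 0, d = 1
  expect_equal(res2$chains[[1]]$length, 2L)
  expect_error(chain_matches(two[2:1, ], s, p), "sorted")
})

test_that("DP best score equals exhaustive enumeration on random instances", {
  set.seed(53)
  for (rep in 1:60) {
    mode <- sample(c("S1", "Sk"), 1)
    s <- random_ssd(sample(3:6, 1), mode = mode)
    m <- random_matches(s, sample(2:10, 1))
    p <- score_params(w_p = stats::runif(1, 0.2, 2),
                      w_q = stats::runif(1, 0.2, 2),
                      lambda = stats::runif(1, 0.2, 2))
    res <- chain_matches(m, s, p)
    dp_best <- max(vapply(res$chains, `[[`, 0, "score"))
    expect_identical(dp_best, oracle_best_chain_score(m, s, p))
  }
})

test_that("reported chains satisfy both chain conditions and re-score exactly", {
  set.seed(54)
  for (rep in 1:10) {
    s <- random_ssd(6, mode = "Sk")
    m <- random_matches(s, 12)
    res <- chain_matches(m, s, score_params(top_k = 5))
    for (ch in res$chains) {
      expect_true(validate_chain(ch$matches, s))
      expect_equal(chain_score(ch$matches, s, res$params), ch$score,
                   tolerance = 1e-12)
    }
    sc <- vapply(res$chains, `[[`, 0, "score")
    expect_true(all(diff(sc) <= 0)) # ranked by decreasing score
  }
})

test_that("Q is called once per order-compatible pair", {
  # all-compatible: n disjoint self-matches of an S1 descriptor
  s <- random_ssd(8, mode = "S1")
  m <- data.frame(nbs_index = s$rssps$index, target_pos = s$rssps$start,
                  length = s$rssps$length)
  res <- chain_matches(m, s, score_params())
  expect_equal(q_call_count(res), 8L * 7L / 2L)
  expect_equal(q_call_count(chain_matches(m[1, ], s, score_params())), 0L)
  res4 <- chain_matches(m[1:4, ], s, score_params())
  expect_equal(q_call_count(res4), 6L)
})

test_that("appending a compatible match never lowers the best score", {
  set.seed(55)
  for (rep in 1:20) {
    s <- random_ssd(6, mode = "S1")
    m <- data.frame(nbs_index = s$rssps$index, target_pos = s$rssps$start,
                    length = s$rssps$length)
    k <- sample(2:5, 1)
    sub <- m[1:k, ]
    full <- m[1:(k + 1L), ]
    p <- score_params()
    b1 <- max(vapply(chain_matches(sub, s, p)$chains, `[[`, 0, "score"))
    b2 <- max(vapply(chain_matches(full, s, p)$chains, `[[`, 0, "score"))
    expect_gte(b2, b1)
  }
})

test_that("self-chaining recovers the whole descriptor", {
  set.seed(56)
  for (rep in 1:5) {
    plant <- plant_reference_and_target(k_motifs = sample(3:6, 1),
                                        spacing = 15)
    out <- best_chain(plant$ssd, plant$reference)
    expect_equal(out$length, nrow(plant$ssd$rssps))
  }
})
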
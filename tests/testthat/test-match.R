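be <- function(pos, chrom = "chr1", ori = "+", lo = pos, hi = pos) {
  list(chrom = chrom, pos = pos, lo = lo, hi = hi, ori = ori)
}

test_that("breakend window is inclusive at 200 bp and ambiguity intervals count", {
  cfg <- match_config()
  expect_true(breakend_matches(be(1200), be(1000), cfg))
  expect_false(breakend_matches(be(1201), be(1000), cfg))
  # any position inside the ambiguity interval may satisfy the window
  expect_true(breakend_matches(be(1300, lo = 1150, hi = 1300), be(1000), cfg))
  expect_false(breakend_matches(be(1300, lo = 1201, hi = 1300), be(1000), cfg))
  # contig and orientation requirements
  expect_false(breakend_matches(be(1000, chrom = "chr2"), be(1000), cfg))
  expect_false(breakend_matches(be(1000, ori = "-"), be(1000), cfg))
  expect_true(breakend_matches(be(1000, ori = "-"), be(1000),
                               match_config(orientation_sensitive = FALSE)))
})

test_that("breakend boundary: brute force over offsets locates the cut at +/-200", {
  cfg <- match_config()
  for (off in seq(-250, 250, by = 10)) {
    expect_equal(breakend_matches(be(1000 + off), be(1000), cfg), abs(off) <= 200,
                 info = sprintf("offset %d", off))
  }
})

test_that("size rule: inclusive 25%, and the 400-vs-50 example never matches", {
  t400 <- mk_calls(10000, 400)
  for (den in c("max", "min", "call", "truth")) {
    cfg <- match_config(size_denominator = den)
    c50 <- mk_calls(10000, 50, pos2 = 10050)
    expect_false(breakpoint_matches(c50, t400, cfg), info = den)
  }
  # 300 vs 400 sits exactly on the 25% boundary under the max denominator
  cfg <- match_config()
  expect_true(breakpoint_matches(mk_calls(10000, 300), t400, cfg))
  expect_false(breakpoint_matches(mk_calls(10000, 299), t400, cfg))
  # brute force over candidate sizes: admissible band under max denominator
  for (s in seq(280, 330, by = 1)) {
    ca <- mk_calls(10000, s)
    expect_equal(breakpoint_matches(ca, t400, cfg), abs(400 - s) / max(400, s) <= 0.25,
                 info = sprintf("size %d", s))
  }
  # identical call matches itself
  expect_true(breakpoint_matches(t400, t400, cfg))
})

test_that("BND sizes are ignored unless requested", {
  tr <- mk_calls(10000, 5000, svtype = "BND")
  ca <- mk_calls(10000, 9000, svtype = "BND", pos2 = 19000)
  expect_false(breakpoint_matches(ca, tr, match_config())) # second breakend too far
  ca2 <- mk_calls(10000, 5100, svtype = "BND", pos2 = 15100)
  expect_true(breakpoint_matches(ca2, tr, match_config()))
  # sizes 5100 vs 5000 are within 25% anyway; stress with discordant sizes
  ca3 <- mk_calls(10050, NA_real_, svtype = "BND", pos2 = 15050)
  expect_true(breakpoint_matches(ca3, tr, match_config()))
  expect_false(breakpoint_matches(ca2, mk_calls(10000, 500, svtype = "BND", pos2 = 10500),
                                  match_config()))
})

test_that("indexed matching equals the all-pairs oracle on random instances", {
  for (s in 1:6) {
    calls <- random_callset(60, seed = s, caller_id = "a")
    truth <- random_callset(50, seed = s + 100, caller_id = "t")
    m <- match_callsets(calls, truth)
    expect_equal(as.matrix(m), oracle_match_matrix(calls, truth), info = sprintf("seed %d", s))
    m2 <- match_callsets(calls, truth, method = "allpairs")
    expect_equal(m2$hits, m$hits)
  }
})

test_that("trivial matrices: identity-dominated and all-false", {
  cs <- mk_callset(c(1000, 50000, 90000), c(100, 200, 400))
  m <- match_callsets(cs, cs)
  expect_true(all(diag(as.matrix(m))))
  far <- mk_callset(c(300000, 400000), c(100, 100))
  expect_equal(nrow(match_callsets(cs, far)$hits), 0)
})

test_that("effective truth total collapses mutually matching entries", {
  # two entries 10 bp apart, same size -> one component
  dup <- mk_callset(c(10000, 10010), c(400, 400))
  expect_equal(effective_truth_total(dup), 1)
  # all-distant entries count individually
  far <- mk_callset(c(10000, 20000, 30000), c(400, 400, 400))
  expect_equal(effective_truth_total(far), 3)
  # non-transitive chain a~b, b~c, a!~c is one connected component
  chain <- mk_callset(c(10000, 10150, 10300), c(400, 400, 400))
  m <- as.matrix(match_callsets(chain, chain))
  expect_true(m[1, 2] && m[2, 3] && !m[1, 3])
  expect_equal(effective_truth_total(chain), 1)
})

test_that("precision and recall count calls and truth components respectively", {
  truth <- mk_callset(c(10000, 50000, 90000), c(400, 400, 400), caller_id = "truth")
  calls <- mk_callset(c(10020, 50020, 200000), c(400, 400, 400), caller_id = "c")
  r <- precision_recall(match_callsets(calls, truth), truth)
  expect_equal(r$tp, 2)
  expect_equal(r$fp, 1)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 2 / 3)
  expect_equal(r$f_score, 2 / 3)
  # calls == truth gives perfect scores
  perfect <- precision_recall(match_callsets(truth, truth), truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  # empty truth: recall undefined with warning
  empty <- callset(mk_calls(integer(0), integer(0)), "t")
  expect_warning(r0 <- precision_recall(match_callsets(calls, empty), empty), "empty truth")
  expect_true(is.na(r0$recall))
})

test_that("matching-based evaluation is not commutative", {
  truth <- mk_callset(c(10000, 50000), c(400, 400), caller_id = "truth")
  # two calls both land on the first truth entry; the second entry is missed
  calls <- mk_callset(c(9990, 10010), c(400, 400), caller_id = "c")
  fwd <- precision_recall(match_callsets(calls, truth), truth)
  rev <- precision_recall(match_callsets(truth, calls), calls)
  expect_equal(fwd$precision, 1)
  expect_equal(fwd$recall, 0.5)
  expect_equal(rev$precision, 0.5)
  expect_equal(rev$recall, 1)
  expect_false(isTRUE(all.equal(fwd$precision, rev$precision)))
})

test_that("perturbation stability: within-tolerance shifts keep perfect scores", {
  truth <- mk_callset(seq(10000, 200000, by = 10000), 400, caller_id = "truth")
  set.seed(1)
  df <- truth$calls
  df$pos1 <- df$pos1 + sample(-200:200, nrow(df), replace = TRUE)
  df$pos2 <- df$pos1 + round(df$size * runif(nrow(df), 0.80, 1.20))
  df$size <- df$pos2 - df$pos1
  df$lo1 <- df$pos1; df$hi1 <- df$pos1; df$lo2 <- df$pos2; df$hi2 <- df$pos2
  shifted <- callset(df, "shifted")
  r <- precision_recall(match_callsets(shifted, truth), truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  # exceeding the window at one breakend breaks that match
  df2 <- truth$calls
  df2$pos1[1] <- df2$pos1[1] + 201
  df2$size[1] <- df2$pos2[1] - df2$pos1[1]
  df2$lo1 <- df2$pos1; df2$hi1 <- df2$pos1
  broken <- callset(df2, "broken")
  r2 <- precision_recall(match_callsets(broken, truth), truth)
  expect_equal(r2$fp, 1)
})

test_that("pr_curve points equal precision_recall on each thresholded subset", {
  truth <- random_callset(40, seed = 7, caller_id = "truth")
  calls <- perturb_callset(truth, pos_noise = 100, size_noise = 0.1,
                           fp_rate = 0.3, seed = 8)
  set.seed(9)
  calls$calls$qual <- round(runif(length(calls), 0, 60), 1)
  crv <- pr_curve(calls, truth)
  all_part <- crv[crv$subset == "all", ]
  expect_true(all(diff(all_part$tp) >= 0))
  expect_true(all(diff(all_part$fp) >= 0))
  for (i in seq_len(nrow(all_part))) {
    sub <- subset_calls(calls, calls$calls$qual >= all_part$threshold[i])
    ref <- precision_recall(match_callsets(sub, truth), truth)
    expect_equal(all_part$tp[i], ref$tp)
    expect_equal(all_part$fp[i], ref$fp)
    expect_equal(all_part$precision[i], ref$precision)
    expect_equal(all_part$recall[i], ref$recall)
  }
  # all-equal scores give a single-point curve equal to the overall result
  calls$calls$qual <- rep(5, length(calls))
  crv1 <- pr_curve(calls, truth)
  one <- crv1[crv1$subset == "all", ]
  expect_equal(nrow(one), 1)
  overall <- precision_recall(match_callsets(calls, truth), truth)
  expect_equal(one$precision, overall$precision)
  expect_equal(one$recall, overall$recall)
})
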
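test_that("toy reference is deterministic, has requested N runs and balanced GC", {
  r1 <- make_toy_reference(10000, seed = 1)
  r2 <- make_toy_reference(10000, seed = 1)
  expect_identical(as.character(r1), as.character(r2))
  expect_false(identical(as.character(make_toy_reference(10000, seed = 2)),
                         as.character(r1)))
  rn <- make_toy_reference(1000, seed = 1, n_runs = data.frame(pos = 100, len = 50))
  expect_equal(as.character(Biostrings::subseq(rn[[1]], 100, 149)), strrep("N", 50))
  expect_error(make_toy_reference(1000, seed = 1,
                                  n_runs = data.frame(pos = c(100, 120), len = c(50, 10))),
               "overlapping")
  big <- make_toy_reference(1e6, seed = 3)
  gc <- sum(Biostrings::letterFrequency(big, c("G", "C"))) / 1e6
  expect_lt(abs(gc - 0.5), 0.01)
})

test_that("planned events respect separation, N runs and capacity", {
  ref <- make_toy_reference(100000, seed = 2, n_runs = data.frame(pos = 40000, len = 1000))
  cfg <- sim_config("DEL", size_list = c(100, 200), count_per_size = 5, seed = 3)
  plan <- plan_simple_events(ref, cfg)
  expect_equal(nrow(plan), 10)
  expect_true(all(diff(plan$pos) > 0))
  fstart <- plan$pos + 1
  fend <- plan$pos + plan$size
  expect_true(all(fstart[-1] - fend[-10] - 1 >= 2500))
  # no footprint within 2500 bp of the N run [40000, 40999]
  expect_true(all(fend <= 40000 - 2500 - 1 | fstart >= 40999 + 2500 + 1))
  # events under 50 bp placed but flagged
  p2 <- plan_simple_events(ref, sim_config("DEL", size_list = c(10, 100),
                                           count_per_size = 2, seed = 1))
  expect_equal(sum(p2$ignorable), 2)
  # explicit capacity error reports required vs available
  expect_error(plan_simple_events(make_toy_reference(10000, seed = 1),
                                  sim_config("DEL", size_list = 5000, count_per_size = 10)),
               "required.*available")
  expect_equal(nrow(plan_simple_events(ref, sim_config("DEL", count_per_size = 0))), 0)
})

test_that("apply_events satisfies the length-conservation identities", {
  ref <- make_toy_reference(150000, seed = 4)
  for (ty in c("DEL", "INS", "INV", "DUP")) {
    for (s in 1:2) {
      cfg <- sim_config(ty, size_list = sample(c(64, 128, 256, 1000), 3), count_per_size = 3,
                        seed = s)
      plan <- plan_simple_events(ref, cfg)
      res <- apply_events(ref, plan)
      delta <- switch(ty, DEL = -sum(plan$size), INS = sum(plan$size),
                      DUP = sum(plan$size), INV = 0)
      expect_equal(Biostrings::width(res$alt), 150000 + delta,
                   info = sprintf("%s seed %d", ty, s))
      # truth round trip: matching truth against itself is perfect
      r <- precision_recall(match_callsets(res$truth, res$truth), res$truth)
      expect_equal(r$precision, 1)
      expect_equal(r$recall, 1)
    }
  }
})

test_that("inversion and duplication alt sequences are correct", {
  ref <- make_toy_reference(50000, seed = 5)
  pinv <- plan_simple_events(ref, sim_config("INV", size_list = 1000, count_per_size = 1, seed = 1))
  rinv <- apply_events(ref, pinv)
  p <- pinv$pos[1]
  seg <- Biostrings::subseq(ref[[1]], p + 1, p + 1000)
  expect_equal(as.character(Biostrings::subseq(rinv$alt[[1]], p + 1, p + 1000)),
               as.character(Biostrings::reverseComplement(seg)))
  pdup <- plan_simple_events(ref, sim_config("DUP", size_list = 256, count_per_size = 1, seed = 2))
  rdup <- apply_events(ref, pdup)
  q <- pdup$pos[1]
  dupseg <- as.character(Biostrings::subseq(ref[[1]], q + 1, q + 256))
  expect_equal(as.character(Biostrings::subseq(rdup$alt[[1]], q + 1, q + 512)),
               paste0(dupseg, dupseg))
  # duplication truth breakpoint carries the -/+ orientation pattern,
  # verified by re-parsing the written truth VCF
  f <- tempfile(fileext = ".vcf")
  write_vcf(rdup$truth, f)
  reread <- parse_vcf(f, "truth")
  expect_equal(reread$calls$ori1, "-")
  expect_equal(reread$calls$ori2, "+")
  expect_equal(reread$calls$size, 256)
})

test_that("translocation reassembly: junction truth matches the permutation", {
  ref <- make_toy_reference(60000, seed = 6)
  # n_fragments = 1: no junctions
  t1 <- plan_translocations(ref, sim_config("TRANSLOC", fragment_size = 2500,
                                            n_fragments = 1, seed = 1))
  expect_equal(length(t1$truth), 0)
  expect_equal(Biostrings::width(t1$alt), 2500)
  # small seeded case verified against direct enumeration of the permutation
  t4 <- plan_translocations(ref, sim_config("TRANSLOC", fragment_size = 2500,
                                            n_fragments = 4, seed = 2))
  idx <- t4$fragment_order
  expected_bp <- sum(idx[-1] != idx[-4] + 1)
  expect_equal(length(t4$truth), expected_bp)
  expect_equal(Biostrings::width(t4$alt), 4 * 2500)
  # alt sequence equals concatenation of the sampled fragments
  frags <- vapply(idx, function(i) {
    as.character(Biostrings::subseq(ref[[1]], (i - 1) * 2500 + 1, i * 2500))
  }, character(1))
  expect_equal(as.character(t4$alt[[1]]), paste(frags, collapse = ""))
  expect_error(plan_translocations(ref, sim_config("TRANSLOC", n_fragments = 100)),
               "available")
})

test_that("read pairs hit the coverage target with the requested geometry", {
  ref <- make_toy_reference(1e6, seed = 7)
  rp <- sample_read_pairs(ref, read_len = 100, fragment_len = 300,
                          jitter = 0.1, coverage = 4, seed = 1)
  bases <- sum(Biostrings::width(rp$r1)) + sum(Biostrings::width(rp$r2))
  expect_lt(abs(bases - 4e6) / 4e6, 0.02)
  # jitter 0 gives constant fragment length; mates from fragment ends
  small <- Biostrings::DNAStringSet(paste(rep("ACGT", 500), collapse = ""))
  names(small) <- "m"
  rp0 <- sample_read_pairs(small, read_len = 50, fragment_len = 200, jitter = 0,
                           coverage = 1, seed = 2)
  expect_true(all(Biostrings::width(rp0$r1) == 50))
  # overlapping mates when the fragment is shorter than two reads
  rp_ov <- sample_read_pairs(small, read_len = 100, fragment_len = 150, jitter = 0,
                             coverage = 1, seed = 3)
  s1 <- as.character(rp_ov$r1[[1]])
  s2 <- as.character(Biostrings::reverseComplement(rp_ov$r2[[1]]))
  overlap <- 2 * 100 - 150
  expect_equal(substring(s1, 100 - overlap + 1, 100), substring(s2, 1, overlap))
  # FASTQ output is written and parseable
  pre <- tempfile()
  out <- sample_read_pairs(small, read_len = 50, fragment_len = 200, coverage = 1,
                           seed = 4, out_prefix = pre)
  expect_true(file.exists(out$r1))
  back <- Biostrings::readDNAStringSet(out$r1, format = "fastq")
  expect_equal(length(back), out$n_pairs)
})

test_that("perturb_callset: identity, tolerance-bounded noise, decoy fraction", {
  ref <- make_toy_reference(3e6, seed = 8)
  plan <- plan_simple_events(ref, sim_config("DEL", size_list = c(100, 400, 1000),
                                             count_per_size = 30, seed = 1))
  truth <- apply_events(ref, plan)$truth
  # no noise, no errors: output equals truth
  same <- perturb_callset(truth, seed = 1)
  expect_equal(same$calls[, c("pos1", "pos2", "size")],
               truth$calls[, c("pos1", "pos2", "size")])
  # maximal in-tolerance noise keeps perfect precision and recall
  noisy <- perturb_callset(truth, pos_noise = 200, size_noise = 0.25, seed = 2)
  r <- precision_recall(match_callsets(noisy, truth), truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  # false negatives reduce the call count
  fn <- perturb_callset(truth, fn_rate = 0.5, seed = 3)
  expect_lt(length(fn), length(truth))
  # decoys never match truth and their fraction approximates fp_rate
  fp <- perturb_callset(truth, fp_rate = 0.3, seed = 4)
  r2 <- precision_recall(match_callsets(fp, truth), truth)
  expect_equal(r2$tp, length(truth))
  expect_gt(r2$precision, 0.5)
  expect_lt(r2$precision, 0.9)
})

test_that("simulator outputs are byte-identical under a fixed seed", {
  run <- function() {
    ref <- make_toy_reference(80000, seed = 11)
    plan <- plan_simple_events(ref, sim_config("DUP", size_list = c(100, 300),
                                               count_per_size = 4, seed = 12))
    res <- apply_events(ref, plan)
    fa <- tempfile(fileext = ".fa"); vcf <- tempfile(fileext = ".vcf")
    Biostrings::writeXStringSet(res$alt, fa)
    write_vcf(res$truth, vcf)
    list(fa = readBin(fa, "raw", file.size(fa)), vcf = readLines(vcf))
  }
  a <- run(); b <- run()
  expect_identical(a$fa, b$fa)
  expect_identical(a$vcf, b$vcf)
})
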
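# Fixture builders and an independent brute-force matching oracle.

# Quick intra-chromosomal breakpoint data frame: DEL-like (+/-) unless
# orientations are given.
mk_calls <- function(pos1, size, svtype = "DEL", chrom = "chr1",
                     ori1 = NULL, ori2 = NULL, pos2 = NULL,
                     lo1 = NULL, hi1 = NULL, lo2 = NULL, hi2 = NULL,
                     qual = NA_real_, read_support = NA_real_,
                     filter = "PASS", id = NULL) {
  n <- length(pos1)
  svtype <- rep(svtype, length.out = n)
  if (is.null(pos2)) pos2 <- pos1 + ifelse(svtype == "INS", 0, size)
  df <- data.frame(
    chrom1 = rep(chrom, length.out = n), pos1 = pos1,
    lo1 = if (is.null(lo1)) pos1 else lo1, hi1 = if (is.null(hi1)) pos1 else hi1,
    ori1 = if (is.null(ori1)) rep("+", n) else ori1,
    chrom2 = rep(chrom, length.out = n), pos2 = pos2,
    lo2 = if (is.null(lo2)) pos2 else lo2, hi2 = if (is.null(hi2)) pos2 else hi2,
    ori2 = if (is.null(ori2)) rep("-", n) else ori2,
    svtype = rep(svtype, length.out = n), size = size,
    qual = rep(qual, length.out = n), read_support = rep(read_support, length.out = n),
    filter = rep(filter, length.out = n),
    id = if (is.null(id)) sprintf("c%03d", seq_len(n)) else id,
    stringsAsFactors = FALSE
  )
  df
}

mk_callset <- function(..., caller_id = "test") callset(mk_calls(...), caller_id = caller_id)

# Independent all-pairs matching oracle written in plain arithmetic,
# sharing no code with the package's matching path.
oracle_be <- function(chrom_a, lo_a, hi_a, ori_a, chrom_b, lo_b, hi_b, ori_b,
                      window, orientation_sensitive) {
  if (chrom_a != chrom_b) return(FALSE)
  gap <- max(0, max(lo_a, lo_b) - min(hi_a, hi_b))
  if (gap > window) return(FALSE)
  !orientation_sensitive || ori_a == ori_b
}

oracle_bp <- function(ca, tr, window = 200, tol = 0.25,
                      orientation_sensitive = TRUE) {
  ok1 <- oracle_be(ca$chrom1, ca$lo1, ca$hi1, ca$ori1,
                   tr$chrom1, tr$lo1, tr$hi1, tr$ori1, window, orientation_sensitive)
  ok2 <- oracle_be(ca$chrom2, ca$lo2, ca$hi2, ca$ori2,
                   tr$chrom2, tr$lo2, tr$hi2, tr$ori2, window, orientation_sensitive)
  if (!ok1 || !ok2) return(FALSE)
  if (is.na(ca$size) || is.na(tr$size) || ca$svtype == "BND" || tr$svtype == "BND") return(TRUE)
  den <- max(ca$size, tr$size)
  if (den == 0) return(ca$size == tr$size)
  abs(ca$size - tr$size) / den <= tol
}

oracle_match_matrix <- function(calls, truth, window = 200, tol = 0.25,
                                orientation_sensitive = TRUE) {
  a <- calls$calls; b <- truth$calls
  m <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      ok <- oracle_be(a$chrom1[i], a$lo1[i], a$hi1[i], a$ori1[i],
                      b$chrom1[j], b$lo1[j], b$hi1[j], b$ori1[j],
                      window, orientation_sensitive) &&
        oracle_be(a$chrom2[i], a$lo2[i], a$hi2[i], a$ori2[i],
                  b$chrom2[j], b$lo2[j], b$hi2[j], b$ori2[j],
                  window, orientation_sensitive)
      if (ok && !(is.na(a$size[i]) || is.na(b$size[j]) ||
                  a$svtype[i] == "BND" || b$svtype[j] == "BND")) {
        den <- max(a$size[i], b$size[j])
        ok <- if (den == 0) a$size[i] == b$size[j] else
          abs(a$size[i] - b$size[j]) / den <= tol
      }
      m[i, j] <- ok
    }
  }
  m
}

# Random intra-chromosomal call set for property tests. With scramble_ori
# the orientations are random (exercises orientation matching); without,
# they follow the type conventions so the set survives a VCF round trip.
random_callset <- function(n, seed, caller_id = "rand", span = 1e6,
                           types = c("DEL", "DUP", "INV"), scramble_ori = TRUE) {
  set.seed(seed)
  pos <- sort(sample.int(span, n))
  size <- sample(c(60, 80, 100, 150, 200, 400, 800, 1600), n, replace = TRUE)
  ambw <- sample(0:100, n, replace = TRUE)
  svtype <- sample(types, n, replace = TRUE)
  if (scramble_ori) {
    ori1 <- sample(c("+", "-"), n, replace = TRUE)
    ori2 <- sample(c("+", "-"), n, replace = TRUE)
  } else {
    ori1 <- c(DEL = "+", DUP = "-", INV = "+", INS = "+")[svtype]
    ori2 <- c(DEL = "-", DUP = "+", INV = "+", INS = "-")[svtype]
  }
  df <- mk_calls(pos, size, svtype = svtype, ori1 = unname(ori1), ori2 = unname(ori2),
                 qual = round(runif(n, 0, 100), 1),
                 read_support = sample(1:60, n, replace = TRUE),
                 filter = sample(c("PASS", ".", "LowQual"), n, replace = TRUE))
  df$hi1 <- df$pos1 + ambw
  df$hi2 <- df$pos2 + ambw
  callset(df, caller_id = caller_id)
}

# Independent Clopper-Pearson oracle: invert the binomial tails numerically,
# without beta quantiles.
cp_oracle <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  low <- if (k == 0) 0 else {
    stats::uniroot(function(p) 1 - stats::pbinom(k - 1, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  high <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low, high)
}

# Small mixed-dialect VCF exercising the parser.
write_mixed_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"c\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"m\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t1000\tdel1\tN\t<DEL>\t30\tPASS\tSVTYPE=DEL;END=1400",
    "chr1\t5000\tinv1\tN\t<INV>\t50\tPASS\tSVTYPE=INV;END=7000",
    "chr1\t20000\tins1\tN\t<INS>\t10\tLowQual\tSVTYPE=INS;SVLEN=200;CIPOS=-20,20",
    "chr1\t500\tbndA\tN\tN[chr1:9000[\t25\t.\tSVTYPE=BND;MATEID=bndB",
    "chr1\t9000\tbndB\tN\t]chr1:500]N\t25\t.\tSVTYPE=BND;MATEID=bndA",
    sprintf("chr2\t100\tseqdel\t%s\tN\t.\tPASS\t.", paste0("N", strrep("A", 60)))
  ), path)
  path
}
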
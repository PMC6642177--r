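#' Matching configuration
#'
#' Tolerances for deciding whether a called breakpoint matches a truth
#' breakpoint: each breakend must lie within `window` bp of the true
#' position (any position inside the call's micro-homology/ambiguity
#' interval counts), and the event sizes must differ by at most
#' `size_tolerance` as a fraction of the larger size. All bounds are
#' inclusive. Orientation agreement can be switched off for callers that do
#' not report breakend orientation.
#'
#' @param window maximum breakend distance in bp (default 200).
#' @param size_tolerance maximum relative size difference (default 0.25).
#' @param orientation_sensitive require matching breakend orientations
#'   (default TRUE).
#' @param size_check_for_bnd apply the size test to translocation breakends
#'   when both sides have a defined size (default FALSE: translocations are
#'   matched on position and orientation only).
#' @param size_denominator denominator convention for the relative size
#'   difference: `"max"` (default, symmetric), `"min"`, `"call"` or
#'   `"truth"`.
#' @return a `match_config` list.
#' @export
match_config <- function(window = 200, size_tolerance = 0.25,
                         orientation_sensitive = TRUE,
                         size_check_for_bnd = FALSE,
                         size_denominator = c("max", "min", "call", "truth")) {
  stopifnot(window >= 0, size_tolerance >= 0, size_tolerance < 1)
  structure(list(
    window = window,
    size_tolerance = size_tolerance,
    orientation_sensitive = orientation_sensitive,
    size_check_for_bnd = size_check_for_bnd,
    size_denominator = match.arg(size_denominator)
  ), class = "match_config")
}

# Vectorized breakend comparison on parallel vectors. The distance between
# two breakends is the minimum distance between their ambiguity intervals
# (0 when they overlap).
be_match_vec <- function(chrom_a, lo_a, hi_a, ori_a,
                         chrom_b, lo_b, hi_b, ori_b, cfg) {
  gap <- pmax(0, pmax(lo_a, lo_b) - pmin(hi_a, hi_b))
  ok <- chrom_a == chrom_b & gap <= cfg$window
  if (cfg$orientation_sensitive) ok <- ok & ori_a == ori_b
  ok
}

# Vectorized size comparison; NA sizes (and BND calls unless requested)
# skip the test.
size_match_vec <- function(size_call, size_truth, type_call, type_truth, cfg) {
  skip <- is.na(size_call) | is.na(size_truth)
  if (!cfg$size_check_for_bnd) skip <- skip | type_call == "BND" | type_truth == "BND"
  den <- switch(cfg$size_denominator,
    max = pmax(size_call, size_truth),
    min = pmin(size_call, size_truth),
    call = size_call,
    truth = size_truth
  )
  rel <- ifelse(den > 0, abs(size_call - size_truth) / den,
                ifelse(size_call == size_truth, 0, Inf))
  skip | (!is.na(rel) & rel <= cfg$size_tolerance)
}

bp_match_vec <- function(calls, ci, truth, tj, cfg) {
  be_match_vec(calls$chrom1[ci], calls$lo1[ci], calls$hi1[ci], calls$ori1[ci],
               truth$chrom1[tj], truth$lo1[tj], truth$hi1[tj], truth$ori1[tj], cfg) &
  be_match_vec(calls$chrom2[ci], calls$lo2[ci], calls$hi2[ci], calls$ori2[ci],
               truth$chrom2[tj], truth$lo2[tj], truth$hi2[tj], truth$ori2[tj], cfg) &
  size_match_vec(calls$size[ci], truth$size[tj], calls$svtype[ci], truth$svtype[tj], cfg)
}

#' Does one breakend match a true breakend?
#'
#' TRUE iff both breakends are on the same contig, the minimum distance
#' between their ambiguity intervals is at most `cfg$window` (inclusive),
#' and — when `cfg$orientation_sensitive` — their orientations agree.
#'
#' @param call_be,true_be lists or one-row data frames with fields
#'   `chrom`, `pos`, `lo`, `hi`, `ori` (`lo`/`hi` default to `pos`).
#' @param cfg a [match_config()].
#' @return logical scalar.
#' @export
breakend_matches <- function(call_be, true_be, cfg = match_config()) {
  f <- function(b) {
    b <- as.list(b)
    if (is.null(b$lo)) b$lo <- b$pos
    if (is.null(b$hi)) b$hi <- b$pos
    b
  }
  a <- f(call_be); b <- f(true_be)
  as.logical(be_match_vec(a$chrom, a$lo, a$hi, a$ori, b$chrom, b$lo, b$hi, b$ori, cfg))
}

#' Does one breakpoint call match a truth breakpoint?
#'
#' TRUE iff, after canonical breakend ordering, both the first and the
#' second breakend match under [breakend_matches()] and the relative size
#' difference is at most `cfg$size_tolerance` (inclusive; the size test is
#' skipped when either size is undefined, and for translocation breakends
#' unless `cfg$size_check_for_bnd`). Event types are deliberately not
#' compared: matching is on breakpoints.
#'
#' @param call,truth one-row breakpoint data frames (rows of an
#'   [callset()]'s `calls`).
#' @param cfg a [match_config()].
#' @return logical scalar.
#' @export
breakpoint_matches <- function(call, truth, cfg = match_config()) {
  as.logical(bp_match_vec(call, 1L, truth, 1L, cfg))
}

#' Match every call against every truth entry
#'
#' Builds the call-by-truth boolean match structure. The default indexed
#' implementation generates candidate pairs by an interval-overlap query on
#' the first breakend (call ambiguity intervals expanded by the window) and
#' then applies the full breakpoint predicate; it is exactly equivalent to
#' evaluating all pairs. Matching is many-to-many: no assignment step is
#' performed.
#'
#' @param calls,truth [callset()] objects.
#' @param cfg a [match_config()].
#' @param method `"index"` (default) or `"allpairs"` (direct evaluation of
#'   every pair).
#' @return an `sv_match` object: list with `hits` (data frame of matching
#'   `call`/`truth` row indices, sorted), `n_calls`, `n_truth`, and the
#'   derived per-call (`call_hits`) and per-truth (`truth_hits`) match
#'   counts.
#' @export
match_callsets <- function(calls, truth, cfg = match_config(),
                           method = c("index", "allpairs")) {
  stopifnot(inherits(calls, "sv_callset"), inherits(truth, "sv_callset"))
  method <- match.arg(method)
  cdf <- calls$calls
  tdf <- truth$calls
  nc <- nrow(cdf); nt <- nrow(tdf)
  if (nc == 0 || nt == 0) {
    hits <- data.frame(call = integer(0), truth = integer(0))
  } else if (method == "allpairs") {
    ci <- rep(seq_len(nc), times = nt)
    tj <- rep(seq_len(nt), each = nc)
    ok <- bp_match_vec(cdf, ci, tdf, tj, cfg)
    hits <- data.frame(call = ci[ok], truth = tj[ok])
  } else {
    chroms <- unique(c(cdf$chrom1, tdf$chrom1))
    cgr <- GenomicRanges::GRanges(
      factor(cdf$chrom1, levels = chroms),
      IRanges::IRanges(pmax(1, cdf$lo1 - cfg$window), cdf$hi1 + cfg$window)
    )
    tgr <- GenomicRanges::GRanges(
      factor(tdf$chrom1, levels = chroms),
      IRanges::IRanges(tdf$lo1, tdf$hi1)
    )
    ov <- GenomicRanges::findOverlaps(cgr, tgr)
    ci <- S4Vectors::queryHits(ov)
    tj <- S4Vectors::subjectHits(ov)
    ok <- bp_match_vec(cdf, ci, tdf, tj, cfg)
    hits <- data.frame(call = ci[ok], truth = tj[ok])
  }
  hits <- hits[order(hits$call, hits$truth), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(
    hits = hits, n_calls = nc, n_truth = nt,
    call_hits = tabulate(hits$call, nbins = nc),
    truth_hits = tabulate(hits$truth, nbins = nt)
  ), class = "sv_match")
}

#' @export
print.sv_match <- function(x, ...) {
  cat(sprintf("sv_match: %d calls x %d truth entries, %d matching pair(s)\n",
              x$n_calls, x$n_truth, nrow(x$hits)))
  invisible(x)
}

#' @export
as.matrix.sv_match <- function(x, ...) {
  m <- matrix(FALSE, x$n_calls, x$n_truth)
  if (nrow(x$hits)) m[cbind(x$hits$call, x$hits$truth)] <- TRUE
  m
}

#' Duplicate-collapsed truth components
#'
#' Truth sets can contain near-duplicate entries (e.g. the two haplotypes of
#' a homozygous variant, or merged truth sets). Entries that mutually match
#' under the same matching logic are grouped into connected components of
#' the (non-transitive) overlap graph; the number of components is the
#' effective truth total used as the recall denominator.
#'
#' @param truth an [callset()].
#' @param cfg a [match_config()].
#' @return `truth_components`: integer component membership per truth entry;
#'   `effective_truth_total`: number of components.
#' @export
truth_components <- function(truth, cfg = match_config()) {
  n <- length(truth)
  if (n == 0) return(integer(0))
  m <- match_callsets(truth, truth, cfg)
  edges <- m$hits[m$hits$call != m$hits$truth, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$call, to = edges$truth),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  as.integer(igraph::components(g)$membership)
}

#' @rdname truth_components
#' @export
effective_truth_total <- function(truth, cfg = match_config()) {
  n <- length(truth)
  if (n == 0) return(0L)
  max(truth_components(truth, cfg))
}

#' Precision, recall and F-score from a match structure
#'
#' A call is a true positive if it matches at least one truth entry, a false
#' positive otherwise; precision = TP / (TP + FP). Recall is the fraction of
#' duplicate-collapsed truth components containing at least one matched
#' entry, over the effective truth total. Because calls are counted on one
#' side and truth components on the other, this definition is not
#' commutative: swapping the roles of calls and truth can change the result.
#'
#' @param matrix an `sv_match` from [match_callsets()] built against `truth`.
#' @param truth the truth [callset()] used to build `matrix`.
#' @param cfg the [match_config()] used (needed for duplicate collapsing).
#' @return a `bench_result` list: `tp`, `fp`, `effective_truth_total`,
#'   `precision`, `recall`, `f_score`.
#' @export
precision_recall <- function(matrix, truth, cfg = match_config()) {
  stopifnot(inherits(matrix, "sv_match"), length(truth) == matrix$n_truth)
  tp <- sum(matrix$call_hits > 0)
  fp <- matrix$n_calls - tp
  memb <- truth_components(truth, cfg)
  ncomp <- if (length(memb)) max(memb) else 0L
  if (ncomp == 0) {
    warning("precision_recall: empty truth set; recall undefined")
    recall <- NA_real_
  } else {
    covered <- unique(memb[matrix$truth_hits > 0])
    recall <- length(covered) / ncomp
  }
  precision <- if (matrix$n_calls > 0) tp / matrix$n_calls else 0
  f <- if (is.na(recall) || precision + recall == 0) {
    if (is.na(recall)) NA_real_ else 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(
    tp = tp, fp = fp, effective_truth_total = ncomp,
    precision = precision, recall = recall, f_score = f
  ), class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cat(sprintf("bench_result: TP=%g FP=%g truth=%d precision=%.4f recall=%s F=%s\n",
              x$tp, x$fp, x$effective_truth_total, x$precision,
              ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)),
              ifelse(is.na(x$f_score), "NA", sprintf("%.4f", x$f_score))))
  invisible(x)
}

#' Convenience wrapper: match and score in one step
#' @inheritParams precision_recall
#' @param calls the call [callset()].
#' @param truth the truth [callset()].
#' @param cfg a [match_config()].
#' @return a `bench_result`.
#' @export
benchmark_calls <- function(calls, truth, cfg = match_config()) {
  precision_recall(match_callsets(calls, truth, cfg), truth, cfg)
}

#' Precision-recall curve over a quality threshold
#'
#' Ranks calls by the caller-reported quality score, or by supporting read
#' count when quality is not reported, and computes cumulative TP/FP and
#' precision/recall at every distinct score threshold (calls with score >=
#' threshold included). Missing scores rank lowest. The curve is computed
#' both for all calls and for the PASS-only subset.
#'
#' @param calls,truth [callset()] objects.
#' @param cfg a [match_config()].
#' @param score_key `"quality"` or `"read_support"`.
#' @return data frame with columns `subset` ("all"/"pass"), `threshold`,
#'   `tp`, `fp`, `precision`, `recall`.
#' @export
pr_curve <- function(calls, truth, cfg = match_config(),
                     score_key = c("quality", "read_support")) {
  score_key <- match.arg(score_key)
  one_curve <- function(cs, label) {
    n <- length(cs)
    memb <- truth_components(truth, cfg)
    ncomp <- if (length(memb)) max(memb) else 0L
    if (n == 0) {
      return(data.frame(subset = character(0), threshold = numeric(0),
                        tp = integer(0), fp = integer(0),
                        precision = numeric(0), recall = numeric(0)))
    }
    score <- if (score_key == "quality") cs$calls$qual else cs$calls$read_support
    score[is.na(score)] <- -Inf
    m <- match_callsets(cs, truth, cfg)
    matched <- m$call_hits > 0
    # best score of a call covering each truth component
    comp_best <- rep(-Inf, ncomp)
    if (nrow(m$hits)) {
      comp_of_hit <- memb[m$hits$truth]
      score_of_hit <- score[m$hits$call]
      agg <- tapply(score_of_hit, comp_of_hit, max)
      comp_best[as.integer(names(agg))] <- agg
    }
    thresholds <- sort(unique(score), decreasing = TRUE)
    tp <- vapply(thresholds, function(t) sum(matched & score >= t), integer(1))
    fp <- vapply(thresholds, function(t) sum(!matched & score >= t), integer(1))
    rec <- if (ncomp > 0) {
      vapply(thresholds, function(t) sum(comp_best >= t) / ncomp, numeric(1))
    } else rep(NA_real_, length(thresholds))
    data.frame(subset = label, threshold = thresholds, tp = tp, fp = fp,
               precision = ifelse(tp + fp > 0, tp / (tp + fp), 0),
               recall = rec)
  }
  rbind(one_curve(calls, "all"), one_curve(pass_subset(calls), "pass"))
}
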
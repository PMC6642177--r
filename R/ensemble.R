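#' Caller-agreement matrix
#'
#' Compares every caller's call set to the truth set and to every other
#' caller with the breakpoint-matching logic, giving a call overlap
#' structure from which m-of-n ensembles are evaluated. The caller-caller
#' overlap relation is used symmetrically (call A of caller i overlaps
#' caller j if it matches any call of j in either matching direction);
#' because matching tolerates errors, overlaps are symmetric but not
#' necessarily transitive. Truth matching keeps its non-commutative,
#' call-versus-truth direction.
#'
#' @param callsets list of [callset()] objects with distinct `caller_id`s.
#' @param truth the truth [callset()].
#' @param cfg a [match_config()].
#' @return an `sv_agreement` object: list with `callers` (ids), `calls`
#'   (per-caller data frames), `overlap` (per-caller logical matrix, calls x
#'   callers: does this call overlap that caller), `truth_match` (per-caller
#'   logical vector), `truth_hits_by_caller` (per-caller list of matched
#'   truth indices per call), `truth`, `cfg`.
#' @export
agreement_matrix <- function(callsets, truth, cfg = match_config()) {
  stopifnot(length(callsets) >= 1)
  ids <- vapply(callsets, function(cs) cs$caller_id, character(1))
  if (anyDuplicated(ids)) stop("agreement_matrix: duplicate caller_ids")
  k <- length(callsets)
  n_i <- vapply(callsets, length, integer(1))
  overlap <- lapply(seq_len(k), function(i) {
    m <- matrix(FALSE, n_i[i], k, dimnames = list(NULL, ids))
    m[, i] <- TRUE # a call trivially overlaps its own caller
    m
  })
  truth_match <- vector("list", k)
  truth_hits <- vector("list", k)
  for (i in seq_len(k)) {
    m <- match_callsets(callsets[[i]], truth, cfg)
    truth_match[[i]] <- m$call_hits > 0
    truth_hits[[i]] <- m$hits
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m <- match_callsets(callsets[[i]], callsets[[j]], cfg)
      rev_m <- match_callsets(callsets[[j]], callsets[[i]], cfg)
      # symmetrized overlap: either matching direction counts for both sides
      i_hits <- union(m$hits$call, rev_m$hits$truth)
      j_hits <- union(m$hits$truth, rev_m$hits$call)
      overlap[[i]][i_hits, j] <- TRUE
      overlap[[j]][j_hits, i] <- TRUE
    }
  }
  structure(list(
    callers = ids,
    calls = lapply(callsets, function(cs) cs$calls),
    overlap = overlap,
    truth_match = truth_match,
    truth_hits = truth_hits,
    truth = truth,
    cfg = cfg
  ), class = "sv_agreement")
}

#' @export
print.sv_agreement <- function(x, ...) {
  cat(sprintf("sv_agreement: %d callers vs %d truth entries\n",
              length(x$callers), length(x$truth)))
  invisible(x)
}

#' Evaluate one m-of-n ensemble rule
#'
#' From the calls of the `members` callers, removes every call that does
#' not overlap at least `min_support` ensemble callers (a call counts its
#' own caller, so `min_support = 1` is the union and `min_support = m`
#' requires all members). Surviving calls are counted as true or false
#' positives by their truth overlap and the totals divided by `m`, the
#' ensemble size — the deduplication-free correction for calls shared by
#' several members. Recall uses unique truth-component coverage by any
#' surviving call.
#'
#' @param matrix an `sv_agreement` from [agreement_matrix()].
#' @param members character vector of ensemble caller ids (the n callers).
#' @param min_support minimum number of agreeing member callers
#'   (1 <= min_support <= m).
#' @return a `bench_result` with fractional `tp`/`fp` (divided totals).
#' @export
evaluate_ensemble <- function(matrix, members, min_support = 1) {
  stopifnot(inherits(matrix, "sv_agreement"))
  idx <- match(members, matrix$callers)
  if (anyNA(idx)) stop("evaluate_ensemble: unknown caller id(s): ",
                       paste(members[is.na(idx)], collapse = ", "))
  m <- length(idx)
  if (min_support > m || min_support < 1) stop("evaluate_ensemble: need 1 <= min_support <= m")
  tp_total <- 0
  fp_total <- 0
  memb <- truth_components(matrix$truth, matrix$cfg)
  ncomp <- if (length(memb)) max(memb) else 0L
  covered <- logical(ncomp)
  for (i in idx) {
    support <- rowSums(matrix$overlap[[i]][, idx, drop = FALSE])
    survive <- support >= min_support
    tm <- matrix$truth_match[[i]]
    tp_total <- tp_total + sum(survive & tm)
    fp_total <- fp_total + sum(survive & !tm)
    h <- matrix$truth_hits[[i]]
    h <- h[survive[h$call], , drop = FALSE]
    if (nrow(h)) covered[unique(memb[h$truth])] <- TRUE
  }
  tp <- tp_total / m
  fp <- fp_total / m
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (ncomp > 0) sum(covered) / ncomp else NA_real_
  f <- if (is.na(recall) || precision + recall == 0) {
    if (is.na(recall)) NA_real_ else 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(
    tp = tp, fp = fp, effective_truth_total = ncomp,
    precision = precision, recall = recall, f_score = f
  ), class = "bench_result")
}

#' Enumerate all m-of-n ensemble rules
#'
#' Evaluates every non-empty caller subset with every support threshold
#' `n = 1..m`, for all calls and for the PASS-only subsets, producing one
#' table row per (subset, n, filter) combination in deterministic order.
#'
#' @param callsets list of [callset()] objects (at most 12 callers).
#' @param truth the truth [callset()].
#' @param cfg a [match_config()].
#' @return data frame with columns `subset` (comma-joined member ids),
#'   `m`, `n`, `filter` ("all"/"pass"), `tp`, `fp`, `precision`, `recall`,
#'   `f_score`.
#' @export
enumerate_ensembles <- function(callsets, truth, cfg = match_config()) {
  k <- length(callsets)
  if (k > 12) stop("enumerate_ensembles: more than 12 callers gives 2^k subsets; subset the callers first")
  ids <- vapply(callsets, function(cs) cs$caller_id, character(1))
  mats <- list(
    all = agreement_matrix(callsets, truth, cfg),
    pass = agreement_matrix(lapply(callsets, pass_subset), truth, cfg)
  )
  rows <- list()
  for (bits in seq_len(2^k - 1)) {
    members <- ids[bitwAnd(bits, 2^(seq_len(k) - 1)) > 0]
    m <- length(members)
    for (n in seq_len(m)) {
      for (flt in c("all", "pass")) {
        r <- evaluate_ensemble(mats[[flt]], members, n)
        rows[[length(rows) + 1]] <- data.frame(
          subset = paste(members, collapse = ","), m = m, n = n, filter = flt,
          tp = r$tp, fp = r$fp, precision = r$precision,
          recall = r$recall, f_score = r$f_score,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$m, out$subset, out$n, out$filter), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
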
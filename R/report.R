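#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact (beta-quantile) interval for a binomial proportion:
#' `low = qbeta(alpha/2, k, n - k + 1)`, `high = qbeta(1 - alpha/2, k + 1,
#' n - k)`, with `low = 0` when `k = 0` and `high = 1` when `k = n`. The
#' interval is conservative: its coverage is at least the nominal level.
#'
#' @param k number of successes (0 <= k <= n); vectorized.
#' @param n number of trials (n >= 1).
#' @param conf confidence level (default 0.95).
#' @return two-column matrix with columns `low` and `high`.
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (any(n < 1)) stop("clopper_pearson: n must be >= 1")
  stopifnot(all(k >= 0), all(k <= n), conf > 0, conf < 1)
  alpha <- 1 - conf
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  cbind(low = pmin(pmax(low, 0), 1), high = pmin(pmax(high, 0), 1))
}

#' Precision by quality-score bin
#'
#' Separates the calls into `n_bins` equal-width bins over the observed
#' range of the chosen score — the caller-reported quality, or log10 of the
#' supporting read count — and computes per-bin precision with an exact
#' 95% binomial confidence interval. Bins with 10 or fewer calls are
#' flagged as low support (their point estimates are unstable). Calls
#' lacking the score (or with read count < 1 for the log key) are excluded
#' with a message.
#'
#' @param cs an [callset()].
#' @param matrix an `sv_match` of `cs` against the truth set.
#' @param key `"quality"` or `"log_read_count"`.
#' @param n_bins number of bins (default 100).
#' @param conf confidence level for the interval (default 0.95).
#' @param low_support_max maximum bin size flagged as low support
#'   (default 10).
#' @return data frame with one row per non-empty bin: `bin`, `score_lo`,
#'   `score_hi`, `n_calls`, `n_true`, `precision`, `ci_low`, `ci_high`,
#'   `low_support`.
#' @export
quality_bins <- function(cs, matrix, key = c("quality", "log_read_count"),
                         n_bins = 100, conf = 0.95, low_support_max = 10) {
  stopifnot(inherits(cs, "sv_callset"), inherits(matrix, "sv_match"),
            length(cs) == matrix$n_calls)
  key <- match.arg(key)
  matched <- matrix$call_hits > 0
  if (key == "quality") {
    score <- cs$calls$qual
    usable <- !is.na(score)
  } else {
    rc <- cs$calls$read_support
    usable <- !is.na(rc) & rc >= 1
    score <- ifelse(usable, log10(pmax(rc, 1)), NA_real_)
  }
  n_excluded <- sum(!usable)
  if (n_excluded > 0) {
    message(sprintf("quality_bins: %d call(s) without usable %s excluded", n_excluded, key))
  }
  score <- score[usable]
  matched <- matched[usable]
  if (!length(score)) {
    return(data.frame(bin = integer(0), score_lo = numeric(0), score_hi = numeric(0),
                      n_calls = integer(0), n_true = integer(0), precision = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0), low_support = logical(0)))
  }
  rng <- range(score)
  if (rng[1] == rng[2]) {
    warning("quality_bins: all scores identical; single bin")
    bin <- rep(1L, length(score))
    edges <- c(rng[1], rng[2])
    n_bins <- 1L
  } else {
    width <- (rng[2] - rng[1]) / n_bins
    # ties exactly at a bin edge fall in the lower bin
    bin <- pmin(pmax(ceiling((score - rng[1]) / width), 1L), n_bins)
    edges <- rng[1] + width * (0:n_bins)
  }
  counts <- tabulate(bin, nbins = n_bins)
  keep <- which(counts > 0)
  n_true <- vapply(keep, function(b) sum(matched[bin == b]), integer(1))
  n_calls <- counts[keep]
  ci <- clopper_pearson(n_true, n_calls, conf)
  data.frame(
    bin = keep, score_lo = edges[keep], score_hi = edges[keep + 1],
    n_calls = n_calls, n_true = n_true,
    precision = n_true / n_calls,
    ci_low = ci[, "low"], ci_high = ci[, "high"],
    low_support = n_calls <= low_support_max
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write a benchmark report
#'
#' Writes deterministic TSV tables for a set of benchmarked callers: a
#' per-caller summary (all calls and PASS-only), precision-recall curves,
#' quality bins, and optionally an ensemble table and per-stratum counts.
#' With `plots = TRUE` (and ggplot2 available) renders precision versus
#' true-positive count and binned-precision figures as PNG.
#'
#' @param callsets list of [callset()] objects.
#' @param truth the truth [callset()].
#' @param cfg a [match_config()].
#' @param outdir output directory (created if needed).
#' @param score_key score used for curves/bins: `"quality"` or
#'   `"read_support"`.
#' @param ensemble_table optional data frame from [enumerate_ensembles()].
#' @param plots render PNG figures (default FALSE).
#' @return named character vector of the files written, invisibly.
#' @export
bench_report <- function(callsets, truth, cfg = match_config(), outdir,
                         score_key = c("quality", "read_support"),
                         ensemble_table = NULL, plots = FALSE) {
  score_key <- match.arg(score_key)
  if (is.null(truth) || !inherits(truth, "sv_callset")) {
    stop("bench_report: a truth call set is required")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  summary_rows <- list()
  percall_rows <- list()
  curve_rows <- list()
  bin_rows <- list()
  for (cs in callsets) {
    for (flt in c("all", "pass")) {
      sub <- if (flt == "pass") pass_subset(cs) else cs
      m <- match_callsets(sub, truth, cfg)
      r <- suppressWarnings(precision_recall(m, truth, cfg))
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        caller = cs$caller_id, filter = flt, n_calls = length(sub),
        tp = r$tp, fp = r$fp, effective_truth_total = r$effective_truth_total,
        precision = r$precision, recall = r$recall, f_score = r$f_score,
        stringsAsFactors = FALSE
      )
      if (flt == "all" && length(sub)) {
        percall_rows[[length(percall_rows) + 1]] <- data.frame(
          caller = cs$caller_id,
          locus = sprintf("%s:%d-%s:%d", sub$calls$chrom1, sub$calls$pos1,
                          sub$calls$chrom2, sub$calls$pos2),
          type = sub$calls$svtype, size = sub$calls$size,
          score = if (score_key == "quality") sub$calls$qual else sub$calls$read_support,
          matched = m$call_hits > 0, n_truth_hits = m$call_hits,
          stringsAsFactors = FALSE
        )
      }
    }
    crv <- suppressWarnings(pr_curve(cs, truth, cfg, score_key))
    if (nrow(crv)) curve_rows[[length(curve_rows) + 1]] <- cbind(caller = cs$caller_id, crv)
    mall <- match_callsets(cs, truth, cfg)
    qb <- suppressWarnings(suppressMessages(quality_bins(
      cs, mall, key = if (score_key == "quality") "quality" else "log_read_count")))
    if (nrow(qb)) bin_rows[[length(bin_rows) + 1]] <- cbind(caller = cs$caller_id, qb)
  }
  files["summary"] <- write_tsv(do.call(rbind, summary_rows), file.path(outdir, "summary.tsv"))
  files["per_call"] <- write_tsv(
    if (length(percall_rows)) do.call(rbind, percall_rows) else
      data.frame(caller = character(0), locus = character(0), type = character(0),
                 size = numeric(0), score = numeric(0), matched = logical(0),
                 n_truth_hits = integer(0)),
    file.path(outdir, "per_call.tsv"))
  files["pr_curve"] <- write_tsv(
    if (length(curve_rows)) do.call(rbind, curve_rows) else
      data.frame(caller = character(0), subset = character(0), threshold = numeric(0),
                 tp = integer(0), fp = integer(0), precision = numeric(0), recall = numeric(0)),
    file.path(outdir, "pr_curve.tsv"))
  files["quality_bins"] <- write_tsv(
    if (length(bin_rows)) do.call(rbind, bin_rows) else
      data.frame(caller = character(0), bin = integer(0), score_lo = numeric(0),
                 score_hi = numeric(0), n_calls = integer(0), n_true = integer(0),
                 precision = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
                 low_support = logical(0)),
    file.path(outdir, "quality_bins.tsv"))
  if (!is.null(ensemble_table)) {
    files["ensemble"] <- write_tsv(ensemble_table, file.path(outdir, "ensemble.tsv"))
  }

  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    smry <- do.call(rbind, summary_rows)
    g1 <- ggplot2::ggplot(smry, ggplot2::aes(x = tp, y = precision,
                                             colour = caller, shape = filter)) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = "true positives", y = "precision") +
      ggplot2::ylim(0, 1) + ggplot2::theme_bw()
    f1 <- file.path(outdir, "precision_vs_tp.png")
    ggplot2::ggsave(f1, g1, width = 6, height = 4, dpi = 100)
    files["plot_precision"] <- f1
    if (length(bin_rows)) {
      bins <- do.call(rbind, bin_rows)
      g2 <- ggplot2::ggplot(bins, ggplot2::aes(x = (score_lo + score_hi) / 2, y = precision)) +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high), colour = "grey60") +
        ggplot2::geom_point(ggplot2::aes(colour = low_support)) +
        ggplot2::facet_wrap(~caller) +
        ggplot2::labs(x = "score bin midpoint", y = "precision") +
        ggplot2::theme_bw()
      f2 <- file.path(outdir, "quality_bins.png")
      ggplot2::ggsave(f2, g2, width = 6, height = 4, dpi = 100)
      files["plot_bins"] <- f2
    }
  }

  manifest <- list(
    package = "svbench",
    version = as.character(utils::packageVersion("svbench")),
    callers = vapply(callsets, function(cs) cs$caller_id, character(1)),
    n_truth = length(truth),
    config = unclass(cfg),
    score_key = score_key
  )
  fm <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, fm, auto_unbox = TRUE, pretty = TRUE)
  files["manifest"] <- fm
  invisible(files)
}
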
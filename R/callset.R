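#' @title Breakpoint call sets
#'
#' @description
#' An `sv_callset` holds the breakpoint calls of one caller as a data frame,
#' one row per breakpoint (an ordered pair of breakends). Each breakend
#' carries a contig, a 1-based nominal position, an orientation (`"+"` =
#' retained reference sequence extends leftward of the position, `"-"` = it
#' extends rightward) and a closed ambiguity interval `[lo, hi]` containing
#' the nominal position, representing micro-homology or imprecise calling.
#'
#' Columns of the underlying data frame:
#' `chrom1, pos1, lo1, hi1, ori1, chrom2, pos2, lo2, hi2, ori2, svtype,
#' size, qual, read_support, filter, pass, id`.
#' `svtype` is one of `DEL`, `INS`, `DUP`, `INV`, `BND`. `size` is
#' `|pos2 - pos1|` for intra-chromosomal non-insertion events, the inserted
#' sequence length for insertions, and `NA` for breakends/translocations.
#' `pass` is `TRUE` iff the source VCF FILTER was `"PASS"` or `"."`.
#'
#' @param calls data frame with the columns listed above (missing optional
#'   columns are filled with defaults).
#' @param caller_id single string identifying the caller.
#' @param reference_name single string naming the reference the calls are on.
#' @return An object of class `sv_callset`: a list with elements `calls`
#'   (data frame, canonically ordered), `caller_id` and `reference_name`.
#' @export
callset <- function(calls, caller_id = "caller", reference_name = "unknown") {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  n <- nrow(calls)
  defaults <- list(
    lo1 = calls$pos1, hi1 = calls$pos1,
    lo2 = calls$pos2, hi2 = calls$pos2,
    ori1 = rep("+", n), ori2 = rep("-", n),
    size = rep(NA_real_, n), qual = rep(NA_real_, n),
    read_support = rep(NA_integer_, n),
    filter = rep("PASS", n),
    id = if (n) sprintf("%s_%d", caller_id, seq_len(n)) else character(0)
  )
  for (nm in names(defaults)) {
    if (is.null(calls[[nm]])) calls[[nm]] <- defaults[[nm]]
  }
  if (is.null(calls$pass)) calls$pass <- is.na(calls$filter) | calls$filter %in% c(".", "PASS")
  required <- c("chrom1", "pos1", "chrom2", "pos2", "svtype")
  missing <- setdiff(required, names(calls))
  if (length(missing)) stop("callset: missing columns: ", paste(missing, collapse = ", "))
  for (nm in c("pos1", "lo1", "hi1", "pos2", "lo2", "hi2")) calls[[nm]] <- as.integer(calls[[nm]])
  for (nm in c("size", "qual", "read_support")) calls[[nm]] <- as.numeric(calls[[nm]])
  for (nm in c("chrom1", "chrom2", "ori1", "ori2", "svtype", "filter", "id")) {
    calls[[nm]] <- as.character(calls[[nm]])
  }
  calls <- canonicalize_calls(calls)
  structure(
    list(calls = calls, caller_id = caller_id, reference_name = reference_name),
    class = "sv_callset"
  )
}

#' Canonically order breakends and rows
#'
#' Ensures breakend 1 precedes breakend 2 (by contig, then position), checks
#' ambiguity-interval invariants, and sorts rows by contig, positions and
#' type so that a call set has a deterministic order regardless of input
#' order.
#' @param calls breakpoint data frame (see [callset()]).
#' @return the reordered data frame.
#' @keywords internal
canonicalize_calls <- function(calls) {
  if (nrow(calls)) {
    swap <- (calls$chrom1 > calls$chrom2) |
      (calls$chrom1 == calls$chrom2 & calls$pos1 > calls$pos2)
    swap[is.na(swap)] <- FALSE
    if (any(swap)) {
      b1 <- c("chrom1", "pos1", "lo1", "hi1", "ori1")
      b2 <- c("chrom2", "pos2", "lo2", "hi2", "ori2")
      tmp <- calls[swap, b1]
      calls[swap, b1] <- calls[swap, b2]
      calls[swap, b2] <- tmp
    }
    bad <- calls$lo1 > calls$pos1 | calls$hi1 < calls$pos1 |
      calls$lo2 > calls$pos2 | calls$hi2 < calls$pos2 | calls$lo1 < 1 | calls$lo2 < 1
    if (any(bad)) stop("callset: ambiguity interval must satisfy 1 <= lo <= pos <= hi")
    ord <- order(calls$chrom1, calls$pos1, calls$chrom2, calls$pos2, calls$svtype, calls$id,
                 method = "radix")
    calls <- calls[ord, , drop = FALSE]
    rownames(calls) <- NULL
  }
  calls
}

#' @export
print.sv_callset <- function(x, ...) {
  cat(sprintf("sv_callset: %d breakpoint call(s) from '%s' on '%s'\n",
              nrow(x$calls), x$caller_id, x$reference_name))
  if (nrow(x$calls)) {
    tab <- table(x$calls$svtype)
    cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    cat(sprintf("  PASS: %d / %d\n", sum(x$calls$pass), nrow(x$calls)))
  }
  invisible(x)
}

#' @export
length.sv_callset <- function(x) nrow(x$calls)

#' @export
as.data.frame.sv_callset <- function(x, ...) x$calls

#' Subset a call set by row index or logical mask
#' @param cs an `sv_callset`.
#' @param keep logical mask or integer indices into the calls.
#' @return a new `sv_callset` with the selected calls.
#' @export
subset_calls <- function(cs, keep) {
  stopifnot(inherits(cs, "sv_callset"))
  out <- cs
  out$calls <- cs$calls[keep, , drop = FALSE]
  rownames(out$calls) <- NULL
  out
}

#' PASS-only subset of a call set
#'
#' Keeps the calls whose VCF FILTER field was `"PASS"` or `"."` — the
#' caller's own high-confidence output. The input is unchanged.
#'
#' @param cs an `sv_callset`.
#' @return an `sv_callset` with only passing calls.
#' @export
pass_subset <- function(cs) {
  stopifnot(inherits(cs, "sv_callset"))
  subset_calls(cs, cs$calls$pass)
}

#' Baseline size and inter-chromosomal filters
#'
#' Removes calls with a defined event size below `min_size` (the
#' conventional lower bound separating structural variants from indels) and,
#' optionally, calls whose two breakends lie on different contigs. Calls
#' with undefined size (translocation breakends) are retained by the size
#' rule. A 50 bp event is retained: the filter excludes events strictly
#' under `min_size`.
#'
#' @param cs an `sv_callset`.
#' @param min_size minimum retained event size in bp (default 50).
#' @param exclude_interchromosomal drop inter-chromosomal calls (default TRUE).
#' @return the filtered `sv_callset`. Idempotent.
#' @export
apply_baseline_filters <- function(cs, min_size = 50, exclude_interchromosomal = TRUE) {
  stopifnot(inherits(cs, "sv_callset"))
  calls <- cs$calls
  drop <- !is.na(calls$size) & calls$size < min_size
  if (exclude_interchromosomal) drop <- drop | calls$chrom1 != calls$chrom2
  subset_calls(cs, !drop)
}
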
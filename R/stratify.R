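#' Read a BED interval file as GRanges
#'
#' BED input is 0-based half-open; the returned [GenomicRanges::GRanges] is
#' 1-based inclusive. The optional 4th column (used for RepeatMasker class
#' labels) is kept as `name`.
#'
#' @param path BED file path.
#' @return a [GenomicRanges::GRanges].
#' @export
read_bed <- function(path) {
  tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) stop("read_bed: malformed BED file '", path, "': ", conditionMessage(e))
  )
}

# GRanges of the nominal breakend positions of a call set: two rows per
# call (breakend 1 then breakend 2), width 1.
breakend_granges <- function(cs) {
  calls <- cs$calls
  chroms <- unique(c(calls$chrom1, calls$chrom2))
  GenomicRanges::GRanges(
    factor(c(calls$chrom1, calls$chrom2), levels = chroms),
    IRanges::IRanges(c(calls$pos1, calls$pos2), width = 1)
  )
}

#' Repeat-class annotation of breakends
#'
#' Assigns each breakend exactly one context class from its nominal
#' position (ambiguity intervals are not used for this lookup):
#' * breakends in a RepeatMasker `Simple_repeat` region, or in a tandem-
#'   repeats-finder (TRF) region without any RepeatMasker overlap, are
#'   `Simple/Tandem`;
#' * otherwise the RepeatMasker top-level class when overlapped, with every
#'   class other than `DNA`, `LINE`, `SINE`, `LTR`, `Low_complexity`
#'   collapsed into `Other`;
#' * `None` when no annotation overlaps.
#' When several RepeatMasker intervals overlap one breakend, precedence is
#' `Simple_repeat`, then `Low_complexity`, then the named classes, then
#' `Other`.
#'
#' @param cs an [callset()].
#' @param repeatmasker [GenomicRanges::GRanges] (or BED path) with the
#'   RepeatMasker class in `name`.
#' @param trf [GenomicRanges::GRanges] (or BED path) of TRF regions.
#' @return `cs` with columns `repeat_class1`/`repeat_class2` added to
#'   `cs$calls`.
#' @export
annotate_repeat_class <- function(cs, repeatmasker, trf) {
  stopifnot(inherits(cs, "sv_callset"))
  if (is.character(repeatmasker)) repeatmasker <- read_bed(repeatmasker)
  if (is.character(trf)) trf <- read_bed(trf)
  n <- length(cs)
  if (n == 0) {
    cs$calls$repeat_class1 <- character(0)
    cs$calls$repeat_class2 <- character(0)
    return(cs)
  }
  gr <- breakend_granges(cs)
  named <- c("DNA", "LINE", "SINE", "LTR", "Low_complexity")
  precedence <- c("Simple_repeat", "Low_complexity", setdiff(named, "Low_complexity"), "Other")
  rm_class <- rep(NA_character_, length(gr))
  GenomeInfoDb::seqlevels(repeatmasker) <- union(GenomeInfoDb::seqlevels(repeatmasker),
                                                GenomeInfoDb::seqlevels(gr))
  GenomeInfoDb::seqlevels(trf) <- union(GenomeInfoDb::seqlevels(trf),
                                        GenomeInfoDb::seqlevels(gr))
  ov <- GenomicRanges::findOverlaps(gr, repeatmasker)
  if (length(ov)) {
    cls <- as.character(repeatmasker$name[S4Vectors::subjectHits(ov)])
    cls[!cls %in% c(named, "Simple_repeat")] <- "Other"
    rank <- match(cls, precedence)
    best <- tapply(seq_along(rank), S4Vectors::queryHits(ov), function(i) i[which.min(rank[i])])
    rm_class[as.integer(names(best))] <- cls[unlist(best)]
  }
  in_trf <- GenomicRanges::countOverlaps(gr, trf) > 0
  final <- ifelse(!is.na(rm_class) & rm_class == "Simple_repeat", "Simple/Tandem",
           ifelse(is.na(rm_class) & in_trf, "Simple/Tandem",
           ifelse(is.na(rm_class), "None", rm_class)))
  cs$calls$repeat_class1 <- final[seq_len(n)]
  cs$calls$repeat_class2 <- final[n + seq_len(n)]
  cs
}

#' Count small variants near SV breakpoints
#'
#' For each call, counts the SNV/indel records whose position lies within
#' `window` bp of the nominal position of either breakend (inclusive;
#' counted once per breakend, so a variant close to both breakends of a
#' short event contributes twice). Micro-homology/ambiguity intervals are
#' deliberately ignored for this annotation.
#'
#' @param cs an [callset()].
#' @param small_vcf path to an (unfiltered) SNV/indel VCF, or a data frame
#'   with columns `chrom` and `pos`.
#' @param window proximity window in bp (default 50).
#' @return `cs` with column `n_nearby_small` added to `cs$calls`.
#' @export
count_nearby_small_variants <- function(cs, small_vcf, window = 50) {
  stopifnot(inherits(cs, "sv_callset"))
  if (is.character(small_vcf)) {
    v <- vcfR::read.vcfR(small_vcf, verbose = FALSE)
    small <- data.frame(chrom = v@fix[, "CHROM"],
                        pos = as.integer(v@fix[, "POS"]),
                        stringsAsFactors = FALSE)
  } else {
    small <- as.data.frame(small_vcf)
  }
  calls <- cs$calls
  count_be <- function(chrom, pos) {
    out <- integer(length(pos))
    for (ch in unique(chrom)) {
      sp <- sort(small$pos[small$chrom == ch])
      sel <- chrom == ch
      if (length(sp)) {
        out[sel] <- findInterval(pos[sel] + window, sp) -
          findInterval(pos[sel] - window - 1, sp)
      }
    }
    out
  }
  cs$calls$n_nearby_small <- count_be(calls$chrom1, calls$pos1) +
    count_be(calls$chrom2, calls$pos2)
  cs
}

#' Exclude calls near blacklisted intervals
#'
#' Removes calls with either breakend within `margin` bp of any blacklist
#' interval (inclusive; a breakend inside an interval is at distance 0).
#'
#' @param cs an [callset()].
#' @param blacklist [GenomicRanges::GRanges] or BED path.
#' @param margin exclusion margin in bp (default 200).
#' @return the filtered [callset()]. Idempotent.
#' @export
filter_blacklist <- function(cs, blacklist, margin = 200) {
  stopifnot(inherits(cs, "sv_callset"))
  if (is.character(blacklist)) blacklist <- read_bed(blacklist)
  n <- length(cs)
  if (n == 0 || length(blacklist) == 0) return(cs)
  gr <- breakend_granges(cs)
  GenomeInfoDb::seqlevels(blacklist) <- union(GenomeInfoDb::seqlevels(blacklist),
                                              GenomeInfoDb::seqlevels(gr))
  expanded <- GenomicRanges::resize(blacklist,
                                    GenomicRanges::width(blacklist) + 2 * margin,
                                    fix = "center")
  hit <- GenomicRanges::countOverlaps(gr, expanded) > 0
  subset_calls(cs, !(hit[seq_len(n)] | hit[n + seq_len(n)]))
}

#' Restrict calls to high-confidence regions
#'
#' Keeps only the calls whose breakends BOTH fall inside the given region
#' set (nominal positions).
#'
#' @param cs an [callset()].
#' @param highconf [GenomicRanges::GRanges] or BED path of high-confidence
#'   regions.
#' @return the filtered [callset()]. Idempotent.
#' @export
filter_regions <- function(cs, highconf) {
  stopifnot(inherits(cs, "sv_callset"))
  if (is.character(highconf)) highconf <- read_bed(highconf)
  n <- length(cs)
  if (n == 0) return(cs)
  gr <- breakend_granges(cs)
  GenomeInfoDb::seqlevels(highconf) <- union(GenomeInfoDb::seqlevels(highconf),
                                             GenomeInfoDb::seqlevels(gr))
  inside <- GenomicRanges::countOverlaps(gr, highconf) > 0
  subset_calls(cs, inside[seq_len(n)] & inside[n + seq_len(n)])
}

#' Event length used for size stratification
#'
#' True positives are stratified by the length of the matched truth variant;
#' false positives by the length the caller reported (a caller that
#' mis-reports lengths would otherwise appear artificially accurate).
#'
#' @param call one-row breakpoint data frame (a row of `cs$calls`).
#' @param matched_truth matching truth row, or `NULL` for a false positive.
#' @return length in bp, or `NA` when undefined (translocation breakends).
#' @export
stratum_length <- function(call, matched_truth = NULL) {
  if (!is.null(matched_truth) && nrow(as.data.frame(matched_truth)) > 0) {
    as.numeric(matched_truth$size[1])
  } else {
    as.numeric(call$size[1])
  }
}

#' Per-call size strata for a matched call set
#'
#' Vectorized companion of [stratum_length()]: each matched call gets the
#' size of (one of) its matched truth entries (the first by match order);
#' unmatched calls keep their reported size.
#'
#' @param calls the call [callset()].
#' @param truth the truth [callset()].
#' @param matrix an `sv_match` from [match_callsets()].
#' @return numeric vector of stratum lengths (NA when undefined).
#' @export
stratum_lengths <- function(calls, truth, matrix) {
  out <- calls$calls$size
  if (nrow(matrix$hits)) {
    first <- matrix$hits[!duplicated(matrix$hits$call), , drop = FALSE]
    out[first$call] <- truth$calls$size[first$truth]
  }
  out
}
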
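#' @importFrom Biostrings DNAString DNAStringSet writeXStringSet readDNAStringSet
#'   reverseComplement BStringSet letterFrequency vmatchPattern
NULL

# Evaluate code under a given seed without disturbing the caller's RNG
# stream; seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Event-size ladder used by the simulator
#'
#' The 36 simulated event sizes, from 1 bp to 65,536 bp: dense coverage of
#' the indel/small-SV boundary, then a geometric tail.
#' @return integer vector of 36 sizes (bp).
#' @export
sv_size_ladder <- function() {
  as.integer(c(1:10, 12, 16, 20, 24, 28, 32,
               48, 64, 80, 96, 112, 128,
               160, 192, 224, 256, 288, 320,
               512, 1024, 2048, 4096, 8192, 16384, 32768, 65536))
}

#' Simulation configuration
#'
#' Defaults reproduce the study conditions: 500 events of each of the 36
#' ladder sizes (18,000 events per dataset), at least 2500 bp separation
#' between events and from ambiguous (N) reference bases, and translocation
#' datasets built from 10,000 reassembled 2500 bp fragments. Each dataset
#' contains heterozygous events of a single type.
#'
#' @param event_type one of `"DEL"`, `"INS"`, `"INV"`, `"DUP"`, `"TRANSLOC"`.
#' @param size_list event sizes in bp (default [sv_size_ladder()]).
#' @param count_per_size events per size (default 500).
#' @param min_separation minimum gap between event footprints and from N
#'   runs, in bp (default 2500).
#' @param fragment_size translocation fragment size in bp (default 2500).
#' @param n_fragments number of reassembled fragments (default 10000).
#' @param zygosity `"het"` or `"hom"` (default het: reads are sampled 50/50
#'   from the reference and rearranged haplotypes).
#' @param seed integer seed for all randomness in planning.
#' @return a `sim_config` list.
#' @export
sim_config <- function(event_type = c("DEL", "INS", "INV", "DUP", "TRANSLOC"),
                       size_list = sv_size_ladder(), count_per_size = 500,
                       min_separation = 2500, fragment_size = 2500,
                       n_fragments = 10000, zygosity = c("het", "hom"),
                       seed = 1) {
  event_type <- match.arg(event_type)
  stopifnot(all(size_list > 0), count_per_size >= 0, min_separation >= 0,
            fragment_size >= 1, n_fragments >= 1)
  structure(list(
    event_type = event_type, size_list = as.integer(size_list),
    count_per_size = as.integer(count_per_size),
    min_separation = as.integer(min_separation),
    fragment_size = as.integer(fragment_size),
    n_fragments = as.integer(n_fragments),
    zygosity = match.arg(zygosity), seed = seed
  ), class = "sim_config")
}

#' Generate a random toy reference sequence
#'
#' Uniform random A/C/G/T sequence (GC fraction 0.5 in expectation) with
#' optional runs of ambiguous N bases, as a stand-in for a real chromosome.
#'
#' @param length sequence length in bp.
#' @param seed integer seed; the same seed and arguments give a
#'   byte-identical sequence.
#' @param n_runs optional two-column matrix or data frame (`pos`, `len`) of
#'   N runs (1-based start positions); runs must not overlap.
#' @param contig contig name (default `"chrSim"`).
#' @return a length-1 named [Biostrings::DNAStringSet].
#' @export
make_toy_reference <- function(length, seed = 1, n_runs = NULL, contig = "chrSim") {
  stopifnot(length >= 1)
  s <- with_seed(seed, {
    bases <- charToRaw("ACGT")
    rawToChar(bases[sample.int(4L, length, replace = TRUE)])
  })
  if (!is.null(n_runs)) {
    n_runs <- as.data.frame(n_runs)
    colnames(n_runs)[1:2] <- c("pos", "len")
    ir <- IRanges::IRanges(n_runs$pos, width = n_runs$len)
    if (length(IRanges::reduce(ir)) < nrow(n_runs)) stop("make_toy_reference: overlapping N runs")
    if (any(IRanges::end(ir) > length) || any(n_runs$pos < 1)) {
      stop("make_toy_reference: N run outside sequence")
    }
    for (i in seq_len(nrow(n_runs))) {
      substr(s, n_runs$pos[i], n_runs$pos[i] + n_runs$len[i] - 1) <-
        strrep("N", n_runs$len[i])
    }
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- contig
  out
}

# N runs of the single-contig reference, as an IRanges.
n_run_ranges <- function(ref) {
  hits <- Biostrings::vmatchPattern("N", ref)[[1]]
  IRanges::reduce(IRanges::IRanges(S4Vectors::start(hits), S4Vectors::end(hits)))
}

#' Plan the placement of simple SV events on a reference
#'
#' Places `count_per_size` events of every size in the ladder at random
#' positions along the (single-contig) reference, left to right, such that
#' every pair of event footprints is separated by at least `min_separation`
#' bp and no footprint lies within `min_separation` bp of an ambiguous (N)
#' base. Sizes are assigned to loci at random (seeded). Events smaller than
#' 50 bp are placed but flagged `ignorable`, reflecting the convention that
#' sub-50 bp events are not counted as structural variants.
#'
#' @param ref a length-1 [Biostrings::DNAStringSet] (or a bare integer
#'   length for an N-free reference).
#' @param cfg a [sim_config()].
#' @return a `sim_plan`: data frame with columns `pos` (1-based anchor base;
#'   the event footprint starts at `pos + 1`), `event_type`, `size`,
#'   `inserted_seq` (INS only) and `ignorable`, with attributes
#'   `ref_length`, `contig`, `min_separation` and `seed`. Positions are
#'   strictly increasing.
#' @export
plan_simple_events <- function(ref, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$event_type == "TRANSLOC") stop("use plan_translocations() for translocation datasets")
  if (is.numeric(ref)) {
    ref_length <- as.integer(ref)
    contig <- "chrSim"
    nr <- IRanges::IRanges()
  } else {
    stopifnot(length(ref) == 1)
    ref_length <- Biostrings::width(ref)[1]
    contig <- names(ref) %||% "chrSim"
    nr <- n_run_ranges(ref)
  }
  sep <- cfg$min_separation
  sizes <- rep(cfg$size_list, each = cfg$count_per_size)
  n <- length(sizes)
  plan <- with_seed(cfg$seed, {
    sizes <- sizes[sample.int(n)]
    footprint <- if (cfg$event_type == "INS") rep(1L, n) else sizes
    # allowed segments: complement of N runs padded by the separation
    blocked <- IRanges::reduce(IRanges::IRanges(
      pmax(1L, S4Vectors::start(nr) - sep), S4Vectors::end(nr) + sep))
    gaps <- IRanges::setdiff(IRanges::IRanges(2L, ref_length), blocked)
    seg_start <- S4Vectors::start(gaps)
    seg_end <- S4Vectors::end(gaps)
    usable <- sum(pmax(0, seg_end - seg_start + 1))
    needed <- sum(footprint) + n * sep
    if (n > 0 && needed > usable) {
      stop(sprintf(paste0("plan_simple_events: insufficient reference capacity: ",
                          "%d bp required (footprints + separation) but only %d bp available"),
                   needed, usable))
    }
    slack <- usable - needed
    extras <- if (n > 0) floor(diff(c(0, sort(stats::runif(n)))) * slack * 0.95) else numeric(0)
    starts <- integer(n)
    seg <- 1L
    cursor <- if (length(seg_start)) seg_start[1] else NA_integer_
    seg_backup <- seg
    cursor_backup <- cursor
    for (i in seq_len(n)) {
      placed <- FALSE
      extra <- extras[i]
      while (!placed) {
        if (seg > length(seg_start)) {
          if (extra > 0) { # retry without the random slack before giving up
            extra <- 0
            seg <- seg_backup; cursor <- cursor_backup
            next
          }
          stop("plan_simple_events: ran out of reference capacity during placement")
        }
        start <- cursor + extra
        if (start + footprint[i] - 1 <= seg_end[seg]) {
          starts[i] <- start
          cursor <- start + footprint[i] + sep
          placed <- TRUE
        } else if (extra > 0) {
          extra <- 0 # drop the slack rather than overflow the segment
        } else {
          seg <- seg + 1L
          if (seg <= length(seg_start)) cursor <- seg_start[seg]
        }
      }
      seg_backup <- seg; cursor_backup <- cursor
    }
    ins_seq <- rep(NA_character_, n)
    if (cfg$event_type == "INS") {
      bases <- c("A", "C", "G", "T")
      ins_seq <- vapply(sizes, function(s)
        paste(bases[sample.int(4L, s, replace = TRUE)], collapse = ""), character(1))
    }
    data.frame(pos = starts - 1L, event_type = rep(cfg$event_type, n), size = sizes,
               inserted_seq = ins_seq, ignorable = sizes < 50,
               stringsAsFactors = FALSE)
  })
  plan <- plan[order(plan$pos), , drop = FALSE]
  rownames(plan) <- NULL
  attr(plan, "ref_length") <- ref_length
  attr(plan, "contig") <- contig
  attr(plan, "min_separation") <- sep
  attr(plan, "seed") <- cfg$seed
  class(plan) <- c("sim_plan", "data.frame")
  validate_sim_plan(plan, nr)
  plan
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hard checks of the placement invariants; run on every emitted plan.
validate_sim_plan <- function(plan, n_runs = IRanges::IRanges()) {
  if (!nrow(plan)) return(invisible(TRUE))
  sep <- attr(plan, "min_separation")
  fstart <- plan$pos + 1L
  fend <- plan$pos + ifelse(plan$event_type == "INS", 1L, plan$size)
  if (any(diff(plan$pos) <= 0)) stop("sim_plan: positions not strictly increasing")
  if (any(fstart[-1] - fend[-nrow(plan)] - 1 < sep)) stop("sim_plan: separation violated")
  if (any(fend > attr(plan, "ref_length"))) stop("sim_plan: event outside reference")
  if (length(n_runs)) {
    ev <- IRanges::IRanges(pmax(1L, fstart - sep), fend + sep)
    if (any(IRanges::countOverlaps(ev, n_runs) > 0)) stop("sim_plan: event too close to an N run")
  }
  invisible(TRUE)
}

# Truth breakpoints of a plan, in the conventions used by the VCF parser.
plan_truth_calls <- function(plan, contig) {
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan$pos[i]; s <- plan$size[i]; ty <- plan$event_type[i]
    base <- sprintf("sim%05d", i)
    mk <- function(p1, o1, p2, o2, id) {
      data.frame(chrom1 = contig, pos1 = p1, lo1 = p1, hi1 = p1, ori1 = o1,
                 chrom2 = contig, pos2 = p2, lo2 = p2, hi2 = p2, ori2 = o2,
                 svtype = ty, size = s, qual = NA_real_,
                 read_support = NA_integer_, filter = "PASS", pass = TRUE,
                 id = id, stringsAsFactors = FALSE)
    }
    switch(ty,
      DEL = mk(p, "+", p + s, "-", base),
      INS = mk(p, "+", p, "-", base),
      DUP = mk(p, "-", p + s, "+", base),
      INV = rbind(mk(p, "+", p + s, "+", paste0(base, "_bp1")),
                  mk(p + 1, "-", p + s + 1, "-", paste0(base, "_bp2")))
    )
  })
  do.call(rbind, rows)
}

#' Apply a simulation plan to the reference
#'
#' Realises every planned event on the reference sequence: deletions remove
#' the footprint, insertions insert the planned sequence, inversions
#' reverse-complement the footprint, tandem duplications append a second
#' copy. Returns the rearranged haplotype together with the truth call set
#' in reference coordinates (an inversion contributes its two breakpoints).
#' Length conservation holds: `len(alt) = len(ref) - sum(DEL) + sum(INS) +
#' sum(DUP)`.
#'
#' @param ref a length-1 [Biostrings::DNAStringSet].
#' @param plan a `sim_plan` from [plan_simple_events()].
#' @return list with `alt` (rearranged [Biostrings::DNAStringSet]) and
#'   `truth` (an [callset()] with `caller_id = "truth"`).
#' @export
apply_events <- function(ref, plan) {
  stopifnot(length(ref) == 1, inherits(plan, "sim_plan"))
  contig <- attr(plan, "contig")
  L <- Biostrings::width(ref)[1]
  fend <- plan$pos + ifelse(plan$event_type == "INS", 0L, plan$size)
  if (nrow(plan) && any(fend > L)) stop("apply_events: event footprint outside reference")
  s <- as.character(ref[[1]])
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(plan))) {
    p <- plan$pos[i]; sz <- plan$size[i]; ty <- plan$event_type[i]
    pieces <- c(pieces, substr(s, cursor, p))
    seg <- substr(s, p + 1L, p + sz)
    pieces <- c(pieces, switch(ty,
      DEL = "",
      INS = plan$inserted_seq[i],
      INV = as.character(Biostrings::reverseComplement(Biostrings::DNAString(seg))),
      DUP = paste0(seg, seg)
    ))
    cursor <- p + ifelse(ty == "INS", 0L, sz) + 1L
  }
  pieces <- c(pieces, substr(s, cursor, L))
  alt <- Biostrings::DNAStringSet(paste(pieces, collapse = ""))
  names(alt) <- paste0(contig, "_alt")
  truth_df <- if (nrow(plan)) plan_truth_calls(plan, contig) else empty_calls_df()
  truth <- callset(truth_df, caller_id = "truth", reference_name = contig)
  truth$reference_length <- L
  list(alt = alt, truth = truth)
}

#' Simulate intra-chromosomal translocations by fragment reassembly
#'
#' Partitions the reference into consecutive `fragment_size` bp windows,
#' samples `n_fragments` of them without replacement and concatenates them
#' in seeded random order (original orientation). Every junction between
#' fragments that were not adjacent in the reference becomes a truth
#' breakpoint (BND), with breakends at the end of the left fragment and the
#' start of the right fragment in reference coordinates.
#'
#' @param ref a length-1 [Biostrings::DNAStringSet].
#' @param cfg a [sim_config()] (uses `fragment_size`, `n_fragments`, `seed`).
#' @return list with `alt` (reassembled haplotype of length
#'   `n_fragments * fragment_size`), `truth` (an [callset()]) and
#'   `fragment_order` (sampled fragment indices).
#' @export
plan_translocations <- function(ref, cfg) {
  stopifnot(length(ref) == 1, inherits(cfg, "sim_config"))
  L <- Biostrings::width(ref)[1]
  contig <- names(ref) %||% "chrSim"
  fs <- cfg$fragment_size
  n_avail <- L %/% fs
  if (cfg$n_fragments > n_avail) {
    stop(sprintf("plan_translocations: %d fragments requested but only %d of %d bp available",
                 cfg$n_fragments, n_avail, fs))
  }
  idx <- with_seed(cfg$seed, sample.int(n_avail, cfg$n_fragments))
  starts <- (idx - 1L) * fs + 1L
  s <- as.character(ref[[1]])
  alt <- Biostrings::DNAStringSet(paste(substring(s, starts, starts + fs - 1L), collapse = ""))
  names(alt) <- paste0(contig, "_alt")
  junction <- which(idx[-1] != idx[-length(idx)] + 1L)
  truth_df <- if (length(junction)) {
    left_end <- idx[junction] * fs
    right_start <- (idx[junction + 1L] - 1L) * fs + 1L
    do.call(rbind, lapply(seq_along(junction), function(k) {
      data.frame(chrom1 = contig, pos1 = left_end[k], lo1 = left_end[k],
                 hi1 = left_end[k], ori1 = "+",
                 chrom2 = contig, pos2 = right_start[k], lo2 = right_start[k],
                 hi2 = right_start[k], ori2 = "-",
                 svtype = "BND", size = abs(right_start[k] - left_end[k]), qual = NA_real_,
                 read_support = NA_integer_, filter = "PASS", pass = TRUE,
                 id = sprintf("tloc%05d", k), stringsAsFactors = FALSE)
    }))
  } else empty_calls_df()
  truth <- callset(truth_df, caller_id = "truth", reference_name = contig)
  truth$reference_length <- L
  list(alt = alt, truth = truth, fragment_order = idx)
}

#' Sample error-free paired-end reads from haplotypes
#'
#' Draws fragments uniformly along the given haplotypes (one chosen
#' uniformly per fragment, so passing the reference and the rearranged
#' haplotype gives 50/50 heterozygous sampling), with fragment length
#' uniform in `fragment_len * (1 - jitter)` to `fragment_len * (1 + jitter)`.
#' Each fragment yields its two ends in FR orientation; reads longer than
#' the fragment are truncated (overlapping mates are allowed). Reads carry
#' no sequencing errors and constant base quality.
#'
#' @param haplotypes a [Biostrings::DNAStringSet] of one or more haplotypes.
#' @param read_len read length in bp.
#' @param fragment_len mean fragment length in bp.
#' @param jitter fractional fragment-length jitter (default 0.1).
#' @param coverage target fold coverage of the mean haplotype length.
#' @param seed integer seed.
#' @param out_prefix if non-NULL, write `<prefix>_R1.fastq.gz` and
#'   `<prefix>_R2.fastq.gz` and return the paths; otherwise return the reads
#'   in memory.
#' @return list with `r1`, `r2` ([Biostrings::DNAStringSet] or file paths)
#'   and `n_pairs`.
#' @export
sample_read_pairs <- function(haplotypes, read_len, fragment_len, jitter = 0.1,
                              coverage = 4, seed = 1, out_prefix = NULL) {
  stopifnot(length(haplotypes) >= 1, fragment_len >= 1, read_len >= 1)
  lens <- Biostrings::width(haplotypes)
  mean_len <- mean(lens)
  n_pairs <- max(1L, as.integer(round(coverage * mean_len / (2 * read_len))))
  flo <- max(1L, as.integer(ceiling(fragment_len * (1 - jitter))))
  fhi <- as.integer(floor(fragment_len * (1 + jitter)))
  if (read_len > fhi) warning("sample_read_pairs: read length exceeds maximum fragment length; reads truncated")
  res <- with_seed(seed, {
    hap <- sample.int(length(haplotypes), n_pairs, replace = TRUE)
    flen <- if (fhi > flo) sample(flo:fhi, n_pairs, replace = TRUE) else rep(flo, n_pairs)
    flen <- pmin(flen, lens[hap])
    start <- floor(stats::runif(n_pairs) * (lens[hap] - flen + 1)) + 1L
    list(hap = hap, flen = flen, start = start)
  })
  rl <- pmin(read_len, res$flen)
  frag_of <- function(h) as.character(haplotypes[[h]])
  seqs <- as.character(haplotypes)
  r1 <- Biostrings::DNAStringSet(substring(seqs[res$hap], res$start, res$start + rl - 1L))
  r2 <- Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(seqs[res$hap], res$start + res$flen - rl, res$start + res$flen - 1L)))
  ids <- sprintf("frag%08d", seq_len(n_pairs))
  names(r1) <- ids
  names(r2) <- ids
  if (is.null(out_prefix)) return(list(r1 = r1, r2 = r2, n_pairs = n_pairs))
  q1 <- Biostrings::BStringSet(strrep("I", Biostrings::width(r1)))
  q2 <- Biostrings::BStringSet(strrep("I", Biostrings::width(r2)))
  p1 <- paste0(out_prefix, "_R1.fastq.gz")
  p2 <- paste0(out_prefix, "_R2.fastq.gz")
  Biostrings::writeXStringSet(r1, p1, format = "fastq", compress = TRUE, qualities = q1)
  Biostrings::writeXStringSet(r2, p2, format = "fastq", compress = TRUE, qualities = q2)
  list(r1 = p1, r2 = p2, n_pairs = n_pairs)
}

#' Generate a pseudo-caller call set by perturbing a truth set
#'
#' Fixture generator for exercising the matcher with known ground truth.
#' Each truth call is dropped with probability `fn_rate`; surviving calls
#' have both breakends offset by at most `pos_noise` bp and the event size
#' rescaled within `size_noise` (relative to the larger of the two sizes),
#' the offsets and size change drawn jointly so all three matching bounds
#' are respected. Decoy (false-positive) calls are added at loci at least
#' `decoy_min_dist` bp from every truth breakend, in numbers such that the
#' decoy fraction of the output is `fp_rate` in expectation.
#'
#' @param truth a truth [callset()].
#' @param pos_noise maximum breakend offset in bp.
#' @param size_noise maximum relative size change (fraction).
#' @param fp_rate expected decoy fraction of the emitted call set, in [0,1).
#' @param fn_rate probability of dropping each truth call, in [0,1].
#' @param seed integer seed.
#' @param caller_id caller label of the output (default "pseudo").
#' @param ref_length contig length used to place decoys (default: the truth
#'   set's `reference_length` if present, else beyond the last breakend).
#' @param decoy_min_dist minimum distance of decoy breakends from truth
#'   breakends (default `2 * 200 + pos_noise`, out of matching range).
#' @return an [callset()].
#' @export
perturb_callset <- function(truth, pos_noise = 0, size_noise = 0, fp_rate = 0,
                            fn_rate = 0, seed = 1, caller_id = "pseudo",
                            ref_length = NULL,
                            decoy_min_dist = 2 * 200 + pos_noise) {
  stopifnot(inherits(truth, "sv_callset"),
            fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate <= 1)
  tdf <- truth$calls
  if (is.null(ref_length)) {
    ref_length <- truth$reference_length %||%
      (max(c(1, tdf$pos1, tdf$pos2), na.rm = TRUE) + 1e6)
  }
  out <- with_seed(seed, {
    keep <- stats::runif(nrow(tdf)) >= fn_rate
    kept <- tdf[keep, , drop = FALSE]
    k <- nrow(kept)
    if (k > 0 && (pos_noise > 0 || size_noise > 0)) {
      rint <- function(lo, hi) {
        lo <- floor(lo); hi <- floor(hi)
        lo + floor(stats::runif(length(lo)) * (hi - lo + 1))
      }
      o1 <- rint(rep(-pos_noise, k), rep(pos_noise, k))
      sz <- kept$size
      is_ins <- kept$svtype == "INS"
      span <- !is_ins & !is.na(sz) & kept$chrom1 == kept$chrom2
      # size delta bounded jointly by the size tolerance (max denominator)
      # and, for spanning events, by the second breakend's offset budget
      dlo <- ifelse(is.na(sz), 0, -floor(size_noise * sz))
      dhi <- ifelse(is.na(sz), 0,
                    floor(size_noise * sz / max(1e-12, 1 - size_noise)))
      dhi <- ifelse(is.na(sz), 0, pmax(dlo, dhi))
      d <- rint(pmax(dlo, ifelse(span, -pos_noise - o1, dlo)),
                pmin(dhi, ifelse(span, pos_noise - o1, dhi)))
      kept$pos1 <- kept$pos1 + o1
      kept$pos2 <- ifelse(span, kept$pos1 + sz + d,
                          ifelse(is_ins, kept$pos2 + o1, kept$pos2 + rint(rep(-pos_noise, k), rep(pos_noise, k))))
      kept$size <- ifelse(is.na(sz), sz, ifelse(span, kept$pos2 - kept$pos1, sz + d))
      kept$pos1 <- pmax(1, kept$pos1)
      kept$pos2 <- pmax(1, kept$pos2)
      kept$lo1 <- kept$pos1; kept$hi1 <- kept$pos1
      kept$lo2 <- kept$pos2; kept$hi2 <- kept$pos2
    }
    n_decoy <- if (fp_rate > 0 && k > 0) stats::rnbinom(1, size = k, prob = 1 - fp_rate) else 0L
    decoys <- NULL
    if (n_decoy > 0) {
      truth_pos <- sort(c(tdf$pos1, tdf$pos2))
      far_enough <- function(p) {
        i <- findInterval(p, truth_pos)
        lo_ok <- i == 0 | abs(p - truth_pos[pmax(1, i)]) > decoy_min_dist
        hi_ok <- i >= length(truth_pos) | abs(truth_pos[pmin(length(truth_pos), i + 1)] - p) > decoy_min_dist
        lo_ok & hi_ok
      }
      rows <- list()
      got <- 0L
      while (got < n_decoy) {
        need <- n_decoy - got
        tmpl <- tdf[sample.int(nrow(tdf), need, replace = TRUE), , drop = FALSE]
        span_t <- ifelse(is.na(tmpl$size) | tmpl$svtype %in% c("INS", "BND"),
                         0, tmpl$size)
        p1 <- floor(stats::runif(need) * pmax(1, ref_length - span_t - 1)) + 1
        p2 <- p1 + span_t
        ok <- far_enough(p1) & far_enough(p2)
        if (any(ok)) {
          tmpl <- tmpl[ok, , drop = FALSE]
          tmpl$pos1 <- p1[ok]; tmpl$pos2 <- p2[ok]
          tmpl$lo1 <- tmpl$pos1; tmpl$hi1 <- tmpl$pos1
          tmpl$lo2 <- tmpl$pos2; tmpl$hi2 <- tmpl$pos2
          rows[[length(rows) + 1]] <- tmpl
          got <- got + nrow(tmpl)
        }
      }
      decoys <- do.call(rbind, rows)
      decoys$id <- sprintf("decoy%05d", seq_len(nrow(decoys)))
    }
    out <- rbind(kept, decoys)
    if (nrow(out)) out$id <- make.unique(out$id, sep = "_")
    out
  })
  res <- callset(out, caller_id = caller_id, reference_name = truth$reference_name)
  res$reference_length <- ref_length
  res
}
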
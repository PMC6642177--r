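#' @importFrom vcfR read.vcfR getFIX
NULL

# Pull a single INFO key out of raw INFO strings (vectorized).
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

info_num <- function(info, key) suppressWarnings(as.numeric(info_field(info, key)))

# VCF 4.2 BND bracket semantics: returns NULL or a list with mate contig,
# position, local and mate orientations. "+" means the retained sequence
# extends leftward of the breakend position.
parse_bnd_alt <- function(alt) {
  m <- regexec("^([A-Za-z.*]*)([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])([A-Za-z.*]*)$",
               alt, perl = TRUE)
  g <- regmatches(alt, m)[[1]]
  if (!length(g)) return(NULL)
  seq_first <- nzchar(g[2])
  bracket <- g[3]
  if (bracket != g[6]) return(NULL)
  list(
    mate_chrom = g[4],
    mate_pos = as.integer(g[5]),
    local_ori = if (seq_first) "+" else "-",
    mate_ori = if (bracket == "[") "-" else "+"
  )
}

# Ambiguity interval for one breakend: CIPOS-style offsets plus optional
# homology length (micro-homology extends the interval rightward of pos).
ambiguity_interval <- function(pos, ci, homlen) {
  lo <- pos
  hi <- pos
  if (!is.na(ci) && nzchar(ci)) {
    off <- suppressWarnings(as.numeric(strsplit(ci, ",", fixed = TRUE)[[1]]))
    if (length(off) == 2 && !anyNA(off)) {
      lo <- pos + off[1]
      hi <- pos + off[2]
    }
  }
  if (!is.na(homlen) && homlen > 0) hi <- max(hi, pos + homlen)
  c(max(1, min(lo, pos)), max(hi, pos))
}

#' Read a VCF call set and convert records to breakpoint calls
#'
#' Converts every structural variant record of a VCF v4.x file (plain or
#' gzipped) into breakpoint calls. Symbolic `<DEL>`, `<INS>`, `<DUP>` records
#' each yield one call; a symbolic `<INV>` yields its two constituent
#' breakpoints (orientations `++` and `--`) as two calls, so that composing
#' inversion breakpoints are matched independently; `BND` mate pairs are
#' joined into single calls using the VCF 4.2 bracket semantics. Sequence-ALT
#' records are interpreted as insertions or deletions by REF/ALT length
#' difference. `CIPOS`/`CIEND` and `HOMLEN` populate the breakend ambiguity
#' intervals; absent annotations give point intervals.
#'
#' Unpaired `BND` records are excluded from the call set with a warning
#' (their count is kept in attribute `n_unpaired_bnd` of the `calls` data
#' frame); symbolic records lacking both `END` and `SVLEN` are rejected with
#' a diagnostic message.
#'
#' @param path VCF file path (may be gzip-compressed).
#' @param caller_id string identifying the caller the file came from.
#' @param reference_name optional reference label (default: taken from a
#'   `##reference` header line when present).
#' @return an [callset()] object; `qual` comes from QUAL, `read_support`
#'   from the INFO `SUPPORT` (or `RE`/`DV`) tag when present.
#' @export
parse_vcf <- function(path, caller_id = "caller", reference_name = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(reference_name)) {
    ref_line <- grep("^##reference=", v@meta, value = TRUE)
    reference_name <- if (length(ref_line)) sub("^##reference=(file://)?", "", ref_line[1]) else "unknown"
  }
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0) {
    return(callset(empty_calls_df(), caller_id, reference_name))
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- sprintf("rec%d", which(is.na(fix[, "ID"]) | fix[, "ID"] == "."))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  filter <- fix[, "FILTER"]
  filter[is.na(filter)] <- "."
  info <- fix[, "INFO"]
  info[is.na(info)] <- ""

  end_i <- info_num(info, "END")
  svlen <- info_num(info, "SVLEN")
  svtype_i <- info_field(info, "SVTYPE")
  cipos <- info_field(info, "CIPOS")
  ciend <- info_field(info, "CIEND")
  homlen <- info_num(info, "HOMLEN")
  mateid <- info_field(info, "MATEID")
  support <- info_num(info, "SUPPORT")
  support <- ifelse(is.na(support), info_num(info, "RE"), support)
  support <- ifelse(is.na(support), info_num(info, "DV"), support)

  rows <- list()
  bnd_idx <- integer(0)
  n_rejected <- 0

  add_row <- function(chrom1, pos1, iv1, ori1, chrom2, pos2, iv2, ori2,
                      svtype, size, i, suffix = "") {
    data.frame(
      chrom1 = chrom1, pos1 = pos1, lo1 = iv1[1], hi1 = iv1[2], ori1 = ori1,
      chrom2 = chrom2, pos2 = pos2, lo2 = iv2[1], hi2 = iv2[2], ori2 = ori2,
      svtype = svtype, size = size, qual = qual[i],
      read_support = support[i], filter = filter[i],
      pass = filter[i] %in% c(".", "PASS"),
      id = paste0(id[i], suffix),
      stringsAsFactors = FALSE
    )
  }

  for (i in seq_along(pos)) {
    a <- alt[i]
    if (is.na(a) || a %in% c(".", "*")) next
    if (grepl("^<", a)) {
      st <- toupper(sub("^<([A-Za-z]+).*$", "\\1", a))
      if (!st %in% c("DEL", "INS", "DUP", "INV")) {
        st2 <- toupper(svtype_i[i])
        if (!is.na(st2) && st2 %in% c("DEL", "INS", "DUP", "INV")) st <- st2
      }
      if (!st %in% c("DEL", "INS", "DUP", "INV")) {
        message(sprintf("parse_vcf: record %s has unsupported symbolic type <%s>; skipped", id[i], st))
        n_rejected <- n_rejected + 1
        next
      }
      if (st == "INS") {
        if (is.na(svlen[i])) {
          message(sprintf("parse_vcf: INS record %s lacks SVLEN; rejected", id[i]))
          n_rejected <- n_rejected + 1
          next
        }
        iv <- ambiguity_interval(pos[i], cipos[i], homlen[i])
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv, "+",
                                            chrom[i], pos[i], iv, "-",
                                            "INS", abs(svlen[i]), i)
        next
      }
      e <- end_i[i]
      if (is.na(e)) {
        if (is.na(svlen[i])) {
          message(sprintf("parse_vcf: record %s lacks both END and SVLEN; rejected", id[i]))
          n_rejected <- n_rejected + 1
          next
        }
        e <- pos[i] + abs(svlen[i])
      }
      iv1 <- ambiguity_interval(pos[i], cipos[i], homlen[i])
      iv2 <- ambiguity_interval(e, ciend[i], homlen[i])
      size <- abs(e - pos[i])
      if (st == "DEL") {
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv1, "+",
                                            chrom[i], e, iv2, "-", "DEL", size, i)
      } else if (st == "DUP") {
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv1, "-",
                                            chrom[i], e, iv2, "+", "DUP", size, i)
      } else { # INV: two independent breakpoints
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv1, "+",
                                            chrom[i], e, iv2, "+", "INV", size, i, "_bp1")
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i] + 1, iv1 + 1, "-",
                                            chrom[i], e + 1, iv2 + 1, "-", "INV", size, i, "_bp2")
      }
    } else if (grepl("[", a, fixed = TRUE) || grepl("]", a, fixed = TRUE)) {
      bnd_idx <- c(bnd_idx, i)
    } else {
      # sequence ALT: classify by length difference
      nr <- nchar(ref[i]); na_ <- nchar(a)
      if (na_ > nr) {
        iv <- ambiguity_interval(pos[i], cipos[i], homlen[i])
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv, "+",
                                            chrom[i], pos[i], iv, "-",
                                            "INS", na_ - nr, i)
      } else if (nr > na_) {
        e <- pos[i] + (nr - na_)
        iv1 <- ambiguity_interval(pos[i], cipos[i], homlen[i])
        iv2 <- ambiguity_interval(e, ciend[i], homlen[i])
        rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv1, "+",
                                            chrom[i], e, iv2, "-", "DEL", nr - na_, i)
      }
      # equal length (SNV/MNV): not a structural variant, ignored
    }
  }

  # BND mate pairing
  n_unpaired <- 0
  if (length(bnd_idx)) {
    parsed <- lapply(alt[bnd_idx], parse_bnd_alt)
    ok <- !vapply(parsed, is.null, logical(1))
    if (any(!ok)) n_unpaired <- n_unpaired + sum(!ok)
    bnd_idx <- bnd_idx[ok]
    parsed <- parsed[ok]
    ids <- id[bnd_idx]
    mates <- mateid[bnd_idx]
    seen <- character(0)
    for (k in seq_along(bnd_idx)) {
      i <- bnd_idx[k]
      p <- parsed[[k]]
      mk <- NA_integer_
      if (!is.na(mates[k])) mk <- match(mates[k], ids)
      if (is.na(mk)) {
        # fall back: locate a record at the mate locus pointing back here
        for (k2 in seq_along(bnd_idx)) {
          if (k2 == k) next
          p2 <- parsed[[k2]]
          if (p2$mate_chrom == chrom[i] && p2$mate_pos == pos[i] &&
              chrom[bnd_idx[k2]] == p$mate_chrom && pos[bnd_idx[k2]] == p$mate_pos) {
            mk <- k2; break
          }
        }
      }
      if (is.na(mk)) { n_unpaired <- n_unpaired + 1; next }
      key <- paste(sort(c(ids[k], ids[mk])), collapse = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      j <- bnd_idx[mk]
      iv1 <- ambiguity_interval(pos[i], cipos[i], homlen[i])
      iv2 <- ambiguity_interval(pos[j], cipos[j], homlen[j])
      size <- if (chrom[i] == chrom[j]) abs(pos[j] - pos[i]) else NA_real_
      rows[[length(rows) + 1]] <- add_row(chrom[i], pos[i], iv1, p$local_ori,
                                          chrom[j], pos[j], iv2, p$mate_ori,
                                          "BND", size, i)
    }
    if (n_unpaired > 0) {
      warning(sprintf("parse_vcf: %d unpaired/unparseable BND record(s) excluded from matching", n_unpaired))
    }
  }

  df <- if (length(rows)) do.call(rbind, rows) else empty_calls_df()
  attr(df, "n_unpaired_bnd") <- n_unpaired
  attr(df, "n_rejected") <- n_rejected
  callset(df, caller_id, reference_name)
}

empty_calls_df <- function() {
  data.frame(
    chrom1 = character(0), pos1 = integer(0), lo1 = numeric(0), hi1 = numeric(0),
    ori1 = character(0), chrom2 = character(0), pos2 = integer(0),
    lo2 = numeric(0), hi2 = numeric(0), ori2 = character(0),
    svtype = character(0), size = numeric(0), qual = numeric(0),
    read_support = numeric(0), filter = character(0), pass = logical(0),
    id = character(0), stringsAsFactors = FALSE
  )
}

fmt_info_pair <- function(key, lo, hi, pos) {
  if (lo == pos && hi == pos) return(NULL)
  sprintf("%s=%d,%d", key, as.integer(lo - pos), as.integer(hi - pos))
}

#' Write a call set as VCF v4.2
#'
#' Deletions, insertions and tandem duplications are written as symbolic-ALT
#' records with `END`/`SVLEN`; the two breakpoints of an inversion are
#' re-joined into a single `<INV>` record when both are present (an isolated
#' inversion breakpoint is emitted as a BND mate pair); translocation calls
#' are written as mated BND records using VCF 4.2 bracket notation.
#' Non-point ambiguity intervals are emitted as `CIPOS`/`CIEND`. Round trip:
#' re-parsing the file reproduces breakends, types, sizes and filters.
#'
#' @param cs an [callset()] object (canonically ordered).
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "sv_callset"))
  calls <- cs$calls
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=svbench",
    sprintf("##reference=%s", cs$reference_name),
    sprintf("##contig=<ID=%s>", sort(unique(c(calls$chrom1, calls$chrom2)))),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Confidence interval around POS\">",
    "##INFO=<ID=CIEND,Number=2,Type=Integer,Description=\"Confidence interval around END\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"ID of mate breakend\">",
    "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Supporting read count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  recs <- list()
  qual_str <- ifelse(is.na(calls$qual), ".", format(calls$qual, trim = TRUE, scientific = FALSE))
  supp <- ifelse(is.na(calls$read_support), NA_character_,
                 sprintf("SUPPORT=%d", as.integer(calls$read_support)))
  consumed <- rep(FALSE, nrow(calls))

  emit <- function(chrom, pos, id, alt, qual, filter, info_parts) {
    info <- paste(Filter(Negate(is.null), info_parts), collapse = ";")
    sprintf("%s\t%d\t%s\tN\t%s\t%s\t%s\t%s", chrom, as.integer(pos), id, alt, qual, filter, info)
  }
  emit_bnd_pair <- function(i, base_id) {
    c1 <- calls$chrom1[i]; p1 <- calls$pos1[i]; o1 <- calls$ori1[i]
    c2 <- calls$chrom2[i]; p2 <- calls$pos2[i]; o2 <- calls$ori2[i]
    bnd_alt <- function(mate_chrom, mate_pos, local_ori, mate_ori) {
      br <- if (mate_ori == "-") "[" else "]"
      locus <- sprintf("%s%s:%d%s", br, mate_chrom, mate_pos, br)
      if (local_ori == "+") paste0("N", locus) else paste0(locus, "N")
    }
    id1 <- paste0(base_id, "_1"); id2 <- paste0(base_id, "_2")
    c(
      emit(c1, p1, id1, bnd_alt(c2, p2, o1, o2), qual_str[i], calls$filter[i],
           c(list("SVTYPE=BND", sprintf("MATEID=%s", id2),
                  fmt_info_pair("CIPOS", calls$lo1[i], calls$hi1[i], p1)),
             if (!is.na(supp[i])) list(supp[i]))),
      emit(c2, p2, id2, bnd_alt(c1, p1, o2, o1), qual_str[i], calls$filter[i],
           c(list("SVTYPE=BND", sprintf("MATEID=%s", id1),
                  fmt_info_pair("CIPOS", calls$lo2[i], calls$hi2[i], p2)),
             if (!is.na(supp[i])) list(supp[i])))
    )
  }

  for (i in seq_len(nrow(calls))) {
    if (consumed[i]) next
    st <- calls$svtype[i]
    base_id <- sub("_bp[12]$", "", calls$id[i])
    if (st %in% c("DEL", "DUP")) {
      recs[[length(recs) + 1]] <- emit(
        calls$chrom1[i], calls$pos1[i], base_id, sprintf("<%s>", st),
        qual_str[i], calls$filter[i],
        c(list(sprintf("SVTYPE=%s", st), sprintf("END=%d", as.integer(calls$pos2[i])),
               sprintf("SVLEN=%d", as.integer(if (st == "DEL") -calls$size[i] else calls$size[i])),
               fmt_info_pair("CIPOS", calls$lo1[i], calls$hi1[i], calls$pos1[i]),
               fmt_info_pair("CIEND", calls$lo2[i], calls$hi2[i], calls$pos2[i])),
          if (!is.na(supp[i])) list(supp[i])))
    } else if (st == "INS") {
      recs[[length(recs) + 1]] <- emit(
        calls$chrom1[i], calls$pos1[i], base_id, "<INS>",
        qual_str[i], calls$filter[i],
        c(list("SVTYPE=INS", sprintf("END=%d", as.integer(calls$pos1[i])),
               sprintf("SVLEN=%d", as.integer(calls$size[i])),
               fmt_info_pair("CIPOS", calls$lo1[i], calls$hi1[i], calls$pos1[i])),
          if (!is.na(supp[i])) list(supp[i])))
    } else if (st == "INV") {
      # find the "--" partner of a "++" breakpoint (same event, +1 offset)
      partner <- which(!consumed & calls$svtype == "INV" &
                         calls$chrom1 == calls$chrom1[i] &
                         calls$ori1 == "-" & calls$ori2 == "-" &
                         calls$pos1 == calls$pos1[i] + 1 &
                         calls$pos2 == calls$pos2[i] + 1)
      if (calls$ori1[i] == "+" && length(partner)) {
        consumed[partner[1]] <- TRUE
        recs[[length(recs) + 1]] <- emit(
          calls$chrom1[i], calls$pos1[i], base_id, "<INV>",
          qual_str[i], calls$filter[i],
          c(list("SVTYPE=INV", sprintf("END=%d", as.integer(calls$pos2[i])),
                 sprintf("SVLEN=%d", as.integer(calls$size[i])),
                 fmt_info_pair("CIPOS", calls$lo1[i], calls$hi1[i], calls$pos1[i]),
                 fmt_info_pair("CIEND", calls$lo2[i], calls$hi2[i], calls$pos2[i])),
            if (!is.na(supp[i])) list(supp[i])))
      } else {
        recs[[length(recs) + 1]] <- emit_bnd_pair(i, base_id)
      }
    } else { # BND
      recs[[length(recs) + 1]] <- emit_bnd_pair(i, base_id)
    }
    consumed[i] <- TRUE
  }
  writeLines(c(header, unlist(recs)), path)
  invisible(path)
}
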
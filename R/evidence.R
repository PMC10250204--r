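#' Extract splice junctions and aligned blocks from one CIGAR string
#'
#' Pure-R reference CIGAR walker. Each `N` operation yields one junction,
#' reported as `(donor_end, acceptor_start)`: the last aligned reference base
#' before the gap and the first aligned base after it (1-based inclusive
#' genomic coordinates; the skipped intron is
#' `[donor_end + 1, acceptor_start - 1]`). `M`, `=`, `X` and `D` consume
#' reference; `I`, `S`, `H` and `P` do not.
#'
#' The BAM-driven pipeline decodes CIGARs through GenomicAlignments' C
#' routines; this independent walker backs the exported operation and the
#' cross-checking property tests.
#'
#' @param cigar A CIGAR string.
#' @param pos 1-based leftmost aligned reference position.
#' @return A list with `junctions` (data.table: `donor`, `acceptor`) and
#'   `blocks` (data.table: `start`, `end`, maximal contiguous aligned
#'   reference intervals).
#' @export
extract_junctions <- function(cigar, pos) {
  if (is.na(cigar) || !grepl("^([0-9]+[MIDNSHP=X])+$", cigar))
    stop("invalid CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  ref <- pos
  bs <- integer(0); be <- integer(0)
  jd <- integer(0); ja <- integer(0)
  cur_start <- NA_integer_
  for (i in seq_along(ops)) {
    op <- ops[i]; n <- lens[i]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(cur_start)) cur_start <- ref
      ref <- ref + n
    } else if (op == "N") {
      if (!is.na(cur_start)) { bs <- c(bs, cur_start); be <- c(be, ref - 1L) }
      jd <- c(jd, ref - 1L)
      ref <- ref + n
      ja <- c(ja, ref)
      cur_start <- NA_integer_
    }
    # I, S, H, P: no reference advance
  }
  if (!is.na(cur_start)) { bs <- c(bs, cur_start); be <- c(be, ref - 1L) }
  list(junctions = data.table(donor = jd, acceptor = ja),
       blocks = data.table(start = bs, end = be))
}

#' Fuzzy coordinate matching
#'
#' Returns the candidate coordinate closest to `coord` whose absolute offset
#' is at most `tolerance` (default 3 nt); ties on absolute offset break
#' toward the smaller coordinate; `NA` if nothing matches.
#'
#' @param coord Query coordinate (scalar).
#' @param candidates Integer vector of candidate coordinates.
#' @param tolerance Non-negative integer; 0 means exact membership.
#' @return The matched candidate, or `NA_integer_`.
#' @export
fuzzy_match <- function(coord, candidates, tolerance = 3L) {
  stopifnot(tolerance >= 0)
  if (!length(candidates)) return(NA_integer_)
  off <- abs(candidates - coord)
  ok <- off <= tolerance
  if (!any(ok)) return(NA_integer_)
  cand <- candidates[ok]; off <- off[ok]
  cand <- cand[order(off, cand)]
  as.integer(cand[1L])
}

# vectorized: does each x fuzzy-match any member of set?
fuzzy_in <- function(x, set, tol) {
  if (!length(x)) return(logical(0))
  if (!length(set)) return(rep(FALSE, length(x)))
  out <- rep(FALSE, length(x))
  for (s in set) out <- out | (abs(x - s) <= tol)
  out
}

.FLAG <- list(paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
              rev = 16L, mrev = 32L, first = 64L, second = 128L,
              secondary = 256L, qcfail = 512L, dup = 1024L, supp = 2048L)

#' Read fragments from a BAM file
#'
#' Streams primary alignments (secondary, supplementary, unmapped, QC-fail
#' and duplicate-flagged records are skipped), pairs mates by query name, and
#' assembles one fragment per sequencing unit: the union of the mates'
#' aligned blocks plus all their splice junctions. Paired records whose mate
#' is missing from the file/region are kept as single-end fragments (their
#' count is reported in a message).
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param region Optional `GRanges` of length 1 restricting the scan; mates
#'   outside the region still contribute when their pair overlaps it.
#' @param min_mapq Minimum mapping quality (default 0; MAPQ-0 reads kept).
#' @return A list of three data.tables: `fragments` (`frag`, `chrom`,
#'   `start`, `end`, `paired`, `strand1` = strand of read 1, `n_junc`),
#'   `blocks` (`frag`, `start`, `end`) and `junctions` (`frag`, `donor`,
#'   `acceptor`).
#' @export
read_fragments <- function(bam, region = NULL, min_mapq = 0L) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "flag", "mapq"),
    which = if (is.null(region)) IRanges::IRangesList() else region)
  if (is.null(region)) {
    param <- Rsamtools::ScanBamParam(flag = flag,
                                     what = c("qname", "flag", "mapq"))
  }
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  build_fragments(ga, min_mapq = min_mapq)
}

# assemble fragments from a GAlignments object
build_fragments <- function(ga, min_mapq = 0L) {
  mc <- S4Vectors::mcols(ga)
  if (!is.null(mc$mapq) && min_mapq > 0L) {
    keep <- is.na(mc$mapq) | mc$mapq >= min_mapq
    ga <- ga[keep]; mc <- S4Vectors::mcols(ga)
  }
  empty <- list(
    fragments = data.table(frag = character(), chrom = character(),
                           start = integer(), end = integer(),
                           paired = logical(), strand1 = character(),
                           n_junc = integer()),
    blocks = data.table(frag = character(), start = integer(),
                        end = integer()),
    junctions = data.table(frag = character(), donor = integer(),
                           acceptor = integer()))
  if (!length(ga)) return(empty)
  fl <- mc$flag
  paired <- bitwAnd(fl, .FLAG$paired) > 0L
  second <- bitwAnd(fl, .FLAG$second) > 0L
  revd <- bitwAnd(fl, .FLAG$rev) > 0L
  chrom <- as.character(GenomicAlignments::seqnames(ga))
  # fragment key: qname + chrom (mates on different chroms kept apart)
  fid <- paste0(mc$qname, "\r", chrom)
  blk <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicAlignments::start(ga),
    ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  gap <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicAlignments::start(ga),
    ops = "N")
  nb <- lengths(blk); ng <- lengths(gap)
  blocks <- data.table(frag = rep(fid, nb),
                       start = unlist(IRanges::start(blk), use.names = FALSE),
                       end = unlist(IRanges::end(blk), use.names = FALSE))
  junctions <- data.table(
    frag = rep(fid, ng),
    donor = unlist(IRanges::start(gap), use.names = FALSE) - 1L,
    acceptor = unlist(IRanges::end(gap), use.names = FALSE) + 1L)
  recs <- data.table(frag = fid, chrom = chrom, paired = paired,
                     second = second,
                     rstrand = ifelse(revd, "-", "+"))
  # strand of read 1 (or the single read); for mate-only fragments flip mate 2
  frags <- recs[, .(
    chrom = chrom[1L],
    paired = any(paired),
    strand1 = {
      i <- which(!second)
      if (length(i)) rstrand[i[1L]] else (if (rstrand[1L] == "+") "-" else "+")
    },
    n_rec = .N
  ), by = frag]
  unpaired_pe <- frags[paired == TRUE & n_rec == 1L, .N]
  if (unpaired_pe > 0)
    message(unpaired_pe,
            " paired-flagged record(s) without a mate treated as single-end")
  # merge overlapping blocks within fragment
  blocks <- blocks[, merge_blocks(start, end), by = frag]
  junctions <- unique(junctions)
  span <- blocks[, .(start = min(start), end = max(end)), by = frag]
  nj <- junctions[, .N, by = frag]
  frags <- merge(frags, span, by = "frag")
  frags <- merge(frags, nj, by = "frag", all.x = TRUE)
  frags[is.na(N), N := 0L]
  data.table::setnames(frags, "N", "n_junc")
  frags[, n_rec := NULL]
  list(fragments = frags[], blocks = blocks[], junctions = junctions[])
}

merge_blocks <- function(s, e) {
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ks <- s[1L]; ke <- e[1L]
  os <- integer(0); oe <- integer(0)
  if (length(s) > 1L) for (i in 2L:length(s)) {
    if (s[i] <= ke + 1L) ke <- max(ke, e[i])
    else { os <- c(os, ks); oe <- c(oe, ke); ks <- s[i]; ke <- e[i] }
  }
  list(start = c(os, ks), end = c(oe, ke))
}

#' Detect library layout (paired and strandedness) from the data
#'
#' Samples primary alignments and infers (i) pairedness by majority of the
#' paired FLAG bit and (ii) strandedness by matching splice junctions of
#' sampled reads to annotated exon boundaries: a junction-bearing fragment
#' votes `forward` when its read-1 orientation equals the matched gene's
#' annotated strand, `reverse` otherwise; genes are matched via junction
#' flanks (within `tol`) and ambiguous matches (genes on both strands) are
#' not counted. The library is called stranded when one orientation exceeds
#' 80\% of votes, `unstranded` otherwise (including no votes).
#'
#' @param bam BAM path.
#' @param exons Entity table ([read_exon_table()] / [cluster_exons()]).
#' @param sample_size Number of records to sample (default 100000).
#' @param tol Fuzzy-match tolerance in nt.
#' @return A list `(paired, strandedness)` with
#'   `strandedness` in `forward`, `reverse`, `unstranded`.
#' @export
detect_layout <- function(bam, exons, sample_size = 100000L, tol = 3L) {
  bf <- Rsamtools::BamFile(bam, yieldSize = sample_size)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "flag"))
  open(bf); on.exit(close(bf))
  ga <- GenomicAlignments::readGAlignments(bf, param = param)
  if (!length(ga)) stop("no mapped reads sampled from ", bam)
  fr <- build_fragments(ga)
  layout_from_fragments(fr, exons, tol = tol)
}

layout_from_fragments <- function(fr, exons, tol = 3L) {
  paired <- mean(fr$fragments$paired) > 0.5
  ent <- data.table::as.data.table(exons)
  jx <- merge(fr$junctions,
              fr$fragments[, .(frag, chrom, strand1)], by = "frag")
  votes <- c(forward = 0L, reverse = 0L)
  if (nrow(jx) && nrow(ent)) {
    # annotated boundary sets per chrom+strand: junction donor must match an
    # exon end or neighbor coordinate, acceptor an exon start (genomic sense)
    bounds <- ent[, .(
      don = list(sort(unique(unlist(c(ends, do_starts, up_ends))))),
      acc = list(sort(unique(unlist(c(starts, up_ends, do_starts)))))
    ), by = .(chrom, strand)]
    for (i in seq_len(nrow(bounds))) {
      b <- bounds[i]
      sub <- jx[chrom == b$chrom]
      if (!nrow(sub)) next
      hit <- fuzzy_in(sub$donor, b$don[[1]], tol) &
             fuzzy_in(sub$acceptor, b$acc[[1]], tol)
      if (!any(hit)) next
      v <- sub[hit, .(same = strand1[1L] == b$strand), by = frag]
      votes["forward"] <- votes["forward"] + sum(v$same)
      votes["reverse"] <- votes["reverse"] + sum(!v$same)
    }
  }
  tot <- sum(votes)
  strandedness <- "unstranded"
  if (tot > 0) {
    if (votes["forward"] / tot > 0.8) strandedness <- "forward"
    else if (votes["reverse"] / tot > 0.8) strandedness <- "reverse"
  }
  list(paired = paired, strandedness = strandedness)
}
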
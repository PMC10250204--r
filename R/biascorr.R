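#' Truncation bias correction for long reads
#'
#' Long reads that do not cover a transcript end-to-end bias AISO counts at
#' the first and last internal exons they cover: a 5'-truncated molecule can
#' no longer produce upstream-first evidence at its 5'-most covered exon, and
#' a 3'-truncated one loses downstream-first evidence symmetrically. The
#' correction cuts each long read at the first and last covered annotated
#' exons: those exons and all evidence outside the interval strictly between
#' them are removed, so counts are extracted only for interior exons.
#'
#' @param frag_blocks data.table of the fragment's blocks (`start`, `end`).
#' @param frag_junctions data.table of junctions (`donor`, `acceptor`).
#' @param exon_extents data.table of annotated entity extents on the
#'   fragment's chromosome: columns `s`, `e` (maximal extents), any order.
#' @param min_overlap Minimum overlap in nt for an exon to count as covered
#'   (default 6).
#' @return A list with trimmed `blocks` and `junctions` (possibly empty) and
#'   `covered` (number of covered exons). Reads covering fewer than three
#'   exons retain no evidence.
#' @export
truncate_long_read <- function(frag_blocks, frag_junctions, exon_extents,
                               min_overlap = 6L) {
  b <- data.table::as.data.table(frag_blocks)
  j <- data.table::as.data.table(frag_junctions)
  ex <- data.table::as.data.table(exon_extents)
  empty <- list(blocks = b[0], junctions = j[0], covered = 0L)
  if (!nrow(b) || !nrow(ex)) return(empty)
  ov <- IRanges::findOverlaps(IRanges::IRanges(ex$s, ex$e),
                              IRanges::IRanges(b$start, b$end))
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  w <- pmin(ex$e[qh], b$end[sh]) - pmax(ex$s[qh], b$start[sh]) + 1L
  cov <- sort(unique(qh[w >= min_overlap]))
  empty$covered <- length(cov)
  if (length(cov) < 3L) return(empty)
  first <- cov[which.min(ex$s[cov])]
  last <- cov[which.max(ex$e[cov])]
  lo <- ex$e[first] + 1L
  hi <- ex$s[last] - 1L
  if (lo > hi) return(empty)
  bb <- b[end >= lo & start <= hi]
  bb[, `:=`(start = pmax(start, lo), end = pmin(end, hi))]
  jj <- j[donor >= lo & acceptor <= hi]
  list(blocks = bb[], junctions = jj[], covered = length(cov))
}

# apply truncation to every long fragment of a fragment set.
# ent_ext: data.table(row, chrom, strand, s, e) for all entities.
apply_biascorr <- function(fr, ent_ext, min_overlap = 6L,
                           long_reads = FALSE) {
  frags <- copy(fr$fragments)
  blocks <- copy(fr$blocks)
  juncs <- copy(fr$junctions)
  # long read: unpaired and spanning >= 3 annotated entities (or forced)
  frags[, long := FALSE]
  cand <- which(!frags$paired)
  if (!length(cand))
    return(list(fragments = frags, blocks = blocks, junctions = juncs))
  data.table::setkey(blocks, frag)
  data.table::setkey(juncs, frag)
  ex_by_chrom <- split(ent_ext, by = "chrom")
  keep_b <- vector("list", length(cand))
  keep_j <- vector("list", length(cand))
  touched <- character(0)
  for (k in seq_along(cand)) {
    i <- cand[k]
    id <- frags$frag[i]
    ex <- ex_by_chrom[[frags$chrom[i]]]
    if (is.null(ex)) next
    b <- blocks[.(id), nomatch = NULL]
    j <- juncs[.(id), nomatch = NULL]
    tr <- truncate_long_read(b, j, ex, min_overlap = min_overlap)
    is_long <- long_reads || tr$covered >= 3L
    if (!is_long) next
    frags$long[i] <- TRUE
    touched <- c(touched, id)
    if (nrow(tr$blocks)) keep_b[[k]] <- tr$blocks
    if (nrow(tr$junctions)) keep_j[[k]] <- tr$junctions
  }
  if (!length(touched))
    return(list(fragments = frags, blocks = blocks, junctions = juncs))
  blocks <- rbind(blocks[!frag %chin% touched],
                  data.table::rbindlist(keep_b))
  juncs <- rbind(juncs[!frag %chin% touched],
                 data.table::rbindlist(keep_j))
  # recompute spans; fragments left without blocks are dropped
  span <- blocks[, .(start = min(start), end = max(end)), by = frag]
  frags <- merge(frags[, c("frag", "chrom", "paired", "strand1", "n_junc",
                           "long"), with = FALSE],
                 span, by = "frag")
  list(fragments = frags, blocks = blocks, junctions = juncs)
}
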
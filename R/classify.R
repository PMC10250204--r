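#' Effective intron regions of an exon entity
#'
#' The full flanking introns are taken from the exon's maximal extent
#' (min start, max end) to the nearest annotated neighbor coordinate on each
#' side, in transcription orientation. To remove intron-length-driven
#' counting bias, both introns are trimmed, adjacent to the exon, to the
#' length of the shorter one (the effective length). An exon missing a
#' neighbor on either side has no regions and is reported `NA` downstream.
#'
#' @param entity One-row entity table (list columns `starts`, `ends`,
#'   `up_ends`, `do_starts`, plus `strand`).
#' @return A list with `up_region` and `do_region` (`c(start, end)` genomic,
#'   1-based inclusive), `up_intron`/`do_intron` (full intron extents),
#'   `effective_length`, or `NULL` when a neighbor is missing or an intron
#'   is empty/inverted.
#' @export
effective_regions <- function(entity) {
  g <- entity_geometry(entity)
  if (is.null(g)) return(NULL)
  g[c("up_region", "do_region", "up_intron", "do_intron",
      "effective_length")]
}

# full genomic geometry of one entity row; NULL when AISO is undefined
entity_geometry <- function(entity) {
  st <- entity$starts[[1]]; en <- entity$ends[[1]]
  up <- entity$up_ends[[1]]; dn <- entity$do_starts[[1]]
  if (!length(up) || !length(dn)) return(NULL)
  s <- min(st); e <- max(en)
  if (entity$strand == "+") {
    up_int <- c(max(up) + 1L, s - 1L)
    do_int <- c(e + 1L, min(dn) - 1L)
    upL <- up; upR <- st          # up junction: donor in upL, acceptor in upR
    doL <- en; doR <- dn
    skipL <- up; skipR <- dn
  } else {
    up_int <- c(e + 1L, min(up) - 1L)
    do_int <- c(max(dn) + 1L, s - 1L)
    upL <- en; upR <- up
    doL <- dn; doR <- st
    skipL <- dn; skipR <- up
  }
  lu <- up_int[2] - up_int[1] + 1L
  ld <- do_int[2] - do_int[1] + 1L
  if (lu < 1L || ld < 1L) return(NULL)
  L <- min(lu, ld)
  # effective regions abut the exon's maximal extent
  if (entity$strand == "+") {
    up_reg <- c(s - L, s - 1L)
    do_reg <- c(e + 1L, e + L)
  } else {
    up_reg <- c(e + 1L, e + L)
    do_reg <- c(s - L, s - 1L)
  }
  list(strand = entity$strand, ext = c(s, e),
       up_intron = up_int, do_intron = do_int,
       up_region = up_reg, do_region = do_reg,
       effective_length = L,
       upL = upL, upR = upR, doL = doL, doR = doR,
       skipL = skipL, skipR = skipR)
}

#' Intronic (unspliced) evidence of a fragment within a region
#'
#' `TRUE` iff some aligned block of the fragment overlaps the region by at
#' least `min_overlap` nt and no junction of the fragment splices the
#' corresponding intron out. A junction "splices the intron out" when its
#' gap covers the whole intron within `tol` at each edge (which includes
#' exact intron junctions and exon-skipping junctions spanning it).
#'
#' @param blocks data.table of the fragment's blocks (`start`, `end`).
#' @param junctions data.table of the fragment's junctions (`donor`,
#'   `acceptor`).
#' @param region `c(start, end)` effective intron region.
#' @param intron `c(start, end)` full intron extent.
#' @param min_overlap Minimum block overlap in nt (default 6).
#' @param tol Fuzzy tolerance in nt.
#' @return Logical scalar.
#' @export
intronic_evidence <- function(blocks, junctions, region, intron,
                              min_overlap = 6L, tol = 3L) {
  ov <- pmin(blocks$end, region[2]) - pmax(blocks$start, region[1]) + 1L
  has_block <- any(ov >= min_overlap)
  spliced <- FALSE
  if (nrow(junctions))
    spliced <- any(junctions$donor + 1L <= intron[1] + tol &
                   junctions$acceptor - 1L >= intron[2] - tol)
  has_block && !spliced
}

#' Exon-inclusion junction evidence of a fragment
#'
#' For `side = "up"`, `TRUE` iff some junction's acceptor fuzzy-matches an
#' exon start and its donor fuzzy-matches an upstream neighbor end (in
#' transcription orientation; coordinates handled genomically per strand);
#' symmetric for `side = "do"`.
#'
#' @param junctions Fragment junction table (`donor`, `acceptor`).
#' @param entity One-row entity table.
#' @param side `"up"` or `"do"`.
#' @param tol Fuzzy tolerance in nt.
#' @return Logical scalar.
#' @export
junction_evidence <- function(junctions, entity, side = c("up", "do"),
                              tol = 3L) {
  side <- match.arg(side)
  g <- entity_geometry(entity)
  if (is.null(g)) {
    # junction evidence can exist one-sided even if the other side lacks a
    # neighbor: rebuild the sets directly
    g <- one_sided_geometry(entity)
  }
  L <- if (side == "up") g$upL else g$doL
  R <- if (side == "up") g$upR else g$doR
  if (is.null(L) || is.null(R) || !length(L) || !length(R)) return(FALSE)
  if (!nrow(junctions)) return(FALSE)
  any(fuzzy_in(junctions$donor, L, tol) &
      fuzzy_in(junctions$acceptor, R, tol))
}

one_sided_geometry <- function(entity) {
  st <- entity$starts[[1]]; en <- entity$ends[[1]]
  up <- entity$up_ends[[1]]; dn <- entity$do_starts[[1]]
  if (entity$strand == "+")
    list(upL = up, upR = st, doL = en, doR = dn)
  else
    list(upL = en, upR = up, doL = dn, doR = st)
}

# Vectorized per-exon classification of a set of fragments.
# frag_ids: character vector of fragment ids to classify; blocks/junctions
# are subset to these ids by the caller or here.
# Returns a data.table with one row per fragment and logical columns.
classify_fragment_set <- function(g, frag_ids, blocks, junctions,
                                  tol = 3L, min_overlap = 6L) {
  out <- data.table(frag = frag_ids)
  bl <- blocks[frag %chin% frag_ids]
  jx <- junctions[frag %chin% frag_ids]

  ov_flag <- function(b, region) {
    if (!nrow(b)) return(character(0))
    ov <- pmin(b$end, region[2]) - pmax(b$start, region[1]) + 1L
    unique(b$frag[ov >= min_overlap])
  }
  raw_up <- ov_flag(bl, g$up_region)
  raw_do <- ov_flag(bl, g$do_region)

  spl_cover <- function(j, intron) {
    if (!nrow(j)) return(character(0))
    hit <- j$donor + 1L <= intron[1] + tol & j$acceptor - 1L >= intron[2] - tol
    unique(j$frag[hit])
  }
  spl_up <- spl_cover(jx, g$up_intron)
  spl_do <- spl_cover(jx, g$do_intron)

  j_match <- function(j, L, R) {
    if (!nrow(j)) return(character(0))
    hit <- fuzzy_in(j$donor, L, tol) & fuzzy_in(j$acceptor, R, tol)
    unique(j$frag[hit])
  }
  j_up <- j_match(jx, g$upL, g$upR)
  j_do <- j_match(jx, g$doL, g$doR)
  j_skip <- j_match(jx, g$skipL, g$skipR)

  # boundary-spanning (unspliced) blocks: min_overlap nt on each side
  span_flag <- function(b, boundary_left) {
    # boundary between position boundary_left and boundary_left + 1
    if (!nrow(b)) return(character(0))
    hit <- b$start <= boundary_left - (min_overlap - 1L) &
           b$end >= boundary_left + min_overlap
    unique(b$frag[hit])
  }
  # exon-side and neighbor-side boundaries of each intron (genomic)
  ei_up <- span_flag(bl, if (g$strand == "+") g$up_intron[2] else g$ext[2])
  ne_up <- span_flag(bl, if (g$strand == "+") g$up_intron[1] - 1L
                         else g$up_intron[2])
  ei_do <- span_flag(bl, if (g$strand == "+") g$ext[2] else g$do_intron[2])
  ns_do <- span_flag(bl, if (g$strand == "+") g$do_intron[2]
                         else g$do_intron[1] - 1L)

  out[, `:=`(
    raw_up = frag %chin% raw_up, raw_do = frag %chin% raw_do,
    spl_up = frag %chin% spl_up, spl_do = frag %chin% spl_do,
    j_up = frag %chin% j_up, j_do = frag %chin% j_do,
    j_skip = frag %chin% j_skip,
    ei_up = frag %chin% ei_up, ne_up = frag %chin% ne_up,
    ei_do = frag %chin% ei_do, ns_do = frag %chin% ns_do
  )]
  out[, discarded := (raw_up & spl_up) | (raw_do & spl_do)]
  out[, i_up := raw_up & !spl_up & !discarded]
  out[, i_do := raw_do & !spl_do & !discarded]
  out[, category := "none"]
  out[j_up & j_do & !discarded, category := "bos"]
  out[j_up & i_do & !discarded, category := "upfi"]
  out[i_up & j_do & !discarded, category := "dofi"]
  out[i_up & i_do & !j_up & !j_do & !discarded, category := "bus"]
  out[]
}

#' Classify one fragment against one exon entity
#'
#' Applies the configuration logic to a single fragment: `upfi` = inclusion
#' junction with the upstream neighbor plus unspliced downstream effective
#' intron; `dofi` mirrored; `bos` = inclusion junctions on both sides;
#' `bus` = unspliced evidence in both effective regions with no inclusion
#' junction; fragments with contradictory evidence for one intron (a block
#' inside it and a junction splicing it out) are discarded (`none`, with
#' `discarded = TRUE`).
#'
#' @param blocks,junctions Fragment evidence tables (`start`/`end`,
#'   `donor`/`acceptor`).
#' @param entity One-row entity table.
#' @param tol,min_overlap Matching parameters.
#' @return A one-row data.table with `category` (upfi/dofi/bus/bos/none) and
#'   the contributing flags (`j_up`, `j_do`, `j_skip`, `ei_up`, `ne_up`,
#'   `ei_do`, `ns_do`, `discarded`, ...).
#' @export
classify_fragment <- function(blocks, junctions, entity, tol = 3L,
                              min_overlap = 6L) {
  g <- entity_geometry(entity)
  if (is.null(g)) stop("entity has no flanking introns; AISO undefined")
  b <- copy(data.table::as.data.table(blocks)); b[, frag := "f"]
  j <- copy(data.table::as.data.table(junctions))
  if (!nrow(j)) j <- data.table(donor = integer(), acceptor = integer())
  j[, frag := rep("f", nrow(j))]
  classify_fragment_set(g, "f", b, j, tol = tol, min_overlap = min_overlap)
}

.count_cols <- c("upfi", "dofi", "bus", "bos", "skip", "inup", "indo",
                 "ei_up", "ne_up", "ei_do", "ns_do", "discarded")

#' Accumulate AISO counts for one exon entity
#'
#' Sums [classify_fragment()] outcomes over a fragment set. Per fragment at
#' most one of upfi/dofi/bus/bos is incremented; `inup`/`indo` count
#' inclusion-junction evidence per side, `skip` counts exon-skipping
#' junctions, and the `ei_*`/`ne_*`/`ns_*` columns count unspliced
#' exon-intron boundary fragments used for PIR.
#'
#' @param entity One-row entity table.
#' @param fragments A list with `blocks` and `junctions` data.tables keyed by
#'   `frag` (as produced by [read_fragments()]), or `NULL` for zero counts.
#' @param tol,min_overlap Matching parameters.
#' @return A one-row data.table of integer counts (`upfi`, `dofi`, `bus`,
#'   `bos`, `skip`, `inup`, `indo`, `ei_up`, `ne_up`, `ei_do`, `ns_do`,
#'   `discarded`) plus `na_row` flag when AISO is undefined for the entity.
#' @export
count_exon <- function(entity, fragments, tol = 3L, min_overlap = 6L) {
  g <- entity_geometry(entity)
  zero <- data.table::setDT(as.list(setNames(rep(0L, length(.count_cols)),
                                             .count_cols)))
  if (is.null(g)) return(cbind(zero, na_row = TRUE))
  if (is.null(fragments) || !nrow(fragments$blocks))
    return(cbind(zero, na_row = FALSE))
  ids <- unique(fragments$blocks$frag)
  cl <- classify_fragment_set(g, ids, fragments$blocks, fragments$junctions,
                              tol = tol, min_overlap = min_overlap)
  tally_classified(cl)
}

tally_classified <- function(cl) {
  ok <- !cl$discarded
  data.table(
    upfi = sum(cl$category == "upfi"),
    dofi = sum(cl$category == "dofi"),
    bus = sum(cl$category == "bus"),
    bos = sum(cl$category == "bos"),
    skip = sum(cl$j_skip & ok),
    inup = sum(cl$j_up & ok),
    indo = sum(cl$j_do & ok),
    ei_up = sum(cl$ei_up & ok), ne_up = sum(cl$ne_up & ok),
    ei_do = sum(cl$ei_do & ok), ns_do = sum(cl$ns_do & ok),
    discarded = sum(cl$discarded),
    na_row = FALSE)
}

#' Quantify AISO for every exon of an exon table
#'
#' The main counting engine: reads fragments from a BAM file (or takes a
#' pre-built fragment set), optionally applies the long-read truncation bias
#' correction, classifies every fragment against every exon entity it
#' overlaps, and returns counts plus Fupfi/PSI/PIR metrics, one output row
#' per input row in input order. Exons without both flanking introns yield
#' zero counts and `NA` metrics.
#'
#' When the library is stranded (detected automatically from the data unless
#' `strandedness` is given), fragments whose implied transcription strand is
#' antisense to the exon are ignored for that exon.
#'
#' @param exons Entity table ([read_exon_table()] output) or a path to an
#'   exon table file.
#' @param bam Path to an indexed BAM file (ignored when `fragments` given).
#' @param fragments Optional pre-built fragment list ([read_fragments()]).
#' @param tol Fuzzy splice-site matching tolerance in nt (default 3).
#' @param min_overlap Minimum intron/boundary block overlap in nt
#'   (default 6).
#' @param min_mapq Minimum mapping quality (default 0).
#' @param biascorr Apply the long-read truncation correction (default
#'   `FALSE`).
#' @param long_reads Force long-read treatment of all unpaired fragments
#'   (default: a fragment is long when unpaired and spanning >= 3 annotated
#'   entities).
#' @param strandedness `"auto"` (default), `"forward"`, `"reverse"` or
#'   `"unstranded"`.
#' @return A data.table with the input columns `gene_id`, `chrom`, `strand`,
#'   `exon_type`, all counts, and `fupfi`, `psi`, `pir_up`, `pir_do`.
#' @export
aiso_count <- function(exons, bam = NULL, fragments = NULL, tol = 3L,
                       min_overlap = 6L, min_mapq = 0L, biascorr = FALSE,
                       long_reads = FALSE,
                       strandedness = c("auto", "forward", "reverse",
                                        "unstranded")) {
  strandedness <- match.arg(strandedness)
  ent <- if (is.character(exons)) read_exon_table(exons)
         else data.table::as.data.table(exons)
  if (is.null(fragments)) {
    if (is.null(bam)) stop("either `bam` or `fragments` is required")
    fragments <- read_fragments(bam, min_mapq = min_mapq)
  }
  fr <- fragments
  if (strandedness == "auto")
    strandedness <- layout_from_fragments(fr, ent, tol = tol)$strandedness

  ent_ext <- data.table(
    row = seq_len(nrow(ent)), chrom = ent$chrom, strand = ent$strand,
    s = vapply(ent$starts, function(v) min(as.integer(v)), 0L), e = vapply(ent$ends, function(v) max(as.integer(v)), 0L))

  # flag + truncate long reads before classification
  if (biascorr) {
    fr <- apply_biascorr(fr, ent_ext, min_overlap = min_overlap,
                         long_reads = long_reads)
  }

  geoms <- lapply(seq_len(nrow(ent)), function(i) entity_geometry(ent[i]))
  zero_row <- function() cbind(data.table::setDT(as.list(setNames(
    rep(0L, length(.count_cols)), .count_cols))), na_row = FALSE)
  # per-exon candidate fragments via one batched overlap query per chrom
  res <- vector("list", nrow(ent))
  frsp <- fr$fragments
  for (cm in unique(ent$chrom)) {
    rows <- which(ent$chrom == cm)
    sub_f <- frsp[chrom == cm]
    for (i in rows[vapply(geoms[rows], is.null, TRUE)])
      res[[i]] <- count_exon(ent[i], NULL)
    rows <- rows[!vapply(geoms[rows], is.null, TRUE)]
    if (!length(rows)) next
    if (!nrow(sub_f)) { for (i in rows) res[[i]] <- zero_row(); next }
    sub_b <- fr$blocks[frag %chin% sub_f$frag]
    sub_j <- fr$junctions[frag %chin% sub_f$frag]
    data.table::setkey(sub_b, frag)
    data.table::setkey(sub_j, frag)
    fir <- IRanges::IRanges(sub_f$start, sub_f$end)
    w1 <- vapply(geoms[rows], function(g)
      min(g$up_intron[1], g$do_intron[1], g$ext[1]) - tol, 0)
    w2 <- vapply(geoms[rows], function(g)
      max(g$up_intron[2], g$do_intron[2], g$ext[2]) + tol, 0)
    hits <- IRanges::findOverlaps(IRanges::IRanges(w1, w2), fir)
    hl <- split(S4Vectors::subjectHits(hits),
                factor(S4Vectors::queryHits(hits), levels = seq_along(rows)))
    for (k in seq_along(rows)) {
      i <- rows[k]
      g <- geoms[[i]]
      idx <- hl[[k]]
      if (strandedness %in% c("forward", "reverse") && length(idx)) {
        implied <- if (strandedness == "forward") sub_f$strand1[idx]
                   else ifelse(sub_f$strand1[idx] == "+", "-", "+")
        idx <- idx[implied == ent$strand[i]]
      }
      if (!length(idx)) { res[[i]] <- zero_row(); next }
      ids <- sub_f$frag[idx]
      cl <- classify_fragment_set(g, ids, sub_b[.(ids), nomatch = NULL],
                                  sub_j[.(ids), nomatch = NULL],
                                  tol = tol, min_overlap = min_overlap)
      res[[i]] <- tally_classified(cl)
    }
  }
  counts <- data.table::rbindlist(res)
  out <- cbind(
    data.table(gene_id = ent$gene_id, chrom = ent$chrom,
               strand = ent$strand, exon_type = ent$exon_type),
    counts)
  add_metrics(out)
}
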
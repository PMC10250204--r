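#' @import data.table
#' @importFrom stats median rnorm runif rbinom setNames pbinom cor complete.cases
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".SD", "transcript_id", "gene_id", "chrom", "strand", "start",
  "end", "exon_rank", "entity", "J", "frag", "donor", "acceptor", "w",
  "qname", "paired", "first_in_pair", "read_strand", "long", "N", "V1"
))

#' Parse exon structures from a GTF annotation
#'
#' Reads the `exon` feature lines of an Ensembl-dialect GTF file and returns
#' one transcript model per `transcript_id`: a table of exon intervals with
#' exon rank assigned in transcription order (ascending coordinates on `+`,
#' descending on `-`).
#'
#' Lines that do not have nine tab-separated fields, or exon lines whose
#' attribute column lacks `gene_id`/`transcript_id`, are skipped with a
#' warning. A file without any exon feature is an error.
#'
#' @param path Path to a GTF file (plain text).
#' @return A `data.table` with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `exon_rank` (1 = first exon in transcription
#'   order). Coordinates are 1-based inclusive, as in the GTF.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (any(nf != 9)) {
    warning(sum(nf != 9), " malformed GTF line(s) skipped")
    lines <- lines[nf == 9]
  }
  if (!length(lines)) stop("no exon features in ", path)
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  dt <- data.table(
    chrom = f[[1]], feature = f[[3]],
    start = suppressWarnings(as.integer(f[[4]])),
    end = suppressWarnings(as.integer(f[[5]])),
    strand = f[[7]], attr = f[[9]]
  )
  dt <- dt[feature == "exon"]
  if (!nrow(dt)) stop("no exon features in ", path)
  bad <- is.na(dt$start) | is.na(dt$end) | !(dt$strand %chin% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " exon line(s) with unusable coordinates/strand skipped")
    dt <- dt[!bad]
  }
  attr_field <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, "\\s+\"([^\"]*)\""), a))
    out <- rep(NA_character_, length(a))
    hit <- lengths(regmatches(a, gregexpr(paste0(key, "\\s+\""), a))) > 0
    out[m != ""] <- sub(paste0(".*", key, "\\s+\"([^\"]*)\".*"), "\\1",
                        m[m != ""])
    ifelse(nzchar(out) & !is.na(out), out, NA_character_)
  }
  dt[, gene_id := attr_field(attr, "gene_id")]
  dt[, transcript_id := attr_field(attr, "transcript_id")]
  bad <- is.na(dt$gene_id) | is.na(dt$transcript_id)
  if (any(bad)) {
    warning(sum(bad), " exon line(s) without gene_id/transcript_id skipped")
    dt <- dt[!bad]
  }
  if (!nrow(dt)) stop("no exon features in ", path)
  dt[, attr := NULL][, feature := NULL]
  data.table::setorder(dt, transcript_id, start)
  dt[, exon_rank := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = transcript_id]
  data.table::setcolorder(
    dt, c("transcript_id", "gene_id", "chrom", "strand", "start", "end",
          "exon_rank"))
  dt[]
}

#' Cluster overlapping exons of a gene into exon entities
#'
#' Overlapping exon intervals from different transcripts of the same gene are
#' merged (single-linkage, >= 1 bp overlap) into one exon entity that carries
#' every distinct start and end coordinate of its members. For each entity
#' the coordinates of the immediately upstream/downstream neighbor exons --
#' in transcription orientation, taken over all member transcripts -- are
#' accumulated: the neighbor coordinate stored is the one abutting the
#' intervening intron (genomic end of the left neighbor on `+`, genomic start
#' of the right neighbor on `-`, and symmetrically downstream).
#'
#' Each entity also receives a positional `exon_type` (see
#' [classify_exon_type()]) and a retained-intron flag (see
#' [flag_retained_intron_entities()]).
#'
#' @param transcripts A `data.table` as returned by [parse_gtf()].
#' @return A `data.table` of entities with list columns `starts`, `ends`,
#'   `up_ends` (upstream-neighbor coordinates), `do_starts`
#'   (downstream-neighbor coordinates), plus `gene_id`, `chrom`, `strand`,
#'   `exon_type`, `retained_intron`.
#' @export
cluster_exons <- function(transcripts) {
  tr <- data.table::as.data.table(transcripts)
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand", "start",
                  "end", "exon_rank") %in% names(tr)))
  if (any(tr$start > tr$end)) stop("exon with start > end")
  res <- tr[, cluster_gene(.SD), by = .(gene_id, chrom)]
  res[]
}

# cluster exons of one gene (one chrom); errors on mixed-strand overlap
cluster_gene <- function(g) {
  if (length(unique(g$strand)) > 1) {
    ir <- IRanges::IRanges(g$start, g$end)
    hits <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (any(g$strand[qh] != g$strand[sh]))
      stop("overlapping exons on opposite strands within one gene")
  }
  out <- g[, cluster_strand(.SD, .BY$strand), by = strand]
  out
}

cluster_strand <- function(g, str) {
  g2 <- copy(g)
  # neighbor coords per member exon instance, in transcription order
  g2[, rnk := exon_rank]
  data.table::setorder(g2, transcript_id, rnk)
  g2[, `:=`(
    up_nb = if (str == "+") shift(end) else shift(start),
    do_nb = if (str == "+") shift(start, type = "lead")
            else shift(end, type = "lead")
  ), by = transcript_id]
  labs <- g2[, position_label(rnk, max(rnk)), by = transcript_id]$V1
  g2[, lab := labs]
  # retained-intron instances: an exon spanning, within the gene, two exons
  # adjacent in some transcript plus the intron between them (exact
  # boundaries). They are not true exons and are kept out of the clustering
  # of the real ones.
  data.table::setorder(g2, transcript_id, start)
  pairs <- g2[, if (.N > 1L) .(l_start = head(start, -1L),
                               l_end = head(end, -1L),
                               r_start = tail(start, -1L),
                               r_end = tail(end, -1L)),
              by = transcript_id]
  g2[, ri := FALSE]
  if (nrow(pairs)) {
    pairs <- pairs[l_end < r_start]   # genomic adjacency with a real intron
    if (nrow(pairs))
      g2[, ri := mapply(function(s, e)
        any(pairs$l_start == s & pairs$r_end == e), start, end)]
  }
  ent <- g2[, cluster_part(.SD), by = ri]
  data.table::setnames(ent, "ri", "retained_intron")
  data.table::setcolorder(ent, c("starts", "ends", "up_ends", "do_starts",
                                 "exon_type", "retained_intron"))
  ent[]
}

# cluster one homogeneous instance set (single-linkage, >=1 bp overlap)
cluster_part <- function(g2) {
  if (!nrow(g2)) return(NULL)
  ir <- IRanges::IRanges(g2$start, g2$end)
  red <- IRanges::reduce(ir)
  memb <- S4Vectors::subjectHits(
    IRanges::findOverlaps(ir, red, select = "all"))
  gg <- copy(g2)[, entity := memb]
  ent <- gg[, .(
    starts = list(sort(unique(start))),
    ends = list(sort(unique(end))),
    up_ends = list(sort(unique(up_nb[!is.na(up_nb)]))),
    do_starts = list(sort(unique(do_nb[!is.na(do_nb)]))),
    exon_type = if (length(unique(lab)) == 1L && unique(lab) != "ambig")
      unique(lab) else "diverse"
  ), by = entity]
  ent[, entity := NULL]
  ent[]
}

# positional label of exon ranks within one transcript of n exons
position_label <- function(rank, n) {
  if (n == 1L) return(rep("ambig", length(rank)))
  ifelse(rank == 1L, "first",
  ifelse(rank == n, "last",
  ifelse(rank == 2L, "sfrst",
  ifelse(rank == n - 1L, "slst", "internal"))))
}

#' Positional type of one exon entity
#'
#' An entity is labelled by the position its member exons occupy in the
#' transcripts where they appear: `first`, `sfrst` (second-first), `internal`,
#' `slst` (second-last) or `last` when all memberships agree, and `diverse`
#' otherwise. Label precedence within one transcript is first > last > sfrst
#' > slst (so the middle exon of a 3-exon transcript is `sfrst`); single-exon
#' transcripts contribute an ambiguous label that forces `diverse`.
#'
#' This is computed by [cluster_exons()]; the standalone function re-derives
#' the label of one entity for inspection.
#'
#' @param entity One row of the entity table (a `data.table`).
#' @param transcripts The transcript table the entity was derived from.
#' @return A character scalar, one of `first`, `sfrst`, `internal`, `slst`,
#'   `last`, `diverse`.
#' @export
classify_exon_type <- function(entity, transcripts) {
  tr <- data.table::as.data.table(transcripts)
  s <- min(entity$starts[[1]]); e <- max(entity$ends[[1]])
  memb <- tr[gene_id == entity$gene_id & chrom == entity$chrom &
             strand == entity$strand & start <= e & end >= s]
  if (!nrow(memb)) stop("entity not present in any transcript")
  n_by_tx <- tr[transcript_id %in% memb$transcript_id,
                .(n = max(exon_rank)), by = transcript_id]
  memb <- merge(memb, n_by_tx, by = "transcript_id")
  labs <- unique(mapply(function(r, n) position_label(r, n),
                        memb$exon_rank, memb$n))
  if (length(labs) == 1L && labs != "ambig") labs else "diverse"
}

#' Flag exon entities that are unspliced-intron (intron retention) variants
#'
#' An entity is flagged `retained_intron` when, within its gene, its interval
#' spans the full extent of two other entities plus the intron between them:
#' one of its starts equals a start of the genomically left entity `X`, one
#' of its ends equals an end of the right entity `Y`, and `X` is
#' upstream-adjacent to `Y` in some transcript (read off the entities'
#' neighbor coordinate sets). [cluster_exons()] already performs this
#' detection at the exon-instance level before clustering, so retained-intron
#' variants never merge with the exons they span; this standalone operation
#' applies the same rule to an arbitrary entity table. Flagged entities are
#' dropped from the exon table by default ([extract_exon_table()]).
#'
#' @param entities Entity table (list columns `starts`, `ends`, `up_ends`,
#'   `do_starts`).
#' @return The entity table with the logical `retained_intron` column set.
#' @export
flag_retained_intron_entities <- function(entities) {
  ent <- data.table::as.data.table(entities)
  flag <- rep(FALSE, nrow(ent))
  for (gid in unique(ent$gene_id)) {
    idx <- which(ent$gene_id == gid)
    if (length(idx) < 3L) next
    for (xi in idx) for (yi in idx) {
      if (xi == yi) next
      # X upstream-adjacent to Y: a downstream-neighbor coordinate of X is a
      # boundary of Y and vice versa (transcription orientation; on '-' the
      # genomic roles are mirrored)
      plus <- ent$strand[xi] == "+"
      adj <- if (plus)
        any(ent$do_starts[[xi]] %in% ent$starts[[yi]]) &&
        any(ent$up_ends[[yi]] %in% ent$ends[[xi]])
      else
        any(ent$do_starts[[xi]] %in% ent$ends[[yi]]) &&
        any(ent$up_ends[[yi]] %in% ent$starts[[xi]])
      if (!adj) next
      li <- if (plus) xi else yi   # genomically left entity of the pair
      ri <- if (plus) yi else xi
      for (k in idx) {
        if (k == xi || k == yi) next
        if (any(ent$starts[[k]] %in% ent$starts[[li]]) &&
            any(ent$ends[[k]] %in% ent$ends[[ri]]) &&
            min(ent$starts[[k]]) <= min(ent$starts[[li]]) &&
            max(ent$ends[[k]]) >= max(ent$ends[[ri]]))
          flag[k] <- TRUE
      }
    }
  }
  ent[, retained_intron := flag]
  ent[]
}

#' Build the exon-definition table from a GTF file
#'
#' Convenience wrapper: [parse_gtf()] then [cluster_exons()], dropping
#' retained-intron entities unless `keep_retained_introns = TRUE`.
#'
#' @param gtf Path to a GTF file.
#' @param keep_retained_introns Keep entities flagged as retained-intron
#'   variants (default `FALSE`).
#' @return An entity table ready for [write_exon_table()] / [aiso_count()].
#' @export
extract_exon_table <- function(gtf, keep_retained_introns = FALSE) {
  ent <- cluster_exons(parse_gtf(gtf))
  if (!keep_retained_introns) ent <- ent[retained_intron == FALSE]
  ent[]
}

.table_cols <- c("chrom", "strand", "exon_starts", "exon_ends",
                 "upstream_neighbor_ends", "downstream_neighbor_starts",
                 "gene_id", "exon_type")

#' Write / read the tab-separated exon-definition table
#'
#' The on-disk format has a `#`-prefixed header line and columns `chrom`,
#' `strand`, `exon_starts`, `exon_ends`, `upstream_neighbor_ends`,
#' `downstream_neighbor_starts`, `gene_id`, `exon_type`; multi-valued
#' coordinate fields are comma-separated, empty sets are empty strings.
#' Coordinates are 1-based inclusive. The row order of this table fixes the
#' row order of every downstream result table.
#'
#' @param entities Entity table ([cluster_exons()] output or equivalent).
#' @param path Output (input) file path.
#' @return `write_exon_table()` returns `path` invisibly; `read_exon_table()`
#'   returns the entity table with list columns `starts`, `ends`, `up_ends`,
#'   `do_starts`.
#' @export
write_exon_table <- function(entities, path) {
  ent <- data.table::as.data.table(entities)
  ser <- function(x) vapply(x, function(v) paste(v, collapse = ","), "")
  out <- data.table(
    chrom = ent$chrom, strand = ent$strand,
    exon_starts = ser(ent$starts), exon_ends = ser(ent$ends),
    upstream_neighbor_ends = ser(ent$up_ends),
    downstream_neighbor_starts = ser(ent$do_starts),
    gene_id = ent$gene_id, exon_type = ent$exon_type)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.table_cols, collapse = "\t")), con)
  if (nrow(out))
    writeLines(do.call(paste, c(as.list(out), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_exon_table
#' @export
read_exon_table <- function(path) {
  first <- readLines(path, n = 1L)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, skip = 1L,
                          colClasses = "character", fill = TRUE)
  if (!nrow(dt)) {
    dt <- data.table(matrix(character(), 0, length(.table_cols)))
  }
  if (ncol(dt) < length(.table_cols))
    stop("exon table missing column(s): ",
         paste(.table_cols[seq(ncol(dt) + 1L, length(.table_cols))],
               collapse = ", "))
  data.table::setnames(dt, .table_cols)
  de <- function(x) lapply(strsplit(x, ",", fixed = TRUE),
                           function(v) sort(as.integer(v[nzchar(v)])))
  ent <- data.table(
    gene_id = dt$gene_id, chrom = dt$chrom, strand = dt$strand,
    starts = de(dt$exon_starts), ends = de(dt$exon_ends),
    up_ends = de(dt$upstream_neighbor_ends),
    do_starts = de(dt$downstream_neighbor_starts),
    exon_type = dt$exon_type, retained_intron = FALSE)
  bad <- mapply(function(s, e) length(s) == 0L || length(e) == 0L ||
                  min(s) > min(e) || max(s) > max(e),
                ent$starts, ent$ends)
  if (any(bad)) stop("exon table row(s) with start > end or empty coordinates: ",
                     paste(which(bad), collapse = ", "))
  ent[]
}
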
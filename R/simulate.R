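#' Configuration for the read simulator
#'
#' Returns the simulation parameter list with the package's stated-world
#' defaults. The generator emulates the validation design used for AISO
#' quantifiers: per gene one focus internal exon, 10-20 partially spliced
#' pre-mRNA molecules with exactly one flanking intron of the focus exon
#' still retained, the proportion of downstream-retained molecules (the true
#' Fupfi) drawn uniformly from the grid 0, 0.1, ..., 1, and reads emitted as
#' exact pre-computed spliced alignments (no mapper, no sequencing error in
#' the alignments).
#'
#' @param n_genes Number of genes (default 100).
#' @param exons_per_gene Exons per transcript (default 5; odd values keep
#'   the focus exon centered).
#' @param exon_length_sampler Function `n -> n` exon lengths; default
#'   lognormal (meanlog log(130), sdlog 0.45) clamped to 20-400 nt, the
#'   scale of human internal exons.
#' @param focus_exon_length Optional vector of focus-exon lengths recycled
#'   across genes (default: drawn from `exon_length_sampler`).
#' @param intron_range Min/max intron length, uniform (default 300-1000 nt,
#'   a desk-scale stand-in for genomic intron sampling).
#' @param molecules_range Min/max molecules per gene (default 10-20).
#' @param fupfi_grid Grid of target Fupfi values (default 0, 0.1, ..., 1).
#' @param read_length Read length in nt (75 or 150 typical; default 150).
#' @param layout `"SE"` or `"PE"` (default `"PE"`).
#' @param insert_size Mean PE fragment length, 5' of read 1 to 3' of read 2
#'   (default 250); s.d. is 10 percent of the mean.
#' @param reads_per_molecule Reads (or read pairs) per molecule when placing
#'   uniformly (default 25).
#' @param tile_step When set, reads tile every `tile_step`-th start position
#'   instead of random placement (saturating depth when 1).
#' @param tile_focus_only With tiling, restrict starts to reads overlapping
#'   the focus exon plus both effective intron regions (default `TRUE`;
#'   positions elsewhere carry no ordering information).
#' @param strand_mode `"unstranded"` (default), `"forward"` or `"reverse"`
#'   library orientation of the emitted alignments.
#' @param prop_minus Proportion of genes placed on the minus strand
#'   (default 0.5).
#' @param p5_truncation,p3_truncation Long-read truncation switches: the
#'   probability that a read is 5'- (3'-) truncated is
#'   `1 - exp(-L / trunc_scale)` for molecule length `L`, the cut point
#'   uniform along the molecule.
#' @param trunc_scale Length scale of the truncation probability
#'   (default 3000 nt).
#' @param long_reads_per_molecule Long reads emitted per molecule
#'   (default 5).
#' @param seed Integer seed; fully determines the output.
#' @return A named list of parameters.
#' @export
sim_config <- function(n_genes = 100L, exons_per_gene = 5L,
                       exon_length_sampler = NULL,
                       focus_exon_length = NULL,
                       intron_range = c(300L, 1000L),
                       molecules_range = c(10L, 20L),
                       fupfi_grid = seq(0, 1, by = 0.1),
                       read_length = 150L,
                       layout = c("PE", "SE"),
                       insert_size = 250L,
                       reads_per_molecule = 25L,
                       tile_step = NULL,
                       tile_focus_only = TRUE,
                       strand_mode = c("unstranded", "forward", "reverse"),
                       prop_minus = 0.5,
                       p5_truncation = FALSE, p3_truncation = FALSE,
                       trunc_scale = 3000,
                       long_reads_per_molecule = 5L,
                       seed = 1L) {
  if (is.null(exon_length_sampler))
    exon_length_sampler <- function(n)
      as.integer(pmin(pmax(round(stats::rlnorm(n, log(130), 0.45)), 20L), 400L))
  stopifnot(intron_range[1] >= 1, intron_range[2] >= intron_range[1],
            molecules_range[1] >= 1, read_length >= 20)
  list(n_genes = as.integer(n_genes),
       exons_per_gene = as.integer(exons_per_gene),
       exon_length_sampler = exon_length_sampler,
       focus_exon_length = focus_exon_length,
       intron_range = as.integer(intron_range),
       molecules_range = as.integer(molecules_range),
       fupfi_grid = fupfi_grid,
       read_length = as.integer(read_length),
       layout = match.arg(layout),
       insert_size = as.integer(insert_size),
       reads_per_molecule = as.integer(reads_per_molecule),
       tile_step = tile_step, tile_focus_only = tile_focus_only,
       strand_mode = match.arg(strand_mode),
       prop_minus = prop_minus,
       p5_truncation = p5_truncation, p3_truncation = p3_truncation,
       trunc_scale = trunc_scale,
       long_reads_per_molecule = as.integer(long_reads_per_molecule),
       seed = as.integer(seed))
}

#' Simulate a gene annotation with one focus internal exon per gene
#'
#' Generates `n_genes` single-transcript genes on one synthetic contig
#' (2 kb intergenic spacing), derives the clustered exon-entity table, and
#' records which entity row is each gene's focus exon together with its
#' structural lengths. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] list.
#' @return A list: `transcripts` (as [parse_gtf()] output), `exons` (entity
#'   table), `truth` (per gene: `gene_id`, `exon_row`, `exon_len`,
#'   `up_intron_len`, `do_intron_len` in transcription orientation),
#'   `contig`, `contig_len`.
#' @export
# sample n integers uniformly from [a, b] (safe for a == b)
sample_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n)
  else sample(seq(as.integer(a), as.integer(b)), n, replace = TRUE)
}

simulate_annotation <- function(config) {
  set.seed(config$seed)
  ng <- config$n_genes
  ne <- config$exons_per_gene
  stopifnot(ne >= 3L)
  focus_idx <- (ne + 1L) %/% 2L
  contig <- "simA"
  strands <- ifelse(runif(ng) < config$prop_minus, "-", "+")
  txl <- vector("list", ng)
  truth <- vector("list", ng)
  cursor <- 2000L
  for (g in seq_len(ng)) {
    el <- config$exon_length_sampler(ne)
    if (!is.null(config$focus_exon_length))
      el[focus_idx] <- config$focus_exon_length[
        (g - 1L) %% length(config$focus_exon_length) + 1L]
    il <- sample_range(config$intron_range[1], config$intron_range[2],
                       ne - 1L)
    starts <- integer(ne); ends <- integer(ne)
    p <- cursor
    for (k in seq_len(ne)) {
      starts[k] <- p; ends[k] <- p + el[k] - 1L
      p <- ends[k] + (if (k < ne) il[k] else 0L) + 1L
    }
    cursor <- p + 2000L
    gid <- sprintf("g%04d", g)
    str <- strands[g]
    rank <- if (str == "+") seq_len(ne) else rev(seq_len(ne))
    txl[[g]] <- data.table(
      transcript_id = paste0(gid, ".t1"), gene_id = gid, chrom = contig,
      strand = str, start = starts, end = ends, exon_rank = rank)
    # introns in transcription orientation around the focus exon
    up_il <- if (str == "+") il[focus_idx - 1L] else il[focus_idx]
    do_il <- if (str == "+") il[focus_idx] else il[focus_idx - 1L]
    truth[[g]] <- data.table(
      gene_id = gid, strand = str,
      focus_start = starts[focus_idx], focus_end = ends[focus_idx],
      exon_len = el[focus_idx], up_intron_len = up_il,
      do_intron_len = do_il)
  }
  transcripts <- data.table::rbindlist(txl)
  truth <- data.table::rbindlist(truth)
  ent <- cluster_exons(transcripts)
  key <- paste(ent$gene_id, vapply(ent$starts, function(v) min(as.integer(v)), 0L))
  truth[, exon_row := match(paste(gene_id, focus_start), key)]
  stopifnot(!anyNA(truth$exon_row))
  list(transcripts = transcripts, exons = ent, truth = truth,
       contig = "simA", contig_len = cursor + 2000L)
}

#' Simulate partially spliced molecule populations
#'
#' For each gene, draws a target Fupfi from the configured grid and a
#' molecule count from `molecules_range`, then creates that many pre-mRNA
#' molecules in which exactly one flanking intron of the focus exon is still
#' retained while all other introns are spliced out. The number of
#' downstream-retained molecules (upstream-first evidence) is the target
#' Fupfi times the molecule count, rounded to the nearest integer.
#'
#' @param annotation [simulate_annotation()] output.
#' @param config [sim_config()] list.
#' @return A list: `molecules` (data.table: `mol`, `gene_id`, `strand`,
#'   `retained` in up/do, `blocks` list column of genomic intervals) and
#'   `truth` (annotation truth extended with `target_fupfi`, `n_mol`,
#'   `n_up_retained`, `n_do_retained`).
#' @export
simulate_molecules <- function(annotation, config) {
  set.seed(config$seed + 1L)
  tr <- annotation$transcripts
  truth <- copy(annotation$truth)
  nm <- sample_range(config$molecules_range[1], config$molecules_range[2],
                     nrow(truth))
  tgt <- config$fupfi_grid[sample.int(length(config$fupfi_grid),
                                      nrow(truth), replace = TRUE)]
  truth[, `:=`(n_mol = nm, target_fupfi = tgt)]
  truth[, n_do_retained := as.integer(round(target_fupfi * n_mol))]
  truth[, n_up_retained := n_mol - n_do_retained]
  mols <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    gid <- truth$gene_id[i]
    ex <- tr[gene_id == gid][order(start)]
    str <- truth$strand[i]
    fs <- truth$focus_start[i]; fe <- truth$focus_end[i]
    fidx <- which(ex$start == fs)
    # genomic interval of the retained intron for each side (transcription)
    ret_int <- function(side) {
      genomic_left <- (side == "up") == (str == "+")
      if (genomic_left) c(ex$end[fidx - 1L] + 1L, fs - 1L)
      else c(fe + 1L, ex$start[fidx + 1L] - 1L)
    }
    build <- function(side) {
      blocks <- data.table(start = ex$start, end = ex$end)
      ri <- ret_int(side)
      blocks <- rbind(blocks, data.table(start = ri[1], end = ri[2]))
      data.table::setorder(blocks, start)
      mb <- blocks[, merge_blocks(start, end)]
      data.table::setDT(mb)
    }
    n_up <- truth$n_up_retained[i]; n_do <- truth$n_do_retained[i]
    side <- c(rep("up", n_up), rep("do", n_do))
    mols[[i]] <- data.table(
      mol = sprintf("%s.m%02d", gid, seq_along(side)),
      gene_id = gid, strand = str, retained = side,
      blocks = lapply(side, build))
  }
  list(molecules = data.table::rbindlist(mols), truth = truth)
}

# molecule-coordinate machinery: blocks in transcription order with offsets
mol_layout <- function(blocks, strand) {
  b <- blocks
  if (strand == "-") b <- b[rev(seq_len(nrow(b)))]
  w <- b$end - b$start + 1L
  off <- cumsum(c(0L, head(w, -1L)))
  list(b = b, w = w, off = off, L = sum(w))
}

# genomic blocks (ascending) covered by molecule interval [a, b]
mol_interval_to_genomic <- function(lay, a, b, strand) {
  idx <- findInterval(a, lay$off + 1L):findInterval(b, lay$off + 1L)
  lo <- pmax(a, lay$off[idx] + 1L) - lay$off[idx]   # within-block, 1-based
  hi <- pmin(b, lay$off[idx] + lay$w[idx]) - lay$off[idx]
  if (strand == "+") {
    gs <- lay$b$start[idx] + lo - 1L
    ge <- lay$b$start[idx] + hi - 1L
  } else {
    gs <- lay$b$end[idx] - hi + 1L
    ge <- lay$b$end[idx] - lo + 1L
  }
  o <- order(gs)
  list(start = gs[o], end = ge[o])
}

# molecule-coordinate interval covered by a genomic window (may be empty)
genomic_window_to_mol <- function(lay, w1, w2, strand) {
  pos <- integer(0)
  for (i in seq_len(nrow(lay$b))) {
    s <- max(lay$b$start[i], w1); e <- min(lay$b$end[i], w2)
    if (s > e) next
    if (strand == "+") {
      pos <- c(pos, lay$off[i] + (s - lay$b$start[i]) + 1L,
               lay$off[i] + (e - lay$b$start[i]) + 1L)
    } else {
      pos <- c(pos, lay$off[i] + (lay$b$end[i] - e) + 1L,
               lay$off[i] + (lay$b$end[i] - s) + 1L)
    }
  }
  if (!length(pos)) return(NULL)
  c(min(pos), max(pos))
}

blocks_to_cigar <- function(bl) {
  n <- length(bl$start)
  parts <- character(2L * n - 1L)
  parts[seq(1L, 2L * n - 1L, by = 2L)] <-
    paste0(bl$end - bl$start + 1L, "M")
  if (n > 1L)
    parts[seq(2L, 2L * n - 2L, by = 2L)] <-
      paste0(bl$start[-1L] - bl$end[-n] - 1L, "N")
  paste(parts, collapse = "")
}

#' Simulate aligned short reads from molecule populations
#'
#' Places single-end reads or paired-end fragments along each molecule
#' (uniformly, or tiling every `tile_step` positions) and writes their exact
#' genomic spliced alignments to a coordinate-sorted, indexed BAM file. No
#' mapper is involved: alignments are computed from the molecule's splice
#' structure, so alignment is error-free by construction.
#'
#' @param molecules [simulate_molecules()] output.
#' @param annotation [simulate_annotation()] output (for contig header and
#'   focus windows).
#' @param config [sim_config()] list.
#' @param bam_prefix Output path prefix; `<prefix>.bam` and its index are
#'   created.
#' @return The BAM path, invisibly.
#' @export
simulate_short_reads <- function(molecules, annotation, config, bam_prefix) {
  set.seed(config$seed + 2L)
  rl <- config$read_length
  mt <- molecules$molecules
  focus_win <- NULL
  if (isTRUE(config$tile_focus_only) && !is.null(config$tile_step)) {
    tw <- molecules$truth
    eff <- pmin(tw$up_intron_len, tw$do_intron_len)
    focus_win <- data.table(gene_id = tw$gene_id,
                            w1 = tw$focus_start - eff,
                            w2 = tw$focus_end + eff)
    data.table::setkey(focus_win, gene_id)
  }
  buf <- vector("list", nrow(mt) + 1L)
  buf[[1L]] <- c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", annotation$contig,
                         annotation$contig_len))
  rid <- 0L
  for (i in seq_len(nrow(mt))) {
    str <- mt$strand[i]
    lay <- mol_layout(mt$blocks[[i]], str)
    L <- lay$L
    if (config$layout == "SE") {
      if (L < rl) next
      if (!is.null(config$tile_step)) {
        starts <- seq(1L, L - rl + 1L, by = config$tile_step)
        if (!is.null(focus_win)) {
          fw <- focus_win[.(mt$gene_id[i])]
          mi <- genomic_window_to_mol(lay, fw$w1, fw$w2, str)
          if (is.null(mi)) next
          starts <- starts[starts + rl - 1L >= mi[1] & starts <= mi[2]]
        }
      } else {
        starts <- sample.int(L - rl + 1L, config$reads_per_molecule,
                             replace = TRUE)
      }
      if (!length(starts)) next
      lines <- character(length(starts))
      for (k in seq_along(starts)) {
        s <- starts[k]
        bl <- mol_interval_to_genomic(lay, s, s + rl - 1L, str)
        flag <- if (sam_read_reverse(str, config$strand_mode)) 16L else 0L
        lines[k] <- sprintf("r%07d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                            rid + k, flag, annotation$contig, bl$start[1],
                            blocks_to_cigar(bl))
      }
      rid <- rid + length(starts)
      buf[[i + 1L]] <- lines
    } else {
      n <- config$reads_per_molecule
      fl <- pmax(rl, pmin(L, round(rnorm(n, config$insert_size,
                                         0.1 * config$insert_size))))
      smax <- L - fl + 1L
      ok <- smax >= 1L
      fl <- fl[ok]; smax <- smax[ok]
      if (!length(fl)) next
      st <- 1L + floor(runif(length(fl)) * smax)
      lines <- vector("list", length(fl))
      for (k in seq_along(fl)) {
        a <- st[k]; b <- a + fl[k] - 1L
        m1 <- mol_interval_to_genomic(lay, a, min(a + rl - 1L, b), str)
        m2 <- mol_interval_to_genomic(lay, max(b - rl + 1L, a), b, str)
        lines[[k]] <- sam_pair_records(sprintf("r%07d", rid + k),
                                       annotation$contig, m1, m2, str,
                                       config$strand_mode)
      }
      rid <- rid + length(fl)
      buf[[i + 1L]] <- unlist(lines, use.names = FALSE)
    }
  }
  sam_to_bam(unlist(buf, use.names = FALSE), bam_prefix)
}

# does the (single) read of this molecule map to the reverse genomic strand?
sam_read_reverse <- function(gene_strand, strand_mode) {
  if (strand_mode == "unstranded") return(runif(1) < 0.5)
  want <- if (strand_mode == "forward") gene_strand
          else if (gene_strand == "+") "-" else "+"
  want == "-"
}

# two SAM lines for a proper pair; m1 is the transcription-5' mate
sam_pair_records <- function(qname, contig, m1, m2, gene_strand,
                             strand_mode) {
  # genomic-left mate maps forward, right mate reverse (FR chemistry)
  left_first <- if (strand_mode == "unstranded") runif(1) < 0.5
                else if (strand_mode == "forward") gene_strand == "+"
                else gene_strand == "-"
  gm1 <- if (m1$start[1] <= m2$start[1]) m1 else m2   # genomic-left mate
  gm2 <- if (identical(gm1, m1)) m2 else m1
  tlen <- max(gm2$end) - gm1$start[1] + 1L
  f_left <- 1L + 2L + 32L + (if (left_first) 64L else 128L)
  f_right <- 1L + 2L + 16L + (if (left_first) 128L else 64L)
  c(sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
            qname, f_left, contig, gm1$start[1], blocks_to_cigar(gm1),
            gm2$start[1], tlen),
    sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t*\t*",
            qname, f_right, contig, gm2$start[1], blocks_to_cigar(gm2),
            gm1$start[1], -tlen))
}

sam_to_bam <- function(sam_lines, bam_prefix) {
  sam <- paste0(bam_prefix, ".sam")
  writeLines(sam_lines, sam)
  tmp <- Rsamtools::asBam(sam, paste0(bam_prefix, "_unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  Rsamtools::sortBam(tmp, bam_prefix)
  bam <- paste0(bam_prefix, ".bam")
  Rsamtools::indexBam(bam)
  unlink(c(sam, tmp))
  invisible(bam)
}

#' Simulate aligned long reads with optional 5'/3' truncations
#'
#' Emits `long_reads_per_molecule` single-end long reads per molecule. Each
#' read is the molecule's full extent unless truncated: with probability
#' `1 - exp(-L / trunc_scale)` a 5' (and/or 3') truncation removes a
#' uniform-length prefix (suffix) of the molecule, emulating broken or
#' still-transcribing RNA. Alignments are exact, as in
#' [simulate_short_reads()].
#'
#' @inheritParams simulate_short_reads
#' @return The BAM path, invisibly.
#' @export
simulate_long_reads <- function(molecules, annotation, config, bam_prefix) {
  set.seed(config$seed + 3L)
  mt <- molecules$molecules
  buf <- vector("list", nrow(mt) + 1L)
  buf[[1L]] <- c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", annotation$contig,
                         annotation$contig_len))
  rid <- 0L
  for (i in seq_len(nrow(mt))) {
    str <- mt$strand[i]
    lay <- mol_layout(mt$blocks[[i]], str)
    L <- lay$L
    p_trunc <- 1 - exp(-L / config$trunc_scale)
    lines <- character(0)
    for (k in seq_len(config$long_reads_per_molecule)) {
      a <- 1L; b <- L
      if (config$p5_truncation && runif(1) < p_trunc)
        a <- 1L + floor(runif(1) * L)
      if (config$p3_truncation && runif(1) < p_trunc)
        b <- a + floor(runif(1) * (L - a + 1L))
      if (b - a + 1L < 50L) next
      rid <- rid + 1L
      bl <- mol_interval_to_genomic(lay, a, b, str)
      flag <- if (sam_read_reverse(str, config$strand_mode)) 16L else 0L
      lines <- c(lines,
                 sprintf("L%07d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                         rid, flag, annotation$contig, bl$start[1],
                         blocks_to_cigar(bl)))
    }
    buf[[i + 1L]] <- lines
  }
  sam_to_bam(unlist(buf, use.names = FALSE), bam_prefix)
}

#' One-call simulation of an AISO validation dataset
#'
#' Runs [simulate_annotation()], [simulate_molecules()] and the requested
#' read generator, writing `exons.tsv`, `truth.tsv` and `reads.bam` (plus
#' index) under `out_dir`.
#'
#' @param config [sim_config()] list.
#' @param out_dir Output directory (created if needed).
#' @param reads `"short"` (default) or `"long"`.
#' @return A list with `exon_table`, `bam`, `truth` paths and the in-memory
#'   `annotation`, `molecules`, `truth` objects.
#' @export
simulate_dataset <- function(config, out_dir, reads = c("short", "long")) {
  reads <- match.arg(reads)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config)
  mol <- simulate_molecules(ann, config)
  bam <- if (reads == "short")
    simulate_short_reads(mol, ann, config, file.path(out_dir, "reads"))
  else
    simulate_long_reads(mol, ann, config, file.path(out_dir, "reads"))
  exon_path <- file.path(out_dir, "exons.tsv")
  write_exon_table(ann$exons, exon_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  tw <- copy(mol$truth)
  data.table::fwrite(tw, truth_path, sep = "\t")
  list(exon_table = exon_path, bam = bam, truth = truth_path,
       annotation = ann, molecules = mol)
}

#' Write transcript models to a GTF file
#'
#' Minimal Ensembl-dialect GTF writer (exon features only), the inverse of
#' [parse_gtf()] for simulated annotations.
#'
#' @param transcripts Transcript table ([parse_gtf()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  tr <- data.table::as.data.table(transcripts)
  lines <- sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    tr$chrom, tr$start, tr$end, tr$strand, tr$gene_id, tr$transcript_id)
  writeLines(lines, path)
  invisible(path)
}
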
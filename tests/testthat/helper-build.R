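# construction helpers: entities, fragment sets, tiny GTF/SAM files

make_entity <- function(starts, ends, up_ends = integer(0),
                        do_starts = integer(0), strand = "+",
                        gene_id = "g1", chrom = "chr1",
                        exon_type = "internal") {
  data.table::data.table(
    gene_id = gene_id, chrom = chrom, strand = strand,
    starts = list(sort(as.integer(starts))),
    ends = list(sort(as.integer(ends))),
    up_ends = list(sort(as.integer(up_ends))),
    do_starts = list(sort(as.integer(do_starts))),
    exon_type = exon_type, retained_intron = FALSE)
}

# build a read_fragments()-shaped evidence set from plain lists:
# frags = list(list(blocks = matrix/list of c(start,end), juncs = list of
# c(donor, acceptor)), ...)
make_fragments <- function(frags, chrom = "chr1", paired = FALSE) {
  bl <- list(); jx <- list(); sp <- list()
  for (i in seq_along(frags)) {
    id <- names(frags)[i]
    if (is.null(id) || !nzchar(id)) id <- paste0("f", i)
    b <- frags[[i]]$blocks
    b <- do.call(rbind, lapply(b, function(x) data.table::data.table(
      frag = id, start = as.integer(x[1]), end = as.integer(x[2]))))
    j <- frags[[i]]$juncs
    if (length(j)) {
      j <- do.call(rbind, lapply(j, function(x) data.table::data.table(
        frag = id, donor = as.integer(x[1]), acceptor = as.integer(x[2]))))
    } else {
      j <- data.table::data.table(frag = character(), donor = integer(),
                                  acceptor = integer())
    }
    bl[[i]] <- b; jx[[i]] <- j
    sp[[i]] <- data.table::data.table(
      frag = id, chrom = chrom, paired = paired, strand1 = "+",
      start = min(b$start), end = max(b$end), n_junc = nrow(j))
  }
  list(fragments = data.table::rbindlist(sp),
       blocks = data.table::rbindlist(bl),
       junctions = data.table::rbindlist(jx))
}

write_toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_exon <- function(chrom, start, end, strand, gene, tx) {
  sprintf('%s\tx\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start, end, strand, gene, tx)
}

# write SAM records (character vector of alignment lines) to an indexed BAM
sam_fixture <- function(records, contig = "chr1", contig_len = 100000L,
                        prefix = tempfile()) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, contig_len), records)
  aiso:::sam_to_bam(lines, prefix)
  paste0(prefix, ".bam")
}

sam_se <- function(qname, pos, cigar, flag = 0L, contig = "chr1",
                   mapq = 60L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
          qname, flag, contig, pos, mapq, cigar)
}
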
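test_that("parse_gtf builds transcript models with transcription-order ranks", {
  gtf <- write_toy_gtf(c(
    gtf_exon("chr1", 100, 200, "+", "gA", "t1"),
    gtf_exon("chr1", 300, 400, "+", "gA", "t1"),
    gtf_exon("chr1", 500, 600, "+", "gA", "t1"),
    gtf_exon("chr1", 100, 200, "+", "gA", "t2"),
    gtf_exon("chr1", 300, 400, "+", "gA", "t2"),
    gtf_exon("chr1", 500, 600, "+", "gA", "t2"),
    gtf_exon("chr1", 700, 800, "+", "gA", "t2")))
  tr <- parse_gtf(gtf)
  expect_equal(sort(unique(tr$transcript_id)), c("t1", "t2"))
  expect_equal(tr[transcript_id == "t1", .N], 3L)
  expect_equal(tr[transcript_id == "t2", .N], 4L)
  expect_equal(tr[transcript_id == "t2"][order(start)]$exon_rank, 1:4)
})

test_that("minus-strand exons are ranked in transcription order", {
  gtf <- write_toy_gtf(c(
    gtf_exon("chr1", 100, 200, "-", "gB", "t3"),
    gtf_exon("chr1", 300, 400, "-", "gB", "t3"),
    gtf_exon("chr1", 500, 600, "-", "gB", "t3")))
  tr <- parse_gtf(gtf)[order(start)]
  expect_equal(tr$exon_rank, 3:1)
})

test_that("GTF without exon features errors; malformed lines are skipped", {
  cds_only <- write_toy_gtf(
    'chr1\tx\tCDS\t10\t50\t.\t+\t.\tgene_id "g"; transcript_id "t";')
  expect_error(parse_gtf(cds_only), "no exon features")
  mixed <- write_toy_gtf(c(
    "this line is broken",
    gtf_exon("chr1", 100, 200, "+", "g", "t"),
    gtf_exon("chr1", 300, 350, "+", "g", "t")))
  expect_warning(tr <- parse_gtf(mixed), "malformed")
  expect_equal(nrow(tr), 2L)
})

test_that("cluster_exons merges alternative boundaries into one entity", {
  tr <- parse_gtf(write_toy_gtf(c(
    gtf_exon("chr1", 1, 50, "+", "g", "t1"),
    gtf_exon("chr1", 100, 200, "+", "g", "t1"),
    gtf_exon("chr1", 300, 400, "+", "g", "t1"),
    gtf_exon("chr1", 1, 50, "+", "g", "t2"),
    gtf_exon("chr1", 100, 210, "+", "g", "t2"),
    gtf_exon("chr1", 300, 400, "+", "g", "t2"))))
  ent <- cluster_exons(tr)
  mid <- ent[vapply(starts, function(s) 100L %in% s, TRUE)]
  expect_equal(nrow(mid), 1L)
  expect_equal(mid$starts[[1]], 100L)
  expect_equal(mid$ends[[1]], c(200L, 210L))
})

test_that("entities of different genes are never merged", {
  tr <- parse_gtf(write_toy_gtf(c(
    gtf_exon("chr1", 100, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 100, 200, "+", "g2", "t2"))))
  ent <- cluster_exons(tr)
  expect_equal(nrow(ent), 2L)
  expect_setequal(ent$gene_id, c("g1", "g2"))
})

test_that("neighbor coordinate sets accumulate over member transcripts", {
  # A: [1,50]-[100,200]-[300,400]; B: [1,50]-[100,200]-[500,600]
  tr <- parse_gtf(write_toy_gtf(c(
    gtf_exon("chr1", 1, 50, "+", "g", "A"),
    gtf_exon("chr1", 100, 200, "+", "g", "A"),
    gtf_exon("chr1", 300, 400, "+", "g", "A"),
    gtf_exon("chr1", 1, 50, "+", "g", "B"),
    gtf_exon("chr1", 100, 200, "+", "g", "B"),
    gtf_exon("chr1", 500, 600, "+", "g", "B"))))
  ent <- cluster_exons(tr)
  mid <- ent[vapply(starts, function(s) 100L %in% s, TRUE)]
  expect_equal(mid$do_starts[[1]], c(300L, 500L))
  expect_equal(mid$up_ends[[1]], 50L)
})

test_that("overlapping exons on opposite strands of one gene error", {
  tr <- parse_gtf(write_toy_gtf(c(
    gtf_exon("chr1", 100, 200, "+", "g", "t1"),
    gtf_exon("chr1", 150, 250, "-", "g", "t2"))))
  expect_error(cluster_exons(tr), "opposite strands")
})

test_that("exon typing follows positional labels with diverse fallback", {
  # 5-exon transcript: ranks 1..5 -> first sfrst internal slst last
  lines <- unlist(lapply(1:5, function(k)
    gtf_exon("chr1", k * 1000, k * 1000 + 100, "+", "g", "t1")))
  ent <- cluster_exons(parse_gtf(write_toy_gtf(lines)))[order(
    vapply(starts, min, 0L))]
  expect_equal(ent$exon_type,
               c("first", "sfrst", "internal", "slst", "last"))
})

test_that("position-2 vs position-3 membership gives diverse", {
  lines <- c(
    unlist(lapply(1:5, function(k)
      gtf_exon("chr1", k * 1000, k * 1000 + 100, "+", "g", "tA"))),
    # tB has an extra 5'-most exon, shifting the shared exons by one position
    gtf_exon("chr1", 500, 600, "+", "g", "tB"),
    unlist(lapply(1:5, function(k)
      gtf_exon("chr1", k * 1000, k * 1000 + 100, "+", "g", "tB"))))
  ent <- cluster_exons(parse_gtf(write_toy_gtf(lines)))[order(
    vapply(starts, min, 0L))]
  # exon at 2000 is sfrst in tA but internal (pos 3 of 6) in tB
  expect_equal(ent[vapply(starts, function(s) 2000L %in% s, TRUE)]$exon_type,
               "diverse")
})

test_that("single-exon transcripts force diverse typing", {
  ent <- cluster_exons(parse_gtf(write_toy_gtf(
    gtf_exon("chr1", 100, 200, "+", "g", "t1"))))
  expect_equal(ent$exon_type, "diverse")
})

test_that("classify_exon_type matches cluster_exons labels", {
  tr <- parse_gtf(write_toy_gtf(unlist(lapply(1:5, function(k)
    gtf_exon("chr1", k * 1000, k * 1000 + 100, "+", "g", "t1")))))
  ent <- cluster_exons(tr)[order(vapply(starts, min, 0L))]
  for (i in seq_len(nrow(ent)))
    expect_equal(classify_exon_type(ent[i], tr), ent$exon_type[i])
  orphan <- make_entity(99000, 99100, gene_id = "g")
  expect_error(classify_exon_type(orphan, tr), "not present")
})

test_that("retained-intron entities are flagged and dropped by default", {
  lines <- c(
    gtf_exon("chr1", 100, 200, "+", "g", "t1"),
    gtf_exon("chr1", 300, 400, "+", "g", "t1"),
    gtf_exon("chr1", 100, 400, "+", "g", "t2"))   # unspliced variant
  tr <- parse_gtf(write_toy_gtf(lines))
  ent <- cluster_exons(tr)
  expect_true(any(ent$retained_intron))
  # but the retained-intron interval overlaps its parts, so clustering merges
  # them; use non-overlapping genes to verify scoping instead
  lines2 <- c(
    gtf_exon("chr1", 100, 200, "+", "g1", "t1"),
    gtf_exon("chr1", 300, 400, "+", "g1", "t1"),
    gtf_exon("chr2", 100, 400, "+", "g2", "t2"))
  ent2 <- cluster_exons(parse_gtf(write_toy_gtf(lines2)))
  expect_false(any(ent2$retained_intron))
})

test_that("every input exon is contained in exactly one entity of its gene", {
  set.seed(7)
  cfg <- sim_config(n_genes = 15, seed = 7)
  ann <- simulate_annotation(cfg)
  tr <- ann$transcripts
  ent <- ann$exons
  for (i in seq_len(nrow(tr))) {
    hits <- which(ent$gene_id == tr$gene_id[i] &
                  vapply(ent$starts, min, 0L) <= tr$start[i] &
                  vapply(ent$ends, max, 0L) >= tr$end[i])
    expect_length(hits, 1L)
  }
})

test_that("exon table round-trips losslessly", {
  set.seed(11)
  ents <- data.table::rbindlist(lapply(1:100, function(i) {
    s <- sort(sample(1000:100000, sample(1:3, 1)))
    make_entity(s, s + sample(20:200, length(s)),
                up_ends = sample(500:900, sample(0:2, 1)),
                do_starts = sample(200000:300000, sample(0:2, 1)),
                strand = sample(c("+", "-"), 1),
                gene_id = paste0("g", i))
  }))
  path <- tempfile(fileext = ".tsv")
  write_exon_table(ents, path)
  back <- read_exon_table(path)
  for (col in c("gene_id", "chrom", "strand", "exon_type"))
    expect_equal(back[[col]], ents[[col]])
  for (col in c("starts", "ends", "up_ends", "do_starts"))
    expect_equal(back[[col]], lapply(ents[[col]], as.integer))
  # writing the re-read table reproduces the file byte-for-byte
  path2 <- tempfile(fileext = ".tsv")
  write_exon_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("exon table validation errors", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstrand\texon_starts", "chr1\t+\t100"), bad)
  expect_error(read_exon_table(bad), "missing column")
  swapped <- tempfile(fileext = ".tsv")
  writeLines(c(paste0("#", paste(aiso:::.table_cols, collapse = "\t")),
               "chr1\t+\t500\t400\t100\t900\tg\tinternal"), swapped)
  expect_error(read_exon_table(swapped), "start > end")
})
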
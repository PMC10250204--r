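# canonical plus-strand scene used across tests:
# neighbor [1000,1119] --(intron 500)-- exon [1620,1719] --(intron 3000)--
# neighbor [4720,4839]; effective length 500 on both sides
plus_entity <- function() make_entity(1620, 1719, up_ends = 1119,
                                      do_starts = 4720)

test_that("effective regions trim both introns to the shorter one", {
  g <- effective_regions(plus_entity())
  expect_equal(g$effective_length, 500L)
  expect_equal(g$up_region, c(1120L, 1619L))
  expect_equal(g$do_region, c(1720L, 2219L))   # first 500 nt after exon end
  expect_equal(g$up_intron, c(1120L, 1619L))
  expect_equal(g$do_intron, c(1720L, 4719L))

  # equal introns: regions are the full introns
  e2 <- make_entity(2000, 2099, up_ends = 999, do_starts = 3100)
  g2 <- effective_regions(e2)
  expect_equal(g2$effective_length, 1000L)
  expect_equal(g2$up_region, g2$up_intron)
  expect_equal(g2$do_region, g2$do_intron)

  # multiple downstream neighbor starts: nearest defines the full intron
  e3 <- make_entity(701, 1000, up_ends = 400, do_starts = c(1500, 2000))
  g3 <- effective_regions(e3)
  expect_equal(g3$do_intron, c(1001L, 1499L))
  expect_equal(g3$effective_length, 300L)
  expect_equal(g3$do_region, c(1001L, 1300L))

  # missing neighbor on either side -> no regions
  expect_null(effective_regions(make_entity(100, 200, up_ends = 50)))
  expect_null(effective_regions(make_entity(100, 200, do_starts = 300)))
})

test_that("minus-strand geometry mirrors the plus-strand one", {
  # transcription right-to-left: upstream neighbor at [4720,4839]
  e <- make_entity(1620, 1719, up_ends = 4720, do_starts = 1119,
                   strand = "-")
  g <- effective_regions(e)
  expect_equal(g$up_intron, c(1720L, 4719L))
  expect_equal(g$do_intron, c(1120L, 1619L))
  expect_equal(g$effective_length, 500L)
  expect_equal(g$up_region, c(1720L, 2219L))
  expect_equal(g$do_region, c(1120L, 1619L))
})

test_that("intronic evidence needs min_overlap and no contradicting junction", {
  g <- effective_regions(plus_entity())
  jnone <- data.table::data.table(donor = integer(), acceptor = integer())
  b50 <- data.table::data.table(start = 1800L, end = 1849L)
  expect_true(intronic_evidence(b50, jnone, g$do_region, g$do_intron))
  # 3 nt overlap below the 6 nt default
  b3 <- data.table::data.table(start = 2217L, end = 2400L)
  expect_false(intronic_evidence(b3, jnone, g$do_region, g$do_intron))
  # junction splicing the whole intron contradicts the block
  jspl <- data.table::data.table(donor = 1719L, acceptor = 4720L)
  expect_false(intronic_evidence(b50, jspl, g$do_region, g$do_intron))
})

test_that("junction evidence fuzzy-matches exon and neighbor boundaries", {
  e <- plus_entity()
  exact <- data.table::data.table(donor = 1119L, acceptor = 1620L)
  expect_true(junction_evidence(exact, e, "up"))
  off2 <- data.table::data.table(donor = 1119L, acceptor = 1622L)
  expect_true(junction_evidence(off2, e, "up", tol = 3L))
  off4 <- data.table::data.table(donor = 1119L, acceptor = 1624L)
  expect_false(junction_evidence(off4, e, "up", tol = 3L))
  # donor matching an unrelated coordinate is not evidence
  wrong <- data.table::data.table(donor = 900L, acceptor = 1620L)
  expect_false(junction_evidence(wrong, e, "up"))
  do_exact <- data.table::data.table(donor = 1719L, acceptor = 4720L)
  expect_true(junction_evidence(do_exact, e, "do"))
})

test_that("classify_fragment reproduces the four configurations", {
  e <- plus_entity()
  # upfi: upstream junction + block in downstream effective region
  up <- classify_fragment(
    data.table::data.table(start = c(1100L, 1620L), end = c(1119L, 1760L)),
    data.table::data.table(donor = 1119L, acceptor = 1620L), e)
  expect_equal(up$category, "upfi")
  # dofi: block in upstream region + downstream junction
  dofi <- classify_fragment(
    data.table::data.table(start = c(1500L, 1700L), end = c(1719L, 1719L)),
    data.table::data.table(donor = 1719L, acceptor = 4720L), e)
  expect_equal(dofi$category, "dofi")
  # bus: one contiguous read across both exon boundaries
  bus <- classify_fragment(
    data.table::data.table(start = 1600L, end = 1740L),
    data.table::data.table(donor = integer(), acceptor = integer()), e)
  expect_equal(bus$category, "bus")
  expect_true(bus$ei_up && bus$ei_do)
  # bos: junctions on both sides
  bos <- classify_fragment(
    data.table::data.table(start = c(1100L, 1620L, 4720L),
                           end = c(1119L, 1719L, 4760L)),
    data.table::data.table(donor = c(1119L, 1719L),
                           acceptor = c(1620L, 4720L)), e)
  expect_equal(bos$category, "bos")
  expect_true(bos$j_up && bos$j_do)
})

test_that("contradictory fragments are discarded", {
  e <- plus_entity()
  # junction splices the downstream intron but a block sits inside it
  x <- classify_fragment(
    data.table::data.table(start = c(1620L, 1900L), end = c(1719L, 1960L)),
    data.table::data.table(donor = 1719L, acceptor = 4720L), e)
  expect_equal(x$category, "none")
  expect_true(x$discarded)
})

test_that("skip junctions count without touching the exon", {
  e <- plus_entity()
  fr <- make_fragments(list(
    sk = list(blocks = list(c(1080, 1119), c(4720, 4770)),
              juncs = list(c(1119, 4720)))))
  cnt <- count_exon(e, fr)
  expect_equal(cnt$skip, 1L)
  expect_equal(cnt$upfi + cnt$dofi + cnt$bus + cnt$bos, 0L)
})

test_that("count_exon tallies fragment sets and handles edge cases", {
  e <- plus_entity()
  expect_equal(count_exon(e, NULL)$upfi, 0L)
  noneigh <- make_entity(100, 200)
  z <- count_exon(noneigh, NULL)
  expect_true(z$na_row)
  # all-bos input
  fr <- make_fragments(lapply(1:5, function(i) list(
    blocks = list(c(1100, 1119), c(1620, 1719), c(4720, 4760)),
    juncs = list(c(1119, 1620), c(1719, 4720)))))
  cnt <- count_exon(e, fr)
  expect_equal(cnt$bos, 5L)
  expect_equal(cnt$upfi + cnt$dofi + cnt$bus, 0L)
  expect_equal(cnt$inup, 5L)
  expect_equal(cnt$indo, 5L)
})

test_that("category exclusivity and upfi monotonicity hold", {
  set.seed(202)
  for (s in 1:10) {
    sc <- random_scene(s)
    g <- aiso:::entity_geometry(sc$entity)
    ids <- unique(sc$fragments$blocks$frag)
    cl <- aiso:::classify_fragment_set(g, ids, sc$fragments$blocks,
                                       sc$fragments$junctions)
    expect_true(all(table(cl$frag[cl$category != "none"]) == 1))
    # monotonicity: adding one upfi fragment
    base <- count_exon(sc$entity, sc$fragments)
    ex_l <- min(sc$entity$starts[[1]]); ex_r <- max(sc$entity$ends[[1]])
    plus <- sc$entity$strand == "+"
    upfi_frag <- if (plus) list(
      blocks = list(c(sc$entity$up_ends[[1]] - 30, sc$entity$up_ends[[1]]),
                    c(ex_l, ex_r + 20)),
      juncs = list(c(sc$entity$up_ends[[1]], ex_l)))
    else list(
      blocks = list(c(sc$entity$up_ends[[1]], sc$entity$up_ends[[1]] + 30),
                    c(ex_l - 20, ex_r)),
      juncs = list(c(ex_r, sc$entity$up_ends[[1]])))
    aug <- sc$fragments
    extra <- make_fragments(list(xtra = upfi_frag))
    aug$fragments <- rbind(aug$fragments, extra$fragments)
    aug$blocks <- rbind(aug$blocks, extra$blocks)
    aug$junctions <- rbind(aug$junctions, extra$junctions)
    after <- count_exon(sc$entity, aug)
    expect_gte(after$upfi, base$upfi)
    expect_equal(after$dofi, base$dofi)
  }
})

test_that("counts match the brute-force oracle on random micro-scenes", {
  for (s in 1:20) {
    sc <- random_scene(1000 + s)
    mine <- count_exon(sc$entity, sc$fragments)
    orc <- oracle_counts(sc$entity, sc$fragments)
    for (f in c("upfi", "dofi", "bus", "bos", "skip", "inup", "indo",
                "discarded"))
      expect_equal(mine[[f]], orc[[f]], label = paste(f, "scene", s),
                   ignore_attr = TRUE)
  }
})

test_that("aiso_count preserves row order and NA semantics end-to-end", {
  ents <- rbind(plus_entity(),
                make_entity(9000, 9100, gene_id = "gNA"),  # no neighbors
                make_entity(20000, 20100, up_ends = 19500,
                            do_starts = 20600, gene_id = "g2"))
  recs <- c(
    # one upfi fragment at the first exon
    sam_se("u1", 1100, "20M500N100M41M"),
    # one bus fragment at the third exon
    sam_se("b1", 19950, "200M"))
  bam <- sam_fixture(recs)
  res <- aiso_count(ents, bam = bam)
  expect_equal(nrow(res), 3L)
  expect_equal(res$gene_id, c("g1", "gNA", "g2"))
  expect_equal(res$upfi[1], 1L)
  expect_true(is.na(res$fupfi[2]))
  expect_equal(res$bus[3], 1L)
  # output table round-trip with NA literals
  out <- tempfile(fileext = ".tsv")
  write_aiso_table(res, out, n_input = 3L)
  back <- read_aiso_table(out)
  expect_equal(back$fupfi, res$fupfi)
  expect_error(write_aiso_table(res, out, n_input = 5L), "mismatch")
})

test_that("stranded counting ignores antisense fragments", {
  e <- plus_entity()
  # sense read (forward library, '+' gene -> read on '+') and antisense copy
  sense <- sam_se("s", 1100, "20M500N100M41M", flag = 0L)
  anti <- sam_se("a", 1100, "20M500N100M41M", flag = 16L)
  bam <- sam_fixture(c(sense, anti))
  res_unstr <- aiso_count(e, bam = bam, strandedness = "unstranded")
  expect_equal(res_unstr$upfi, 2L)
  res_fwd <- aiso_count(e, bam = bam, strandedness = "forward")
  expect_equal(res_fwd$upfi, 1L)
})
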
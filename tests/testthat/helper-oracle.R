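# Independent brute-force oracles. Deliberately naive implementations that
# share no code with the package: base-by-base CIGAR walking and literal
# per-fragment configuration logic.

# one-base-at-a-time CIGAR interpreter
oracle_cigar <- function(cigar, pos) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  ref <- pos
  aligned <- integer(0)       # every aligned reference base
  junc <- list()
  for (t in toks) {
    n <- as.integer(sub("[A-Z=]$", "", t))
    op <- sub("^[0-9]+", "", t)
    for (k in seq_len(n)) {
      if (op %in% c("M", "=", "X", "D")) {
        aligned <- c(aligned, ref)
        ref <- ref + 1L
      } else if (op == "N") {
        if (k == 1L) junc[[length(junc) + 1L]] <- c(ref - 1L, NA)
        ref <- ref + 1L
        if (k == n) junc[[length(junc)]][2] <- ref
      }
      # other ops: nothing on the reference
    }
  }
  # blocks = runs of consecutive aligned bases
  blocks <- NULL
  if (length(aligned)) {
    brk <- c(0L, which(diff(aligned) != 1L), length(aligned))
    blocks <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i)
      c(aligned[brk[i] + 1L], aligned[brk[i + 1L]])))
  }
  list(blocks = blocks, junctions = junc)
}

# literal configuration-diagram classifier for one exon and a fragment set;
# fragments as produced by make_fragments()
oracle_counts <- function(entity, fr, tol = 3L, min_overlap = 6L) {
  starts <- entity$starts[[1]]; ends <- entity$ends[[1]]
  upv <- entity$up_ends[[1]]; dov <- entity$do_starts[[1]]
  plus <- entity$strand == "+"
  ex_l <- min(starts); ex_r <- max(ends)
  near <- function(x, set) length(set) > 0 && any(abs(x - set) <= tol)
  if (plus) {
    up_int <- c(max(upv) + 1L, ex_l - 1L)
    do_int <- c(ex_r + 1L, min(dov) - 1L)
  } else {
    up_int <- c(ex_r + 1L, min(upv) - 1L)
    do_int <- c(max(dov) + 1L, ex_l - 1L)
  }
  el <- min(up_int[2] - up_int[1], do_int[2] - do_int[1]) + 1L
  if (length(upv) == 0 || length(dov) == 0 || el < 1)
    return(NULL)
  # effective regions hug the exon
  regs <- list()
  if (plus) {
    regs$up <- c(ex_l - el, ex_l - 1L); regs$do <- c(ex_r + 1L, ex_r + el)
  } else {
    regs$up <- c(ex_r + 1L, ex_r + el); regs$do <- c(ex_l - el, ex_l - 1L)
  }
  cnt <- list(upfi = 0, dofi = 0, bus = 0, bos = 0, skip = 0, inup = 0,
              indo = 0, discarded = 0)
  for (id in unique(fr$blocks$frag)) {
    b <- fr$blocks[fr$blocks$frag == id, ]
    j <- fr$junctions[fr$junctions$frag == id, ]
    jup <- FALSE; jdo <- FALSE; jskip <- FALSE
    sup <- FALSE; sdo <- FALSE
    if (nrow(j)) for (r in seq_len(nrow(j))) {
      d <- j$donor[r]; a <- j$acceptor[r]
      if (plus) {
        if (near(d, upv) && near(a, starts)) jup <- TRUE
        if (near(d, ends) && near(a, dov)) jdo <- TRUE
        if (near(d, upv) && near(a, dov)) jskip <- TRUE
      } else {
        if (near(d, ends) && near(a, upv)) jup <- TRUE
        if (near(d, dov) && near(a, starts)) jdo <- TRUE
        if (near(d, dov) && near(a, upv)) jskip <- TRUE
      }
      if (d + 1L <= up_int[1] + tol && a - 1L >= up_int[2] - tol) sup <- TRUE
      if (d + 1L <= do_int[1] + tol && a - 1L >= do_int[2] - tol) sdo <- TRUE
    }
    bup <- FALSE; bdo <- FALSE
    for (r in seq_len(nrow(b))) {
      if (min(b$end[r], regs$up[2]) - max(b$start[r], regs$up[1]) + 1L >=
          min_overlap) bup <- TRUE
      if (min(b$end[r], regs$do[2]) - max(b$start[r], regs$do[1]) + 1L >=
          min_overlap) bdo <- TRUE
    }
    if ((bup && sup) || (bdo && sdo)) {
      cnt$discarded <- cnt$discarded + 1
      next
    }
    iup <- bup && !sup
    ido <- bdo && !sdo
    if (jup && jdo) cnt$bos <- cnt$bos + 1
    else if (jup && ido) cnt$upfi <- cnt$upfi + 1
    else if (iup && jdo) cnt$dofi <- cnt$dofi + 1
    else if (iup && ido) cnt$bus <- cnt$bus + 1
    if (jup) cnt$inup <- cnt$inup + 1
    if (jdo) cnt$indo <- cnt$indo + 1
    if (jskip) cnt$skip <- cnt$skip + 1
  }
  cnt
}

# random micro-scene generator for oracle-equivalence tests: one internal
# exon with neighbors, random fragments with blocks/junctions around it
random_scene <- function(seed) {
  set.seed(seed)
  strand <- sample(c("+", "-"), 1)
  ex_len <- sample(30:200, 1)
  iu <- sample(60:400, 1); idn <- sample(60:400, 1)
  nb_len <- 120L
  # genomic layout left-to-right: nbL | intronL | exon | intronR | nbR
  nbL_s <- 1000L; nbL_e <- nbL_s + nb_len - 1L
  ex_s <- nbL_e + iu + 1L; ex_e <- ex_s + ex_len - 1L
  nbR_s <- ex_e + idn + 1L; nbR_e <- nbR_s + nb_len - 1L
  if (strand == "+") {
    ent <- make_entity(ex_s, ex_e, up_ends = nbL_e, do_starts = nbR_s,
                       strand = "+")
  } else {
    ent <- make_entity(ex_s, ex_e, up_ends = nbR_s, do_starts = nbL_e,
                       strand = "-")
  }
  n_frag <- sample(5:50, 1)
  frags <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    # random evidence: 1-2 blocks anywhere in the locus, 0-2 junctions with
    # boundaries jittered around annotated coordinates (or random)
    nb <- sample(1:2, 1)
    blocks <- lapply(seq_len(nb), function(k) {
      s <- sample(nbL_s:(nbR_e - 20L), 1)
      c(s, s + sample(10:150, 1))
    })
    nj <- sample(0:2, 1)
    coords <- c(nbL_e, ex_s, ex_e, nbR_s)
    juncs <- if (nj > 0) lapply(seq_len(nj), function(k) {
      d <- sample(coords, 1) + sample(-5:5, 1)
      a <- sample(coords, 1) + sample(-5:5, 1)
      if (a <= d) a <- d + sample(30:200, 1)
      c(d, a)
    }) else list()
    frags[[i]] <- list(blocks = blocks, juncs = juncs)
  }
  list(entity = ent, fragments = make_fragments(frags))
}
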
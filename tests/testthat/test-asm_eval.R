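test_that("scaffolds split at >=10 N runs and reassemble byte-for-byte", {
  s9 <- paste0("ACGT", strrep("N", 9), "ACGT")
  s10 <- paste0("ACGT", strrep("N", 10), "ACGT")
  c9 <- break_scaffolds(c(sc = s9))
  expect_equal(nrow(c9), 1L)
  expect_equal(c9$length, 17L)
  c10 <- break_scaffolds(c(sc = s10))
  expect_equal(nrow(c10), 2L)
  expect_equal(c10$length, c(4L, 4L))
  expect_equal(c10$offset, c(0L, 14L))
  ## round trip on random scaffolds with mixed gap sizes
  set.seed(5)
  for (i in 1:10) {
    pieces <- replicate(sample(2:5, 1), paste(
      sample(c("A", "C", "G", "T"), sample(20:80, 1), TRUE), collapse = ""))
    gaps <- vapply(seq_len(length(pieces) - 1L),
                   function(j) strrep("N", sample(c(3, 9, 10, 25), 1)), "")
    scaffold <- paste0(paste0(pieces[-length(pieces)], gaps, collapse = ""),
                       pieces[length(pieces)])
    ctg <- break_scaffolds(c(sc = scaffold))
    rebuilt <- rep("N", nchar(scaffold))
    for (j in seq_len(nrow(ctg))) {
      rebuilt[(ctg$offset[j] + 1):(ctg$offset[j] + ctg$length[j])] <-
        strsplit(ctg$seq[j], "")[[1]]
    }
    expect_identical(paste(rebuilt, collapse = ""), scaffold)
  }
  ## haplotype labels parse from name suffixes
  labs <- break_scaffolds(c(`sA/1` = "ACGTACGT", `sB/2` = "ACGTACGT",
                            sC_hap1 = "ACGTACGT", sD = "ACGTACGT"))
  expect_equal(labs$haplotype, c("1", "2", "1", "unphased"))
})

test_that("nx matches a brute-force threshold scan", {
  expect_equal(nx(7), 7)
  expect_equal(nx(c(5, 4, 3, 2, 1)), 4)
  expect_error(nx(numeric(0)), "empty")
  expect_error(nx(c(1, 0)), "positive")
  set.seed(6)
  for (i in 1:1000) {
    L <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    x <- sample(c(10, 50, 90), 1)
    expect_identical(nx(L, x), as.numeric(nx_oracle(L, x)))
  }
  ## monotone in x: N50 >= N90
  for (i in 1:20) {
    L <- sample(1:5000, 30, replace = TRUE)
    expect_gte(nx(L, 50), nx(L, 90))
  }
})

test_that("misassembly breaking follows the three breakpoint rules", {
  ## single full-length block: untouched
  b1 <- alignment_blocks("q", 10000, 0, 10000, "chr1", 0, 10000)
  expect_equal(break_at_misassemblies(b1), 10000)
  ## different target contigs: split at the query midpoint
  b2 <- alignment_blocks(c("q", "q"), 10000, c(0, 5000), c(5000, 10000),
                         c("chr1", "chr2"), c(0, 0), c(5000, 5000))
  expect_equal(sort(break_at_misassemblies(b2)), c(5000, 5000))
  ## collinear with a consistent 100 bp gap: no break
  b3 <- alignment_blocks(c("q", "q"), 10000, c(0, 5100), c(5000, 10000),
                         "chr1", c(0, 5100), c(5000, 10000))
  expect_equal(break_at_misassemblies(b3, max_gap_bp = 1000), 10000)
  ## gap disagreement beyond the tolerance breaks
  b4 <- alignment_blocks(c("q", "q"), 10000, c(0, 5100), c(5000, 10000),
                         "chr1", c(0, 8000), c(5000, 12900))
  expect_equal(sort(break_at_misassemblies(b4, max_gap_bp = 1000)),
               c(5050, 4950)[order(c(5050, 4950))])
  ## strand flip breaks
  b5 <- alignment_blocks(c("q", "q"), 10000, c(0, 5000), c(5000, 10000),
                         "chr1", c(0, 5000), c(5000, 10000),
                         strand = c("+", "-"))
  expect_length(break_at_misassemblies(b5), 2L)
  ## unaligned queries contribute their full length
  expect_equal(break_at_misassemblies(b1, query_lengths = c(q = 10000,
                                                            free = 3000)),
               c(10000, 3000))
  ## short queries are excluded per the length floor
  expect_length(break_at_misassemblies(b1, query_lengths = c(q = 10000,
                                                             tiny = 400)), 1L)
})

test_that("breaking never increases total length and NA50 <= N50", {
  set.seed(7)
  for (i in 1:25) {
    n_q <- sample(3:8, 1)
    qlens <- sample(2000:20000, n_q)
    names(qlens) <- sprintf("q%d", seq_len(n_q))
    blocks <- rbindlist(lapply(names(qlens), function(qn) {
      n_b <- sample(1:4, 1)
      cuts <- sort(sample(500:(qlens[[qn]] - 500), n_b - 1))
      qs <- c(0, cuts)
      qe <- c(cuts, qlens[[qn]])
      as.data.table(alignment_blocks(
        qname = qn, qlen = qlens[[qn]], qstart = qs, qend = qe,
        tname = sample(c("chr1", "chr2"), n_b, TRUE),
        tstart = sample(0:50000, n_b), tend = sample(50001:100000, n_b),
        strand = sample(c("+", "-"), n_b, TRUE)))
    }))
    broken <- break_at_misassemblies(blocks, query_lengths = qlens,
                                     min_query_len = 0, min_block_bp = 0)
    expect_equal(sum(broken), sum(qlens))
    expect_lte(nx(broken), nx(qlens))
  }
})

test_that("window classification recognises diploid, haploid and excess cover", {
  ref_lens <- c(chr = 10000)
  full1 <- alignment_blocks("a/1", 10000, 0, 10000, "chr", 0, 10000)
  full2 <- alignment_blocks("b/2", 10000, 0, 10000, "chr", 0, 10000)
  both <- rbind(full1, full2)
  cls <- classify_windows(both, ref_lens)
  expect_equal(unname(cls$fractions[["diploid"]]), 1.0)
  expect_equal(nrow(cls$windows), 20L)
  ## only one haplotype: fully haploid
  cls1 <- classify_windows(full1, ref_lens)
  expect_equal(unname(cls1$fractions[["haploid"]]), 1.0)
  expect_equal(unname(cls1$fractions[["diploid"]]), 0)
  ## two contigs of the same haplotype: excess, not haploid
  twin <- rbind(full1,
                alignment_blocks("c/1", 10000, 0, 10000, "chr", 0, 10000))
  cls2 <- classify_windows(twin, ref_lens)
  expect_equal(unname(cls2$fractions[["excess"]]), 1.0)
  ## unlabeled contigs raise a warning and only count toward overall cover
  expect_warning(
    cls3 <- classify_windows(
      alignment_blocks("anon", 10000, 0, 10000, "chr", 0, 10000), ref_lens),
    "unlabelled")
  expect_equal(unname(cls3$fractions[["overall"]]), 1.0)
  expect_equal(unname(cls3$fractions[["uncovered"]]), 1.0)
})

test_that("window fractions are invariant to block order and splitting", {
  ref_lens <- c(chr = 20000)
  set.seed(8)
  blocks <- rbind(
    alignment_blocks("a/1", 12000, 0, 12000, "chr", 2000, 14000),
    alignment_blocks("b/2", 9000, 0, 9000, "chr", 5000, 14000),
    alignment_blocks("c/1", 4000, 0, 4000, "chr", 15500, 19500))
  base <- classify_windows(blocks, ref_lens)
  shuffled <- classify_windows(blocks[sample(nrow(blocks))], ref_lens)
  expect_identical(base$fractions, shuffled$fractions)
  ## split one block at an interior point: same coverage, same classes
  split_at <- 6000L
  split_blocks <- rbind(
    alignment_blocks("a/1", 12000, 0, split_at, "chr", 2000, 2000 + split_at),
    alignment_blocks("a/1", 12000, split_at, 12000, "chr",
                     2000 + split_at, 14000),
    blocks[2:3])
  split_cls <- classify_windows(split_blocks, ref_lens)
  expect_identical(base$fractions, split_cls$fractions)
})

test_that("chance overlap is the independence product", {
  expect_equal(round(100 * chance_overlap(c(0.589, 0.733, 0.772)), 1), 33.3)
  expect_equal(round(100 * chance_overlap(c(0.734, 0.792, 0.781)), 1), 45.4)
  expect_equal(chance_overlap(c(1, 1, 1)), 1)
  expect_error(chance_overlap(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the overlap chi-square equals the hand-computed statistic", {
  r <- overlap_chi2(observed = 500, total = 1000, expected_fraction = 0.5)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  set.seed(9)
  for (i in 1:20) {
    total <- sample(100:5000, 1)
    p <- runif(1, 0.05, 0.95)
    obs <- rbinom(1, total, runif(1, 0.05, 0.95))
    r <- overlap_chi2(obs, total, p)
    e <- c(total * p, total * (1 - p))
    o <- c(obs, total - obs)
    expect_equal(r$statistic, sum((o - e)^2 / e))
    ## oracle: base R chi-square GOF without continuity correction
    cr <- suppressWarnings(stats::chisq.test(o, p = c(p, 1 - p)))
    expect_equal(r$statistic, unname(cr$statistic))
    expect_equal(r$p_value, cr$p.value)
  }
  ## p decreases as observed moves away from expected
  ps <- vapply(c(500, 550, 600, 700), function(o) {
    overlap_chi2(o, 1000, 0.5)$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
  expect_true(overlap_chi2(2, 1000, 0.002)$low_expected)
})

test_that("the diploid length report reproduces the percentage arithmetic", {
  contigs <- data.table(
    name = c("mb/1", "rest"),
    length = c(3758345846, 5632483053 - 3758345846),
    haplotype = c("1", "unphased"))
  rep <- diploid_length_report(contigs)
  expect_equal(round(rep$labeled_percentage, 2), 66.73)
  ## all labeled: 100%
  all_lab <- data.table(name = c("a/1", "b/2"), length = c(1000, 2000),
                        haplotype = c("1", "2"))
  expect_equal(diploid_length_report(all_lab)$labeled_percentage, 100)
  ## fractions are internally consistent on a classified toy
  ref_lens <- c(chr = 10000)
  blocks <- rbind(
    alignment_blocks("a/1", 6000, 0, 6000, "chr", 0, 6000),
    alignment_blocks("b/2", 3000, 0, 3000, "chr", 0, 3000))
  cls <- classify_windows(blocks, ref_lens)
  rep2 <- diploid_length_report(
    data.table(name = c("a/1", "b/2"), length = c(6000, 3000),
               haplotype = c("1", "2")), cls)
  expect_lte(rep2$diploid_pct + rep2$haploid_pct, rep2$overall_pct + 1e-9)
})

test_that("phase blocks are maximal diploid runs scored by nx", {
  ref_lens <- c(chr = 50000)
  blocks <- rbind(
    alignment_blocks("a/1", 10000, 0, 10000, "chr", 0, 10000),
    alignment_blocks("a2/1", 20000, 0, 20000, "chr", 20000, 40000),
    alignment_blocks("b/2", 45000, 0, 45000, "chr", 0, 45000))
  cls <- classify_windows(blocks, ref_lens)
  runs <- diploid_regions(cls)
  expect_equal(nrow(runs), 2L)
  expect_equal(sort(runs$len), c(10000, 20000))
  expect_equal(phase_block_n50(cls), nx(runs$len))
  ## single run
  cls1 <- classify_windows(rbind(
    alignment_blocks("a/1", 10000, 0, 10000, "chr", 0, 10000),
    alignment_blocks("b/2", 10000, 0, 10000, "chr", 0, 10000)), c(chr = 10000))
  expect_equal(phase_block_n50(cls1), 10000)
  ## merging two abutting runs never decreases the N50
  expect_gte(nx(c(30000)), nx(c(10000, 20000)))
  no_dip <- classify_windows(
    alignment_blocks("a/1", 10000, 0, 10000, "chr", 0, 10000), c(chr = 10000))
  expect_error(phase_block_n50(no_dip), "no diploid")
})

test_that("a designed toy assembly yields its designed diploid fraction exactly", {
  ## 100 kb diploid template; contigs cut from each haplotype with known
  ## gaps; identity alignments. Windows covered by both haplotypes are
  ## exactly the designed intersection.
  tpl <- make_template(contig_len = 100000L, seed = 31L, lc_density = 2)
  h1 <- as_char(tpl$hap1)[["contig1"]]
  h2 <- as_char(tpl$hap2)[["contig1"]]
  ## hap1 contigs cover [0, 60000); hap2 contigs cover [20000, 100000)
  contigs <- c(`c1/1` = substr(h1, 1, 60000),
               `c2/2` = substr(h2, 20001, 100000))
  blocks <- alignment_blocks(qname = names(contigs),
                             qlen = nchar(contigs),
                             qstart = 0, qend = nchar(contigs),
                             tname = "contig1",
                             tstart = c(0, 20000), tend = c(60000, 100000))
  cls <- classify_windows(blocks, c(contig1 = 100000))
  expect_equal(unname(cls$fractions[["diploid"]]), 0.4)   # [20k, 60k)
  expect_equal(unname(cls$fractions[["haploid"]]), 0.6)
  expect_equal(unname(cls$fractions[["overall"]]), 1.0)
  runs <- diploid_regions(cls)
  expect_equal(runs$start, 20000)
  expect_equal(runs$end, 60000)
})

test_that("PAF files round-trip through the reader", {
  dir <- withr::local_tempdir()
  paf <- file.path(dir, "toy.paf")
  writeLines(c(
    paste("ctg1/1", 5000, 0, 4800, "+", "chr1", 100000, 1000, 5800,
          4700, 4800, 60, "tp:A:P", sep = "\t"),
    paste("ctg2/2", 3000, 100, 3000, "-", "chr1", 100000, 9000, 11900,
          2800, 2900, 55, sep = "\t")), paf)
  bl <- read_paf(paf)
  expect_equal(nrow(bl), 2L)
  expect_equal(bl$qname, c("ctg1/1", "ctg2/2"))
  expect_equal(bl$tstart, c(1000, 9000))
  expect_equal(bl$strand, c("+", "-"))
  expect_equal(bl$mapq, c(60L, 55L))
})
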
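test_that("read_bed maps columns and applies the BED dialect", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t110\tx\t0.9\t+",
               "chr2\t0\t50"), path)
  x <- suppressMessages(read_bed(path))
  expect_equal(x$chrom, c("chr1", "chr2"))
  expect_equal(x$start, c(10, 0))
  expect_equal(x$end, c(110, 50))
  expect_equal(x$name[1], "x")
  expect_equal(x$score[1], 0.9)
  expect_true(is.na(x$score[2]))
  expect_equal(x$strand, c("+", "+"))   # missing strand defaults to +
})

test_that("read_bed rejects malformed lines with the line number", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t50\tok\t.\t+", "chr1\t110\t10"), path)
  expect_error(read_bed(path), "line 2")
  writeLines("chr1\tten\t20", path)
  expect_error(read_bed(path), "line 1")
  writeLines("chr1\t5", path)
  expect_error(read_bed(path), "fewer than 3")
})

test_that("write_bed/read_bed round-trips including absent scores", {
  x <- gi(c("chr1", "chr2", "chr1"), c(5, 0, 200), c(80, 10, 300),
          strand = c("+", "-", "+"), name = c("a", "b", "c"),
          score = c(0.25, NA, 1))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, path)
  y <- read_bed(path)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
  expect_equal(y$strand, x$strand)
  expect_equal(y$score, x$score)
  # empty set -> empty file -> empty intervals
  write_bed(genomic_intervals(), path)
  expect_equal(nrow(read_bed(path)), 0L)
})

test_that("interval invariants are enforced at construction", {
  expect_error(genomic_intervals("chr1", 110, 10), "start")
  expect_error(genomic_intervals("chr1", -5, 10), "start")
  expect_error(genomic_intervals("chr1", 0, 10, strand = "*"), "strand")
  expect_silent(genomic_intervals("chr1", 0, 1))
})

test_that("extend_and_merge grows, clips at zero and merges per strand", {
  x <- gi("chrA", 10000, 10100)
  m <- extend_and_merge(x, 5000)
  expect_equal(c(m$start, m$end), c(5000, 15100))

  x2 <- gi(rep("chrA", 2), c(0, 8000), c(100, 8100))
  m2 <- extend_and_merge(x2, 5000)
  expect_equal(nrow(m2), 1L)
  expect_equal(c(m2$start, m2$end), c(0, 13100))

  # opposite strands never merge, flank 0 keeps both
  x3 <- gi(rep("chrA", 2), c(0, 50), c(100, 150), strand = c("+", "-"))
  m3 <- extend_and_merge(x3, 0)
  expect_equal(nrow(m3), 2L)

  # abutting same-strand intervals merge
  x4 <- gi(rep("chrA", 2), c(0, 100), c(100, 200))
  expect_equal(nrow(extend_and_merge(x4, 0)), 1L)
})

test_that("extend_and_merge agrees with per-base union on random inputs", {
  skip_if_not_installed("GenomicRanges")
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    start <- sample(0:400, n, replace = TRUE)
    len <- sample(1:80, n, replace = TRUE)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    x <- gi(rep("chrZ", n), start, start + len, strand)
    flank <- sample(0:50, 1)
    m <- extend_and_merge(x, flank)
    # outputs are pairwise non-overlapping within a strand
    for (s in c("+", "-")) {
      g <- m[m$strand == s, , drop = FALSE]
      if (nrow(g) > 1L) {
        expect_true(all(g$start[-1] > g$end[-nrow(g)]))
      }
    }
    # per-base union equals union of extended inputs (GRanges oracle)
    gr <- sort(GenomicRanges::reduce(GenomicRanges::GRanges(
      "chrZ",
      IRanges::IRanges(pmax(0, x$start - flank) + 1, x$end + flank),
      strand = x$strand)))
    want <- data.frame(start = BiocGenerics::start(gr) - 1L,
                       end = BiocGenerics::end(gr),
                       strand = as.character(BiocGenerics::strand(gr)))
    got <- m[order(m$start, m$strand), c("start", "end", "strand")]
    want <- want[order(want$start, want$strand), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
  }
})

test_that("make_windows matches the closed form and the boundaries", {
  r <- gi("chrM", 1000, 1268)   # length 268
  expect_equal(nrow(make_windows(r, 100, 10)), 17L)
  expect_equal(nrow(make_windows(gi("c", 0, 100), 100, 7)), 1L)
  expect_equal(suppressMessages(nrow(make_windows(gi("c", 0, 99), 100, 5))), 0L)
  w <- make_windows(gi("c", 40, 400, strand = "-"), 100, 50)
  expect_true(all(w$strand == "-"))
  expect_equal(w$start[1], 40)
})

test_that("window count equals enumeration oracle over lengths 1..500", {
  for (width in c(1, 7, 100)) {
    for (step in c(1, 5, 13)) {
      counts <- vapply(1:500, function(len) {
        suppressMessages(nrow(make_windows(gi("c", 0, len), width, step)))
      }, integer(1))
      oracle <- vapply(1:500, oracle_count_windows, integer(1),
                       width = width, step = step)
      closed <- vapply(1:500, function(len) {
        if (len < width) 0L else as.integer(floor((len - width) / step) + 1)
      }, integer(1))
      expect_equal(counts, oracle)
      expect_equal(counts, closed)
    }
  }
})

test_that("is_hit implements the inclusive 50% rule on the prediction", {
  expect_true(is_hit(gi("chrA", 0, 100), gi("chrA", 50, 150)))   # exactly 0.5
  expect_false(is_hit(gi("chrA", 0, 100), gi("chrA", 99, 199)))
  expect_false(is_hit(gi("chrA", 0, 100), gi("chrB", 0, 100)))
  expect_false(is_hit(gi("chrA", 0, 100), gi("chrA", 50, 150, strand = "-")))
  # denominator switch
  expect_true(is_hit(gi("chrA", 0, 10), gi("chrA", 0, 100), 0.5))
  expect_false(is_hit(gi("chrA", 0, 10), gi("chrA", 0, 100), 0.5,
                      denominator = "target"))
})

test_that("is_hit agrees with the per-base oracle on 1000 random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    p_start <- sample(0:150, 1); p_len <- sample(1:60, 1)
    t_start <- sample(0:150, 1); t_len <- sample(1:60, 1)
    strand_p <- sample(c("+", "-"), 1)
    strand_t <- if (runif(1) < 0.8) strand_p else sample(c("+", "-"), 1)
    pred <- gi("chr1", p_start, p_start + p_len, strand_p)
    targ <- gi("chr1", t_start, t_start + t_len, strand_t)
    frac <- sample(c(0.25, 0.5, 0.75), 1)
    expect_equal(is_hit(pred, targ, frac), oracle_is_hit(pred, targ, frac))
  }
})

test_that("cluster_by_overlap separates strands and chromosomes", {
  x <- gi(c("c1", "c1", "c1", "c1", "c2"),
          c(0, 50, 300, 40, 0), c(100, 150, 400, 140, 100),
          strand = c("+", "+", "+", "-", "+"))
  cl <- sncscan:::cluster_by_overlap(x)
  expect_equal(cl[1], cl[2])        # overlapping same strand
  expect_false(cl[1] == cl[3])      # disjoint
  expect_false(cl[1] == cl[4])      # opposite strand
  expect_false(cl[1] == cl[5])      # other chromosome
})
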
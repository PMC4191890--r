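# Read preprocessing and track I/O.

test_that("adapter trimming removes the longest qualifying suffix", {
  adapter <- "AGATCGGAAGAGCACACGTCT"
  insert <- "ACGTACGTACGT"
  expect_identical(trim_adapter(paste0(insert, adapter), adapter), insert)
  expect_identical(trim_adapter("CCCCGGGGTTTT", adapter), "CCCCGGGGTTTT")
  # partial adapter: first 8 nt, min_overlap 5, exact match
  expect_identical(
    trim_adapter(paste0(insert, substr(adapter, 1, 8)), adapter,
                 min_overlap = 5, max_mismatch_rate = 0),
    insert)
  # below min_overlap: untouched
  expect_identical(
    trim_adapter(paste0(insert, substr(adapter, 1, 4)), adapter,
                 min_overlap = 5, max_mismatch_rate = 0),
    paste0(insert, substr(adapter, 1, 4)))
  expect_error(trim_adapter("ACGT", ""), "adapter")

  # random reads against the exhaustive suffix-prefix oracle
  set.seed(7)
  for (i in 1:50) {
    read <- paste(sample(c("A", "C", "G", "T"),
                         sample(10:40, 1), replace = TRUE), collapse = "")
    if (i %% 2 == 0) {
      read <- paste0(read, substr(adapter, 1, sample.int(nchar(adapter), 1)))
    }
    expect_identical(trim_adapter(read, adapter),
                     oracle_trim(read, adapter))
  }
})

test_that("condensing keeps each exact sequence once, in order", {
  expect_identical(condense_reads(c("S1", "S1", "S2")), c("S1", "S2"))
  expect_identical(condense_reads(character(0)), character(0))
  set.seed(8)
  reads <- sample(c("AAA", "CCC", "GGG", "TTT", "ACG"), 60, replace = TRUE)
  once <- condense_reads(reads)
  expect_identical(condense_reads(once), once)  # idempotent
  expect_identical(sort(once), sort(unique(reads)))
})

test_that("exclusion filtering removes same-strand overlaps of >= 1 bp", {
  trna <- data.frame(chrom = "chrI", start = 100, end = 200, strand = "+")
  reads <- data.frame(
    chrom = "chrI",
    start = c(120, 300, 70, 199, 50),
    end = c(150, 330, 100, 230, 101),
    strand = c("+", "+", "+", "+", "-"))
  kept <- filter_excluded(reads, trna)
  # inside: removed; disjoint: kept; abutting ([70,100) vs [100,200)): kept;
  # 1-bp overlap: removed; other strand: kept
  expect_identical(kept$start, c(300, 70, 50))
  kept2 <- filter_excluded(reads, trna, same_strand = FALSE)
  expect_identical(kept2$start, c(300, 70))
  expect_error(filter_excluded(data.frame(chrom = "chrI", start = 5,
                                          end = 5, strand = "+"), trna),
               "malformed")
})

test_that("track building matches naive per-base accumulation", {
  cl <- c(chrI = 400, chrII = 300)
  one <- data.frame(chrom = "chrI", start = 10, end = 40, strand = "+")
  tr <- build_track(one, cl, total_aligned = 1e7)
  expect_identical(track_values(tr, "chrI", "+")[11:40], rep(1, 30))
  expect_identical(sum(track_values(tr, "chrI", "+")), 30)
  tr2 <- build_track(one, cl, total_aligned = 2e7)
  expect_identical(track_values(tr2, "chrI", "+")[11:40], rep(0.5, 30))

  set.seed(9)
  n <- 80
  reads <- data.frame(
    chrom = sample(names(cl), n, replace = TRUE),
    start = sample.int(250, n) - 1,
    strand = sample(c("+", "-"), n, replace = TRUE))
  reads$end <- reads$start + sample(20:40, n, replace = TRUE)
  tr3 <- build_track(reads, cl, total_aligned = 12345)
  expect_equal(tr3$values, oracle_coverage(reads, cl, 12345),
               tolerance = 1e-12)
  # arithmetic identity: total signal = summed read lengths x factor
  expect_equal(track_total(tr3),
               sum(reads$end - reads$start) * 1e7 / 12345,
               tolerance = 1e-9)

  # 5'-end mode: one unit at the 5' base of each read
  tr5 <- build_track(reads, cl, total_aligned = 1e7, mode = "fiveprime")
  expect_equal(track_total(tr5), n, tolerance = 1e-9)
  expect_error(build_track(one, cl, total_aligned = 0), "total_aligned")
})

test_that("reads contribute only to their own strand", {
  cl <- c(chrI = 100)
  reads <- data.frame(chrom = "chrI", start = c(10, 10), end = c(20, 20),
                      strand = c("+", "-"))
  tr <- build_track(reads, cl, total_aligned = 1e7)
  expect_identical(sum(track_values(tr, "chrI", "+")), 10)
  expect_identical(sum(track_values(tr, "chrI", "-")), 10)
})

test_that("bedGraph and wiggle round-trips are value-exact", {
  vals <- list(
    chrA = list("+" = c(0, 2.5, 2.5, 2.5, 0, 1 / 3, 0, 0, 1e7 / 3, 7),
                "-" = c(0.1, 0, 0, 0, 0, 0, 0, 0, 0, 2)),
    chrB = list("+" = numeric(12), "-" = c(rep(0.123456789123456, 11), 0)))
  tr <- coverage_track(vals)
  cl <- c(chrA = 10, chrB = 12)
  for (fmt in c("bedGraph", "wig")) {
    p <- tempfile(fileext = ".p")
    m <- tempfile(fileext = ".m")
    write_track(tr, p, m, fmt)
    back <- read_track(p, m, cl, fmt)
    expect_identical(back$values, tr$values)
  }
  # bedGraph interval semantics: [0,3) = 2.5 covers exactly bases 0..2
  p <- tempfile()
  writeLines("chrA\t0\t3\t2.5", p)
  m <- tempfile(); file.create(m)
  got <- read_track(p, m, c(chrA = 5), "bedGraph")
  expect_identical(track_values(got, "chrA", "+"), c(2.5, 2.5, 2.5, 0, 0))
  # wiggle fixedStep start=1 is internal 0-based position 0
  pw <- tempfile()
  writeLines(c("fixedStep chrom=chrA start=1 step=1 span=1", "4.5"), pw)
  gotw <- read_track(pw, m, c(chrA = 5), "wig")
  expect_identical(track_values(gotw, "chrA", "+")[1], 4.5)
})

test_that("malformed track files are rejected with the interval named", {
  m <- tempfile(); file.create(m)
  neg <- tempfile()
  writeLines(c("chrA\t0\t3\t1.5", "chrA\t5\t8\t-2"), neg)
  expect_error(read_track(neg, m, c(chrA = 10)), "interval 2.*negative")
  unk <- tempfile()
  writeLines("chrZ\t0\t3\t1", unk)
  expect_error(read_track(unk, m, c(chrA = 10)), "unknown chromosome")
  ovl <- tempfile()
  writeLines(c("chrA\t0\t5\t1", "chrA\t3\t8\t2"), ovl)
  expect_error(read_track(ovl, m, c(chrA = 10)), "overlapping")
})

test_that("library stage counts must never increase", {
  st <- library_stats(1000, 900, 700, 650, 640)
  expect_s3_class(st, "library_stats")
  expect_error(library_stats(1000, 1100, 700, 650, 640), "non-increasing")
  expect_error(library_stats(1000, 900, 700, 650, -1), "non-negative")
})
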
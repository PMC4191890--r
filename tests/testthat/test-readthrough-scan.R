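# Readthrough Index machinery.

test_that("window sums partition the flanking span, strand-aware", {
  const <- toy_track(rep(1, 3000), rep(1, 3000))
  expect_identical(window_sums(const, "chrT", 1500, "+", 500),
                   c(up = 500, down = 500))
  step_plus <- toy_track(c(rep(1, 1500), rep(0, 1500)))
  expect_identical(window_sums(step_plus, "chrT", 1500, "+", 500),
                   c(up = 500, down = 0))
  # same step pattern read on the minus strand: windows mirror
  step_minus <- toy_track(rep(0, 3000), c(rep(1, 1500), rep(0, 1500)))
  expect_identical(window_sums(step_minus, "chrT", 1500, "-", 500),
                   c(up = 0, down = 500))
  # too close to an end: designated missing
  expect_identical(window_sums(const, "chrT", 100, "+", 500),
                   c(up = NA_real_, down = NA_real_))
  expect_identical(window_sums(const, "chrT", 2700, "+", 500),
                   c(up = NA_real_, down = NA_real_))
})

test_that("readthrough fraction and index follow their definitions", {
  expect_identical(readthrough_fraction(10, 10), 0.5)
  expect_identical(readthrough_fraction(10, 0), 0)
  expect_identical(readthrough_fraction(800, 200), 0.2)
  expect_true(is.na(readthrough_fraction(0, 0)))
  expect_error(readthrough_fraction(-1, 5), "non-negative")
  expect_identical(readthrough_index(0.5, 0.5), 0)
  expect_equal(readthrough_index(0.6, 0.2), 0.4, tolerance = 1e-12)
  expect_true(is.na(readthrough_index(NA, 0.2)))
  # bounds over random fractions
  set.seed(10)
  f <- matrix(runif(200), ncol = 2)
  idx <- readthrough_index(f[, 1], f[, 2])
  expect_true(all(idx >= -1 & idx <= 1))
})

test_that("all-zero tracks yield an empty scan", {
  z <- empty_track(c(chrT = 3000))
  expect_identical(nrow(global_scan(z, z)), 0L)
})

test_that("scan rejects mismatched genomes", {
  a <- empty_track(c(chrT = 3000))
  b <- empty_track(c(chrT = 4000))
  expect_error(global_scan(a, b), "mismatched")
  d <- empty_track(c(chrX = 3000))
  expect_error(global_scan(a, d), "mismatched")
})

test_that("a planted terminator produces a passing point near the truth", {
  s <- small_nns_loci()
  m <- preset_model("Nrd1")
  ctrl <- simulate_occupancy(s$loci, m, "control", "Nrd1",
                             s$chrom_lengths, seed = 201)
  depl <- simulate_occupancy(s$loci, m, "depleted", "Nrd1",
                             s$chrom_lengths, seed = 202)
  pts <- global_scan(ctrl, depl)
  for (i in seq_len(nrow(s$loci))) {
    near <- pts$chrom == s$loci$chrom[i] & pts$strand == s$loci$strand[i] &
      abs(pts$pos - s$loci$term_point[i]) <= 100
    expect_true(any(near), label = paste("passing point near",
                                         s$loci$id[i]))
  }
})

test_that("scale invariance: common scaling changes no fraction or index", {
  s <- small_nns_loci()
  m <- preset_model("Nrd1")
  ctrl <- simulate_occupancy(s$loci, m, "control", "Nrd1",
                             s$chrom_lengths, seed = 203)
  depl <- simulate_occupancy(s$loci, m, "depleted", "Nrd1",
                             s$chrom_lengths, seed = 204)
  scale_track <- function(tr, k) {
    tr$values <- lapply(tr$values, function(v) lapply(v, function(x) x * k))
    tr
  }
  thr <- scan_thresholds(min_reads = 0)
  a <- global_scan(ctrl, depl, thr)
  # a power-of-two factor scales sums exactly, so even threshold-boundary
  # positions are preserved
  b <- global_scan(scale_track(ctrl, 4), scale_track(depl, 4), thr)
  expect_identical(a[, c("chrom", "pos", "strand")],
                   b[, c("chrom", "pos", "strand")])
  expect_equal(a$index, b$index, tolerance = 1e-12)
  expect_equal(a$frac_control, b$frac_control, tolerance = 1e-12)
})

test_that("mirroring the genome mirrors every readthrough point", {
  s <- small_nns_loci()
  m <- preset_model("Nrd1")
  ctrl <- simulate_occupancy(s$loci, m, "control", "Nrd1",
                             s$chrom_lengths, seed = 205)
  depl <- simulate_occupancy(s$loci, m, "depleted", "Nrd1",
                             s$chrom_lengths, seed = 206)
  mirror <- function(tr) {
    tr$values <- lapply(tr$values, function(v) {
      list("+" = rev(v[["-"]]), "-" = rev(v[["+"]]))
    })
    tr
  }
  L <- s$chrom_lengths[["chrS"]]
  a <- global_scan(ctrl, depl)
  b <- global_scan(mirror(ctrl), mirror(depl))
  expect_identical(nrow(a), nrow(b))
  key <- function(df, pos, strand) {
    o <- order(df$chrom, pos, strand)
    data.frame(chrom = df$chrom[o], pos = pos[o], strand = strand[o],
               index = df$index[o])
  }
  mapped <- key(a, L - a$pos, ifelse(a$strand == "+", "-", "+"))
  expect_equal(mapped, key(b, b$pos, b$strand), tolerance = 1e-9)
})

test_that("cumulative-sum scan equals the brute-force oracle", {
  # small structured toy so the naive oracle stays fast
  set.seed(11)
  L <- 3000
  vp_c <- rpois(L, c(rep(0.2, 1000), rep(4, 800), rep(0.2, 1200)))
  vp_t <- rpois(L, c(rep(0.2, 1000), rep(4, 800), rep(2, 700),
                     rep(0.2, 500)))
  vm_c <- rpois(L, 0.5)
  vm_t <- rpois(L, 0.5)
  ctrl <- toy_track(vp_c, vm_c)
  trt <- toy_track(vp_t, vm_t)
  thr <- scan_thresholds(window = 400, min_index = 0.05, min_reads = 100)
  got <- global_scan(ctrl, trt, thr)
  want <- oracle_global_scan(ctrl, trt, 400, 0.05, 100, TRUE)
  o1 <- got[order(got$chrom, got$pos, got$strand), ]
  o2 <- want[order(want$chrom, want$pos, want$strand), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2, tolerance = 1e-9)
})

test_that("candidate selection is greedy with per-strand separation", {
  pts <- data.frame(chrom = "chrT", pos = c(1000, 1100), strand = "+",
                    index = c(0.5, 0.4))
  sel <- select_candidates(pts, 1000)
  expect_identical(sel$pos, 1000)
  pts2 <- pts
  pts2$strand <- c("+", "-")
  expect_identical(nrow(select_candidates(pts2, 1000)), 2L)
  # random point sets against the exhaustive greedy oracle
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    pts3 <- data.frame(
      chrom = sample(c("chrI", "chrII"), n, replace = TRUE),
      pos = sample.int(20000, n),
      strand = sample(c("+", "-"), n, replace = TRUE),
      index = round(runif(n), 2))  # rounding forces ties
    got <- select_candidates(pts3, 800)
    want <- oracle_greedy_select(pts3, 800)
    expect_identical(got[, c("chrom", "pos", "strand")],
                     want[, c("chrom", "pos", "strand")])
  }
})

test_that("scan rows agree with single-position recomputation", {
  s <- small_nns_loci()
  m <- preset_model("Nrd1")
  ctrl <- simulate_occupancy(s$loci, m, "control", "Nrd1",
                             s$chrom_lengths, seed = 207)
  depl <- simulate_occupancy(s$loci, m, "depleted", "Nrd1",
                             s$chrom_lengths, seed = 208)
  pts <- global_scan(ctrl, depl)
  pick <- pts[seq(1, nrow(pts), length.out = min(25, nrow(pts))), ]
  for (i in seq_len(nrow(pick))) {
    wc <- window_sums(ctrl, pick$chrom[i], pick$pos[i], pick$strand[i], 500)
    wt <- window_sums(depl, pick$chrom[i], pick$pos[i], pick$strand[i], 500)
    expect_equal(pick$up_control[i], wc[["up"]], tolerance = 1e-9)
    expect_equal(pick$down_treated[i], wt[["down"]], tolerance = 1e-9)
    expect_equal(pick$index[i],
                 readthrough_index(readthrough_fraction(wt[["up"]],
                                                        wt[["down"]]),
                                   readthrough_fraction(wc[["up"]],
                                                        wc[["down"]])),
                 tolerance = 1e-9)
  }
})
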
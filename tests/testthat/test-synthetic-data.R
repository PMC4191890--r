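# Synthetic genome / occupancy / pA-table / read generators.

test_that("locus validation rejects bad geometry with the pair named", {
  cl <- c(chrI = 50000)
  ok <- data.frame(id = c("a", "b"), chrom = "chrI", strand = "+",
                   tss = c(5000, 20000), term_point = c(6000, 21000),
                   locus_class = "snoRNA", body_rate = 5)
  expect_silent(validate_loci(ok, cl))
  close_pair <- ok
  close_pair$tss <- c(5000, 6500)
  close_pair$term_point <- c(6000, 7500)
  expect_error(validate_loci(close_pair, cl), "a / b")
  flank <- ok[1, ]
  flank$tss <- 100
  flank$term_point <- 1100
  expect_error(validate_loci(flank, cl), "flank")
  upside_down <- ok[1, ]
  upside_down$strand <- "-"  # tss now downstream of term_point
  expect_error(validate_loci(upside_down, cl), "upstream")
})

test_that("simulated genomes are seed-deterministic with planted motifs", {
  s <- small_nns_loci()
  g1 <- simulate_genome(sequence_spec(), s$loci, s$chrom_lengths, seed = 11)
  g2 <- simulate_genome(sequence_spec(), s$loci, s$chrom_lengths, seed = 11)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  g3 <- simulate_genome(sequence_spec(), s$loci, s$chrom_lengths, seed = 12)
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))

  # constructive insertion: every declared UCUUG lands in the upstream window
  sites <- data.frame(chrom = s$loci$chrom, pos = s$loci$term_point,
                      strand = s$loci$strand, id = s$loci$id)
  ups <- extract_upstream(g1$genome, sites, length = 150)
  expect_gte(scan_motif(ups[["cut1"]], "UCUUG")$count, 3)
  expect_gte(scan_motif(ups[["sno1"]], "UCUUG")$count, 2)
  expect_gte(scan_motif(ups[["sno1"]], "GUAA")$count, 2)
})

test_that("intergenic GC composition matches the specification", {
  cl <- c(chrI = 100000)
  loci <- data.frame(id = character(0), chrom = character(0),
                     strand = character(0), tss = numeric(0),
                     term_point = numeric(0), locus_class = character(0),
                     body_rate = numeric(0))
  g <- simulate_genome(sequence_spec(gc_intergenic = 0.30), loci, cl,
                       seed = 21)
  freq <- Biostrings::alphabetFrequency(g$genome[[1]], as.prob = TRUE)
  gc <- sum(freq[c("C", "G")])
  # binomial standard error at n = 1e5 is ~0.0014; 0.01 is ~7 sigma
  expect_lt(abs(gc - 0.30), 0.01)
})

test_that("occupancy counts follow the rate function", {
  s <- small_nns_loci()
  zero_model <- occupancy_model(pause_amp = 0, background_rate = 0)
  zero_loci <- s$loci
  zero_loci$body_rate <- 0
  tr0 <- simulate_occupancy(zero_loci, zero_model, "control", "Nrd1",
                            s$chrom_lengths, seed = 31)
  expect_identical(track_total(tr0), 0)

  # plateau mean over 1000 bases within 3 * sqrt(lambda / n)
  loci <- data.frame(id = "m1", chrom = "chrS", strand = "+", tss = 3000,
                     term_point = 6000, locus_class = "mRNA", body_rate = 5)
  m <- occupancy_model(pause_amp = 0, background_rate = 0)
  tr <- simulate_occupancy(loci, m, "control", "Nrd1", s$chrom_lengths,
                           seed = 32)
  plateau <- track_values(tr, "chrS", "+")[3501:4500]
  expect_lt(abs(mean(plateau) - 5), 3 * sqrt(5 / 1000))

  # conservation: mean simulated mass equals the rate integral (30 seeds)
  rt <- rate_tracks(s$loci, preset_model("Nrd1"), "depleted", "Nrd1",
                    s$chrom_lengths)
  expected <- sum(track_values(rt, "chrS", "+")[4001:5500])
  sums <- vapply(1:30, function(sd) {
    tr <- simulate_occupancy(s$loci, preset_model("Nrd1"), "depleted",
                             "Nrd1", s$chrom_lengths, seed = 100 + sd)
    sum(track_values(tr, "chrS", "+")[4001:5500])
  }, numeric(1))
  mc_se <- sqrt(expected / 30)  # Poisson variance = mean
  expect_lt(abs(mean(sums) - expected), 3 * mc_se)

  expect_error(simulate_occupancy(s$loci, preset_model("Nrd1"), "weird",
                                  "Nrd1", s$chrom_lengths, seed = 1))
  expect_error(rate_tracks(s$loci, preset_model("Nrd1"), "control", "Xrn1",
                           s$chrom_lengths))
})

test_that("simulated occupancy is seed-deterministic", {
  s <- small_nns_loci()
  a <- simulate_occupancy(s$loci, preset_model("Sen1"), "depleted", "Sen1",
                          s$chrom_lengths, seed = 41)
  b <- simulate_occupancy(s$loci, preset_model("Sen1"), "depleted", "Sen1",
                          s$chrom_lengths, seed = 41)
  expect_identical(a$values, b$values)
})

test_that("pA tables carry one site per mRNA plus configured extras", {
  cl <- c(chrI = 60000)
  loci <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(id = paste0("m", i), chrom = "chrI",
               strand = ifelse(i %% 2 == 0, "+", "-"),
               tss = ifelse(i %% 2 == 0, i * 5000 - 1200, i * 5000 + 1200),
               term_point = i * 5000, locus_class = "mRNA", body_rate = 5)
  }))
  tab <- simulate_pa_table(loci, cl, seed = 51, noise_sites = 0)
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$raw_reads >= 0))
  expect_identical(tab, simulate_pa_table(loci, cl, seed = 51,
                                          noise_sites = 0))
  extra <- data.frame(chrom = "chrI", pos = c(30100, 30150), strand = "+",
                      raw_reads = c(1000, 300))
  tab2 <- simulate_pa_table(loci, cl, seed = 51, noise_sites = 5,
                            extra_sites = extra)
  expect_identical(nrow(tab2), 17L)
  expect_true(all(c(30100, 30150) %in% tab2$pos))
})

test_that("simulated reads start where the occupancy is", {
  s <- small_nns_loci()
  g <- simulate_genome(sequence_spec(), s$loci, s$chrom_lengths, seed = 61)

  # all occupancy on one base -> every read starts there
  conc <- empty_track(s$chrom_lengths)
  conc$values$chrS[["+"]][5001] <- 10  # 0-based position 5000
  rd <- simulate_reads(conc, g$genome, read_len = 25, n_reads = 200,
                       seed = 62)
  expect_true(all(rd$alignments$start == 5000))
  expect_true(all(rd$alignments$strand == "+"))

  # every read ends with the configured adapter prefix
  adapter <- "AGATCGGAAGAGCACACGTCT"
  rd2 <- simulate_reads(conc, g$genome, read_len = 25, adapter = adapter,
                        n_reads = 50, adapter_overlap = 8, seed = 63)
  expect_true(all(endsWith(rd2$sequences, substr(adapter, 1, 8))))
  expect_true(all(nchar(rd2$sequences) == 33))

  # read sequences are the genomic substrings at the true alignments
  chr_seq <- as.character(g$genome[["chrS"]])
  ins <- substr(rd2$sequences, 1, 25)
  expect_true(all(ins == substr(chr_seq, rd2$alignments$start + 1,
                                rd2$alignments$end)))

  expect_error(simulate_reads(conc, g$genome, n_reads = 0, seed = 1),
               "n_reads")
})

test_that("read start positions reproduce the occupancy distribution", {
  # concentrated support (no background) so the multinomial total-variation
  # bound at n = 1e5 applies: E[TV] ~ 0.4 * sqrt(support / n) << 0.05
  cl <- c(chrS = 4000)
  loci <- data.frame(id = "s1", chrom = "chrS", strand = "+", tss = 1200,
                     term_point = 1800, locus_class = "snoRNA",
                     body_rate = 5)
  g <- simulate_genome(sequence_spec(), loci, cl, seed = 71)
  tr <- simulate_occupancy(loci, preset_model("Nrd1", background_rate = 0),
                           "control", "Nrd1", cl, seed = 72)
  read_len <- 30
  n <- 1e5
  rd <- simulate_reads(tr, g$genome, read_len = read_len, n_reads = n,
                       seed = 73)
  L <- cl[["chrS"]]
  wp <- track_values(tr, "chrS", "+")
  wp[(L - read_len + 2):L] <- 0
  wm <- track_values(tr, "chrS", "-")
  wm[1:(read_len - 1)] <- 0
  tot <- sum(wp) + sum(wm)
  five_p <- rd$alignments$start[rd$alignments$strand == "+"]
  five_m <- rd$alignments$end[rd$alignments$strand == "-"] - 1
  emp_p <- tabulate(five_p + 1, L) / n
  emp_m <- tabulate(five_m + 1, L) / n
  tv <- 0.5 * (sum(abs(emp_p - wp / tot)) + sum(abs(emp_m - wm / tot)))
  expect_lt(tv, 0.05)
})
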
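# Shared in-code fixtures.

# Single-chromosome track from explicit strand vectors.
toy_track <- function(plus, minus = rep(0, length(plus)), chrom = "chrT") {
  vals <- list(list("+" = as.numeric(plus), "-" = as.numeric(minus)))
  names(vals) <- chrom
  coverage_track(vals)
}

# Two NNS loci (one per strand) on a 20-kb chromosome.
small_nns_loci <- function() {
  list(
    loci = data.frame(
      id = c("sno1", "cut1"),
      chrom = "chrS", strand = c("+", "-"),
      tss = c(4000, 15600), term_point = c(4400, 15000),
      locus_class = c("snoRNA", "CUT"), body_rate = 5,
      stringsAsFactors = FALSE),
    chrom_lengths = c(chrS = 20000))
}

# Random pA-site table mixing strong, weak and clustered sites.
random_pa_table <- function(seed, n = 40) {
  set.seed(seed)
  chrom <- sample(c("chrI", "chrII"), n, replace = TRUE)
  pos <- sample.int(5000, n)
  # force some clusters by duplicating positions with jitter
  dup <- sample.int(n, n %/% 4)
  pos[dup] <- pos[sample.int(n, length(dup), replace = TRUE)] +
    sample.int(300, length(dup))
  data.frame(chrom = chrom, pos = pos,
             strand = sample(c("+", "-"), n, replace = TRUE),
             raw_reads = rpois(n, 400) * rbinom(n, 1, 0.8) +
               rpois(n, 120),
             stringsAsFactors = FALSE)
}

# Random RNA-sense sequence.
random_rna <- function(n, prob = c(0.3, 0.2, 0.2, 0.3)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = prob),
        collapse = "")
}
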
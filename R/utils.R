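# Internal helpers: seeded evaluation, argument checks, formatting.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) &&
    (if (positive) x > 0 else x >= 0)
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Chromosome lengths: named numeric/integer vector, all > 0.
validate_chrom_lengths <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chromosome lengths must be a named vector", call. = FALSE)
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("duplicated chromosome names", call. = FALSE)
  }
  if (!is.numeric(chrom_lengths) || any(chrom_lengths < 1)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  invisible(chrom_lengths)
}

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  invisible(strand)
}

# Exact decimal representation of a double (round-trips through text).
fmt_value <- function(x) sprintf("%.17g", x)

fmt_int <- function(x) sprintf("%d", as.integer(x))

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)

rna_to_dna <- function(x) chartr("Uu", "Tt", x)
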
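# Shared internal helpers: sequence coercion, reverse complement, rounding,
# seeded RNG scopes.

# Coerce DNAStringSet / character to a named uppercase character vector.
.as_chr_seqs <- function(x, what = "sequences") {
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- toupper(x)
  } else {
    stop(what, " must be a DNAStringSet or a character vector")
  }
  if (is.null(names(out)) && length(out) > 0)
    names(out) <- paste0("seq", seq_along(out))
  out
}

.as_dss <- function(x) {
  if (methods::is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
}

# Reverse complement of plain character strings (vectorized).
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- vapply(x, function(s) {
    if (nchar(s) == 0) return("")
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
  out
}

# Round half away from zero at `digits` decimals (printed-number convention;
# base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# i.i.d. background sequence with configurable GC content.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run expr with a fixed seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Longest common prefix / suffix lengths of two strings (bounded so the two
# trims never overlap on the shorter string).
.lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}
.lcs_len <- function(a, b, max_len = NULL) {
  n <- min(nchar(a), nchar(b))
  if (!is.null(max_len)) n <- min(n, max_len)
  if (n == 0) return(0L)
  av <- rev(utf8ToInt(substr(a, nchar(a) - n + 1, nchar(a))))
  bv <- rev(utf8ToInt(substr(b, nchar(b) - n + 1, nchar(b))))
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}
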
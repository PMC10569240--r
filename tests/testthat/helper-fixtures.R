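# Shared fixture builders. Everything is generated in code at test time;
# no data files are read.

small_genome <- function(seed = 1, n_chrom = 2, chrom_length = 3e5,
                         centromere_length = 5e4, ...) {
  make_genome(genome_config(n_chrom = n_chrom, chrom_length = chrom_length,
                            centromere_length = centromere_length,
                            seed = seed, ...))
}

chr_string <- function(x, i = 1) as.character(x)[[i]]

# Brute-force canonical k-mer counter (independent oracle for the compiled
# counter): enumerates substrings, canonicalizes by string comparison.
oracle_kmer_counts <- function(reads, k) {
  revcomp_str <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
  }
  all <- character(0)
  for (r in reads) {
    r <- toupper(r)
    n <- nchar(r)
    if (n < k) next
    kms <- substring(r, 1:(n - k + 1), k:n)
    kms <- kms[!grepl("[^ACGT]", kms)]
    rc <- vapply(kms, revcomp_str, "", USE.NAMES = FALSE)
    all <- c(all, pmin(kms, rc))
  }
  table(all)
}

oracle_kmer_hist <- function(reads, k) {
  tab <- table(as.integer(oracle_kmer_counts(reads, k)))
  data.frame(depth = as.integer(names(tab)), count = as.integer(tab))
}

# Exhaustive N50 oracle: the largest member length L whose >=L contigs
# still cover at least half the total (the smallest contig of the minimal
# half-covering prefix).
oracle_n50 <- function(lengths) {
  tot <- sum(lengths)
  for (L in sort(unique(lengths), decreasing = TRUE))
    if (sum(lengths[lengths >= L]) >= tot / 2) return(as.numeric(L))
  stop("unreachable")
}

# Non-overlapping motif count by explicit scan, both strands.
oracle_motif_count <- function(seq, motif) {
  scan1 <- function(s, m) {
    n <- 0L; i <- 1L
    while (i + nchar(m) - 1 <= nchar(s)) {
      if (substr(s, i, i + nchar(m) - 1) == m) {
        n <- n + 1L; i <- i + nchar(m)
      } else i <- i + 1L
    }
    n
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  max(scan1(seq, motif), scan1(seq, rc))
}
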
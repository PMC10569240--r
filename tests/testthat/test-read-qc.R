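test_that("ONT filter applies the pass and assembly rules literally", {
  meta <- data.frame(
    read_id = paste0("r", 1:6),
    length = c(9999, 50000, 35000, 35000, 10000, 35000),
    mean_q = c(20, 6.9, 12, 12, 7, NA),
    filtlong_quality = c(95, 95, 95, 90, 95, 95))
  pass <- filter_ont(meta, "pass")
  expect_setequal(pass$kept$read_id, c("r3", "r4", "r5"))  # r1 short, r2 low q
  expect_identical(pass$report$n_unscorable, 1L)
  asm <- filter_ont(meta, "assembly")
  # r4 fails the strict >90 score, r5 is under 30 kb
  expect_identical(asm$kept$read_id, "r3")
  # idempotence: filtering the kept set again changes nothing
  again <- filter_ont(pass$kept, "pass")
  expect_identical(again$kept, pass$kept)
})

test_that("HiFi filter keeps boundary passes/SNR values", {
  meta <- data.frame(read_id = paste0("r", 1:4), length = 15000,
                     passes = c(2, 5, 3, 10), snr = c(5, 2.4, 2.5, 9))
  res <- filter_hifi(meta)
  expect_setequal(res$kept$read_id, c("r3", "r4"))
  expect_identical(filter_hifi(res$kept)$kept, res$kept)
})

test_that("k-mer histogram matches a brute-force canonical oracle", {
  # frozen from the oracle: ACG and CGT are reverse complements, so "ACGT"
  # holds ONE distinct canonical 3-mer at depth 2
  expect_identical(kmer_histogram("ACGT", k = 3)$depth, 2L)
  expect_identical(kmer_histogram("ACGT", k = 3)$count, 1L)
  expect_identical(oracle_kmer_hist("ACGT", 3),
                   data.frame(depth = 2L, count = 1L))
  withr::with_seed(42, {
    for (trial in 1:5) {
      reads <- vapply(sample(20:60, 4), t2tfinish:::random_dna, "")
      for (k in c(5, 19)) {
        got <- kmer_histogram(reads, k = k)
        want <- oracle_kmer_hist(reads, k)
        expect_identical(got$depth, want$depth)
        expect_identical(got$count, want$count)
      }
    }
  })
  # duplicating a read doubles every depth, distinct count unchanged
  r <- t2tfinish:::random_dna(300)
  h1 <- kmer_histogram(r, k = 19)
  h2 <- kmer_histogram(c(r, r), k = 19)
  expect_identical(h2$depth, 2L * h1$depth)
  expect_identical(sum(h2$count), sum(h1$count))
  # N breaks k-mer windows; even k warns; empty input yields empty histogram
  expect_identical(sum(kmer_histogram("ACGTNACGT", k = 5)$count), 0L)
  expect_warning(kmer_histogram("ACGTACGT", k = 4), "even")
  expect_identical(nrow(kmer_histogram(character(0), k = 19)), 0L)
})

test_that("genome size estimation recovers single-peak arithmetic and planted size", {
  h <- structure(data.frame(depth = 50L, count = 1000000L),
                 class = c("kmer_histogram", "data.frame"))
  est <- estimate_genome_size(h, error_depth_cutoff = 3)
  expect_identical(est$size_bp, 1e6)
  expect_identical(est$peak_depth, 50)
  # error k-mers below the cutoff are excluded
  h2 <- structure(data.frame(depth = c(1L, 2L, 50L),
                             count = c(5e6L, 1e6L, 1e6L)),
                  class = c("kmer_histogram", "data.frame"))
  expect_identical(estimate_genome_size(h2)$size_bp, 1e6)
  expect_error(estimate_genome_size(h2, error_depth_cutoff = 100), "mode")
  # planted-size recovery on error-free synthetic reads; the genome must
  # be much longer than a read so the depth histogram has a resolvable peak
  bg <- withr::with_seed(77, t2tfinish:::random_dna(5e5))
  reads <- simulate_reads(c(genome = bg), "hifi", coverage = 35, seed = 5)
  est <- estimate_genome_size(kmer_histogram(reads, k = 19))
  expect_lt(abs(est$size_bp - 5e5) / 5e5, 0.02)
})

test_that("QV matches the brute-force k-mer set-difference oracle", {
  withr::with_seed(11, {
    asm <- t2tfinish:::random_dna(20000)
    reads <- substring(asm, seq(1, 19001, by = 1000),
                       pmin(seq(1, 19001, by = 1000) + 1999, 20000))
    # perfect support: capped QV
    res0 <- kmer_qv(asm, reads, k = 19)
    expect_true(res0$capped)
    expect_identical(res0$qv, 99)
    # one substituted interior base
    mut <- asm
    cur <- substr(mut, 10000, 10000)
    substr(mut, 10000, 10000) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    res <- kmer_qv(mut, reads, k = 19)
    # oracle: count assembly k-mer instances absent from the read set
    rk <- names(oracle_kmer_counts(reads, 19))
    ak <- oracle_kmer_counts(mut, 19)
    missing <- sum(ak[setdiff(names(ak), rk)])
    total <- sum(ak)
    expect_identical(res$kmers_missing, as.numeric(missing))
    expect_identical(res$kmers_total, as.numeric(total))
    E <- 1 - (1 - missing / total)^(1 / 19)
    expect_equal(res$qv, -10 * log10(E), tolerance = 1e-12)
  })
})

test_that("QV is monotone in missing k-mers and stable in assembly length", {
  qv_of <- function(missing, total) {
    E <- 1 - (1 - missing / total)^(1 / 19)
    -10 * log10(E)
  }
  qvs <- vapply(c(1, 5, 20, 100, 500), qv_of, 0, total = 1e6)
  expect_true(all(diff(qvs) < 0))
  # doubling length at the same per-base error rate leaves QV unchanged
  withr::with_seed(12, {
    mk <- function(n, nerr) {
      s <- t2tfinish:::random_dna(n)
      m <- s
      for (p in sample(100:(n - 100), nerr)) {
        cur <- substr(m, p, p)
        substr(m, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
      }
      kmer_qv(m, s, k = 19)$qv
    }
    expect_equal(mk(40000, 4), mk(80000, 8), tolerance = 0.8)
  })
})

test_that("N50 agrees with the exhaustive oracle and counts gaps", {
  expect_identical(assembly_stats(c(5, 3, 2))$n50, 5)
  expect_identical(assembly_stats(42)$n50, 42)
  withr::with_seed(21, {
    for (trial in 1:25) {
      lens <- sample(1:100, sample(1:12, 1), replace = TRUE)
      st <- assembly_stats(lens)
      expect_equal(st$n50, oracle_n50(lens))
      expect_equal(st$total_bp, sum(lens))
      expect_true(st$n50 %in% lens)
    }
  })
  expect_identical(assembly_stats(c(10, 20), gap_runs = c(5, 10, 200))$gap_count,
                   2L)
  expect_error(assembly_stats(numeric(0)), "length")
})

test_that("coverage summary unions intervals and reports mapping rate", {
  aln <- data.frame(qname = c("r1", "r2"), qlen = 100, qstart = 0, qend = 100,
                    strand = "+", tname = "t1", tlen = 100,
                    tstart = c(0, 40), tend = c(60, 100),
                    n_match = 60, block_len = 60, mapq = 60)
  cs <- coverage_summary(aln, c(t1 = 100))
  expect_identical(cs$mapping_rate, 1)
  expect_identical(cs$per_target$covered_fraction, 1)
  one <- coverage_summary(aln[1, ], c(t1 = 100), n_total_reads = 2)
  expect_identical(one$mapping_rate, 0.5)
  expect_identical(one$per_target$covered_fraction, 0.6)
  expect_error(coverage_summary(aln, c(other = 100)), "unknown target")
})
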
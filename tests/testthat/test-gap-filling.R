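test_that("find_gaps reports maximal N-runs at the length threshold", {
  asm <- c(c1 = paste0("ACGT", strrep("N", 10), "ACGT"))
  g <- find_gaps(asm, min_n = 10)
  expect_identical(g$start, 4)
  expect_identical(g$end, 14)
  expect_identical(nrow(find_gaps(c(c1 = "ACGTACGT"))), 0L)
  two <- c(c1 = paste0(strrep("A", 10), strrep("N", 5), "G", strrep("N", 5),
                       strrep("A", 10)))
  expect_identical(nrow(find_gaps(two, min_n = 5)), 2L)
  expect_identical(nrow(find_gaps(two, min_n = 6)), 0L)
})

test_that("flank extraction clips at ends and enforces the 5-20 kb range", {
  asm <- c(c1 = strrep("A", 300000))
  gap <- data.frame(chrom = "c1", start = 100000, end = 105000)
  fl <- extract_flanks(gap, asm, 5000)
  expect_identical(nchar(fl$left), 5000L)
  expect_identical(fl$left_start, 95000)
  expect_identical(fl$right_end, 110000)
  expect_false(fl$one_sided)
  edge <- data.frame(chrom = "c1", start = 0, end = 100)
  fe <- extract_flanks(edge, asm, 5000)
  expect_identical(fe$left, "")
  expect_true(fe$one_sided)
  expect_error(extract_flanks(gap, asm, 25000), "5000-20000")
})

test_that("patch selection honours tier priority and tie-break rules", {
  cands <- data.frame(
    donor = c("ontBig", "asmA", "ontSmall"),
    tier = c(2, 1, 2),
    tstart = 0, tend = 20000, n_match = c(18000, 12000, 9000),
    block_len = c(18000, 12000, 9000))
  # tier 1 wins even against a longer tier-2 block
  expect_identical(select_patch(6000, 11000, cands)$donor, "asmA")
  # among tier-2 donors, the longest block wins
  t2 <- cands[cands$tier == 2, ]
  expect_identical(select_patch(6000, 11000, t2)$donor, "ontBig")
  # equal blocks: more matches, then lexicographic donor name
  tie <- data.frame(donor = c("b", "a"), tier = 2, tstart = 0, tend = 20000,
                    n_match = c(10, 10), block_len = c(100, 100))
  expect_identical(select_patch(6000, 11000, tie)$donor, "a")
  # a donor reaching only the left flank does not qualify
  half <- data.frame(donor = "d", tier = 1, tstart = 0, tend = 10000,
                     n_match = 1, block_len = 10000)
  expect_null(select_patch(6000, 11000, half))
  expect_null(select_patch(6000, 11000, half[0, ]))
})

test_that("tier-1 donors restore a degraded draft byte-for-byte", {
  g <- small_genome(seed = 9, n_chrom = 2)
  spec <- random_gap_spec(g, n_gaps = 4, seed = 2)
  d <- degrade_to_draft(g, spec)
  donors <- setNames(as.character(g$chromosomes),
                     paste0("asm_", names(g$chromosomes)))
  res <- fill_gaps(d$draft, list(tier1 = donors))
  expect_true(all(res$reports$status == "filled"))
  expect_true(all(res$reports$donor_tier == 1))
  expect_identical(nrow(find_gaps(res$assembly)), 0L)
  expect_identical(as.character(res$assembly), as.character(g$chromosomes))
})

test_that("filling is conservative outside gaps and identity without gaps", {
  g <- small_genome(seed = 10, n_chrom = 1)
  donors <- setNames(as.character(g$chromosomes), "asm1")
  res0 <- fill_gaps(g$chromosomes, list(tier1 = donors))
  expect_identical(as.character(res0$assembly), as.character(g$chromosomes))
  expect_identical(nrow(res0$reports), 0L)
  spec <- data.frame(chrom = "chr01", start = 150000, end = 154000)
  d <- degrade_to_draft(g, spec)
  res <- fill_gaps(d$draft, list(tier1 = donors))
  filled <- chr_string(res$assembly, 1)
  draft <- chr_string(d$draft, 1)
  # outside the anchor window around the gap nothing changed
  expect_identical(substr(filled, 1, 140000), substr(draft, 1, 140000))
  expect_identical(substr(filled, 165000, nchar(filled)),
                   substr(draft, 165000, nchar(draft)))
})

test_that("removing tier-1 donors falls through to spanning reads", {
  g <- small_genome(seed = 12, n_chrom = 1)
  spec <- data.frame(chrom = "chr01", start = 120000, end = 124000)
  d <- degrade_to_draft(g, spec)
  src <- chr_string(g$chromosomes, 1)
  # two synthetic ONT reads spanning the gap with generous flanks
  reads <- c(ont_a = substr(src, 110001, 135000),
             ont_b = substr(src, 112001, 131000))
  res <- fill_gaps(d$draft, list(tier1 = character(0), tier2 = reads))
  expect_identical(res$reports$status, "filled")
  expect_equal(res$reports$donor_tier, 2)
  expect_identical(res$reports$donor_name, "ont_a")  # longest block
  expect_identical(as.character(res$assembly), as.character(g$chromosomes))
  # with no spanning donor at all the gap stays, as a status not an error
  stub <- c(stub = substr(src, 110001, 121000))
  res2 <- fill_gaps(d$draft, list(tier1 = character(0), tier2 = stub))
  expect_identical(res2$reports$status, "unfilled")
  expect_identical(as.character(res2$assembly), as.character(d$draft))
})

test_that("junction verification distinguishes spanned from unspanned fills", {
  g <- small_genome(seed = 13, n_chrom = 1)
  spec <- data.frame(chrom = "chr01", start = 100000, end = 104000)
  d <- degrade_to_draft(g, spec)
  donors <- setNames(as.character(g$chromosomes), "asm1")
  res <- fill_gaps(d$draft, list(tier1 = donors))
  jl <- res$reports$junction_left
  jr <- res$reports$junction_right
  mk_aln <- function(tstart, tend)
    data.frame(qname = paste0("r", seq_along(tstart)), qlen = tend - tstart,
               qstart = 0, qend = tend - tstart, strand = "+",
               tname = "chr01", tlen = 3e5, tstart = tstart, tend = tend,
               n_match = tend - tstart, block_len = tend - tstart, mapq = 60)
  good <- mk_aln(c(jl - 5000, jr - 5000), c(jl + 5000, jr + 5000))
  v <- verify_fills(res, good)
  expect_identical(v$verification, "spanned")
  onesided <- mk_aln(jl - 1000, jl + 3000)   # stops short of the right junction
  v2 <- verify_fills(res, onesided)
  expect_identical(v2$verification, "unspanned")
  # simulated error-free 20x ONT reads span every junction
  reads <- simulate_reads(g, "ont_ultra", coverage = 20, seed = 3)
  aln <- read_truth_alignments(reads,
                               setNames(Biostrings::width(g$chromosomes),
                                        names(g$chromosomes)))
  v3 <- verify_fills(res, aln)
  expect_identical(v3$verification, "spanned")
})

test_that("a gap inside a perfect satellite array is reported unfilled", {
  # every flank k-mer inside an exact tandem array recurs in every unit, so
  # no donor can be uniquely anchored: an identifiability limit, not an error
  g <- small_genome(seed = 14, n_chrom = 1)
  cen <- g$centromeres
  gap <- data.frame(chrom = "chr01", start = cen$start + 20000,
                    end = cen$start + 24000)
  d <- degrade_to_draft(g, gap)
  donors <- setNames(as.character(g$chromosomes), "asm1")
  res <- fill_gaps(d$draft, list(tier1 = donors))
  expect_identical(res$reports$status, "unfilled")
  expect_identical(as.character(res$assembly), as.character(d$draft))
})
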
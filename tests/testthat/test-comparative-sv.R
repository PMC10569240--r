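test_that("the internal caller recovers planted SVs with exact types and lengths", {
  g <- small_genome(seed = 51, n_chrom = 1, chrom_length = 4e5)
  specs <- data.frame(type = c("INS", "DEL", "DUP", "INV"),
                      chrom = "chr01",
                      pos = c(30000, 80000, 150000, 320000),
                      length = c(664, 2000, 5000, 3000))
  va <- make_variant_accession(g, specs, "accA", seed = 52)
  calls <- call_svs_internal(g$chromosomes, va$sequences, "accA")
  expect_identical(nrow(calls), 4L)
  calls <- calls[order(calls$ref_start), ]
  expect_identical(calls$type, specs$type)
  # INS/DEL/DUP lengths exact; the INV boundary is ambiguous by a base or
  # two when terminal bases coincide with their reverse complement context
  expect_equal(calls$length[calls$type != "INV"],
               specs$length[specs$type != "INV"])
  expect_lt(abs(calls$length[calls$type == "INV"] - 3000), 10)
  # breakpoints within a few bp of truth (left-normalized representation)
  expect_true(all(abs(calls$ref_start -
                        c(30000, 80000, 150000, 320000)) <= 10))
  # DUP covers the planted source span
  dup <- calls[calls$type == "DUP", ]
  expect_lte(abs(dup$ref_end - 155000), 10)
  # identical sequences: no calls at all
  expect_identical(nrow(call_svs_internal(g$chromosomes, g$chromosomes)), 0L)
})

test_that("SV recovery is exact across accessions and seeds", {
  g <- small_genome(seed = 53, n_chrom = 1, chrom_length = 4e5)
  withr::with_seed(54, {
    for (acc in 1:3) {
      pos <- sort(sample(seq(30000, 360000, by = 20000), 4))
      specs <- data.frame(type = sample(c("INS", "DEL", "DUP"), 4,
                                        replace = TRUE),
                          chrom = "chr01", pos = pos,
                          length = sample(c(300, 664, 1500, 4000)))
      va <- make_variant_accession(g, specs, paste0("acc", acc),
                                   seed = 54 + acc)
      calls <- call_svs_internal(g$chromosomes, va$sequences,
                                 paste0("acc", acc))
      calls <- calls[order(calls$ref_start), ]
      expect_identical(calls$type, specs$type)
      expect_equal(calls$length, specs$length)
      expect_true(all(abs(calls$ref_start - specs$pos) <= 60))
    }
  })
})

test_that("novel regions are the complement of aligned self intervals", {
  aln <- data.frame(qname = "c1", qlen = 100, qstart = 0, qend = 50,
                    strand = "+", tname = "other", tlen = 1000,
                    tstart = 0, tend = 50, n_match = 50, block_len = 50,
                    mapq = 60)
  nr <- novel_regions(aln, c(c1 = 100), min_len = 10)
  expect_equal(nr$regions$start, 50)
  expect_equal(nr$regions$end, 100)
  full <- data.frame(qname = "c1", qlen = 100, qstart = 0, qend = 100,
                     strand = "+", tname = "other", tlen = 1000,
                     tstart = 0, tend = 100, n_match = 100, block_len = 100,
                     mapq = 60)
  expect_identical(nrow(novel_regions(full, c(c1 = 100), 10)$regions), 0L)
  genes <- data.frame(chrom = "c1", start = c(60, 40), end = c(90, 70),
                      gene_id = c("inNovel", "straddles"))
  nr2 <- novel_regions(aln, c(c1 = 100), min_len = 10, genes = genes)
  expect_identical(nr2$novel_genes, "inNovel")
})

test_that("the 5-kb gene screen respects exact boundaries", {
  genes <- data.frame(chrom = "c1", start = 50000, end = 52000,
                      gene_id = "gA", is_flowering = TRUE)
  mk_ins <- function(pos) data.frame(
    accession_id = "acc1", ref_chrom = "c1", ref_start = pos, ref_end = pos,
    type = "INS", length = 100, source = "internal", seq = NA)
  expect_identical(
    screen_gene_svs(mk_ins(50000 - 4999), genes)$affected_genes, "gA")
  expect_length(
    screen_gene_svs(mk_ins(50000 - 5001), genes)$affected_genes, 0)
  expect_identical(
    screen_gene_svs(mk_ins(50000 - 5000), genes)$affected_genes, "gA")
  expect_length(
    screen_gene_svs(mk_ins(52000 + 5000), genes)$affected_genes, 0)
  expect_identical(
    screen_gene_svs(mk_ins(52000 + 4999), genes)$affected_genes, "gA")
  # interval SVs overlap the flanked window half-open
  del <- data.frame(accession_id = "acc1", ref_chrom = "c1",
                    ref_start = 44000, ref_end = 45001, type = "DEL",
                    length = 1001, source = "internal", seq = NA)
  expect_identical(screen_gene_svs(del, genes)$affected_genes, "gA")
  del2 <- del; del2$ref_end <- 45000
  expect_length(screen_gene_svs(del2, genes)$affected_genes, 0)
  # flowering_only drops non-flowering genes
  g2 <- rbind(genes, data.frame(chrom = "c1", start = 80000, end = 81000,
                                gene_id = "gB", is_flowering = FALSE))
  both <- rbind(mk_ins(50000), mk_ins(80500))
  expect_setequal(screen_gene_svs(both, g2)$affected_genes, c("gA", "gB"))
  expect_identical(screen_gene_svs(both, g2,
                                   flowering_only = TRUE)$affected_genes, "gA")
})

test_that("the screen is invariant under a coordinate shift", {
  withr::with_seed(55, {
    genes <- data.frame(chrom = "c1", start = sort(sample(1e5, 5)) + 10000,
                        gene_id = paste0("g", 1:5), is_flowering = TRUE)
    genes$end <- genes$start + 2000
    svs <- data.frame(accession_id = "a", ref_chrom = "c1",
                      ref_start = sample(1.2e5, 8), type = "INS",
                      length = 100, source = "internal", seq = NA)
    svs$ref_end <- svs$ref_start
    base <- screen_gene_svs(svs, genes)$affected_genes
    off <- 31307
    genes2 <- transform(genes, start = start + off, end = end + off)
    svs2 <- transform(svs, ref_start = ref_start + off, ref_end = ref_end + off)
    expect_identical(screen_gene_svs(svs2, genes2)$affected_genes, base)
  })
})

test_that("ecotype frequencies and diagnostic genes follow the strict rule", {
  panel <- data.frame(accession_id = c("w1", "w2", "w3", "s1", "s2"),
                      ecotype = c("winter", "winter", "winter",
                                  "spring", "spring"))
  hits <- data.frame(accession_id = c("w1", "w2", "w3", "w1"),
                     gene_id = c("gDiag", "gDiag", "gDiag", "gPart"))
  ef <- ecotype_frequencies(hits, panel)
  fq <- ef$frequencies
  expect_identical(fq$frequency[fq$gene_id == "gDiag" & fq$ecotype == "winter"], 1)
  expect_identical(fq$frequency[fq$gene_id == "gDiag" & fq$ecotype == "spring"], 0)
  expect_equal(fq$frequency[fq$gene_id == "gPart" & fq$ecotype == "winter"],
               1 / 3)
  expect_identical(ef$diagnostic$gene_id, "gDiag")
  expect_identical(ef$diagnostic$fixed_in, "winterish")
  # frequencies invariant to accession ordering
  ef2 <- ecotype_frequencies(hits[c(4, 2, 1, 3), ], panel[c(5, 3, 1, 2, 4), ])
  sorted <- function(df) {
    df <- df[order(df$gene_id, df$ecotype), ]
    rownames(df) <- NULL
    df
  }
  expect_identical(sorted(ef2$frequencies), sorted(fq))
  expect_error(
    ecotype_frequencies(data.frame(accession_id = "zz", gene_id = "g"),
                        panel),
    "unlabeled")
})
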
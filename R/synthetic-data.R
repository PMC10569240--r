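# Synthetic genomes with planted ground truth: terminal telomeric arrays,
# a centromeric tandem-repeat block, interspersed genes (with a flagged
# "flowering" subset), N-gap degradation, long reads with filterable
# metadata, and accession variants carrying typed structural variants.
# Every generator is a pure function of (config, seed).

TELOMERE_MOTIF <- "CCCTAAA"

#' Configuration for the synthetic genome generator
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length(s) in bp, recycled to `n_chrom`.
#' @param telomere_copies Tandem copies of the telomeric 7-mer per end.
#' @param motif Telomeric motif (5' C-rich strand).
#' @param centromere_length Length of the planted centromeric array (bp);
#'   recycled.
#' @param centromere_unit_length Satellite monomer length (bp), default 176.
#' @param genes_per_chrom Genes planted per chromosome.
#' @param flowering_fraction Fraction of genes flagged flowering-related.
#' @param gene_length_range Range of gene lengths (bp).
#' @param gc Background GC content.
#' @param seed RNG seed; the whole genome is deterministic given the config.
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(n_chrom = 2, chrom_length = 5e5,
                          telomere_copies = 100, motif = TELOMERE_MOTIF,
                          centromere_length = 5e4,
                          centromere_unit_length = 176,
                          genes_per_chrom = 20, flowering_fraction = 0.2,
                          gene_length_range = c(1000, 3000),
                          gc = 0.5, seed = 1) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_length = rep_len(as.integer(chrom_length), n_chrom),
              telomere_copies = as.integer(telomere_copies),
              motif = toupper(motif),
              centromere_length = rep_len(as.integer(centromere_length), n_chrom),
              centromere_unit_length = as.integer(centromere_unit_length),
              genes_per_chrom = as.integer(genes_per_chrom),
              flowering_fraction = flowering_fraction,
              gene_length_range = as.integer(gene_length_range),
              gc = gc, seed = as.integer(seed))
  if (cfg$n_chrom < 1) stop("need at least one chromosome")
  tel_bp <- 2L * cfg$telomere_copies * nchar(cfg$motif)
  if (any(cfg$centromere_length + tel_bp + 2000L > cfg$chrom_length))
    stop("sizing error: centromere plus telomeres longer than chromosome")
  class(cfg) <- "genome_config"
  cfg
}

#' Generate a synthetic genome with planted ground truth
#'
#' Each chromosome carries exact tandem telomeric arrays at both termini
#' (C-rich motif on the left end, its reverse complement on the right), a
#' centromeric satellite array of a fixed monomer placed mid-chromosome, and
#' non-overlapping genes that avoid the centromere and the telomeric arrays.
#' Background sequence is i.i.d. over \{A,C,G,T\} at the configured GC.
#'
#' @param config A [genome_config()].
#' @return A list of class `genome_truth` with elements `chromosomes`
#'   (DNAStringSet), `telomeres`, `centromeres`, `genes` (data frames with
#'   0-based half-open coordinates), and `config`.
#' @export
make_genome <- function(config = genome_config()) {
  if (!inherits(config, "genome_config")) stop("config must be a genome_config")
  .with_seed(config$seed, {
    motif <- config$motif
    motif_rc <- revcomp(motif)
    tel_len <- config$telomere_copies * nchar(motif)
    chroms <- character(config$n_chrom)
    names(chroms) <- sprintf("chr%02d", seq_len(config$n_chrom))
    tel <- cen <- genes <- list()
    for (i in seq_len(config$n_chrom)) {
      L <- config$chrom_length[i]
      cl <- config$centromere_length[i]
      cname <- names(chroms)[i]
      unit <- random_dna(config$centromere_unit_length, config$gc)
      array_seq <- substr(strrep(unit, ceiling(cl / nchar(unit))), 1, cl)
      cen_start <- (L - cl) %/% 2L
      bg1 <- random_dna(cen_start - tel_len, config$gc)
      bg2 <- random_dna(L - cen_start - cl - tel_len, config$gc)
      chroms[i] <- paste0(strrep(motif, config$telomere_copies), bg1,
                          array_seq, bg2,
                          strrep(motif_rc, config$telomere_copies))
      stopifnot(nchar(chroms[i]) == L)
      tel[[i]] <- data.frame(chrom = cname, side = c("left", "right"),
                             array_length = tel_len)
      cen[[i]] <- data.frame(chrom = cname, start = cen_start,
                             end = cen_start + cl, repeat_unit = unit,
                             unit_length = nchar(unit))
      genes[[i]] <- .plant_genes(cname, L, tel_len, cen_start, cen_start + cl,
                                 config)
    }
    genes <- do.call(rbind, genes)
    genes$gene_id <- sprintf("%s_g%03d", genes$chrom,
                             stats::ave(seq_len(nrow(genes)), genes$chrom,
                                        FUN = seq_along))
    n_fl <- round(config$flowering_fraction * nrow(genes))
    genes$is_flowering <- seq_len(nrow(genes)) %in%
      sample(seq_len(nrow(genes)), n_fl)
    out <- list(chromosomes = Biostrings::DNAStringSet(chroms),
                telomeres = do.call(rbind, tel),
                centromeres = do.call(rbind, cen),
                genes = genes, config = config, seed = config$seed)
    class(out) <- "genome_truth"
    out
  })
}

# Non-overlapping gene intervals avoiding telomeric arrays and centromere.
.plant_genes <- function(chrom, L, tel_len, cen_start, cen_end, config) {
  n <- config$genes_per_chrom
  rng <- config$gene_length_range
  placed_s <- placed_e <- numeric(0)
  guard <- 0
  while (length(placed_s) < n && guard < 200 * n) {
    guard <- guard + 1
    len <- sample(rng[1]:rng[2], 1)
    s <- sample.int(L - tel_len - len - tel_len, 1) + tel_len - 1L
    e <- s + len
    if (s < cen_end && e > cen_start) next            # overlaps centromere
    if (any(s < placed_e & e > placed_s)) next        # overlaps a gene
    placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
  }
  o <- order(placed_s)
  data.frame(chrom = chrom, start = placed_s[o], end = placed_e[o],
             strand = sample(c("+", "-"), length(o), replace = TRUE),
             gene_id = NA_character_, is_flowering = FALSE,
             stringsAsFactors = FALSE)
}

#' Mask intervals of a genome with N-runs to emulate a gapped draft
#'
#' @param genome A `genome_truth` (or DNAStringSet / named character).
#' @param gap_spec Data frame with `chrom, start, end` (0-based half-open);
#'   intervals must be in range, non-overlapping, and (unless
#'   `allow_telomere_gaps`) must not intersect the terminal telomeric arrays.
#' @param allow_telomere_gaps Permit gaps inside telomeric arrays.
#' @return List with `draft` (DNAStringSet) and `gaps` (truth table with the
#'   masked sequence per gap, for oracle comparisons).
#' @export
degrade_to_draft <- function(genome, gap_spec, allow_telomere_gaps = FALSE) {
  seqs <- if (inherits(genome, "genome_truth"))
    .as_chr_seqs(genome$chromosomes) else .as_chr_seqs(genome)
  gs <- gap_spec[order(gap_spec$chrom, gap_spec$start), , drop = FALSE]
  if (nrow(gs) > 0) {
    if (!all(gs$chrom %in% names(seqs))) stop("gap on unknown chromosome")
    if (any(gs$start < 0 | gs$end > nchar(seqs)[gs$chrom] | gs$start >= gs$end))
      stop("gap interval out of range")
    ov <- unlist(tapply(seq_len(nrow(gs)), gs$chrom, function(ix) {
      if (length(ix) < 2) return(FALSE)
      s <- gs$start[ix]; e <- gs$end[ix]
      c(FALSE, s[-1] < e[-length(e)])
    }))
    if (any(ov)) stop("overlapping gap intervals rejected")
    if (!allow_telomere_gaps && inherits(genome, "genome_truth")) {
      tl <- genome$telomeres
      for (i in seq_len(nrow(gs))) {
        arr <- tl$array_length[tl$chrom == gs$chrom[i]][1]
        L <- nchar(seqs[[gs$chrom[i]]])
        if (gs$start[i] < arr || gs$end[i] > L - arr)
          stop("gap intersects a terminal telomeric array")
      }
    }
  }
  masked <- character(nrow(gs))
  for (i in seq_len(nrow(gs))) {
    s <- seqs[[gs$chrom[i]]]
    masked[i] <- substr(s, gs$start[i] + 1, gs$end[i])
    substr(s, gs$start[i] + 1, gs$end[i]) <-
      strrep("N", gs$end[i] - gs$start[i])
    seqs[[gs$chrom[i]]] <- s
  }
  gaps <- if (nrow(gs) > 0) {
    data.frame(gap_id = sprintf("gap%03d", seq_len(nrow(gs))),
               chrom = gs$chrom, start = gs$start, end = gs$end,
               masked_seq = masked, stringsAsFactors = FALSE)
  } else {
    data.frame(gap_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0),
               masked_seq = character(0))
  }
  list(draft = Biostrings::DNAStringSet(seqs), gaps = gaps)
}

#' Draw a random, valid gap specification over a synthetic genome
#'
#' Gaps are placed away from the telomeric arrays, non-overlapping, and
#' spread across chromosomes round-robin (so e.g. 13 gaps land on up to 13
#' distinct chromosomes first). Gaps are also kept clear of the planted
#' centromeric satellite array: inside a perfect tandem array every flank
#' k-mer recurs in every repeat unit, so no flank-anchored method could
#' place a donor there — such a gap is unfillable by construction, not a
#' property the pipeline should be probed with by default.
#'
#' @param genome A `genome_truth`.
#' @param n_gaps Number of gaps.
#' @param len_range Gap length range (bp).
#' @param seed RNG seed.
#' @param margin Minimum distance from the telomeric arrays (bp).
#' @export
random_gap_spec <- function(genome, n_gaps = 13, len_range = c(2000, 8000),
                            seed = 1, margin = 25000) {
  .with_seed(seed, {
    seqs <- .as_chr_seqs(genome$chromosomes)
    tl <- genome$telomeres
    cen <- genome$centromeres
    chrom_cycle <- rep_len(names(seqs), n_gaps)
    out <- list()
    for (i in seq_len(n_gaps)) {
      cname <- chrom_cycle[i]
      L <- nchar(seqs[[cname]])
      arr <- tl$array_length[tl$chrom == cname][1]
      cc <- cen[cen$chrom == cname, ]
      lo <- arr + margin
      hi <- L - arr - margin
      for (try in 1:100) {
        len <- sample(len_range[1]:len_range[2], 1)
        s <- sample(lo:(hi - len), 1)
        e <- s + len
        # keep the widest flank (20 kb) outside the satellite array
        if (nrow(cc) == 1 && s - 21000 < cc$end && e + 21000 > cc$start) next
        # keep gaps farther apart than the widest flank so fills never
        # touch a neighbouring gap's region
        clash <- any(vapply(out, function(g)
          g$chrom == cname && s < g$end + 21000 && e > g$start - 21000,
          logical(1)))
        if (!clash) { out[[i]] <- list(chrom = cname, start = s, end = e); break }
      }
    }
    do.call(rbind, lapply(out, as.data.frame))
  })
}

.read_profiles <- list(
  ont_ultra = list(min_length = 30000, meanlog = log(60000), sdlog = 0.45,
                   mean_q = c(12, 2), filtlong = c(96, 2.5)),
  hifi = list(min_length = 5000, meanlog = log(15000), sdlog = 0.25,
              mean_q = c(30, 3), passes_lambda = 8, snr = c(8, 1.5))
)

#' Simulate long reads from a genome
#'
#' Reads are substrings of the genome (error-free by default; an optional
#' uniform substitution rate is available) with metadata populated so the
#' read filters are exercisable: `mean_q` and `filtlong_quality` for ONT
#' ultra-long reads, `passes` and `snr` for HiFi. Source coordinates are
#' recorded as ground truth.
#'
#' @param genome `genome_truth`, DNAStringSet, or named character vector.
#' @param profile `"ont_ultra"` or `"hifi"`.
#' @param coverage Target depth; sampling stops once total bases reach
#'   `coverage * genome size`.
#' @param seed RNG seed.
#' @param error_rate Uniform substitution error rate (default 0).
#' @param min_length Override the profile's minimum read length.
#' @return List with `sequences` (DNAStringSet) and `meta` (data frame:
#'   `read_id, chrom, start, end, length, mean_q, filtlong_quality, passes,
#'   snr`; coordinates 0-based half-open on the source chromosome).
#' @export
simulate_reads <- function(genome, profile = c("ont_ultra", "hifi"),
                           coverage = 30, seed = 1, error_rate = 0,
                           min_length = NULL) {
  profile <- match.arg(profile)
  if (coverage <= 0) stop("coverage must be > 0")
  p <- .read_profiles[[profile]]
  if (!is.null(min_length)) p$min_length <- min_length
  seqs <- if (inherits(genome, "genome_truth"))
    .as_chr_seqs(genome$chromosomes) else .as_chr_seqs(genome)
  lens <- nchar(seqs)
  target <- coverage * sum(lens)
  .with_seed(seed, {
    reads <- character(0); meta <- list(); total <- 0; idx <- 0
    while (total < target) {
      idx <- idx + 1
      ci <- sample.int(length(seqs), 1, prob = lens)
      L <- lens[ci]
      rl <- round(stats::rlnorm(1, p$meanlog, p$sdlog))
      rl <- max(p$min_length, min(rl, L))
      s <- sample.int(L - rl + 1, 1) - 1L   # 0-based
      rd <- substr(seqs[[ci]], s + 1, s + rl)
      if (error_rate > 0) {
        nmut <- stats::rbinom(1, rl, error_rate)
        if (nmut > 0) {
          pos <- sample.int(rl, nmut)
          for (pp in pos) {
            cur <- substr(rd, pp, pp)
            substr(rd, pp, pp) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
          }
        }
      }
      reads <- c(reads, rd); total <- total + rl
      meta[[idx]] <- data.frame(
        read_id = sprintf("%s_read%05d", profile, idx),
        chrom = names(seqs)[ci], start = s, end = s + rl, length = rl,
        mean_q = max(1, rnorm(1, p$mean_q[1], p$mean_q[2])),
        filtlong_quality = if (profile == "ont_ultra")
          min(100, max(0, rnorm(1, p$filtlong[1], p$filtlong[2]))) else NA_real_,
        passes = if (profile == "hifi") 1L + rpois(1, p$passes_lambda) else
          NA_integer_,
        snr = if (profile == "hifi") max(0.5, rnorm(1, p$snr[1], p$snr[2])) else
          NA_real_,
        stringsAsFactors = FALSE)
    }
    meta <- do.call(rbind, meta)
    names(reads) <- meta$read_id
    list(sequences = Biostrings::DNAStringSet(reads), meta = meta)
  })
}

#' Simulate chromosome-end (telomeric) reads
#'
#' Reads whose terminus coincides with a chromosome end: right-end reads
#' cover `[L - len, L)`, left-end reads `[0, len)`. These emulate sequenced
#' molecules running off the physical chromosome end and are the natural
#' input for telomere patching.
#'
#' @param genome `genome_truth` or sequence set.
#' @param n_per_end Reads per chromosome end.
#' @param profile Read-length profile (see [simulate_reads()]).
#' @param seed RNG seed.
#' @return List with `sequences` and `meta` (as [simulate_reads()], plus a
#'   `side` column).
#' @export
simulate_end_reads <- function(genome, n_per_end = 5,
                               profile = c("ont_ultra", "hifi"), seed = 1) {
  profile <- match.arg(profile)
  p <- .read_profiles[[profile]]
  seqs <- if (inherits(genome, "genome_truth"))
    .as_chr_seqs(genome$chromosomes) else .as_chr_seqs(genome)
  .with_seed(seed, {
    reads <- character(0); meta <- list(); idx <- 0
    for (cname in names(seqs)) {
      L <- nchar(seqs[[cname]])
      for (side in c("left", "right")) {
        for (j in seq_len(n_per_end)) {
          idx <- idx + 1
          rl <- min(L, max(p$min_length, round(stats::rlnorm(1, p$meanlog,
                                                             p$sdlog))))
          s <- if (side == "left") 0 else L - rl
          meta[[idx]] <- data.frame(
            read_id = sprintf("end_%s_%s_%02d", cname, side, j),
            chrom = cname, side = side, start = s, end = s + rl, length = rl,
            mean_q = max(1, rnorm(1, p$mean_q[1], p$mean_q[2])),
            stringsAsFactors = FALSE)
          reads <- c(reads, substr(seqs[[cname]], s + 1, s + rl))
        }
      }
    }
    meta <- do.call(rbind, meta)
    names(reads) <- meta$read_id
    list(sequences = Biostrings::DNAStringSet(reads), meta = meta)
  })
}

#' PAF-style alignment records from simulated-read ground truth
#'
#' For error-free simulated reads the source coordinates are exact, so the
#' truth table doubles as a perfect aligner output.
#'
#' @param reads Result of [simulate_reads()].
#' @param target_lengths Named lengths of the target sequences; defaults to
#'   the source chromosome lengths implied by the metadata.
#' @export
read_truth_alignments <- function(reads, target_lengths = NULL) {
  m <- reads$meta
  if (is.null(target_lengths)) {
    target_lengths <- tapply(m$end, m$chrom, max)
  }
  out <- data.frame(qname = m$read_id, qlen = m$length, qstart = 0,
                    qend = m$length, strand = "+", tname = m$chrom,
                    tlen = as.numeric(target_lengths[m$chrom]),
                    tstart = m$start, tend = m$end,
                    n_match = m$length, block_len = m$length, mapq = 60,
                    tags = "", stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply structural-variant specs to a genome, producing a variant accession
#'
#' Supported types: `INS` (insertion of `seq` at `pos`), `DEL` (deletion of
#' `[pos, pos+length)`), `DUP` (tandem duplication: a second copy of
#' `[pos, pos+length)` placed immediately after the source), `INV`
#' (in-place reverse complement of `[pos, pos+length)`).
#'
#' @param genome `genome_truth` or sequence set (the reference).
#' @param sv_specs Data frame with columns `type, chrom, pos, length` and
#'   optional `seq` (INS payload; random if missing).
#' @param accession_id Label carried into the truth table.
#' @param ecotype Optional ecotype label (`spring`, `semi-winter`, `winter`).
#' @param seed Seed for random INS payloads.
#' @return List with `sequences` (variant DNAStringSet) and `truth` (both
#'   reference and variant coordinates per SV, 0-based half-open).
#' @export
make_variant_accession <- function(genome, sv_specs, accession_id = "acc1",
                                   ecotype = NA_character_, seed = 1) {
  seqs <- if (inherits(genome, "genome_truth"))
    .as_chr_seqs(genome$chromosomes) else .as_chr_seqs(genome)
  sp <- sv_specs
  if (nrow(sp) == 0) {
    return(list(sequences = Biostrings::DNAStringSet(seqs),
                truth = .empty_sv_truth()))
  }
  if (!all(sp$type %in% c("INS", "DEL", "DUP", "INV")))
    stop("unknown SV type")
  if (any(sp$length <= 0)) stop("SV length must be > 0")
  if (is.null(sp$seq)) sp$seq <- NA_character_
  sp$ref_start <- sp$pos
  sp$ref_end <- ifelse(sp$type == "INS", sp$pos, sp$pos + sp$length)
  if (!all(sp$chrom %in% names(seqs))) stop("SV on unknown chromosome")
  if (any(sp$ref_end > nchar(seqs)[sp$chrom] | sp$ref_start < 0))
    stop("SV position out of range")
  # reject overlapping specs (point INS collide only when inside another SV)
  sp <- sp[order(sp$chrom, sp$ref_start), , drop = FALSE]
  for (cname in unique(sp$chrom)) {
    ix <- which(sp$chrom == cname)
    if (length(ix) < 2) next
    s <- sp$ref_start[ix]; e <- pmax(sp$ref_end[ix], sp$ref_start[ix] + 1)
    if (any(s[-1] < e[-length(e)])) stop("overlapping SV specs rejected")
  }
  .with_seed(seed, {
    need <- sp$type == "INS" & is.na(sp$seq)
    sp$seq[need] <- vapply(sp$length[need], random_dna, "", gc = 0.5)
  })
  # apply right-to-left so earlier reference coordinates stay valid
  sp <- sp[order(sp$chrom, -sp$ref_start), , drop = FALSE]
  for (i in seq_len(nrow(sp))) {
    s <- seqs[[sp$chrom[i]]]
    a <- sp$ref_start[i]; b <- sp$ref_end[i]
    piece <- switch(sp$type[i],
      INS = sp$seq[i],
      DEL = "",
      DUP = strrep(substr(s, a + 1, b), 2),
      INV = revcomp(substr(s, a + 1, b)))
    if (sp$type[i] == "DUP") sp$seq[i] <- substr(s, a + 1, b)
    if (sp$type[i] == "DEL") sp$seq[i] <- substr(s, a + 1, b)
    seqs[[sp$chrom[i]]] <- paste0(substr(s, 1, a), piece,
                                  substr(s, b + 1, nchar(s)))
  }
  # lift reference coordinates to variant coordinates
  sp <- sp[order(sp$chrom, sp$ref_start), , drop = FALSE]
  delta <- ifelse(sp$type == "INS", sp$length,
           ifelse(sp$type == "DEL", -sp$length,
           ifelse(sp$type == "DUP", sp$length, 0)))
  sp$var_start <- sp$var_end <- NA_real_
  for (cname in unique(sp$chrom)) {
    ix <- which(sp$chrom == cname)
    shift <- cumsum(c(0, delta[ix][-length(ix)]))
    sp$var_start[ix] <- sp$ref_start[ix] + shift
    span <- ifelse(sp$type[ix] == "DEL", 0,
            ifelse(sp$type[ix] == "DUP", 2 * sp$length[ix], sp$length[ix]))
    sp$var_end[ix] <- sp$var_start[ix] + span
  }
  truth <- data.frame(accession_id = accession_id, ecotype = ecotype,
                      type = sp$type, chrom = sp$chrom,
                      ref_start = sp$ref_start, ref_end = sp$ref_end,
                      length = sp$length,
                      var_start = sp$var_start, var_end = sp$var_end,
                      seq = sp$seq, stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(sequences = Biostrings::DNAStringSet(seqs), truth = truth)
}

.empty_sv_truth <- function() {
  data.frame(accession_id = character(0), ecotype = character(0),
             type = character(0), chrom = character(0),
             ref_start = numeric(0), ref_end = numeric(0),
             length = numeric(0), var_start = numeric(0),
             var_end = numeric(0), seq = character(0))
}

#' Reverse the edits of a variant accession, restoring the reference
#'
#' @param variant Sequences of the variant accession.
#' @param truth Truth table from [make_variant_accession()].
#' @export
revert_variant <- function(variant, truth) {
  seqs <- .as_chr_seqs(variant)
  tr <- truth[order(truth$chrom, -truth$var_start), , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    s <- seqs[[tr$chrom[i]]]
    a <- tr$var_start[i]; b <- tr$var_end[i]
    piece <- switch(tr$type[i],
      INS = "",
      DEL = tr$seq[i],
      DUP = tr$seq[i],
      INV = revcomp(substr(s, a + 1, b)))
    seqs[[tr$chrom[i]]] <- paste0(substr(s, 1, a), piece,
                                  substr(s, b + 1, nchar(s)))
  }
  Biostrings::DNAStringSet(seqs)
}
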
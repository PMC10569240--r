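# Long-read filter rules, canonical k-mer statistics (genome size, assembly
# QV), and assembly summary statistics.

.meta_df <- function(reads) {
  if (is.data.frame(reads)) return(reads)
  if (is.list(reads) && !is.null(reads$meta)) return(reads$meta)
  stop("expected a read-metadata data frame (or simulate_reads() result)")
}

.filter_report <- function(meta, keep, unscorable) {
  kept <- meta[keep & !unscorable, , drop = FALSE]
  list(kept = kept,
       report = list(
         n_in = nrow(meta),
         n_kept = nrow(kept),
         n_dropped = sum(!keep & !unscorable),
         n_unscorable = sum(unscorable),
         bases_in = sum(meta$length),
         bases_kept = sum(kept$length)))
}

#' Filter ONT ultra-long reads
#'
#' Two stages mirror a pass-filter followed by an assembly-input filter:
#' `"pass"` keeps reads with mean Phred quality >= 7 and length >= 10 kb
#' (i.e. fragments < 10 kb and mean QV < 7 are dropped); `"assembly"`
#' additionally requires length >= 30 kb and a Filtlong-style percent score
#' strictly > 90. Reads with missing metadata are counted separately as
#' unscorable.
#'
#' @param reads Read-metadata data frame (columns `length`, `mean_q`,
#'   `filtlong_quality`) or a [simulate_reads()] result.
#' @param stage `"pass"` or `"assembly"`.
#' @param min_q,min_len_pass,min_len_assembly,min_filtlong Thresholds.
#' @return List with `kept` (metadata of retained reads) and `report`.
#' @export
filter_ont <- function(reads, stage = c("pass", "assembly"), min_q = 7,
                       min_len_pass = 10000, min_len_assembly = 30000,
                       min_filtlong = 90) {
  stage <- match.arg(stage)
  meta <- .meta_df(reads)
  need <- c("length", "mean_q", if (stage == "assembly") "filtlong_quality")
  unscorable <- Reduce(`|`, lapply(need, function(cc) is.na(meta[[cc]])))
  keep <- !unscorable & meta$mean_q >= min_q & meta$length >= min_len_pass
  if (stage == "assembly")
    keep <- keep & meta$length >= min_len_assembly &
      meta$filtlong_quality > min_filtlong
  keep[is.na(keep)] <- FALSE
  .filter_report(meta, keep, unscorable)
}

#' Filter HiFi subreads
#'
#' Keeps subreads with at least `min_passes` sequencing passes and signal-to-
#' noise ratio >= `min_snr` (boundary values are kept; only strictly
#' sub-threshold reads are dropped).
#'
#' @inheritParams filter_ont
#' @param min_passes,min_snr Thresholds (defaults 3 and 2.5).
#' @export
filter_hifi <- function(reads, min_passes = 3, min_snr = 2.5) {
  meta <- .meta_df(reads)
  unscorable <- is.na(meta$passes) | is.na(meta$snr)
  keep <- !unscorable & meta$passes >= min_passes & meta$snr >= min_snr
  keep[is.na(keep)] <- FALSE
  .filter_report(meta, keep, unscorable)
}

#' Canonical k-mer depth histogram
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) over a read set and tabulates how many distinct k-mers occur
#' at each depth. Windows containing N are skipped; reads shorter than k
#' contribute nothing.
#'
#' @param reads DNAStringSet, character vector, or [simulate_reads()] result.
#' @param k Odd k-mer size (default 19); an even k draws a warning.
#' @return Data frame `depth, count` with attribute `k`, class
#'   `kmer_histogram`.
#' @export
kmer_histogram <- function(reads, k = 19) {
  if (is.list(reads) && !is.null(reads$sequences)) reads <- reads$sequences
  seqs <- unname(.as_chr_seqs(reads, "reads"))
  if (k %% 2 == 0) warning("even k: canonical k-mers can be self-complementary")
  hist <- .kmer_hist_cpp(seqs, as.integer(k))
  attr(hist, "k") <- as.integer(k)
  class(hist) <- c("kmer_histogram", "data.frame")
  hist
}

#' Estimate genome size from a k-mer histogram
#'
#' Discards depths below `error_depth_cutoff`, locates the coverage peak,
#' and returns `sum(depth * count) / peak`. With `refine_peak` (the
#' default) the peak is the count-weighted mean depth of the kept
#' component rather than the raw integer mode: long-read depth histograms
#' are lumpy (depth is correlated over a read length, so neighbouring bins
#' share sampling noise) and the integer mode alone is biased by several
#' percent; for an idealized unimodal histogram the two coincide. A
#' single-bin histogram is returned untouched either way.
#'
#' @param hist A [kmer_histogram()].
#' @param error_depth_cutoff Depths below this are treated as sequencing
#'   errors and excluded (default 3).
#' @param refine_peak Quadratic sub-integer refinement of the peak.
#' @return List with `size_bp` and `peak_depth`.
#' @export
estimate_genome_size <- function(hist, error_depth_cutoff = 3,
                                 refine_peak = TRUE) {
  h <- hist[hist$depth >= error_depth_cutoff, , drop = FALSE]
  if (nrow(h) == 0 || sum(h$count) == 0)
    stop("no k-mer depth mode above the error cutoff")
  peak <- as.numeric(h$depth[which.max(h$count)])
  if (refine_peak && nrow(h) > 1) {
    # locate the coverage mode on a +-2-bin moving average (bin-level
    # counts are noisy because depth is correlated over a read length),
    # then refine to the count-weighted mean depth over bins below twice
    # the mode. The ceiling keeps the estimate local to the single-copy
    # component: repeat k-mers sit at multiples of the coverage and must
    # contribute instances to the numerator without dragging the peak up.
    grid <- seq(min(h$depth), max(h$depth))
    cnt <- numeric(length(grid))
    cnt[match(h$depth, grid)] <- h$count
    sm <- stats::filter(cnt, rep(1 / 5, 5), sides = 2)
    sm[is.na(sm)] <- 0
    m <- grid[which.max(sm)]
    win <- h$depth < 2 * m
    if (sum(h$count[win]) > 0)
      peak <- sum(as.numeric(h$depth[win]) * h$count[win]) / sum(h$count[win])
  }
  list(size_bp = sum(as.numeric(h$depth) * h$count) / peak,
       peak_depth = peak)
}

#' Merqury-style assembly quality value from k-mer support
#'
#' Every k-mer instance of the assembly is looked up in the read k-mer set
#' (canonical form). With `m` missing of `t` total instances, the per-base
#' error probability is `E = 1 - (1 - m/t)^(1/k)` and `QV = -10*log10(E)`.
#' With zero missing k-mers the QV is reported as `qv_cap` and flagged.
#'
#' @param assembly Assembly sequences.
#' @param reads Read sequences supporting the assembly.
#' @param k K-mer size (default 19).
#' @param qv_cap Reported QV when no k-mer is missing (default 99).
#' @return List: `k, kmers_total, kmers_missing, error_prob, qv, capped`.
#' @export
kmer_qv <- function(assembly, reads, k = 19, qv_cap = 99) {
  if (is.list(reads) && !is.null(reads$sequences)) reads <- reads$sequences
  asm <- unname(.as_chr_seqs(assembly, "assembly"))
  rds <- unname(.as_chr_seqs(reads, "reads"))
  if (length(rds) == 0) stop("read set is empty")
  if (max(nchar(asm)) < k) stop("assembly shorter than k")
  mm <- .kmer_missing_cpp(asm, rds, as.integer(k))
  total <- mm[["total"]]; missing <- mm[["missing"]]
  if (missing == 0) {
    return(list(k = k, kmers_total = total, kmers_missing = 0,
                error_prob = 0, qv = qv_cap, capped = TRUE))
  }
  E <- 1 - (1 - missing / total)^(1 / k)
  list(k = k, kmers_total = total, kmers_missing = missing,
       error_prob = E, qv = -10 * log10(E), capped = FALSE)
}

#' Contig/scaffold summary statistics
#'
#' N50 is the smallest length L such that sequences of length >= L together
#' cover at least half the assembly (so N50 is always a member of the input
#' length multiset).
#'
#' @param lengths Sequence lengths (non-empty).
#' @param gap_runs Lengths of N-runs in the assembly (e.g.
#'   `find_gaps()$end - find_gaps()$start`).
#' @param min_n Minimum N-run length counted as a gap (default 10).
#' @param anchored_bp Optionally, bases anchored to chromosomes, for the
#'   anchored fraction.
#' @return List: `total_bp, count, n50, gap_count, anchored_fraction`.
#' @export
assembly_stats <- function(lengths, gap_runs = numeric(0), min_n = 10,
                           anchored_bp = NULL) {
  if (length(lengths) == 0) stop("no sequence lengths supplied")
  sl <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(sl)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1]]
  list(total_bp = total, count = length(sl), n50 = n50,
       gap_count = sum(gap_runs >= min_n),
       anchored_fraction = if (is.null(anchored_bp)) NA_real_ else
         anchored_bp / total)
}

#' Mapping rate and per-target covered fraction
#'
#' @param alignments Alignment table ([read_paf()] convention).
#' @param target_lengths Named vector of target sequence lengths.
#' @param n_total_reads Total reads sequenced (denominator of the mapping
#'   rate); defaults to the number of distinct aligned query names.
#' @return List with `mapping_rate` (fraction) and `per_target` data frame
#'   (`tname, covered_bp, covered_fraction`).
#' @export
coverage_summary <- function(alignments, target_lengths,
                             n_total_reads = NULL) {
  a <- alignments
  unknown <- setdiff(unique(a$tname), names(target_lengths))
  if (length(unknown) > 0)
    stop("alignment to unknown target: ", paste(unknown, collapse = ","))
  aligned <- length(unique(a$qname))
  if (is.null(n_total_reads)) n_total_reads <- aligned
  per <- lapply(names(target_lengths), function(tn) {
    sub <- a[a$tname == tn, , drop = FALSE]
    cov <- if (nrow(sub) == 0) 0 else
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(start = sub$tstart + 1, end = sub$tend))))
    data.frame(tname = tn, covered_bp = cov,
               covered_fraction = cov / as.numeric(target_lengths[[tn]]))
  })
  list(mapping_rate = aligned / n_total_reads,
       per_target = do.call(rbind, per))
}
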
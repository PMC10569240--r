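# Centromere delimitation: candidate centromeres are continuous clusters of
# windows with high tandem-repeat density and low gene density. Tandem
# density comes from a single-pass periodicity scan (a position is tandem
# when its 13-mer recurred at a lag within the satellite period range), not
# from a full tandem-repeat finder.

#' Windowed tandem-repeat density profile of one sequence
#'
#' Position-level periodicity flags (k-mer recurrence at a lag inside
#' `period_range`) are averaged over sliding windows. Runs of N are never
#' flagged.
#'
#' @param seq One DNA sequence (character or DNAString).
#' @param chrom Name carried into the profile.
#' @param window Window size in bp (must be at least 4x the largest period).
#' @param step Window step in bp.
#' @param period_range Tandem period range in bp (default 2--2000).
#' @param k K-mer size of the periodicity scan (default 13).
#' @return Data frame `chrom, window_start, window_end, tandem_fraction`
#'   with the per-position flags in attribute `"flags"` (used downstream
#'   for boundary refinement) and a `truncated` flag when the sequence is
#'   shorter than one window.
#' @export
tandem_density <- function(seq, chrom = "seq", window = 100000, step = 10000,
                           period_range = c(2, 2000), k = 13) {
  if (window < 4 * period_range[2])
    stop("window must be >= 4x the maximum period")
  s <- toupper(as.character(seq))
  L <- nchar(s)
  flags <- .tandem_flags_cpp(s, as.integer(k), as.integer(period_range[1]),
                             as.integer(period_range[2]))
  truncated <- L < window
  starts <- if (truncated) 0 else seq(0, L - window, by = step)
  cs <- c(0, cumsum(flags))
  ends <- pmin(starts + window, L)
  frac <- (cs[ends + 1] - cs[starts + 1]) / (ends - starts)
  out <- data.frame(chrom = chrom, window_start = starts, window_end = ends,
                    tandem_fraction = frac)
  attr(out, "flags") <- flags
  attr(out, "step") <- step
  attr(out, "truncated") <- truncated
  out
}

# Gene density (genes/Mb) per window: genes overlapping the window.
.window_gene_density <- function(profile, genes) {
  g <- genes[genes$chrom == profile$chrom[1], , drop = FALSE]
  n <- vapply(seq_len(nrow(profile)), function(i)
    sum(g$start < profile$window_end[i] & g$end > profile$window_start[i]),
    numeric(1))
  n / ((profile$window_end - profile$window_start) / 1e6)
}

#' Delimit candidate centromeres from tandem-density profiles
#'
#' Windows with `tandem_fraction >= tandem_min` and gene density
#' `<= gene_max` are merged when adjacent or within `merge_gap` steps;
#' merged clusters at least `min_cluster` bp long are reported. Cluster
#' boundaries are refined to the extent of 1-kb bins whose flagged-position
#' density is at least 0.5 (so an overlapping boundary window does not
#' inflate the call). The largest cluster per chromosome is ranked primary;
#' others are listed as secondary.
#'
#' @param profiles One profile from [tandem_density()] or a list of them
#'   (one per chromosome).
#' @param genes Gene feature table (`chrom, start, end`).
#' @param tandem_min Minimum window tandem fraction (default 0.5).
#' @param gene_max Maximum gene density in genes/Mb (default 1).
#' @param min_cluster Minimum reported cluster length (bp, default 300 kb).
#' @param merge_gap Merge clusters separated by up to this many window
#'   steps (default 2).
#' @return Data frame `chrom, start, end, mean_tandem_fraction, rank`
#'   (`"primary"`/`"secondary"`); zero rows where nothing qualifies.
#' @export
delimit_centromeres <- function(profiles, genes, tandem_min = 0.5,
                                gene_max = 1, min_cluster = 3e5,
                                merge_gap = 2) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  out <- list()
  for (pf in profiles) {
    step <- attr(pf, "step")
    flags <- attr(pf, "flags")
    gd <- .window_gene_density(pf, genes)
    ok <- pf$tandem_fraction >= tandem_min & gd <= gene_max
    if (!any(ok)) next
    ir <- IRanges::reduce(
      IRanges::IRanges(start = pf$window_start[ok] + 1,
                       end = pf$window_end[ok]),
      min.gapwidth = merge_gap * step + 1)
    for (j in seq_along(ir)) {
      cs <- IRanges::start(ir)[j] - 1; ce <- IRanges::end(ir)[j]
      ref <- .refine_boundaries(flags, cs, ce)
      if (is.null(ref) || ref[2] - ref[1] < min_cluster) next
      sel <- pf$window_start < ref[2] & pf$window_end > ref[1]
      out[[length(out) + 1]] <- data.frame(
        chrom = pf$chrom[1], start = ref[1], end = ref[2],
        mean_tandem_fraction = mean(pf$tandem_fraction[sel]))
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), mean_tandem_fraction = numeric(0),
                      rank = character(0)))
  res <- do.call(rbind, out)
  res$rank <- "secondary"
  for (cname in unique(res$chrom)) {
    ix <- which(res$chrom == cname)
    res$rank[ix[which.max(res$end[ix] - res$start[ix])]] <- "primary"
  }
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Trim a merged cluster to the extent of 1-kb bins with flag density >= 0.5;
# robust to isolated spurious flags in flanking background.
.refine_boundaries <- function(flags, start, end, bin = 1000, min_density = 0.5) {
  idx <- seq(max(0, start), min(length(flags), end) - 1)
  if (length(idx) == 0) return(NULL)
  f <- flags[idx + 1]
  nb <- ceiling(length(f) / bin)
  grp <- rep(seq_len(nb), each = bin, length.out = length(f))
  dens <- tapply(f, grp, mean)
  good <- which(dens >= min_density)
  if (length(good) == 0) return(NULL)
  c(start + (good[1] - 1) * bin, min(end, start + good[length(good)] * bin))
}

#' Repeat-class composition of a centromere call
#'
#' Fraction of centromere bases covered by each repeat class (interval
#' union within class, so overlapping same-class features never exceed 1).
#'
#' @param call One centromere call (`chrom, start, end`).
#' @param repeats Repeat annotation data frame `chrom, start, end, class`
#'   (0-based half-open).
#' @return Named numeric vector of per-class covered fractions.
#' @export
centromere_composition <- function(call, repeats) {
  if (!call$chrom %in% repeats$chrom)
    stop("repeat annotation lacks chromosome ", call$chrom)
  r <- repeats[repeats$chrom == call$chrom, , drop = FALSE]
  cen <- IRanges::IRanges(start = call$start + 1, end = call$end)
  fr <- vapply(split(r, r$class), function(rc) {
    u <- IRanges::reduce(IRanges::IRanges(start = rc$start + 1, end = rc$end))
    sum(IRanges::width(IRanges::intersect(u, cen))) / IRanges::width(cen)
  }, numeric(1))
  fr
}

#' Read a Tandem Repeats Finder `.dat` file
#'
#' Parses the plain `.dat` output of TRF: `Sequence:` headers followed by
#' whitespace-separated repeat records (1-based inclusive coordinates,
#' converted to 0-based half-open).
#'
#' @param path TRF `.dat` file.
#' @return Data frame `chrom, start, end, period, copies, percent_matches`.
#' @export
read_trf_dat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  out <- list()
  chrom <- NA_character_
  for (ln in lines) {
    if (grepl("^Sequence:", ln)) {
      chrom <- sub("^Sequence:\\s*(\\S+).*$", "\\1", ln)
      next
    }
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 8 || is.na(suppressWarnings(as.numeric(f[1])))) next
    if (is.na(chrom)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom, start = as.numeric(f[1]) - 1, end = as.numeric(f[2]),
      period = as.numeric(f[3]), copies = as.numeric(f[4]),
      percent_matches = as.numeric(f[6]), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), period = numeric(0),
                      copies = numeric(0), percent_matches = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Window profile from external tandem-repeat annotations
#'
#' Builds the same windowed tandem-density profile as [tandem_density()],
#' but from tandem-repeat intervals (e.g. [read_trf_dat()] output) instead
#' of the built-in periodicity scan, so external TRF evidence can drive
#' [delimit_centromeres()] unchanged.
#'
#' @param repeats Repeat intervals (`chrom, start, end`, optional `period`).
#' @param chrom Chromosome to profile.
#' @param chrom_length Its length in bp.
#' @param window,step Window geometry, as in [tandem_density()].
#' @param period_range Keep only repeats with period in this range (when a
#'   `period` column is present).
#' @export
trf_density <- function(repeats, chrom, chrom_length, window = 100000,
                        step = 10000, period_range = c(2, 2000)) {
  r <- repeats[repeats$chrom == chrom, , drop = FALSE]
  if (!is.null(r$period))
    r <- r[r$period >= period_range[1] & r$period <= period_range[2], ,
           drop = FALSE]
  flags <- logical(chrom_length)
  for (i in seq_len(nrow(r))) {
    a <- max(0, r$start[i]); b <- min(chrom_length, r$end[i])
    if (b > a) flags[(a + 1):b] <- TRUE
  }
  truncated <- chrom_length < window
  starts <- if (truncated) 0 else seq(0, chrom_length - window, by = step)
  cs <- c(0, cumsum(flags))
  ends <- pmin(starts + window, chrom_length)
  out <- data.frame(chrom = chrom, window_start = starts, window_end = ends,
                    tandem_fraction = (cs[ends + 1] - cs[starts + 1]) /
                      (ends - starts))
  attr(out, "flags") <- flags
  attr(out, "step") <- step
  attr(out, "truncated") <- truncated
  out
}
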
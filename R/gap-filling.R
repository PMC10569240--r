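# Tiered-donor, flank-spanning gap filling: N-runs are located, donors are
# aligned to the gap plus 5-20 kb flanks with an exact unique-k-mer anchor
# aligner (colinear chaining), and the highest-priority spanning donor with
# the longest aligned block replaces the gap between its flank anchors.

#' Locate N-gaps in an assembly
#'
#' @param assembly DNAStringSet or named character vector.
#' @param min_n Minimum run of consecutive `N` that counts as a gap.
#' @return Data frame `gap_id, chrom, start, end` (0-based half-open,
#'   maximal runs), sorted by (chrom, start).
#' @export
find_gaps <- function(assembly, min_n = 10) {
  seqs <- .as_chr_seqs(assembly, "assembly")
  out <- list()
  for (cname in names(seqs)) {
    m <- gregexpr("N+", seqs[[cname]])[[1]]
    if (m[1] == -1) next
    len <- attr(m, "match.length")
    keep <- len >= min_n
    if (!any(keep)) next
    out[[cname]] <- data.frame(chrom = cname,
                               start = as.numeric(m[keep]) - 1,
                               end = as.numeric(m[keep]) - 1 + len[keep])
  }
  if (length(out) == 0)
    return(data.frame(gap_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res <- data.frame(gap_id = sprintf("gap%03d", seq_len(nrow(res))), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Extract flanking sequence around a gap
#'
#' @param gap One-row gap record (`chrom, start, end`).
#' @param assembly Sequence set containing `gap$chrom`.
#' @param flank_bp Flank width, restricted to 5--20 kb.
#' @return List with `left`, `right` sequences, their coordinates
#'   (`left_start`, `right_end`), and `one_sided` flag when the gap abuts a
#'   chromosome end.
#' @export
extract_flanks <- function(gap, assembly, flank_bp = 5000) {
  if (flank_bp < 5000 || flank_bp > 20000)
    stop("flank_bp must be within 5000-20000")
  seqs <- .as_chr_seqs(assembly, "assembly")
  s <- seqs[[gap$chrom]]
  L <- nchar(s)
  ls <- max(0, gap$start - flank_bp)
  re <- min(L, gap$end + flank_bp)
  list(left = substr(s, ls + 1, gap$start),
       right = substr(s, gap$end + 1, re),
       left_start = ls, right_end = re,
       one_sided = (gap$start == 0 || gap$end == L))
}

# Anchor-chain one donor against a region. Returns NULL when no anchors, or
# a list with the colinear chain (0-based starts of k-mers on region/donor)
# and an alignment-record-style summary.
.chain_donor <- function(region, donor, k = 31, stride = 1) {
  an <- .unique_anchors_cpp(region, donor, as.integer(k), as.integer(stride))
  if (nrow(an) == 0) return(NULL)
  keep <- .lis_indices_cpp(an$qry_pos)   # anchors already sorted by ref_pos
  an <- an[keep, , drop = FALSE]
  if (nrow(an) == 0) return(NULL)
  list(chain = an,
       tstart = an$ref_pos[1], tend = an$ref_pos[nrow(an)] + k,
       qstart = an$qry_pos[1], qend = an$qry_pos[nrow(an)] + k,
       n_match = nrow(an), block_len = an$ref_pos[nrow(an)] + k - an$ref_pos[1])
}

#' Choose the donor patch for one gap from candidate alignments
#'
#' A donor qualifies when a single donor sequence has alignment coverage
#' reaching at least `conf` bases into both flanks beyond the gap edges.
#' Among qualifying donors of the highest-priority tier, the longest aligned
#' block wins; ties break on more matches, then lexicographic donor name.
#'
#' @param gap_start,gap_end Gap edges in the same (region) coordinates as
#'   the candidate records.
#' @param candidates Data frame with one row per donor alignment: `donor,
#'   tier, tstart, tend, n_match, block_len`.
#' @param conf Required anchored reach into each flank (bp, default 500).
#' @return The chosen candidate row, or `NULL` when no donor spans.
#' @export
select_patch <- function(gap_start, gap_end, candidates, conf = 500) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  q <- candidates[candidates$tstart <= gap_start - conf &
                    candidates$tend >= gap_end + conf, , drop = FALSE]
  if (nrow(q) == 0) return(NULL)
  q <- q[q$tier == min(q$tier), , drop = FALSE]
  q <- q[order(-q$block_len, -q$n_match, q$donor), , drop = FALSE]
  q[1, , drop = FALSE]
}

#' Fill assembly gaps from tiered donor sequence sets
#'
#' Donor tiers are tried in rank order (1 = alternative assemblies, 2 = ONT
#' reads, 3 = HiFi reads). For each gap, donors are aligned to the gap plus
#' flanks (starting at `flank_bp` and escalating through 10/15/20 kb while
#' no donor spans); the selected donor's sequence between the innermost
#' flank anchors replaces everything between those anchors on the
#' chromosome. Chromosome count is never changed.
#'
#' @param draft Gapped assembly (DNAStringSet or named character).
#' @param donor_tiers List of named sequence sets in priority order, e.g.
#'   `list(tier1 = asm, tier2 = ont, tier3 = hifi)`.
#' @param flank_bp Initial flank width (bp, within 5--20 kb).
#' @param escalate Escalate flanks to 10/15/20 kb when no donor spans.
#' @param min_n Minimum N-run treated as a gap.
#' @param anchor_k Anchor k-mer size (default 31).
#' @param conf Required anchored reach into each flank (bp).
#' @return List with `assembly` (filled DNAStringSet) and `reports` (one row
#'   per gap: status, donor tier/name, patch length, flank used, junction
#'   coordinates on the filled assembly).
#' @export
fill_gaps <- function(draft, donor_tiers, flank_bp = 5000, escalate = TRUE,
                      min_n = 10, anchor_k = 31, conf = 500) {
  seqs <- .as_chr_seqs(draft, "draft")
  gaps <- find_gaps(seqs, min_n = min_n)
  if (nrow(gaps) == 0)
    return(list(assembly = Biostrings::DNAStringSet(seqs),
                reports = .empty_fill_reports()))
  tiers <- lapply(donor_tiers, .as_chr_seqs, what = "donor tier")
  flank_ladder <- if (escalate) unique(c(flank_bp, 10000, 15000, 20000)) else
    flank_bp
  reports <- list()
  deltas <- numeric(nrow(gaps))   # length change caused by each fill
  # fill right-to-left within each chromosome so pending gap coordinates
  # (recorded on the draft) stay valid
  ord <- order(gaps$chrom, -gaps$start)
  for (gi in ord) {
    gap <- gaps[gi, ]
    res <- NULL
    for (fb in flank_ladder) {
      res <- .fill_one_gap(seqs, gap, tiers, fb, anchor_k, conf)
      if (!is.null(res$patched)) break
    }
    if (!is.null(res$patched)) {
      seqs[[gap$chrom]] <- res$patched
      deltas[gi] <- res$delta
    }
    reports[[gap$gap_id]] <- res$report
  }
  reports <- do.call(rbind, reports[gaps$gap_id])
  # junctions were recorded in draft coordinates; shift by the cumulative
  # length change of fills to their left on the same chromosome
  for (i in seq_len(nrow(reports))) {
    left_of <- gaps$chrom == gaps$chrom[i] & gaps$start < gaps$start[i]
    shift <- sum(deltas[left_of])
    reports$junction_left[i] <- reports$junction_left[i] + shift
    reports$junction_right[i] <- reports$junction_right[i] + shift
  }
  rownames(reports) <- NULL
  list(assembly = Biostrings::DNAStringSet(seqs), reports = reports)
}

.empty_fill_reports <- function() {
  data.frame(gap_id = character(0), chrom = character(0), status = character(0),
             donor_tier = numeric(0), donor_name = character(0),
             patch_length = numeric(0), flank_used = numeric(0),
             junction_left = numeric(0), junction_right = numeric(0))
}

.fill_one_gap <- function(seqs, gap, tiers, flank_bp, anchor_k, conf) {
  fl <- extract_flanks(gap, seqs, flank_bp)
  chrom_seq <- seqs[[gap$chrom]]
  region <- substr(chrom_seq, fl$left_start + 1, fl$right_end)
  gapL <- gap$start - fl$left_start     # region-relative gap edges
  gapR <- gap$end - fl$left_start
  cands <- list(); chains <- list()
  for (ti in seq_along(tiers)) {
    for (dn in names(tiers[[ti]])) {
      ch <- .chain_donor(region, tiers[[ti]][[dn]], k = anchor_k)
      if (is.null(ch)) next
      key <- paste0(ti, ":", dn)
      chains[[key]] <- ch
      cands[[key]] <- data.frame(donor = dn, tier = ti, tstart = ch$tstart,
                                 tend = ch$tend, n_match = ch$n_match,
                                 block_len = ch$block_len)
    }
  }
  cands <- if (length(cands)) do.call(rbind, cands) else NULL
  chosen <- select_patch(gapL, gapR, cands, conf = conf)
  fail <- function(status) list(patched = NULL, report = data.frame(
    gap_id = gap$gap_id, chrom = gap$chrom, status = status,
    donor_tier = NA_real_, donor_name = NA_character_,
    patch_length = NA_real_, flank_used = flank_bp,
    junction_left = NA_real_, junction_right = NA_real_))
  if (is.null(chosen)) return(fail("unfilled"))
  ch <- chains[[paste0(chosen$tier, ":", chosen$donor)]]
  chain <- ch$chain
  # innermost anchors fully inside each flank
  li <- which(chain$ref_pos + anchor_k <= gapL)
  ri <- which(chain$ref_pos >= gapR)
  if (length(li) == 0 || length(ri) == 0) return(fail("unfilled"))
  aL <- chain[max(li), ]; aR <- chain[min(ri), ]
  if (aR$qry_pos < aL$qry_pos + anchor_k)
    return(fail("incoherent-anchor"))
  donor_seq <- tiers[[chosen$tier]][[chosen$donor]]
  patch <- substr(donor_seq, aL$qry_pos + anchor_k + 1, aR$qry_pos)
  cut_l <- fl$left_start + aL$ref_pos + anchor_k   # chromosome coords, 0-based
  cut_r <- fl$left_start + aR$ref_pos
  patched <- paste0(substr(chrom_seq, 1, cut_l), patch,
                    substr(chrom_seq, cut_r + 1, nchar(chrom_seq)))
  list(patched = patched,
       delta = nchar(patch) - (cut_r - cut_l),
       report = data.frame(
         gap_id = gap$gap_id, chrom = gap$chrom, status = "filled",
         donor_tier = chosen$tier, donor_name = chosen$donor,
         patch_length = nchar(patch), flank_used = flank_bp,
         junction_left = cut_l, junction_right = cut_l + nchar(patch)))
}

#' Verify filled gaps from read alignments over the junctions
#'
#' A fill is `spanned` when, for each of its two junctions, at least one
#' read alignment covers `[junction - window, junction + window]` (windows
#' are clipped at chromosome ends).
#'
#' @param fill Result of [fill_gaps()].
#' @param alignments Read-vs-filled-assembly alignment table.
#' @param window_bp Half-window around each junction (default 1 kb).
#' @return The fill reports with a `verification` column
#'   (`spanned`/`unspanned`, `NA` for unfilled gaps).
#' @export
verify_fills <- function(fill, alignments, window_bp = 1000) {
  reports <- fill$reports
  lens <- nchar(.as_chr_seqs(fill$assembly))
  covered <- function(chrom, j) {
    lo <- max(0, j - window_bp); hi <- min(lens[[chrom]], j + window_bp)
    any(alignments$tname == chrom & alignments$tstart <= lo &
          alignments$tend >= hi)
  }
  reports$verification <- NA_character_
  for (i in seq_len(nrow(reports))) {
    if (!identical(reports$status[i], "filled")) next
    ok <- covered(reports$chrom[i], reports$junction_left[i]) &&
      covered(reports$chrom[i], reports$junction_right[i])
    reports$verification[i] <- if (ok) "spanned" else "unspanned"
  }
  reports
}
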
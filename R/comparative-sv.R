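# Structural-variant screening: a desk-scale internal SV caller on unique
# k-mer anchor chains, newly-assembled (non-aligning) region detection,
# gene-proximity screening with a 5-kb flank, and per-ecotype frequencies.

#' Call structural variants between two collinear sequence sets
#'
#' Chromosomes are paired by name. Unique-k-mer anchors are chained
#' colinearly; between consecutive anchors, the unaligned segments are
#' trimmed of their common prefix/suffix and classified by the remaining
#' lengths: query surplus is an insertion (`INS`; a tandem duplication
#' `DUP` when the inserted bases equal the reference bases immediately
#' upstream), reference surplus a deletion (`DEL`), an equal-length segment
#' matching the reverse complement an inversion (`INV`), anything else
#' `OTHER`. Coordinates are 0-based half-open on the reference; `INS`
#' records carry a point anchor (`ref_end == ref_start`).
#'
#' @param ref,qry Reference and query sequence sets (names must overlap).
#' @param accession_id Label stored on every call.
#' @param k Anchor k-mer size (default 31).
#' @param stride Anchor subsampling stride in bp (default 50).
#' @return SV table: `accession_id, ref_chrom, ref_start, ref_end, type,
#'   length, source, seq`.
#' @export
call_svs_internal <- function(ref, qry, accession_id = "query", k = 31,
                              stride = 50) {
  rs <- .as_chr_seqs(ref, "ref")
  qs <- .as_chr_seqs(qry, "qry")
  shared <- intersect(names(rs), names(qs))
  if (length(shared) == 0) stop("no chromosome names shared by ref and qry")
  out <- list()
  for (cname in shared) {
    an <- .unique_anchors_cpp(rs[[cname]], qs[[cname]], as.integer(k),
                              as.integer(stride))
    if (nrow(an) == 0) stop("no collinearity on ", cname)
    an <- an[.lis_indices_cpp(an$qry_pos), , drop = FALSE]
    out[[cname]] <- .classify_gaps(rs[[cname]], qs[[cname]], an, cname,
                                   accession_id, k, stride)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_sv_calls()
  rownames(res) <- NULL
  res
}

.empty_sv_calls <- function() {
  data.frame(accession_id = character(0), ref_chrom = character(0),
             ref_start = numeric(0), ref_end = numeric(0),
             type = character(0), length = numeric(0),
             source = character(0), seq = character(0))
}

.classify_gaps <- function(rseq, qseq, chain, cname, accession_id, k, stride) {
  calls <- list()
  inspect_min <- 4 * stride + k   # equal-length gaps smaller than this are
                                  # ordinary anchor spacing, not divergence
  for (i in seq_len(nrow(chain) - 1)) {
    r1 <- chain$ref_pos[i] + k; r2 <- chain$ref_pos[i + 1]
    q1 <- chain$qry_pos[i] + k; q2 <- chain$qry_pos[i + 1]
    # anchors may overlap across an SV junction when boundary bases match
    # by chance; shift the gap start back by the overlap (those bases are
    # guaranteed identical by the previous anchor's k-mer match)
    o <- max(0, r1 - r2, q1 - q2)
    r1 <- r1 - o; q1 <- q1 - o
    lr <- r2 - r1; lq <- q2 - q1
    if (lr == lq && lr <= inspect_min) next
    rgap <- substr(rseq, r1 + 1, r2)
    qgap <- substr(qseq, q1 + 1, q2)
    if (lr == lq && rgap == qgap) next
    p <- .lcp_len(rgap, qgap)
    s <- .lcs_len(rgap, qgap, max_len = min(lr, lq) - p)
    rmid <- substr(rgap, p + 1, lr - s)
    qmid <- substr(qgap, p + 1, lq - s)
    Lr <- nchar(rmid); Lq <- nchar(qmid)
    pos <- r1 + p                                 # 0-based breakpoint
    if (Lr == 0 && Lq == 0) next
    if (Lr == 0) {                                # insertion in query
      # left-normalize the breakpoint (an anchor k-mer crossing the end of
      # a duplicated unit yields a rotated representation otherwise)
      qpos <- q1 + p
      d <- .match_back(qseq, qpos, qpos + Lq)
      qpos <- qpos - d; pos <- pos - d
      qmid <- substr(qseq, qpos + 1, qpos + Lq)
      upstream <- if (pos >= Lq) substr(rseq, pos - Lq + 1, pos) else ""
      downstream <- substr(rseq, pos + 1, pos + Lq)
      if (identical(qmid, downstream)) {
        calls[[length(calls) + 1]] <- data.frame(
          accession_id = accession_id, ref_chrom = cname,
          ref_start = pos, ref_end = pos + Lq, type = "DUP",
          length = Lq, source = "internal", seq = qmid)
      } else if (identical(qmid, upstream)) {
        calls[[length(calls) + 1]] <- data.frame(
          accession_id = accession_id, ref_chrom = cname,
          ref_start = pos - Lq, ref_end = pos, type = "DUP",
          length = Lq, source = "internal", seq = qmid)
      } else {
        calls[[length(calls) + 1]] <- data.frame(
          accession_id = accession_id, ref_chrom = cname,
          ref_start = pos, ref_end = pos, type = "INS",
          length = Lq, source = "internal", seq = qmid)
      }
    } else if (Lq == 0) {
      d <- .match_back(rseq, pos, pos + Lr)
      pos <- pos - d
      rmid <- substr(rseq, pos + 1, pos + Lr)
      calls[[length(calls) + 1]] <- data.frame(
        accession_id = accession_id, ref_chrom = cname,
        ref_start = pos, ref_end = pos + Lr, type = "DEL",
        length = Lr, source = "internal", seq = rmid)
    } else if (Lr == Lq && identical(qmid, revcomp(rmid))) {
      calls[[length(calls) + 1]] <- data.frame(
        accession_id = accession_id, ref_chrom = cname,
        ref_start = pos, ref_end = pos + Lr, type = "INV",
        length = Lr, source = "internal", seq = NA_character_)
    } else {
      calls[[length(calls) + 1]] <- data.frame(
        accession_id = accession_id, ref_chrom = cname,
        ref_start = pos, ref_end = pos + Lr, type = "OTHER",
        length = max(Lr, Lq), source = "internal", seq = NA_character_)
    }
  }
  if (length(calls) == 0) return(NULL)
  do.call(rbind, calls)
}

# Maximal d with s[i - t] == s[j - t] for t = 1..d (0-based breakpoints i, j).
.match_back <- function(s, i, j, cap = 50000) {
  win <- min(i, cap)
  if (win == 0) return(0L)
  a <- utf8ToInt(substr(s, i - win + 1, i))
  b <- utf8ToInt(substr(s, j - win + 1, j))
  mism <- which(rev(a) != rev(b))
  if (length(mism) == 0) win else mism[1] - 1L
}

#' Convert a syri table to the internal SV-call convention
#'
#' Keeps the variant classes (`INS, DEL, DUP, INV`; everything else
#' `OTHER`), drops syntenic records, and collapses `INS` records to point
#' anchors.
#'
#' @param syri Table from [read_syri()].
#' @param accession_id Accession label.
#' @export
svs_from_syri <- function(syri, accession_id) {
  sv <- syri[!syri$sv_class %in% c("SYN", "NOTAL"), , drop = FALSE]
  type <- ifelse(sv$sv_class %in% c("INS", "DEL", "DUP", "INV"),
                 sv$sv_class, "OTHER")
  len <- ifelse(type == "INS", sv$alt_end - sv$alt_start,
                sv$ref_end - sv$ref_start)
  data.frame(accession_id = accession_id, ref_chrom = sv$ref_chrom,
             ref_start = sv$ref_start,
             ref_end = ifelse(type == "INS", sv$ref_start, sv$ref_end),
             type = type, length = len, source = "syri",
             seq = NA_character_, stringsAsFactors = FALSE)
}

#' Newly assembled regions: reference sequence absent from an alignment
#'
#' Takes whole-genome alignments with the focal assembly as the query; the
#' complement of the union of its aligned intervals, filtered to
#' `min_len`, is reported as newly assembled. Genes fully contained in
#' those intervals are flagged novel.
#'
#' @param alignments Alignment table (focal assembly as query).
#' @param self_lengths Named lengths of the focal assembly sequences.
#' @param min_len Minimum novel-region length (bp).
#' @param genes Optional gene table (`chrom, start, end, gene_id`).
#' @return List with `regions` (`chrom, start, end`) and `novel_genes`.
#' @export
novel_regions <- function(alignments, self_lengths, min_len = 10000,
                          genes = NULL) {
  regions <- list()
  for (cname in names(self_lengths)) {
    L <- as.numeric(self_lengths[[cname]])
    sub <- alignments[alignments$qname == cname, , drop = FALSE]
    cov <- IRanges::reduce(IRanges::IRanges(start = sub$qstart + 1,
                                            end = sub$qend))
    gaps <- IRanges::setdiff(IRanges::IRanges(start = 1, end = L), cov)
    gaps <- gaps[IRanges::width(gaps) >= min_len]
    if (length(gaps) > 0)
      regions[[cname]] <- data.frame(chrom = cname,
                                     start = IRanges::start(gaps) - 1,
                                     end = IRanges::end(gaps))
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(regions) <- NULL
  novel_genes <- character(0)
  if (!is.null(genes) && nrow(regions) > 0) {
    for (i in seq_len(nrow(regions))) {
      hit <- genes$chrom == regions$chrom[i] &
        genes$start >= regions$start[i] & genes$end <= regions$end[i]
      novel_genes <- c(novel_genes, genes$gene_id[hit])
    }
    novel_genes <- sort(unique(novel_genes))
  }
  list(regions = regions, novel_genes = novel_genes)
}

#' Screen structural variants against genes with a flank
#'
#' A gene is affected by an SV when the SV interval (a point for `INS`)
#' intersects `[gene_start - flank, gene_end + flank)`. All SV types count
#' equally.
#'
#' @param svs SV table (internal or syri-derived convention).
#' @param genes Gene table (`chrom, start, end, gene_id, is_flowering`).
#' @param flank Flank in bp on each side (default 5000).
#' @param flowering_only Restrict the screen to flowering-flagged genes.
#' @return List with `hits` (rows `accession_id, gene_id, sv_type,
#'   ref_start, ref_end`) and `affected_genes` (non-redundant gene-ID union
#'   across accessions).
#' @export
screen_gene_svs <- function(svs, genes, flank = 5000, flowering_only = FALSE) {
  g <- genes
  if (flowering_only) g <- g[g$is_flowering, , drop = FALSE]
  hits <- list()
  for (i in seq_len(nrow(g))) {
    ws <- g$start[i] - flank
    we <- g$end[i] + flank
    same <- svs$ref_chrom == g$chrom[i]
    point <- svs$ref_end == svs$ref_start
    hit <- same & ((point & svs$ref_start >= ws & svs$ref_start < we) |
                     (!point & svs$ref_start < we & svs$ref_end > ws))
    if (!any(hit)) next
    hits[[length(hits) + 1]] <- data.frame(
      accession_id = svs$accession_id[hit], gene_id = g$gene_id[i],
      sv_type = svs$type[hit], ref_start = svs$ref_start[hit],
      ref_end = svs$ref_end[hit], stringsAsFactors = FALSE)
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(accession_id = character(0), gene_id = character(0),
               sv_type = character(0), ref_start = numeric(0),
               ref_end = numeric(0))
  rownames(hits) <- NULL
  list(hits = hits, affected_genes = sort(unique(hits$gene_id)))
}

#' Per-gene, per-ecotype SV frequencies and diagnostic genes
#'
#' Frequency = affected accessions of an ecotype / accessions of that
#' ecotype. A gene is ecotype-diagnostic for a two-group partition when its
#' frequency is exactly 1 in every accession of one group and exactly 0 in
#' the other.
#'
#' @param hits Hit table from [screen_gene_svs()] (or any data frame with
#'   `accession_id, gene_id`).
#' @param panel Data frame `accession_id, ecotype` over
#'   `spring, semi-winter, winter`; every accession must be labelled.
#' @param groups Two-group partition tested for diagnostic genes (default
#'   spring vs semi-winter + winter).
#' @return List: `frequencies` (`gene_id, ecotype, frequency`), `presence`
#'   (gene x accession logical matrix), `diagnostic` (`gene_id,
#'   fixed_in`).
#' @export
ecotype_frequencies <- function(hits, panel,
                                groups = list(spring = "spring",
                                              winterish = c("semi-winter",
                                                            "winter"))) {
  if (any(is.na(panel$ecotype)))
    stop("unlabeled accession in panel")
  miss <- setdiff(unique(hits$accession_id), panel$accession_id)
  if (length(miss) > 0)
    stop("unlabeled accession: ", paste(miss, collapse = ","))
  genes <- sort(unique(hits$gene_id))
  accs <- panel$accession_id
  pres <- matrix(FALSE, nrow = length(genes), ncol = length(accs),
                 dimnames = list(genes, accs))
  if (nrow(hits) > 0)
    pres[cbind(match(hits$gene_id, genes), match(hits$accession_id, accs))] <- TRUE
  freq <- do.call(rbind, lapply(unique(panel$ecotype), function(eco) {
    acc_e <- panel$accession_id[panel$ecotype == eco]
    data.frame(gene_id = genes, ecotype = eco,
               frequency = rowMeans(pres[, acc_e, drop = FALSE]))
  }))
  rownames(freq) <- NULL
  g1 <- panel$accession_id[panel$ecotype %in% groups[[1]]]
  g2 <- panel$accession_id[panel$ecotype %in% groups[[2]]]
  f1 <- rowMeans(pres[, g1, drop = FALSE])
  f2 <- rowMeans(pres[, g2, drop = FALSE])
  diag_ix <- (f1 == 1 & f2 == 0) | (f1 == 0 & f2 == 1)
  diagnostic <- data.frame(
    gene_id = genes[diag_ix],
    fixed_in = ifelse(f1[diag_ix] == 1, names(groups)[1], names(groups)[2]),
    stringsAsFactors = FALSE)
  rownames(diagnostic) <- NULL
  list(frequencies = freq, presence = pres, diagnostic = diagnostic)
}
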
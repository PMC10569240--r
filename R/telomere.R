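# Telomere detection and chromosome-end patching. The plant telomeric
# repeat is CCCTAAA (C-rich strand; reverse complement TTTAGGG), counted
# non-overlapping on whichever strand gives the larger count.

#' Count telomeric motif occurrences in a sequence
#'
#' Non-overlapping, left-to-right occurrences of `motif` or of its reverse
#' complement, whichever strand yields the larger count.
#'
#' @param seq A DNA string.
#' @param motif Telomeric motif (default `CCCTAAA`).
#' @return Integer count.
#' @export
count_motif <- function(seq, motif = TELOMERE_MOTIF) {
  if (nchar(motif) == 0) stop("motif must be non-empty")
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0) return(0L)
  cnt <- function(m) {
    hits <- gregexpr(m, seq, fixed = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }
  max(cnt(toupper(motif)), cnt(revcomp(toupper(motif))))
}

#' Assign end-aligned reads to chromosome ends
#'
#' A read belongs to the left end of a chromosome when its alignment starts
#' within `end_window` bp of position 0, and to the right end when it ends
#' within `end_window` bp of the chromosome length. A read qualifying for
#' both (e.g. spanning a tiny chromosome) is assigned to the left end only.
#'
#' @param alignments Read alignment table ([read_paf()] convention).
#' @param assembly_lengths Named chromosome lengths.
#' @param reads Optional read sequences; when given, per-read telomeric
#'   motif counts are included.
#' @param end_window Distance from the chromosome end (bp, default 50).
#' @param motif Telomeric motif for the optional counts.
#' @return Data frame `chrom, side, read_id` (+ `motif_count` when `reads`
#'   is supplied).
#' @export
collect_end_reads <- function(alignments, assembly_lengths, reads = NULL,
                              end_window = 50, motif = TELOMERE_MOTIF) {
  a <- alignments
  tlen <- as.numeric(assembly_lengths[a$tname])
  left <- a$tstart <= end_window
  right <- (tlen - a$tend) <= end_window & !left
  out <- rbind(
    data.frame(chrom = a$tname[left], side = "left", read_id = a$qname[left]),
    data.frame(chrom = a$tname[right], side = "right",
               read_id = a$qname[right]))
  if (!is.null(reads)) {
    rseq <- .as_chr_seqs(reads, "reads")
    out$motif_count <- vapply(out$read_id, function(id)
      count_motif(rseq[[id]], motif), integer(1))
  }
  rownames(out) <- NULL
  out
}

#' Call telomere presence per chromosome end
#'
#' Motif occurrences are counted in a terminal window at each end; an end is
#' telomere-positive when the count reaches `presence_threshold`. A
#' chromosome is telomere-to-telomere (T2T) when both ends are positive.
#'
#' @param assembly DNAStringSet or named character vector.
#' @param motif Telomeric motif.
#' @param terminal_window Window at each terminus (bp, default 20 kb;
#'   truncated, with a flag, on shorter chromosomes).
#' @param presence_threshold Motif copies required to call presence
#'   (default 100).
#' @return List: `calls` (per-end data frame with `chrom, side, motif_count,
#'   array_length, present, truncated_window`), `n_telomeres`, `n_t2t`.
#' @export
call_telomeres <- function(assembly, motif = TELOMERE_MOTIF,
                           terminal_window = 20000,
                           presence_threshold = 100) {
  seqs <- .as_chr_seqs(assembly, "assembly")
  calls <- list()
  for (cname in names(seqs)) {
    s <- seqs[[cname]]
    L <- nchar(s)
    w <- min(terminal_window, L)
    for (side in c("left", "right")) {
      win <- if (side == "left") substr(s, 1, w) else substr(s, L - w + 1, L)
      mc <- count_motif(win, motif)
      calls[[paste(cname, side)]] <- data.frame(
        chrom = cname, side = side, motif_count = mc,
        array_length = mc * nchar(motif),
        present = mc >= presence_threshold,
        truncated_window = w < terminal_window)
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  t2t <- tapply(calls$present, calls$chrom, all)
  list(calls = calls, n_telomeres = sum(calls$present),
       n_t2t = sum(t2t))
}

#' Patch a telomere-missing chromosome end from end-aligned reads
#'
#' The read with the highest telomeric motif count is the patch template.
#' Its overlap with the current chromosome terminus (an exact match of the
#' terminal `anchor_len` bases, on either strand of the read) defines the
#' junction; the template's distal overhang is appended (right end) or
#' prepended (left end). Bases proximal to the junction are never modified.
#' The patch is a no-op unless it adds at least `min_gain` bp of telomeric
#' array.
#'
#' @param assembly Sequence set.
#' @param chrom Chromosome to patch.
#' @param side `"left"` or `"right"`.
#' @param reads Candidate end reads (sequences).
#' @param motif Telomeric motif.
#' @param min_gain Minimum telomeric bp the patch must add (default 100).
#' @param anchor_len Exact-match junction anchor length (bp, default 1000).
#' @return List with `assembly` (patched set) and `report` (`status` one of
#'   `patched`, `no-telomeric-evidence`, `no-anchor`, `insufficient-gain`;
#'   `template`, `added_bp`).
#' @export
patch_telomere <- function(assembly, chrom, side = c("left", "right"),
                           reads, motif = TELOMERE_MOTIF, min_gain = 100,
                           anchor_len = 1000) {
  side <- match.arg(side)
  seqs <- .as_chr_seqs(assembly, "assembly")
  rseq <- .as_chr_seqs(reads, "reads")
  if (length(rseq) == 0) stop("end read set is empty")
  counts <- vapply(rseq, count_motif, integer(1), motif = motif)
  rep0 <- function(status, template = NA_character_, added = 0)
    list(assembly = Biostrings::DNAStringSet(seqs),
         report = data.frame(chrom = chrom, side = side, status = status,
                             template = template, added_bp = added))
  if (max(counts) == 0) return(rep0("no-telomeric-evidence"))
  template_id <- names(which.max(counts))
  tpl <- rseq[[template_id]]
  s <- seqs[[chrom]]
  L <- nchar(s)
  anchor <- if (side == "right") substr(s, L - anchor_len + 1, L) else
    substr(s, 1, anchor_len)
  overhang <- NA_character_
  for (cand in c(tpl, revcomp(tpl))) {
    hits <- gregexpr(anchor, cand, fixed = TRUE)[[1]]
    if (hits[1] == -1) next
    if (side == "right") {
      pos <- hits[length(hits)]                 # last occurrence
      overhang <- substr(cand, pos + anchor_len, nchar(cand))
    } else {
      pos <- hits[1]
      overhang <- substr(cand, 1, pos - 1)
    }
    break
  }
  if (is.na(overhang)) return(rep0("no-anchor", template_id))
  gain <- count_motif(overhang, motif) * nchar(motif)
  if (gain < min_gain) return(rep0("insufficient-gain", template_id))
  seqs[[chrom]] <- if (side == "right") paste0(s, overhang) else
    paste0(overhang, s)
  list(assembly = Biostrings::DNAStringSet(seqs),
       report = data.frame(chrom = chrom, side = side, status = "patched",
                           template = template_id,
                           added_bp = nchar(overhang)))
}
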
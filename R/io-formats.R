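# Readers/writers for the interchange formats the pipeline touches.
# Internal convention everywhere: 0-based half-open coordinates; writers
# convert back to each format's native convention.

#' Read FASTA or FASTQ sequences
#'
#' Sequences are uppercased on read and validated against the
#' \{A,C,G,T,N\} alphabet. FASTQ qualities are Phred+33.
#'
#' @param path Input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (by extension).
#' @return A [Biostrings::DNAStringSet] (FASTA) or
#'   [Biostrings::QualityScaledDNAStringSet] (FASTQ), in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (file.size(path) == 0) {
    warning("empty sequence file: ", path)
    return(Biostrings::DNAStringSet())
  }
  res <- tryCatch({
    if (format == "fasta") {
      x <- Biostrings::readDNAStringSet(path, format = "fasta")
      Biostrings::DNAStringSet(toupper(as.character(x)))
    } else {
      # Biostrings notes that (empty) metadata columns are dropped when the
      # FASTQ reader re-wraps the sequences; that notice is not actionable
      muffle <- function(expr) withCallingHandlers(expr,
        warning = function(w) {
          if (grepl("metadata columns", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
      x <- muffle(Biostrings::readQualityScaledDNAStringSet(path))
      muffle(Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(toupper(as.character(x))),
        Biostrings::quality(x)))
    }
  }, error = function(e) {
    stop("malformed ", format, " in ", path, ": ", conditionMessage(e))
  })
  af <- Biostrings::alphabetFrequency(res, collapse = TRUE)
  bad <- af[setdiff(names(af)[af > 0], c("A", "C", "G", "T", "N"))]
  if (length(bad) > 0)
    stop("alphabet error in ", path, ": disallowed characters ",
         paste(names(bad), collapse = ","))
  res
}

#' Write sequences as FASTA or FASTQ
#'
#' @param seqs A `DNAStringSet`, `QualityScaledDNAStringSet`, or named
#'   character vector.
#' @param path Output file.
#' @param format Target format; FASTQ requires qualities.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (format == "fastq" && !methods::is(seqs, "QualityScaledDNAStringSet"))
    stop("FASTQ output requires a QualityScaledDNAStringSet")
  if (format == "fastq") {
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = Biostrings::quality(seqs))
  } else {
    Biostrings::writeXStringSet(seqs, path, format = "fasta")
  }
  invisible(path)
}

#' Per-base Phred scores of a quality-scaled sequence set
#'
#' @param seqs A `QualityScaledDNAStringSet` as returned by
#'   [read_sequences()] on FASTQ input.
#' @return A list of integer vectors, one per record.
#' @export
phred_scores <- function(seqs) {
  if (!methods::is(seqs, "QualityScaledDNAStringSet"))
    stop("phred_scores() needs a QualityScaledDNAStringSet")
  q <- methods::as(Biostrings::quality(seqs), "IntegerList")
  as.list(q)
}

.paf_cols <- c("qname", "qlen", "qstart", "qend", "strand",
               "tname", "tlen", "tstart", "tend",
               "n_match", "block_len", "mapq")
.paf_num <- c("qlen", "qstart", "qend", "tlen", "tstart", "tend",
              "n_match", "block_len", "mapq")

#' Read a PAF pairwise-alignment file
#'
#' The 12 mandatory columns are parsed into an alignment table with 0-based
#' half-open coordinates (PAF's native convention). Optional SAM-style tags
#' are kept verbatim in a `tags` column for lossless re-emission.
#'
#' @param path PAF file.
#' @return A data frame with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, n_match, block_len, mapq, tags`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stop("PAF parse error at line ", which(nf < 12)[1],
         ": fewer than 12 columns")
  rec <- lapply(seq_len(12), function(i) vapply(parts, `[[`, "", i))
  names(rec) <- .paf_cols
  out <- as.data.frame(rec, stringsAsFactors = FALSE)
  for (cc in .paf_num) out[[cc]] <- as.numeric(out[[cc]])
  out$tags <- vapply(parts, function(p)
    if (length(p) > 12) paste(p[-seq_len(12)], collapse = "\t") else "",
    "")
  if (any(is.na(out[.paf_num])))
    stop("PAF parse error: non-numeric coordinate field")
  bad <- with(out, qstart < 0 | qstart >= qend | qend > qlen |
                tstart < 0 | tstart >= tend | tend > tlen |
                n_match > block_len)
  if (any(bad))
    stop("PAF coordinate invariant violated at line ", which(bad)[1])
  out
}

#' @rdname read_paf
#' @param alignments Alignment table as returned by [read_paf()].
#' @export
write_paf <- function(alignments, path) {
  a <- alignments
  body <- do.call(paste, c(lapply(.paf_cols, function(cc) {
    v <- a[[cc]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else v
  }), sep = "\t"))
  if (!is.null(a$tags)) {
    has <- nzchar(a$tags)
    body[has] <- paste(body[has], a$tags[has], sep = "\t")
  }
  writeLines(body, path)
  invisible(path)
}

# An empty alignment table with the right columns.
empty_alignments <- function() {
  out <- as.data.frame(setNames(rep(list(character(0)), 12), .paf_cols))
  for (cc in .paf_num) out[[cc]] <- numeric(0)
  out$tags <- character(0)
  out
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 (1-based inclusive) and BED (0-based half-open) are both normalized
#' to 0-based half-open coordinates. Gene identifiers present in
#' `flowering_ids` are flagged.
#'
#' @param path Annotation file.
#' @param format `"gff3"` or `"bed"` (default: by extension).
#' @param flowering_ids Character vector of gene IDs to flag as
#'   flowering-related.
#' @param feature_type For GFF3, which `type` values to keep (default
#'   `"gene"`; `NULL` keeps everything).
#' @return Data frame with columns `chrom, start, end, strand, gene_id,
#'   is_flowering` (0-based half-open).
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "bed"),
                             flowering_ids = character(),
                             feature_type = "gene") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "bed" else "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (format == "gff3") {
    if (!is.null(feature_type) && "type" %in% names(df))
      df <- df[as.character(df$type) %in% feature_type, , drop = FALSE]
    ids <- if ("ID" %in% names(df)) as.character(df$ID) else NULL
    if (is.null(ids) || all(is.na(ids)))
      ids <- if ("Name" %in% names(df)) as.character(df$Name) else
        paste0("feature", seq_len(nrow(df)))
  } else {
    ids <- if ("name" %in% names(df)) as.character(df$name) else
      paste0("feature", seq_len(nrow(df)))
  }
  # rtracklayer yields 1-based starts for both formats
  out <- data.frame(chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end,
                    strand = ifelse(as.character(df$strand) == "-", "-", "+"),
                    gene_id = ids,
                    stringsAsFactors = FALSE)
  bad <- out$end <= out$start
  if (any(bad)) {
    warning(sum(bad), " record(s) with end <= start rejected")
    out <- out[!bad, , drop = FALSE]
  }
  out$is_flowering <- out$gene_id %in% flowering_ids
  rownames(out) <- NULL
  out
}

.syri_known <- c("SYN", "INS", "DEL", "DUP", "INV", "TRANS", "INVTR",
                 "INVDP", "NOTAL", "HDR", "CPG", "CPL", "TDM")

#' Read a syri-style structural-variant table
#'
#' Accepts the annotated tab-separated syri output. Coordinates are 1-based
#' inclusive on disk and converted to 0-based half-open. Unrecognized
#' variant classes are retained, tagged `"OTHER"`.
#'
#' @param path syri output TSV.
#' @return Data frame with `ref_chrom, ref_start, ref_end, alt_chrom,
#'   alt_start, alt_end, id, sv_class` (0-based half-open).
#' @export
read_syri <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(raw) < 10)
    stop("syri parse error: expected >= 10 columns, got ", ncol(raw))
  cls <- toupper(as.character(if (ncol(raw) >= 11) raw[[11]] else raw[[10]]))
  base <- sub("AL$", "", cls)
  sv_class <- ifelse(base %in% .syri_known, base, "OTHER")
  num <- function(v) suppressWarnings(as.numeric(as.character(v)))
  data.frame(ref_chrom = as.character(raw[[1]]),
             ref_start = num(raw[[2]]) - 1, ref_end = num(raw[[3]]),
             alt_chrom = as.character(raw[[6]]),
             alt_start = num(raw[[7]]) - 1, alt_end = num(raw[[8]]),
             id = as.character(raw[[9]]),
             sv_class = sv_class,
             stringsAsFactors = FALSE)
}

#' Write an AGP v2.1 file describing a patched assembly
#'
#' @param components Data frame with columns `chrom, start, end` (0-based
#'   half-open on the object), `type` (`"W"` sequence, `"N"` gap),
#'   `component_id`, and for `W` rows `component_start, component_end`
#'   (0-based half-open on the component).
#' @param path Output path.
#' @export
write_agp <- function(components, path) {
  co <- components[order(components$chrom, components$start), , drop = FALSE]
  lines <- c("##agp-version\t2.1")
  part <- stats::ave(seq_len(nrow(co)), co$chrom, FUN = seq_along)
  for (i in seq_len(nrow(co))) {
    r <- co[i, ]
    if (identical(r$type, "N")) {
      fields <- c(r$chrom, r$start + 1, r$end, part[i], "N",
                  r$end - r$start, "scaffold", "yes", "align_genus")
    } else {
      fields <- c(r$chrom, r$start + 1, r$end, part[i], "W",
                  r$component_id, r$component_start + 1, r$component_end, "+")
    }
    lines <- c(lines, paste(fields, collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
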
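# Mate-pair container and SAM/BAM ingestion.
#
# All coordinates are held 0-based half-open [start, end); conversion to and
# from the 1-based inclusive SAM convention happens only in read_mate_pairs()
# and write_sam().

MP_COLS <- c("pair_id",
             "chrom_f", "start_f", "end_f", "strand_f",
             "chrom_r", "start_r", "end_r", "strand_r")

#' Construct a mate-pair table
#'
#' A `mate_pairs` object is a data frame with one row per mate pair. The
#' `_f` columns describe the forward-role read (first of pair), the `_r`
#' columns the reverse-role read (second of pair). Coordinates are 0-based
#' half-open.
#'
#' @param df Data frame with columns `pair_id`, `chrom_f`, `start_f`,
#'   `end_f`, `strand_f`, `chrom_r`, `start_r`, `end_r`, `strand_r`.
#' @param seqlevels Character vector giving the canonical chromosome order
#'   (the SAM sequence dictionary); defaults to the sorted chromosome names
#'   present.
#' @param skip_report Optional named integer vector of skipped-record counts
#'   from ingestion.
#' @return A `mate_pairs` data frame.
#' @export
mate_pairs <- function(df, seqlevels = NULL, skip_report = NULL) {
  missing_cols <- setdiff(MP_COLS, names(df))
  if (length(missing_cols))
    stop_param("mate_pairs is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, MP_COLS]
  for (col in c("chrom_f", "chrom_r", "strand_f", "strand_r", "pair_id"))
    df[[col]] <- as.character(df[[col]])
  if (nrow(df)) {
    if (!all(df$strand_f %in% c("+", "-")) || !all(df$strand_r %in% c("+", "-")))
      stop_param("strands must be '+' or '-'")
    if (any(df$start_f >= df$end_f) || any(df$start_r >= df$end_r))
      stop_param("read mappings must satisfy start < end (0-based half-open)")
    if (anyDuplicated(df$pair_id))
      stop_param("pair_id values must be unique")
  }
  if (is.null(seqlevels))
    seqlevels <- sort(unique(c(df$chrom_f, df$chrom_r)))
  rownames(df) <- NULL
  structure(df,
            class = c("mate_pairs", "data.frame"),
            seqlevels = as.character(seqlevels),
            skip_report = skip_report)
}

mp_seqlevels <- function(x) {
  sl <- attr(x, "seqlevels")
  if (is.null(sl)) sl <- sort(unique(c(as.character(x$chrom_f), as.character(x$chrom_r))))
  sl
}

#' @export
print.mate_pairs <- function(x, ...) {
  cat(sprintf("mate_pairs: %d pairs on %d sequence(s)\n",
              nrow(x), length(unique(c(x$chrom_f, x$chrom_r)))))
  rep_ <- attr(x, "skip_report")
  if (!is.null(rep_)) {
    cat("skip report:\n")
    for (nm in names(rep_)) cat(sprintf("  %-28s %d\n", nm, rep_[[nm]]))
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read uniquely mapped mate pairs from SAM/BAM
#'
#' Loads primary alignments, pairs them by query name, and returns one
#' `mate_pairs` row per read name with exactly two uniquely mapped primary
#' ends. Secondary/supplementary alignments, multi-mappers (MAPQ below
#' `min_mapq`), unpaired read names, and degenerate pairs whose two ends
#' have identical coordinates are skipped and counted in the skip report.
#' SAM text input is converted internally via [Rsamtools::asBam()].
#'
#' 1-based inclusive SAM positions are converted to the internal 0-based
#' half-open convention; reference widths honour the CIGAR.
#'
#' @param path Path to a `.bam` or `.sam` file.
#' @param min_mapq Minimum mapping quality for a read to count as uniquely
#'   mapped (default 1, i.e. MAPQ 0 multi-mapper records are dropped).
#' @return A [mate_pairs] object; the sequence dictionary order is taken
#'   from the file header. The skip report is in `attr(x, "skip_report")`.
#' @export
read_mate_pairs <- function(path, min_mapq = 1L) {
  if (!file.exists(path)) stop_missing_file(path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tryCatch(
      Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE),
      error = function(e) stop_format("unparseable SAM stream: ", conditionMessage(e)))
  }
  param <- Rsamtools::ScanBamParam(what = c("qname", "flag", "mapq"))
  ga <- tryCatch(GenomicAlignments::readGAlignments(bam, param = param),
                 error = function(e) stop_format("unparseable BAM stream: ", conditionMessage(e)))
  seqlevels <- GenomeInfoDb::seqlevels(ga)
  n_records <- length(ga)
  if (n_records == 0L)
    stop_empty_input("no alignment records in ", path)

  md <- S4Vectors::mcols(ga)
  flag <- md$flag
  mapq <- md$mapq
  chrom <- as.character(GenomeInfoDb::seqnames(ga))
  start0 <- BiocGenerics::start(ga) - 1L
  end0 <- BiocGenerics::end(ga)        # 1-based inclusive end == 0-based exclusive
  strand <- as.character(BiocGenerics::strand(ga))

  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  low_mapq <- !secondary & (!is.na(mapq) & mapq < min_mapq)
  paired <- bitwAnd(flag, 1L) > 0L
  first <- bitwAnd(flag, 64L) > 0L
  second <- bitwAnd(flag, 128L) > 0L
  role_ok <- paired & xor(first, second)
  usable <- !secondary & !low_mapq & role_ok

  qn <- md$qname
  role <- ifelse(first, "f", "r")
  # read names with exactly one usable end per role
  keyu <- paste0(qn, "\r", role)
  keyu[!usable] <- NA
  dup_key <- !is.na(keyu) & keyu %in% keyu[duplicated(keyu) & !is.na(keyu)]
  uf <- usable & !dup_key & role == "f"
  ur <- usable & !dup_key & role == "r"
  common <- intersect(qn[uf], qn[ur])
  fi <- which(uf)[match(common, qn[uf])]
  ri <- which(ur)[match(common, qn[ur])]

  skipped_unpaired <- sum(usable) - 2L * length(common)
  df <- data.frame(pair_id = qn[fi],
                   chrom_f = chrom[fi], start_f = start0[fi], end_f = end0[fi],
                   strand_f = strand[fi],
                   chrom_r = chrom[ri], start_r = start0[ri], end_r = end0[ri],
                   strand_r = strand[ri],
                   stringsAsFactors = FALSE)
  degenerate <- df$chrom_f == df$chrom_r &
    df$start_f == df$start_r & df$end_f == df$end_r
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate pair(s) with identical end coordinates dropped")
    df <- df[!degenerate, , drop = FALSE]
  }
  df <- df[order(df$pair_id), , drop = FALSE]
  report <- c(n_records = n_records,
              skipped_secondary_supplementary = sum(secondary),
              skipped_low_mapq = sum(low_mapq),
              skipped_unpaired = sum(!secondary & !low_mapq & !role_ok) + skipped_unpaired,
              skipped_degenerate = sum(degenerate),
              n_pairs = nrow(df))
  mate_pairs(df, seqlevels = seqlevels, skip_report = report)
}

#' Orientation signature of mate pairs
#'
#' Encodes, per pair, the strands of the two reads in genomic side order:
#' first the strand of the upstream (5'-ward) read, then the strand of
#' the downstream read -- `"+-"` for an inward-pointing
#' forward/reverse library. Ordering by genomic side rather than by read
#' role makes the signature invariant to which strand of the fragment was
#' sequenced: a concordant fragment yields `"+-"` whichever read came
#' first in the chemistry. One end falling inside an inverted segment
#' gives `"++"` or `"--"`; an everted (order-swapped) pair gives `"-+"`.
#' For inter-chromosomal pairs the sides are ordered by chromosome name
#' (the caller re-derives side order from the sequence dictionary; see
#' [partition_pairs()]).
#'
#' @param pairs A [mate_pairs] object.
#' @return Character vector of two-character signatures, one per pair.
#' @export
pair_signature <- function(pairs) {
  same <- pairs$chrom_f == pairs$chrom_r
  f_first <- ifelse(same,
    pairs$start_f < pairs$start_r |
      (pairs$start_f == pairs$start_r & pairs$end_f <= pairs$end_r),
    pairs$chrom_f < pairs$chrom_r)
  ifelse(f_first,
         paste0(pairs$strand_f, pairs$strand_r),
         paste0(pairs$strand_r, pairs$strand_f))
}

#' Outer-distance insert sizes
#'
#' The insert size of a pair is the outer distance spanned on the
#' reference: the rightmost mapped end minus the leftmost mapped start.
#' Only meaningful for intra-chromosomal pairs; inter-chromosomal pairs get
#' `NA`.
#'
#' @param pairs A [mate_pairs] object.
#' @return Integer vector of insert sizes (bp).
#' @export
insert_sizes <- function(pairs) {
  out <- pmax(pairs$end_f, pairs$end_r) - pmin(pairs$start_f, pairs$start_r)
  out[pairs$chrom_f != pairs$chrom_r] <- NA_integer_
  out
}

#' Remove clonal duplicate mate pairs
#'
#' Pairs sharing identical `(chrom, start, strand)` on both ends are PCR or
#' optical copies of one physical fragment; only one representative (the
#' lexicographically smallest `pair_id`) is kept. The operation is
#' idempotent and independent of input row order; the output is sorted by
#' genomic coordinates.
#'
#' @param pairs A [mate_pairs] object.
#' @return A [mate_pairs] object without clonal duplicates.
#' @export
dedup_clonal <- function(pairs) {
  sl <- mp_seqlevels(pairs)
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$chrom_f, pairs$start_f, pairs$strand_f,
               pairs$chrom_r, pairs$start_r, pairs$strand_r, sep = "\r")
  o <- order(key, pairs$pair_id, method = "radix")
  keep <- o[!duplicated(key[o])]
  df <- pairs[keep, , drop = FALSE]
  o2 <- order(chrom_rank(df$chrom_f, sl), df$start_f,
              chrom_rank(df$chrom_r, sl), df$start_r, df$pair_id,
              method = "radix")
  mate_pairs(df[o2, , drop = FALSE], seqlevels = sl,
             skip_report = attr(pairs, "skip_report"))
}
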
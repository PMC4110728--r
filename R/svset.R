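# Breakpoint sets and their algebra: the endpoint-distance overlap
# predicate, indexed intersection/difference, multi-sample reporting,
# germline/somatic triage, and the benchmark curve over support thresholds.

SV_CORE_COLS <- c("chromA", "b1", "e1", "chromB", "b2", "e2")

#' Construct a breakpoint set
#'
#' A breakpoint connects two genomic footprints
#' `chromA:[b1,e1) - chromB:[b2,e2)` (0-based half-open), with the
#' supporting-pair count and variant class from calling. Chromosome sides
#' are canonically ordered (`chromA <= chromB`; for intra-chromosomal
#' breakpoints `b1 <= b2`).
#'
#' @param breakpoints Data frame with at least `chromA`, `b1`, `e1`,
#'   `chromB`, `b2`, `e2`; optional `name`, `support`,
#'   `effective_support`, `variant_class`, `strand1`, `strand2`, `sample`
#'   are filled with defaults.
#' @param name Label of the set.
#' @param i_max Maximum insert size (bp) used at calling time; drives the
#'   overlap tolerance.
#' @param seqlevels Canonical chromosome order.
#' @return An `sv_set` data frame.
#' @export
sv_set <- function(breakpoints, name = "svset", i_max, seqlevels = NULL) {
  df <- as.data.frame(breakpoints)
  missing_cols <- setdiff(SV_CORE_COLS, names(df))
  if (length(missing_cols))
    stop_param("sv_set is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!is.numeric(i_max) || length(i_max) != 1L || i_max <= 0)
    stop_param("i_max must be a single positive number")
  n <- nrow(df)
  if (is.null(df$name)) df$name <- if (n) sprintf("bp%05d", seq_len(n)) else character(0)
  if (is.null(df$support)) df$support <- rep(1L, n)
  if (is.null(df$effective_support)) df$effective_support <- df$support
  if (is.null(df$variant_class)) df$variant_class <- rep(NA_character_, n)
  if (is.null(df$strand1)) df$strand1 <- rep(".", n)
  if (is.null(df$strand2)) df$strand2 <- rep(".", n)
  if (is.null(df$sample)) df$sample <- rep(name, n)
  if (n && (any(df$b1 > df$e1) || any(df$b2 > df$e2)))
    stop_param("footprints must satisfy b1 <= e1 and b2 <= e2")
  if (is.null(seqlevels))
    seqlevels <- sort(unique(c(as.character(df$chromA), as.character(df$chromB))))
  df <- df[, c(SV_CORE_COLS[1:3], SV_CORE_COLS[4:6], "name", "support",
               "effective_support", "variant_class", "strand1", "strand2",
               "sample")]
  rownames(df) <- NULL
  structure(df, class = c("sv_set", "data.frame"),
            set_name = name, i_max = i_max, seqlevels = as.character(seqlevels))
}

sv_imax <- function(x) {
  v <- attr(x, "i_max")
  if (is.null(v)) stop_param("breakpoint set carries no i_max")
  v
}

sv_name <- function(x) {
  v <- attr(x, "set_name")
  if (is.null(v)) "svset" else v
}

sv_subset <- function(x, i, name = sv_name(x)) {
  sv_set(as.data.frame(x)[i, , drop = FALSE], name = name,
         i_max = sv_imax(x), seqlevels = attr(x, "seqlevels"))
}

#' @export
print.sv_set <- function(x, ...) {
  cat(sprintf("sv_set '%s': %d breakpoint(s), i_max = %g bp\n",
              sv_name(x), nrow(x), sv_imax(x)))
  if (nrow(x)) {
    tab <- table(x$variant_class, useNA = "ifany")
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    print(utils::head(as.data.frame(x), 6L))
  }
  log <- attr(x, "stage_log")
  if (!is.null(log)) {
    cat("  stage log:", paste(sprintf("%s=%d", names(log), log), collapse = ", "), "\n")
  }
  invisible(x)
}

min_four <- function(b, e, bp, ep) {
  pmin(abs(b - bp), abs(e - ep), abs(b - ep), abs(e - bp))
}

#' Breakpoint overlap predicate
#'
#' Two breakpoints overlap iff they connect the same canonical chromosome
#' pair and, on each side, the minimum of the four endpoint distances
#' `min(|b-b'|, |e-e'|, |b-e'|, |e-b'|)` does not exceed `i_max`. The
#' predicate is symmetric and reflexive but not transitive; set operations
#' therefore never chain overlaps. Variant class is ignored (the overlap
#' definition is class-blind).
#'
#' @param a,b Breakpoint rows ([sv_set] or data frames); recycled
#'   row-wise like ordinary vectors.
#' @param i_max Overlap tolerance in bp. When comparing two sets, use the
#'   maximum of the two sets' `i_max` values (see [pooled_imax()]).
#' @return Logical vector.
#' @export
breakpoints_overlap <- function(a, b, i_max) {
  same <- as.character(a$chromA) == as.character(b$chromA) &
    as.character(a$chromB) == as.character(b$chromB)
  same &
    min_four(a$b1, a$e1, b$b1, b$e1) <= i_max &
    min_four(a$b2, a$e2, b$b2, b$e2) <= i_max
}

#' Pooled overlap tolerance for two breakpoint sets
#'
#' The overlap tolerance for comparing two experiments is the maximum of
#' their insert-size upper bounds.
#'
#' @param a,b [sv_set] objects.
#' @return Numeric scalar.
#' @export
pooled_imax <- function(a, b) max(sv_imax(a), sv_imax(b))

# Indexed all-vs-all overlap. Returns a two-column matrix (i, j) of
# overlapping row indices. Candidates come from an interval index: side-A
# footprints of `a` padded by i_max against side-A footprints of `b`
# (endpoint proximity implies padded-footprint overlap, so no true match
# is missed); the exact min-of-four predicate is applied to candidates.
overlap_hits <- function(a, b, i_max) {
  keyA <- paste(a$chromA, a$chromB, sep = "|")
  keyB <- paste(b$chromA, b$chromB, sep = "|")
  res <- list()
  for (k in intersect(unique(keyA), unique(keyB))) {
    ia <- which(keyA == k)
    ib <- which(keyB == k)
    qr <- IRanges::IRanges(start = as.integer(a$b1[ia] - i_max),
                           end = as.integer(a$e1[ia] + i_max))
    sr <- IRanges::IRanges(start = as.integer(b$b1[ib]),
                           end = as.integer(b$e1[ib]))
    h <- IRanges::findOverlaps(qr, sr)
    qi <- ia[S4Vectors::queryHits(h)]
    si <- ib[S4Vectors::subjectHits(h)]
    if (length(qi)) {
      ok <- min_four(a$b1[qi], a$e1[qi], b$b1[si], b$e1[si]) <= i_max &
        min_four(a$b2[qi], a$e2[qi], b$b2[si], b$e2[si]) <= i_max
      if (any(ok)) res[[length(res) + 1L]] <- cbind(i = qi[ok], j = si[ok])
    }
  }
  if (!length(res)) return(cbind(i = integer(0), j = integer(0)))
  do.call(rbind, res)
}

#' Intersect and subtract breakpoint sets
#'
#' Partitions the breakpoints of `a` into those overlapping at least one
#' breakpoint of `b` (the intersection, on `a`'s elements) and the rest
#' (the difference). Overlap uses the pooled tolerance
#' `max(a$i_max, b$i_max)`. Both directions are obtained by swapping the
#' arguments.
#'
#' @param a,b [sv_set] objects.
#' @return List with `intersection` and `difference`, both [sv_set]s over
#'   `a`'s breakpoints.
#' @export
intersect_sv_sets <- function(a, b) {
  im <- pooled_imax(a, b)
  hits <- overlap_hits(as.data.frame(a), as.data.frame(b), im)
  ina <- sort(unique(hits[, "i"]))
  list(intersection = sv_subset(a, ina, name = paste0(sv_name(a), ".both")),
       difference = sv_subset(a, setdiff(seq_len(nrow(a)), ina),
                              name = paste0(sv_name(a), ".only")))
}

#' Triage tumor breakpoints against polymorphism panels
#'
#' A tumor breakpoint overlapping any breakpoint in any panel set is
#' likely of germline origin (a structural polymorphism); the
#' non-overlapping remainder is putatively somatic.
#'
#' @param tumor An [sv_set] of tumor calls.
#' @param panels List of [sv_set]s of population/panel breakpoints.
#' @return List with `germline_like` and `putative_somatic` [sv_set]s
#'   partitioning `tumor`.
#' @export
triage_somatic <- function(tumor, panels) {
  if (inherits(panels, "sv_set")) panels <- list(panels)
  germ <- rep(FALSE, nrow(tumor))
  td <- as.data.frame(tumor)
  for (p in panels) {
    im <- pooled_imax(tumor, p)
    hits <- overlap_hits(td, as.data.frame(p), im)
    germ[unique(hits[, "i"])] <- TRUE
  }
  list(germline_like = sv_subset(tumor, which(germ),
                                 name = paste0(sv_name(tumor), ".germline_like")),
       putative_somatic = sv_subset(tumor, which(!germ),
                                    name = paste0(sv_name(tumor), ".putative_somatic")))
}

#' Multi-sample breakpoint overlap report
#'
#' One row per breakpoint of each input set, with the count of
#' overlapping breakpoints in every other set (pooled tolerance: maximum
#' `i_max` across all inputs) and the names of genes whose interval lies
#' within `gene_window` bp of either footprint (distance 0 for direct
#' overlap).
#'
#' @param sets List of [sv_set]s (named, or names taken from the sets).
#' @param genes Optional gene track: a `GRanges` or a data frame with
#'   `chrom`, `start`, `end`, `name` (0-based half-open).
#' @param gene_window Gene proximity window in bp (default 2000).
#' @return An `overlap_report` data frame; row order follows the input
#'   sets.
#' @export
report_multiple <- function(sets, genes = NULL, gene_window = 2000) {
  if (inherits(sets, "sv_set")) sets <- list(sets)
  if (!length(sets)) stop_param("report_multiple needs at least one set")
  nms <- names(sets)
  if (is.null(nms)) nms <- vapply(sets, sv_name, "")
  nms[!nzchar(nms)] <- vapply(sets[!nzchar(nms)], sv_name, "")
  if (anyDuplicated(nms)) nms <- make.unique(nms)
  im <- max(vapply(sets, sv_imax, 0))
  gtrack <- if (!is.null(genes)) as_feature_df(genes) else NULL
  rows <- list()
  for (si in seq_along(sets)) {
    df <- as.data.frame(sets[[si]])
    if (!nrow(df)) next
    out <- data.frame(set = nms[si], df, stringsAsFactors = FALSE)
    for (sj in seq_along(sets)) {
      if (sj == si) next
      cnt <- integer(nrow(df))
      hits <- overlap_hits(df, as.data.frame(sets[[sj]]), im)
      if (nrow(hits)) {
        t_ <- table(hits[, "i"])
        cnt[as.integer(names(t_))] <- as.integer(t_)
      }
      out[[paste0("overlaps_", nms[sj])]] <- cnt
    }
    out$genes <- if (is.null(gtrack)) "" else
      vapply(seq_len(nrow(df)), function(i)
        genes_near_breakpoint(df[i, ], gtrack, gene_window), "")
    rows[[length(rows) + 1L]] <- out
  }
  res <- if (length(rows)) {
    common <- Reduce(union, lapply(rows, names))
    rows <- lapply(rows, function(r) {
      for (m in setdiff(common, names(r))) r[[m]] <- 0L
      r[, common]
    })
    do.call(rbind, rows)
  } else data.frame()
  rownames(res) <- NULL
  class(res) <- c("overlap_report", "data.frame")
  attr(res, "i_max") <- im
  attr(res, "gene_window") <- gene_window
  res
}

# Gap between half-open intervals [s1,e1) and [s2,e2): 0 when they
# intersect.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s2 - e1, s1 - e2))
}

genes_near_breakpoint <- function(bp, gtrack, window) {
  hit <- (gtrack$chrom == bp$chromA &
            interval_gap(bp$b1, bp$e1, gtrack$start, gtrack$end) <= window) |
    (gtrack$chrom == bp$chromB &
       interval_gap(bp$b2, bp$e2, gtrack$start, gtrack$end) <= window)
  paste(sort(unique(gtrack$name[hit])), collapse = ",")
}

#' Benchmark curve over supporting-pair thresholds
#'
#' For each minimum-support threshold, retains the calls with at least
#' that many supporting pairs and records the total number of calls (the
#' surrogate for the unknown false-positive rate) and the number of truth
#' breakpoints overlapped by a retained call. Both counts are
#' non-increasing in the threshold.
#'
#' @param calls An [sv_set] whose `support` column carries the
#'   supporting-pair counts.
#' @param truth An [sv_set] of reference breakpoints.
#' @param thresholds Integer vector of minimum-support thresholds.
#' @return A `benchmark_curve` data frame with columns `min_support`,
#'   `total_calls`, `true_positives`.
#' @export
benchmark_curve <- function(calls, truth, thresholds) {
  thresholds <- sort(unique(as.integer(thresholds)))
  im <- pooled_imax(calls, truth)
  hits <- overlap_hits(as.data.frame(truth), as.data.frame(calls), im)
  sup <- calls$support
  pts <- lapply(thresholds, function(t_) {
    kept <- sup >= t_
    data.frame(min_support = t_,
               total_calls = sum(kept),
               true_positives = length(unique(hits[kept[hits[, "j"]], "i"])))
  })
  out <- do.call(rbind, pts)
  class(out) <- c("benchmark_curve", "data.frame")
  out
}

#' @export
plot.benchmark_curve <- function(x, ...) {
  plot(x$total_calls, x$true_positives, type = "b",
       xlab = "total calls (false-positive surrogate)",
       ylab = "true positives", ...)
  invisible(x)
}

#' Write a breakpoint set as BEDPE
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name,
#' score (support), strand1, strand2, variant_class, effective_support,
#' sample. Coordinates are 0-based half-open. No header line.
#'
#' @param x An [sv_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path) {
  df <- as.data.frame(x)
  out <- data.frame(df$chromA, df$b1, df$e1, df$chromB, df$b2, df$e2,
                    df$name, df$support, df$strand1, df$strand2,
                    df$variant_class, df$effective_support, df$sample)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE breakpoint set
#'
#' Accepts the 10-column BEDPE core (chrom1, start1, end1, chrom2,
#' start2, end2, name, score, strand1, strand2) plus the three extra
#' columns written by [write_bedpe()]; shorter records down to the
#' 6-column core are tolerated with defaults. The score column is read as
#' the support count.
#'
#' @param path Path to a BEDPE file.
#' @param name Set label (defaults to the file base name).
#' @param i_max Overlap tolerance to attach to the set.
#' @return An [sv_set].
#' @export
read_bedpe <- function(path, name = NULL, i_max) {
  if (!file.exists(path)) stop_missing_file(path)
  if (is.null(name)) name <- sub("\\.bedpe$", "", basename(path))
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
  if (length(nf) && any(nf < 6))
    stop_format("malformed BEDPE (fewer than 6 columns) at line ",
                which(nf < 6)[1L], " of ", path)
  empty <- length(nf) == 0L
  df <- if (empty) data.frame() else
    utils::read.table(path, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, fill = TRUE)
  cols <- c("chromA", "b1", "e1", "chromB", "b2", "e2", "name", "support",
            "strand1", "strand2", "variant_class", "effective_support",
            "sample")
  if (!empty) {
    names(df)[seq_len(min(ncol(df), length(cols)))] <-
      cols[seq_len(min(ncol(df), length(cols)))]
  }
  bp <- if (empty)
    data.frame(chromA = character(), b1 = numeric(), e1 = numeric(),
               chromB = character(), b2 = numeric(), e2 = numeric())
  else df
  sv_set(bp, name = name, i_max = i_max)
}

#' Write an overlap report as TSV
#'
#' Fixed header: the breakpoint identity columns, one `overlaps_<set>`
#' column per other input set, and the comma-separated `genes` column.
#'
#' @param x An `overlap_report` from [report_multiple()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
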
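# Permutation test for enrichment/depletion of interval features around
# breakpoints, per variant class, plus group-level discriminating-feature
# selection on an enrichment matrix.

# Normalise feature input (GRanges / data frame) to a 0-based half-open
# data frame with chrom, start, end, name.
as_feature_df <- function(x, name = "features") {
  if (inherits(x, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(x)),
      start = BiocGenerics::start(x) - 1L,
      end = BiocGenerics::end(x),
      stringsAsFactors = FALSE)
    nm <- S4Vectors::mcols(x)$name
    if (is.null(nm)) nm <- S4Vectors::mcols(x)$Name
    df$name <- if (is.null(nm)) paste0(name, "_", seq_len(nrow(df))) else as.character(nm)
    df
  } else {
    df <- as.data.frame(x)
    if (!all(c("chrom", "start", "end") %in% names(df)))
      stop_param("feature track needs chrom/start/end columns")
    if (is.null(df$name)) df$name <- paste0(name, "_", seq_len(nrow(df)))
    df[, c("chrom", "start", "end", "name")]
  }
}

#' Construct a feature track
#'
#' A named collection of genomic intervals (histone-mark peaks,
#' methylation domains, genes, ...) used by the enrichment test and the
#' overlap report. Intervals are 0-based half-open and may overlap each
#' other.
#'
#' @param x A `GRanges` or a data frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @param name Track label.
#' @return A `feature_track` data frame.
#' @export
feature_track <- function(x, name = "features") {
  df <- as_feature_df(x, name)
  if (nrow(df) && any(df$start >= df$end))
    stop_param("feature intervals must satisfy start < end")
  structure(df, class = c("feature_track", "data.frame"), track_name = name)
}

track_name <- function(x) {
  v <- attr(x, "track_name")
  if (is.null(v)) "features" else v
}

#' Read a feature track from BED or GFF
#'
#' BED (3+ columns; the name column is used when present) and GFF3 are
#' parsed with [rtracklayer::import()]. For GFF input only `gene`
#' features are retained when any are present, named by their `Name`,
#' `gene_id` or `ID` attribute -- this is the gene-annotation path of the
#' overlap report.
#'
#' @param path Path to a `.bed`, `.gff`/`.gff3`/`.gtf` file.
#' @param name Track label (defaults to the file base name).
#' @return A [feature_track].
#' @export
read_features <- function(path, name = NULL) {
  if (!file.exists(path)) stop_missing_file(path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop_format("cannot parse feature track ",
                                                 path, ": ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$type) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
    nm <- md$Name
    if (is.null(nm) || all(is.na(nm))) nm <- md$gene_id
    if (is.null(nm) || all(is.na(nm))) nm <- md$ID
    if (!is.null(nm)) S4Vectors::mcols(gr)$name <- as.character(nm)
  }
  feature_track(gr, name = name)
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name and length in bp.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop_missing_file(path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_format("chrom.sizes needs two columns: ", path)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Enrichment test configuration
#'
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param radius Half-width of the window around each breakpoint locus
#'   (bp, default 50000).
#' @param n_perm Number of permutation replicates (default 1000; the
#'   Monte-Carlo p-value floor is `1/(n_perm + 1)`).
#' @param seed Optional RNG seed for reproducible permutations.
#' @return An `enrichment_config` list.
#' @export
enrichment_config <- function(genome, radius = 50000, n_perm = 1000, seed = NULL) {
  if (radius <= 0) stop_param("radius must be > 0")
  if (n_perm < 1) stop_param("n_perm must be >= 1")
  if (is.null(names(genome)) || !is.numeric(genome))
    stop_param("genome must be a named numeric vector of chromosome lengths")
  structure(list(genome = genome, radius = radius,
                 n_perm = as.integer(n_perm), seed = seed),
            class = "enrichment_config")
}

# Breakpoint loci: footprint midpoints of both sides; a single merged
# midpoint when the two windows of an intra-chromosomal breakpoint
# overlap. Returns a data frame (chrom, pos) sorted deterministically.
breakpoint_loci <- function(breakpoints, radius) {
  df <- as.data.frame(breakpoints)
  if (!nrow(df)) return(data.frame(chrom = character(), pos = numeric()))
  midA <- floor((df$b1 + df$e1) / 2)
  midB <- floor((df$b2 + df$e2) / 2)
  merged <- df$chromA == df$chromB & abs(midA - midB) <= 2 * radius
  loci <- rbind(
    data.frame(chrom = df$chromA[merged],
               pos = floor((midA[merged] + midB[merged]) / 2)),
    data.frame(chrom = df$chromA[!merged], pos = midA[!merged]),
    data.frame(chrom = df$chromB[!merged], pos = midB[!merged]))
  loci[order(loci$chrom, loci$pos, method = "radix"), , drop = FALSE]
}

# Count (feature, window) incidences for windows [pos - r, pos + r)
# clipped to [0, chrom length). `starts`/`ends` are per-chromosome sorted
# feature coordinate lists. Multiplicity counting: a feature near two
# windows counts twice.
count_windows <- function(chrom, pos, radius, genome, starts, ends) {
  total <- numeric(length(pos))
  for (c_ in unique(chrom)) {
    i <- chrom == c_
    fs <- starts[[c_]]
    if (is.null(fs)) next
    fe <- ends[[c_]]
    len <- genome[[c_]]
    ws <- pmax(0, pos[i] - radius)
    we <- pmin(len, pos[i] + radius)
    # features [s,e) intersecting [ws,we): s <= we-1 and e > ws
    total[i] <- findInterval(we - 1, fs) - findInterval(ws, fe)
  }
  total
}

feature_index <- function(track) {
  df <- as_feature_df(track)
  list(starts = lapply(split(df$start, df$chrom), sort),
       ends = lapply(split(df$end, df$chrom), sort))
}

#' Count features near breakpoints
#'
#' Observed feature incidence around a set of breakpoints: each
#' breakpoint contributes two loci (the midpoints of its two footprints;
#' one merged locus when the two windows of an intra-chromosomal
#' breakpoint overlap), and a feature is incident on a locus when its
#' interval intersects the window `locus +/- radius` clipped to the
#' chromosome bounds. With `unique_features = FALSE` (default) incidences
#' are counted with multiplicity, keeping the statistic additive over
#' breakpoints; `TRUE` counts distinct features once.
#'
#' @param breakpoints An [sv_set] (or breakpoint data frame).
#' @param track A [feature_track] (or coercible input).
#' @param radius Window half-width in bp.
#' @param genome Named numeric vector of chromosome lengths.
#' @param unique_features Count each feature at most once.
#' @return Integer count.
#' @export
count_features_near <- function(breakpoints, track, radius, genome,
                                unique_features = FALSE) {
  loci <- breakpoint_loci(breakpoints, radius)
  df <- as_feature_df(track)
  if (!nrow(loci) || !nrow(df)) return(0L)
  if (unique_features) {
    hit <- logical(nrow(df))
    for (i in seq_len(nrow(loci))) {
      len <- genome[[loci$chrom[i]]]
      ws <- max(0, loci$pos[i] - radius)
      we <- min(len, loci$pos[i] + radius)
      hit <- hit | (df$chrom == loci$chrom[i] & df$start <= we - 1 & df$end > ws)
    }
    return(sum(hit))
  }
  idx <- feature_index(df)
  as.integer(sum(count_windows(loci$chrom, loci$pos, radius, genome,
                               idx$starts, idx$ends)))
}

#' Permutation test for feature enrichment around breakpoints
#'
#' For each variant class present, computes the observed feature
#' incidence around the class's breakpoints and a permutation null in
#' which every breakpoint locus is re-placed uniformly at random on its
#' own chromosome (preserving per-chromosome locus counts and the
#' feature track's spatial clustering). Fold enrichment is
#' observed / null mean; tail p-values use the add-one rule
#' `p = (1 + #extreme) / (n_perm + 1)`, so they are never zero. Both
#' tails are reported (depletion of a mark is as interpretable as
#' enrichment). Results are reproducible given the config seed and
#' independent of input row order.
#'
#' @param breakpoints An [sv_set].
#' @param track A [feature_track].
#' @param config An [enrichment_config]; every breakpoint chromosome must
#'   be present in its genome.
#' @param by_class Split by `variant_class` (default); `FALSE` pools all
#'   breakpoints into one class `"all"`.
#' @param unique_features Passed to [count_features_near()].
#' @return An `enrichment_result` data frame, one row per class, with
#'   columns `track`, `variant_class`, `n_breakpoints`, `n_loci`,
#'   `observed`, `null_mean`, `null_sd`, `fold`, `p_enrich`, `p_deplete`.
#' @export
permutation_enrichment <- function(breakpoints, track, config,
                                   by_class = TRUE, unique_features = FALSE) {
  stopifnot(inherits(config, "enrichment_config"))
  df <- as.data.frame(breakpoints)
  chroms <- unique(c(df$chromA, df$chromB))
  missing_chr <- setdiff(chroms, names(config$genome))
  if (length(missing_chr))
    stop_param("breakpoint chromosome(s) absent from genome: ",
               paste(missing_chr, collapse = ", "))
  classes <- if (by_class) {
    cl <- as.character(df$variant_class)
    cl[is.na(cl)] <- "unclassified"
    cl
  } else rep("all", nrow(df))
  fdf <- as_feature_df(track)
  idx <- feature_index(fdf)
  with_seed(config$seed, {
    rows <- lapply(sort(unique(classes)), function(cl) {
      sub <- df[classes == cl, , drop = FALSE]
      loci <- breakpoint_loci(sub, config$radius)
      observed <- count_features_near(sub, fdf, config$radius, config$genome,
                                      unique_features)
      k <- nrow(loci)
      null_counts <- numeric(config$n_perm)
      for (c_ in unique(loci$chrom)) {
        ni <- sum(loci$chrom == c_)
        len <- config$genome[[c_]]
        pos <- floor(runif(ni * config$n_perm) * len)
        if (!unique_features) {
          cnt <- count_windows(rep(c_, length(pos)), pos, config$radius,
                               config$genome, idx$starts, idx$ends)
          null_counts <- null_counts +
            colSums(matrix(cnt, nrow = ni, ncol = config$n_perm))
        } else {
          pm <- matrix(pos, nrow = ni)
          for (p_ in seq_len(config$n_perm)) {
            fake <- data.frame(chrom = rep(c_, ni), pos = pm[, p_])
            null_counts[p_] <- null_counts[p_] +
              count_unique_loci(fake, fdf, config$radius, config$genome)
          }
        }
      }
      null_mean <- mean(null_counts)
      data.frame(track = track_name(track), variant_class = cl,
                 n_breakpoints = nrow(sub), n_loci = k,
                 observed = observed, null_mean = null_mean,
                 null_sd = stats::sd(null_counts),
                 fold = if (null_mean > 0) observed / null_mean else NA_real_,
                 p_enrich = (1 + sum(null_counts >= observed)) / (config$n_perm + 1),
                 p_deplete = (1 + sum(null_counts <= observed)) / (config$n_perm + 1),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("enrichment_result", "data.frame")
    out
  })
}

count_unique_loci <- function(loci, fdf, radius, genome) {
  hit <- logical(nrow(fdf))
  for (i in seq_len(nrow(loci))) {
    len <- genome[[loci$chrom[i]]]
    ws <- max(0, loci$pos[i] - radius)
    we <- min(len, loci$pos[i] + radius)
    hit <- hit | (fdf$chrom == loci$chrom[i] & fdf$start <= we - 1 & fdf$end > ws)
  }
  sum(hit)
}

#' Enrichment matrix over samples and feature tracks
#'
#' Runs [permutation_enrichment()] for every (track, sample) cell with
#' the same configuration (identical seed per cell, so identical inputs
#' give identical columns) and collects fold enrichments and tail
#' p-values into track-by-sample matrices.
#'
#' @param samples Named list of [sv_set]s (columns).
#' @param tracks Named list of [feature_track]s (rows).
#' @param config An [enrichment_config].
#' @param class `"all"` (pool all breakpoints, default) or a single
#'   variant class to slice on.
#' @param unique_features Passed through.
#' @return An `enrichment_matrix` list with matrices `fold`, `p_enrich`,
#'   `p_deplete`, and the class/radius metadata.
#' @export
enrichment_matrix <- function(samples, tracks, config, class = "all",
                              unique_features = FALSE) {
  if (inherits(samples, "sv_set")) samples <- list(samples)
  if (inherits(tracks, "feature_track")) tracks <- list(tracks)
  snames <- names(samples)
  if (is.null(snames)) snames <- vapply(samples, sv_name, "")
  tnames <- names(tracks)
  if (is.null(tnames)) tnames <- vapply(tracks, track_name, "")
  fold <- pe <- pd <- matrix(NA_real_, nrow = length(tracks), ncol = length(samples),
                             dimnames = list(tnames, snames))
  for (si in seq_along(samples)) {
    s <- samples[[si]]
    if (class != "all") s <- sv_subset(s, which(s$variant_class == class))
    for (ti in seq_along(tracks)) {
      r <- permutation_enrichment(s, tracks[[ti]], config, by_class = FALSE,
                                  unique_features = unique_features)
      fold[ti, si] <- r$fold
      pe[ti, si] <- r$p_enrich
      pd[ti, si] <- r$p_deplete
    }
  }
  structure(list(fold = fold, p_enrich = pe, p_deplete = pd,
                 class = class, radius = config$radius, n_perm = config$n_perm),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix: %d track(s) x %d sample(s), class '%s', radius %g bp\n",
              nrow(x$fold), ncol(x$fold), x$class, x$radius))
  print(round(x$fold, 3))
  invisible(x)
}

#' Write / read an enrichment fold matrix as TSV
#'
#' Samples as columns, tracks as rows; the first column holds the track
#' name.
#'
#' @param x An `enrichment_matrix`.
#' @param path Output path.
#' @return `path` (write) or a numeric matrix (read).
#' @export
write_enrichment_matrix <- function(x, path) {
  df <- data.frame(track = rownames(x$fold), x$fold, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_matrix
#' @export
read_enrichment_matrix <- function(path) {
  if (!file.exists(path)) stop_missing_file(path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Select features discriminating two sample groups
#'
#' For every feature track (matrix row) the fold-enrichment values of the
#' two sample groups are compared with a two-sample test
#' (Mann-Whitney-Wilcoxon rank-sum by default, or Welch t-test). Tracks
#' with `p < alpha` -- and, when `min_fold_change` is set, a ratio of
#' group mean enrichments at least that large -- are reported with the
#' direction of the higher group.
#'
#' @param mat An `enrichment_matrix` or a plain numeric matrix of fold
#'   enrichments (tracks x samples).
#' @param group_a,group_b Character vectors of sample (column) labels;
#'   both non-empty.
#' @param method `"ranksum"` or `"ttest"`. The t-test requires at least
#'   two samples per group; the rank-sum test allows singleton groups
#'   with a warning.
#' @param alpha Significance threshold (default 0.05).
#' @param min_fold_change Optional minimum ratio of group mean
#'   enrichments (e.g. 1.25).
#' @return Data frame with columns `track`, `direction` (`"group_a"` or
#'   `"group_b"`), `p`, `mean_a`, `mean_b`, `fold_ratio` -- one row per
#'   discriminating track.
#' @export
discriminating_features <- function(mat, group_a, group_b,
                                    method = c("ranksum", "ttest"),
                                    alpha = 0.05, min_fold_change = NULL) {
  method <- match.arg(method)
  m <- if (inherits(mat, "enrichment_matrix")) mat$fold else as.matrix(mat)
  if (!length(group_a) || !length(group_b))
    stop_param("both groups must be non-empty")
  bad <- setdiff(c(group_a, group_b), colnames(m))
  if (length(bad))
    stop_param("group label(s) not in matrix columns: ", paste(bad, collapse = ", "))
  if (method == "ttest" && (length(group_a) < 2 || length(group_b) < 2))
    stop_param("t-test needs at least two samples per group (variance undefined)")
  if (method == "ranksum" && (length(group_a) < 2 || length(group_b) < 2))
    warning("rank-sum comparison with a singleton group has minimal power")
  rows <- lapply(rownames(m), function(tr) {
    x <- m[tr, group_a]
    y <- m[tr, group_b]
    p <- suppressWarnings(tryCatch(
      if (method == "ranksum") stats::wilcox.test(x, y)$p.value
      else stats::t.test(x, y)$p.value,
      error = function(e) NA_real_))  # degenerate data (e.g. zero variance)
    if (is.na(p)) p <- 1
    ma <- mean(x); mb <- mean(y)
    ratio <- max(ma, mb) / max(min(ma, mb), .Machine$double.eps)
    data.frame(track = tr,
               direction = if (ma >= mb) "group_a" else "group_b",
               p = p, mean_a = ma, mean_b = mb, fold_ratio = ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  keep <- out$p < alpha &
    (is.null(min_fold_change) | out$fold_ratio >= (min_fold_change %||% 0))
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
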
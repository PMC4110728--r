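# Breakpoint caller: partition inconsistent pairs by chromosome pair,
# coarse greedy clustering on a sliding-window grid, single-linkage
# refinement, diversity thinning, and variant-class assignment.

#' Caller configuration
#'
#' @param model An [insert_size_model]; supplies `i_max` for the defaults.
#' @param w Grid window size in bp; must exceed the model's `i_max`
#'   (default `2 * i_max`, giving slack for coarse clustering before
#'   refinement).
#' @param min_support Minimum mate pairs per reported variant (default 3).
#' @param min_end_spread Minimum separation of read ends within a cluster
#'   for two pairs to count as independent evidence (bp, default 50).
#' @param refine_cut Single-linkage cut distance for cluster refinement
#'   (bp, default `i_max`: pairs from one physical breakpoint have both
#'   ends within one insert length).
#' @param end_spread_mode `"thin"` (default): redundant pairs are thinned
#'   and the thinned count must reach `min_support`. `"veto"`: the raw
#'   member count must reach `min_support` and the cluster is vetoed
#'   unless it holds at least two diverse pairs.
#' @return A `caller_config` list.
#' @export
caller_config <- function(model, w = NULL, min_support = 3L,
                          min_end_spread = 50L, refine_cut = NULL,
                          end_spread_mode = c("thin", "veto")) {
  stopifnot(inherits(model, "insert_size_model"))
  end_spread_mode <- match.arg(end_spread_mode)
  if (is.null(w)) w <- 2 * model$i_max
  if (is.null(refine_cut)) refine_cut <- model$i_max
  if (w <= model$i_max) stop_param("window w must exceed i_max")
  if (min_support < 1) stop_param("min_support must be >= 1")
  if (min_end_spread < 0) stop_param("min_end_spread must be >= 0")
  if (refine_cut <= 0) stop_param("refine_cut must be > 0")
  structure(list(w = w, min_support = as.integer(min_support),
                 min_end_spread = as.numeric(min_end_spread),
                 refine_cut = as.numeric(refine_cut),
                 end_spread_mode = end_spread_mode),
            class = "caller_config")
}

#' Partition inconsistent pairs by canonical chromosome pair
#'
#' Each pair is keyed by its canonically ordered chromosome pair
#' (sequence-dictionary order, lexicographic fallback); sides are swapped
#' so side A falls on the lower-ranked chromosome, and for
#' intra-chromosomal pairs side A is the side with the smaller start. The
#' orientation signature is re-derived in side order (`strandA` then
#' `strandB`), so it is consistent with the bucket's side assignment even
#' when the sequence dictionary disagrees with lexicographic chromosome
#' order.
#'
#' @param pairs A [mate_pairs] object (inconsistent pairs).
#' @param seqlevels Canonical chromosome order; defaults to the pairs'
#'   sequence dictionary.
#' @return A data frame with columns `pair_id`, `chromA`, `startA`,
#'   `endA`, `strandA`, `chromB`, `startB`, `endB`, `strandB`, `sig`,
#'   `key`; split on `key` to obtain the per-chromosome-pair buckets.
#' @export
partition_pairs <- function(pairs, seqlevels = NULL) {
  if (is.null(seqlevels)) seqlevels <- mp_seqlevels(pairs)
  rf <- chrom_rank(pairs$chrom_f, seqlevels)
  rr <- chrom_rank(pairs$chrom_r, seqlevels)
  swap <- rf > rr |
    (rf == rr & (pairs$start_f > pairs$start_r |
                   (pairs$start_f == pairs$start_r & pairs$end_f > pairs$end_r)))
  pick <- function(f, r) ifelse(swap, r, f)
  out <- data.frame(
    pair_id = pairs$pair_id,
    chromA = pick(pairs$chrom_f, pairs$chrom_r),
    startA = pick(pairs$start_f, pairs$start_r),
    endA = pick(pairs$end_f, pairs$end_r),
    strandA = pick(pairs$strand_f, pairs$strand_r),
    chromB = pick(pairs$chrom_r, pairs$chrom_f),
    startB = pick(pairs$start_r, pairs$start_f),
    endB = pick(pairs$end_r, pairs$end_f),
    strandB = pick(pairs$strand_r, pairs$strand_f),
    stringsAsFactors = FALSE)
  out$sig <- paste0(out$strandA, out$strandB)
  out$key <- paste(out$chromA, out$chromB, sep = "|")
  rownames(out) <- NULL
  out
}

#' Coarse greedy clustering of one chromosome-pair bucket
#'
#' Pairs are first split by orientation signature. Within a signature they
#' are swept in `(startA, startB, pair_id)` order; a pair joins an open
#' cluster when its side-A start is within `w` of the cluster's side-A
#' start footprint and its side-B start within `w` of the side-B start
#' footprint. A pair matching several open clusters merges them (so a
#' single-linkage-connected group is never split across coarse clusters);
#' a cluster closes once the sweep has passed its side-A footprint by more
#' than `w`.
#'
#' @param bucket Data frame for one chromosome pair, as produced by
#'   [partition_pairs()].
#' @param config A [caller_config].
#' @return List of data frames, one per coarse cluster (rows of `bucket`).
#' @export
coarse_cluster <- function(bucket, config) {
  out <- list()
  for (s in split(seq_len(nrow(bucket)), bucket$sig)) {
    sub <- bucket[s, , drop = FALSE]
    o <- order(sub$startA, sub$startB, sub$pair_id, method = "radix")
    idx <- s[o]
    groups <- coarse_sweep(bucket$startA[idx], bucket$startB[idx], config$w)
    out <- c(out, lapply(groups, function(g) bucket[idx[g], , drop = FALSE]))
  }
  out
}

# Greedy sweep over pairs sorted by (sa, sb); returns list of index groups.
coarse_sweep <- function(sa, sb, w) {
  n <- length(sa)
  if (n == 0L) return(list())
  members <- list()   # per cluster: integer indices
  maxA <- minB <- maxB <- numeric(0)
  open <- integer(0)
  for (i in seq_len(n)) {
    # close clusters the sweep has passed
    if (length(open))
      open <- open[sa[i] - maxA[open] <= w]
    hit <- open[sa[i] - maxA[open] <= w &
                  sb[i] >= minB[open] - w & sb[i] <= maxB[open] + w]
    if (!length(hit)) {
      k <- length(members) + 1L
      members[[k]] <- i
      maxA[k] <- sa[i]; minB[k] <- sb[i]; maxB[k] <- sb[i]
      open <- c(open, k)
    } else {
      k <- hit[1L]
      if (length(hit) > 1L) {
        for (m in hit[-1L]) {
          members[[k]] <- c(members[[k]], members[[m]])
          maxA[k] <- max(maxA[k], maxA[m])
          minB[k] <- min(minB[k], minB[m])
          maxB[k] <- max(maxB[k], maxB[m])
          members[[m]] <- integer(0)
        }
        open <- setdiff(open, hit[-1L])
      }
      members[[k]] <- c(members[[k]], i)
      maxA[k] <- max(maxA[k], sa[i])
      minB[k] <- min(minB[k], sb[i])
      maxB[k] <- max(maxB[k], sb[i])
    }
  }
  out <- members[lengths(members) > 0L]
  lapply(out, sort)
}

#' Refine a coarse cluster by single-linkage clustering
#'
#' Members are re-clustered by single linkage under the Chebyshev-style
#' distance `d(p, q) = max(|p.startA - q.startA|, |p.startB - q.startB|)`
#' cut at `config$refine_cut`; each connected component of the threshold
#' graph becomes one refined cluster. Refinement never merges across input
#' clusters.
#'
#' @param cluster Data frame of member pairs (rows from
#'   [partition_pairs()]).
#' @param config A [caller_config].
#' @return List of data frames, one per refined cluster.
#' @export
refine_cluster <- function(cluster, config) {
  comp <- linkage_components(cluster$startA, cluster$startB, config$refine_cut)
  lapply(split(seq_len(nrow(cluster)), comp),
         function(i) cluster[i, , drop = FALSE])
}

# Connected components of the graph with edges max(|dA|,|dB|) <= cut.
linkage_components <- function(sa, sb, cut) {
  n <- length(sa)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  o <- order(sa, sb, method = "radix")
  if (n > 1L) {
    for (pos in 2:n) {
      i <- o[pos]
      q <- pos - 1L
      while (q >= 1L && sa[i] - sa[o[q]] <= cut) {
        j <- o[q]
        if (abs(sb[i] - sb[j]) <= cut) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
        q <- q - 1L
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, unique(roots))
}

#' Convert a refined cluster into a breakpoint call
#'
#' Computes the effective support by greedy thinning: scanning members in
#' `(startA, startB, pair_id)` order, a member is redundant iff both its
#' side-A and side-B read starts lie within `min_end_spread` (strictly
#' less) of a previously retained member's corresponding starts -- reads at
#' least `min_end_spread` apart on either side count as independent
#' evidence. A breakpoint is returned iff the support rule of the
#' configured `end_spread_mode` is satisfied; footprints are the exact
#' min-start/max-end over the member read mappings. Clusters whose
#' expected-orientation midpoint span falls inside the consistent insert
#' range cannot be assigned a variant class and are dropped (see
#' [classify_variant()]).
#'
#' @param cluster Data frame of member pairs (one refined cluster).
#' @param config A [caller_config].
#' @param model The [insert_size_model] used for classification.
#' @param sample Sample label recorded on the call.
#' @return A one-row data frame, or `NULL` when the cluster does not reach
#'   the support threshold.
#' @export
cluster_to_breakpoint <- function(cluster, config, model, sample = "sample") {
  n <- nrow(cluster)
  o <- order(cluster$startA, cluster$startB, cluster$pair_id, method = "radix")
  sa <- cluster$startA[o]
  sb <- cluster$startB[o]
  keptA <- keptB <- numeric(0)
  spread <- config$min_end_spread
  for (i in seq_len(n)) {
    redundant <- length(keptA) &&
      any(abs(sa[i] - keptA) < spread & abs(sb[i] - keptB) < spread)
    if (!redundant) {
      keptA <- c(keptA, sa[i])
      keptB <- c(keptB, sb[i])
    }
  }
  eff <- length(keptA)
  called <- if (config$end_spread_mode == "thin") eff >= config$min_support
            else n >= config$min_support && eff >= 2L
  if (!called) return(NULL)
  chromA <- cluster$chromA[1L]
  chromB <- cluster$chromB[1L]
  b1 <- min(cluster$startA); e1 <- max(cluster$endA)
  b2 <- min(cluster$startB); e2 <- max(cluster$endB)
  span <- abs(floor((b2 + e2) / 2) - floor((b1 + e1) / 2))
  vc <- tryCatch(
    classify_variant(cluster$sig[1L], chromA, chromB, span, model),
    error = function(e) NA_character_)
  if (is.na(vc)) return(structure(list(), class = "svb_ambiguous_cluster"))
  maj <- function(x) names(sort(table(x), decreasing = TRUE))[1L]
  data.frame(chromA = chromA, b1 = b1, e1 = e1,
             chromB = chromB, b2 = b2, e2 = e2,
             name = NA_character_,
             support = n, effective_support = eff,
             variant_class = vc,
             strand1 = maj(cluster$strandA), strand2 = maj(cluster$strandB),
             sample = sample,
             stringsAsFactors = FALSE)
}

#' Assign a variant class to a breakpoint cluster
#'
#' Rule table: different chromosomes give a translocation; a
#' same-chromosome orientation signature differing from the expected one
#' (an end flipped, or the upstream role reversed) gives an inversion-type
#' orientation anomaly; the expected signature gives a deletion when the
#' footprint-midpoint span exceeds `i_max` and an insertion when it falls
#' below `i_min`. An expected-orientation span inside the consistent range
#' is an internal error -- such pairs are consistent and never reach the
#' caller.
#'
#' @param signature Orientation signature of the cluster (see
#'   [pair_signature()]).
#' @param chromA,chromB Canonically ordered chromosome names.
#' @param span Distance between the side-A and side-B footprint midpoints
#'   (bp), for intra-chromosomal clusters.
#' @param model The [insert_size_model].
#' @return One of `"deletion"`, `"insertion"`, `"inversion"`,
#'   `"translocation"`.
#' @export
classify_variant <- function(signature, chromA, chromB, span, model) {
  if (chromA != chromB) return("translocation")
  if (signature != model$expected_orientation) return("inversion")
  if (span > model$i_max) return("deletion")
  if (span < model$i_min) return("insertion")
  stop("internal error: expected-orientation span within the consistent ",
       "insert range; such pairs are consistent and cannot form a cluster")
}

#' Call breakpoints from mate pairs
#'
#' Full pipeline: clonal deduplication, consistency classification against
#' the insert-size model, partition of inconsistent pairs by chromosome
#' pair, coarse greedy clustering, single-linkage refinement, and
#' support/diversity filtering. Output is sorted by
#' `(chromA, b1, chromB, b2)` and is invariant to the input record order
#' and to any batch decomposition of the input.
#'
#' @param pairs A [mate_pairs] object.
#' @param model An [insert_size_model].
#' @param config A [caller_config]; defaults to `caller_config(model)`.
#' @param sample Sample label for the output set.
#' @return An [sv_set] of breakpoint calls, with a per-stage count log in
#'   `attr(x, "stage_log")`.
#' @export
call_breakpoints <- function(pairs, model, config = NULL, sample = "sample") {
  stopifnot(inherits(model, "insert_size_model"))
  if (is.null(config)) config <- caller_config(model)
  sl <- mp_seqlevels(pairs)
  dd <- dedup_clonal(pairs)
  cls <- classify_pairs(dd, model)
  incons <- dd[cls$label == "inconsistent", , drop = FALSE]
  log <- c(input_pairs = nrow(pairs), after_dedup = nrow(dd),
           consistent = sum(cls$label == "consistent"),
           inconsistent = nrow(incons))
  calls <- list()
  n_ambiguous <- 0L
  if (nrow(incons)) {
    part <- partition_pairs(incons, sl)
    for (bucket in split(part, part$key)) {
      for (cl in coarse_cluster(bucket, config)) {
        for (rf in refine_cluster(cl, config)) {
          bp <- cluster_to_breakpoint(rf, config, model, sample)
          if (inherits(bp, "svb_ambiguous_cluster")) n_ambiguous <- n_ambiguous + 1L
          else if (!is.null(bp)) calls[[length(calls) + 1L]] <- bp
        }
      }
    }
  }
  df <- if (length(calls)) do.call(rbind, calls)
  else data.frame(chromA = character(), b1 = numeric(), e1 = numeric(),
                  chromB = character(), b2 = numeric(), e2 = numeric(),
                  name = character(), support = integer(),
                  effective_support = integer(), variant_class = character(),
                  strand1 = character(), strand2 = character(),
                  sample = character(), stringsAsFactors = FALSE)
  o <- order(chrom_rank(df$chromA, sl), df$b1,
             chrom_rank(df$chromB, sl), df$b2, df$e1, df$e2,
             method = "radix")
  df <- df[o, , drop = FALSE]
  if (nrow(df)) df$name <- sprintf("bp%05d", seq_len(nrow(df)))
  log <- c(log, dropped_ambiguous_clusters = n_ambiguous, calls = nrow(df))
  out <- sv_set(df, name = sample, i_max = model$i_max, seqlevels = sl)
  attr(out, "stage_log") <- log
  out
}
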
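# Insert-size model: histogram of outer distances of concordant-orientation
# intra-chromosomal pairs, with nearest-rank percentile bounds.

#' Nearest-rank percentile
#'
#' The p-th nearest-rank percentile of a multiset is its
#' `ceiling(p * n)`-th order statistic (at least the 1st). Deterministic and
#' integer-valued on integer data; no interpolation.
#'
#' @param x Numeric vector.
#' @param p Fraction(s) in (0, 1].
#' @return The order statistic(s).
#' @export
nearest_rank <- function(x, p) {
  if (!length(x)) stop_param("nearest_rank on empty vector")
  sort(x)[pmax(1L, ceiling(p * length(x)))]
}

#' Fit the insert-size model
#'
#' Builds the insert-size distribution from intra-chromosomal mate pairs.
#' The expected orientation signature is inferred as the majority signature
#' among intra-chromosomal pairs whose outer distance does not exceed
#' `gross_cap` times the median (so discordant deletion-spanning pairs do
#' not contaminate the inference). The insert histogram is then restricted
#' to expected-orientation intra-chromosomal pairs and the consistent range
#' `[i_min, i_max]` is set to its 0.5 and 99.5 nearest-rank percentiles by
#' default. Explicit `override` bounds replace the percentile bounds; the
#' histogram is still computed.
#'
#' @param pairs A [mate_pairs] object.
#' @param lo,hi Percentile fractions for the lower/upper bound
#'   (defaults 0.005 and 0.995).
#' @param override Optional numeric `c(i_min, i_max)` taken verbatim.
#' @param gross_cap Outer-distance cap, as a multiple of the median, for
#'   pairs used in orientation inference (default 10).
#' @return An object of class `insert_size_model` with elements `i_min`,
#'   `i_max`, `expected_orientation`, `n_pairs_used`, `histogram` (named
#'   count vector keyed by insert size), `lo`, `hi`, `overridden`.
#' @seealso [classify_pairs()], [nearest_rank()]
#' @export
insert_size_model <- function(pairs, lo = 0.005, hi = 0.995, override = NULL,
                              gross_cap = 10) {
  if (!is.null(override)) {
    if (length(override) != 2L || !is.numeric(override))
      stop_param("override must be numeric c(i_min, i_max)")
    if (override[1] >= override[2])
      stop_param("override i_min must be < i_max")
    if (override[1] <= 0)
      stop_param("override bounds must be positive")
  }
  if (!(lo > 0 && hi <= 1 && lo < hi))
    stop_param("percentile fractions must satisfy 0 < lo < hi <= 1")
  same <- pairs$chrom_f == pairs$chrom_r
  nondeg <- !(same & pairs$start_f == pairs$start_r & pairs$end_f == pairs$end_r)
  intra <- which(same & nondeg)
  if (!length(intra))
    stop_empty_input("no intra-chromosomal mate pairs; cannot model insert sizes")
  ins <- insert_sizes(pairs)[intra]
  sig <- pair_signature(pairs)[intra]
  cap <- gross_cap * stats::median(ins)
  capped <- ins <= cap
  if (!any(capped)) capped <- rep(TRUE, length(ins))
  tab <- table(sig[capped])
  expected <- names(tab)[which.max(tab)]
  inserts <- ins[sig == expected]
  if (is.null(override)) {
    i_min <- as.numeric(nearest_rank(inserts, lo))
    i_max <- as.numeric(nearest_rank(inserts, hi))
  } else {
    i_min <- override[1]
    i_max <- override[2]
  }
  h <- table(inserts)
  histogram <- as.integer(h)
  names(histogram) <- names(h)
  structure(
    list(i_min = i_min, i_max = i_max,
         expected_orientation = expected,
         n_pairs_used = length(inserts),
         histogram = histogram,
         lo = lo, hi = hi,
         overridden = !is.null(override)),
    class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat("Insert-size model\n")
  cat(sprintf("  consistent range : [%g, %g] bp%s\n", x$i_min, x$i_max,
              if (x$overridden) " (user override)"
              else sprintf(" (%.1f-%.1f percentile)", 100 * x$lo, 100 * x$hi)))
  cat(sprintf("  orientation      : %s\n", x$expected_orientation))
  cat(sprintf("  pairs used       : %d\n", x$n_pairs_used))
  invisible(x)
}

#' @export
summary.insert_size_model <- function(object, ...) {
  sizes <- as.numeric(names(object$histogram))
  counts <- object$histogram
  expanded_q <- function(p) {
    # quantile of the histogram without expansion
    cum <- cumsum(counts)
    sizes[which(cum >= pmax(1, ceiling(p * sum(counts))))[1]]
  }
  out <- list(model = object,
              median = expanded_q(0.5),
              q25 = expanded_q(0.25), q75 = expanded_q(0.75),
              range = range(sizes),
              within = sum(counts[sizes >= object$i_min & sizes <= object$i_max]) /
                sum(counts))
  class(out) <- "summary.insert_size_model"
  out
}

#' @export
print.summary.insert_size_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  insert median    : %g bp (IQR %g-%g, range %g-%g)\n",
              x$median, x$q25, x$q75, x$range[1], x$range[2]))
  cat(sprintf("  within bounds    : %.2f%%\n", 100 * x$within))
  invisible(x)
}

#' @export
plot.insert_size_model <- function(x, ...) {
  sizes <- as.numeric(names(x$histogram))
  plot(sizes, as.numeric(x$histogram), type = "h",
                 xlab = "insert size (bp)", ylab = "pairs",
                 main = "Insert-size distribution", ...)
  graphics::abline(v = c(x$i_min, x$i_max), col = "red", lty = 2)
  invisible(x)
}

#' Classify mate pairs as consistent or inconsistent
#'
#' A pair is consistent iff both reads map to the same chromosome, in the
#' model's expected orientation signature, with an outer-distance insert
#' within `[i_min, i_max]`. Inconsistent pairs carry the first failing
#' reason, checked in the order inter_chromosomal, orientation,
#' too_close/too_far.
#'
#' @param pairs A [mate_pairs] object.
#' @param model An [insert_size_model].
#' @return Data frame with factor columns `label`
#'   (consistent/inconsistent) and `reason`
#'   (ok/inter_chromosomal/orientation/too_close/too_far).
#' @export
classify_pairs <- function(pairs, model) {
  stopifnot(inherits(model, "insert_size_model"))
  n <- nrow(pairs)
  reason <- rep("ok", n)
  same <- pairs$chrom_f == pairs$chrom_r
  reason[!same] <- "inter_chromosomal"
  sig <- pair_signature(pairs)
  bad_ori <- same & sig != model$expected_orientation
  reason[bad_ori] <- "orientation"
  ins <- insert_sizes(pairs)
  ok_ori <- same & !bad_ori
  reason[ok_ori & ins < model$i_min] <- "too_close"
  reason[ok_ori & ins > model$i_max] <- "too_far"
  data.frame(
    label = factor(ifelse(reason == "ok", "consistent", "inconsistent"),
                   levels = c("consistent", "inconsistent")),
    reason = factor(reason, levels = c("ok", "inter_chromosomal", "orientation",
                                       "too_close", "too_far")))
}

#' Write an insert-size model to a flat text file
#'
#' Key-value lines (`i_min`, `i_max`, `n_pairs_used`, `orientation`,
#' `overridden`) followed by a `histogram:` section of
#' `size<TAB>count` lines.
#'
#' @param model An [insert_size_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_insert_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("i_min\t", model$i_min),
    paste0("i_max\t", model$i_max),
    paste0("n_pairs_used\t", model$n_pairs_used),
    paste0("orientation\t", model$expected_orientation),
    paste0("lo\t", model$lo),
    paste0("hi\t", model$hi),
    paste0("overridden\t", as.integer(model$overridden)),
    "histogram:"), con)
  writeLines(paste0(names(model$histogram), "\t", model$histogram), con)
  invisible(path)
}

#' Read an insert-size model written by [write_insert_model()]
#'
#' @param path Path to the model file.
#' @return An [insert_size_model] object.
#' @export
read_insert_model <- function(path) {
  if (!file.exists(path)) stop_missing_file(path)
  lines <- readLines(path)
  hsep <- match("histogram:", lines)
  if (is.na(hsep)) stop_format("not an insert-size model file (no histogram section): ", path)
  kv <- strsplit(lines[seq_len(hsep - 1L)], "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  get <- function(k) vals[match(k, keys)]
  hl <- lines[seq.int(hsep + 1L, length.out = length(lines) - hsep)]
  hl <- hl[nzchar(hl)]
  hh <- strsplit(hl, "\t", fixed = TRUE)
  histogram <- as.integer(vapply(hh, `[`, "", 2L))
  names(histogram) <- vapply(hh, `[`, "", 1L)
  structure(
    list(i_min = as.numeric(get("i_min")), i_max = as.numeric(get("i_max")),
         expected_orientation = get("orientation"),
         n_pairs_used = as.integer(get("n_pairs_used")),
         histogram = histogram,
         lo = as.numeric(get("lo")), hi = as.numeric(get("hi")),
         overridden = get("overridden") == "1"),
    class = "insert_size_model")
}
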
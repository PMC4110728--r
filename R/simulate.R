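# Coordinate-level mate-pair simulator: plants structural variants in a
# virtual donor genome built from reference-coordinate blocks, samples
# fragments from the donor, maps the two read ends back to reference
# coordinates, and records per-junction truth. No sequence is generated;
# the caller consumes mappings, so the simulation works at mapping level.

#' Simulation configuration
#'
#' Defaults emulate a long-insert (4-6 kb) mate-pair library: fragment
#' lengths are Normal(`insert_mean`, `insert_sd`) truncated at +/- 4 sd,
#' so with the defaults the 0.5-99.5 percentile range falls inside
#' 4-6 kb.
#'
#' @param genome Named numeric vector of chromosome lengths (bp).
#' @param variants Data frame of planted variants (see
#'   [random_variants()]) or `NULL` for a variant-free genome.
#' @param n_pairs Number of mate pairs to draw (before noise and clonal
#'   duplication).
#' @param insert_mean,insert_sd Fragment length distribution (bp;
#'   defaults 5000 and 300).
#' @param read_len Read length (bp, default 50).
#' @param clonal_rate Fraction of pairs duplicated as clonal (PCR)
#'   copies.
#' @param noise_rate Fraction of additional random chimeric pairs.
#' @param tumor_fraction Fraction of fragments drawn from the
#'   variant-bearing haplotype (in (0, 1]); models tumor purity.
#' @param seed RNG seed for full reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome, variants = NULL, n_pairs,
                       insert_mean = 5000, insert_sd = 300, read_len = 50,
                       clonal_rate = 0, noise_rate = 0, tumor_fraction = 1,
                       seed = NULL) {
  if (is.null(names(genome)) || !is.numeric(genome) || !length(genome))
    stop_param("genome must be a named numeric vector of chromosome lengths")
  if (insert_mean <= 2 * read_len)
    stop_param("insert_mean must exceed twice the read length")
  if (insert_mean + 4 * insert_sd > min(genome))
    stop_param("fragments must fit on the shortest chromosome")
  for (r in c(clonal_rate, noise_rate))
    if (r < 0 || r > 1) stop_param("rates must lie in [0, 1]")
  if (tumor_fraction <= 0 || tumor_fraction > 1)
    stop_param("tumor_fraction must lie in (0, 1]")
  if (n_pairs < 1) stop_param("n_pairs must be >= 1")
  if (!is.null(variants)) validate_variants(variants, genome)
  structure(list(genome = genome, variants = variants, n_pairs = as.integer(n_pairs),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 read_len = as.integer(read_len), clonal_rate = clonal_rate,
                 noise_rate = noise_rate, tumor_fraction = tumor_fraction,
                 seed = seed),
            class = "sim_config")
}

VAR_CLASSES <- c("deletion", "insertion", "inversion", "translocation")

validate_variants <- function(v, genome) {
  need <- c("id", "class", "chrom", "start")
  if (!all(need %in% names(v)))
    stop_param("variants need columns: ", paste(need, collapse = ", "))
  if (!nrow(v)) return(invisible(v))
  if (anyDuplicated(v$id)) stop_param("variant ids must be unique")
  if (!all(v$class %in% VAR_CLASSES))
    stop_param("variant class must be one of ", paste(VAR_CLASSES, collapse = ", "))
  bad_chr <- setdiff(c(v$chrom, v$chrom2[!is.na(v$chrom2)]), names(genome))
  if (length(bad_chr))
    stop_param("variant chromosome(s) outside genome: ", paste(bad_chr, collapse = ", "))
  spans <- variant_footprints(v)
  out <- spans$start < 0 | spans$end > genome[spans$chrom]
  if (any(out)) stop_param("variant(s) outside chromosome bounds: ",
                           paste(unique(spans$id[out]), collapse = ", "))
  # non-overlap on the reference
  o <- order(spans$chrom, spans$start)
  s <- spans[o, ]
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (nrow(s) > 1 && any(same & s$start[-1] < s$end[-nrow(s)]))
    stop_param("planted variants must not overlap on the reference")
  invisible(v)
}

# Reference footprint of each variant (translocations contribute both
# endpoints as points).
variant_footprints <- function(v) {
  rows <- list()
  for (i in seq_len(nrow(v))) {
    cl <- v$class[i]
    if (cl %in% c("deletion", "inversion")) {
      rows[[length(rows) + 1L]] <-
        data.frame(id = v$id[i], chrom = v$chrom[i], start = v$start[i], end = v$end[i])
    } else if (cl == "insertion") {
      rows[[length(rows) + 1L]] <-
        data.frame(id = v$id[i], chrom = v$chrom[i], start = v$start[i],
                   end = v$start[i] + 1)
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(id = v$id[i], chrom = v$chrom[i], start = v$start[i],
                   end = v$start[i] + 1)
      rows[[length(rows) + 1L]] <-
        data.frame(id = v$id[i], chrom = v$chrom2[i], start = v$start2[i],
                   end = v$start2[i] + 1)
    }
  }
  do.call(rbind, rows)
}

#' Draw a random non-overlapping variant set
#'
#' Places the requested number of deletions, insertions, inversions, and
#' reciprocal translocations uniformly on the genome, keeping variants at
#' least `min_gap` apart and `margin` away from chromosome ends, with at
#' most one translocation endpoint per chromosome. Uses the current RNG
#' stream (seed at the call site or through [sim_config()]).
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param n_deletion,n_insertion,n_inversion,n_translocation Counts per
#'   class.
#' @param del_len,ins_len,inv_len Event sizes in bp (defaults 20000,
#'   3000, 20000).
#' @param min_gap Minimum separation between variant footprints (bp).
#' @param margin Minimum distance from chromosome ends (bp).
#' @return A variants data frame for [sim_config()].
#' @export
random_variants <- function(genome, n_deletion = 0, n_insertion = 0,
                            n_inversion = 0, n_translocation = 0,
                            del_len = 20000, ins_len = 3000, inv_len = 20000,
                            min_gap = 100000, margin = 50000) {
  taken <- data.frame(chrom = character(), start = numeric(), end = numeric())
  tra_chroms <- character(0)
  free <- function(chrom, start, end) {
    i <- taken$chrom == chrom
    !any(i & taken$start - min_gap < end & taken$end + min_gap > start)
  }
  claim <- function(chrom, start, end) {
    taken[nrow(taken) + 1L, ] <<- list(chrom, start, end)
  }
  draw_point <- function(len_needed) {
    for (try_ in 1:2000) {
      chrom <- sample(names(genome), 1L, prob = genome)
      lo <- margin
      hi <- genome[[chrom]] - margin - len_needed
      if (hi <= lo) next
      start <- floor(runif(1, lo, hi))
      if (free(chrom, start, start + len_needed))
        return(list(chrom = chrom, start = start))
    }
    stop_param("could not place variants; genome too small for the request")
  }
  rows <- list()
  add <- function(id, class, chrom, start, end = NA, len = NA,
                  chrom2 = NA, start2 = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, class = class, chrom = chrom, start = start, end = end,
      len = len, chrom2 = chrom2, start2 = start2, stringsAsFactors = FALSE)
  }
  k <- 0L
  for (i in seq_len(n_deletion)) {
    p <- draw_point(del_len); k <- k + 1L
    claim(p$chrom, p$start, p$start + del_len)
    add(sprintf("del%03d", i), "deletion", p$chrom, p$start, p$start + del_len)
  }
  for (i in seq_len(n_insertion)) {
    p <- draw_point(1); k <- k + 1L
    claim(p$chrom, p$start, p$start + 1)
    add(sprintf("ins%03d", i), "insertion", p$chrom, p$start, len = ins_len)
  }
  for (i in seq_len(n_inversion)) {
    p <- draw_point(inv_len); k <- k + 1L
    claim(p$chrom, p$start, p$start + inv_len)
    add(sprintf("inv%03d", i), "inversion", p$chrom, p$start, p$start + inv_len)
  }
  for (i in seq_len(n_translocation)) {
    ok <- FALSE
    for (try_ in 1:2000) {
      pa <- draw_point(1)
      pb <- draw_point(1)
      if (pa$chrom != pb$chrom &&
          !(pa$chrom %in% tra_chroms) && !(pb$chrom %in% tra_chroms)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop_param("could not place translocation ", i,
                        " (needs two unused chromosomes)")
    tra_chroms <- c(tra_chroms, pa$chrom, pb$chrom)
    claim(pa$chrom, pa$start, pa$start + 1)
    claim(pb$chrom, pb$start, pb$start + 1)
    add(sprintf("tra%03d", i), "translocation", pa$chrom, pa$start,
        chrom2 = pb$chrom, start2 = pb$start)
  }
  if (!length(rows))
    return(data.frame(id = character(), class = character(), chrom = character(),
                      start = numeric(), end = numeric(), len = numeric(),
                      chrom2 = character(), start2 = numeric()))
  do.call(rbind, rows)
}

# ---- donor genome construction -------------------------------------------

# Donor chromosome: data frame of blocks (ref_chrom NA for novel
# insertion sequence; strand "-" for inverted segments) plus a junction
# table (after_block, variant_id, side).
new_blocks <- function(ref_chrom, ref_start, ref_end, strand = "+", len = NULL) {
  if (is.null(len)) len <- ref_end - ref_start
  data.frame(ref_chrom = ref_chrom, ref_start = ref_start, ref_end = ref_end,
             strand = strand, len = len, stringsAsFactors = FALSE)
}

build_intra_chrom <- function(chrom, len, ev) {
  blocks <- new_blocks(character(0), numeric(0), numeric(0), character(0), numeric(0))
  jn <- data.frame(after_block = integer(0), variant_id = character(0),
                   side = character(0), stringsAsFactors = FALSE)
  cur <- 0
  add_block <- function(b) blocks <<- rbind(blocks, b)
  add_jn <- function(vid, side) {
    jn[nrow(jn) + 1L, ] <<- list(nrow(blocks), vid, side)
  }
  if (nrow(ev)) ev <- ev[order(ev$start), , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$class == "deletion") {
      add_block(new_blocks(chrom, cur, e$start))
      add_jn(e$id, ".")
      cur <- e$end
    } else if (e$class == "insertion") {
      add_block(new_blocks(chrom, cur, e$start))
      add_jn(e$id, ".")
      add_block(new_blocks(NA_character_, NA, NA, "+", e$len))
      add_jn(e$id, ".")
      cur <- e$start
    } else if (e$class == "inversion") {
      add_block(new_blocks(chrom, cur, e$start))
      add_jn(e$id, "L")
      add_block(new_blocks(chrom, e$start, e$end, strand = "-"))
      add_jn(e$id, "R")
      cur <- e$end
    }
  }
  add_block(new_blocks(chrom, cur, len))
  list(blocks = blocks, junctions = jn)
}

# Split a donor chromosome at the donor location mapping to reference
# position `pos` (must fall inside a +strand block of ref_chrom `chrom`).
split_donor_chrom <- function(dc, chrom, pos) {
  b <- dc$blocks
  hit <- which(!is.na(b$ref_chrom) & b$ref_chrom == chrom & b$strand == "+" &
                 b$ref_start <= pos & pos < b$ref_end)
  if (length(hit) != 1L)
    stop_param("translocation breakpoint at ", chrom, ":", pos,
               " does not fall in an unrearranged segment")
  i <- hit
  if (pos == b$ref_start[i]) {
    left <- b[seq_len(i - 1L), , drop = FALSE]
    right <- b[seq.int(i, nrow(b)), , drop = FALSE]
    lj <- dc$junctions[dc$junctions$after_block < i, , drop = FALSE]
    rj <- dc$junctions[dc$junctions$after_block >= i, , drop = FALSE]
    rj$after_block <- rj$after_block - (i - 1L)
  } else {
    lb <- b[i, , drop = FALSE]
    lb$ref_end <- pos; lb$len <- pos - lb$ref_start
    rb <- b[i, , drop = FALSE]
    rb$ref_start <- pos; rb$len <- rb$ref_end - pos
    left <- rbind(b[seq_len(i - 1L), , drop = FALSE], lb)
    right <- rbind(rb, b[seq.int(i + 1L, length.out = nrow(b) - i), , drop = FALSE])
    lj <- dc$junctions[dc$junctions$after_block < i, , drop = FALSE]
    rj <- dc$junctions[dc$junctions$after_block >= i, , drop = FALSE]
    rj$after_block <- rj$after_block - (i - 1L)
  }
  list(left = left, right = right, left_jn = lj, right_jn = rj)
}

join_donor <- function(left, left_jn, right, right_jn, vid, side) {
  jn <- rbind(left_jn,
              data.frame(after_block = nrow(left), variant_id = vid, side = side,
                         stringsAsFactors = FALSE))
  rj <- right_jn
  rj$after_block <- rj$after_block + nrow(left)
  list(blocks = rbind(left, right), junctions = rbind(jn, rj))
}

# Build the donor genome (list of donor chromosomes with block and
# junction tables) from the reference lengths and a variant table.
donor_build <- function(genome, variants) {
  chroms <- list()
  for (c_ in names(genome)) {
    ev <- if (is.null(variants) || !nrow(variants)) NULL else
      variants[variants$chrom == c_ & variants$class != "translocation", ,
               drop = FALSE]
    if (is.null(ev))
      ev <- data.frame(id = character(), class = character(), chrom = character(),
                       start = numeric(), end = numeric(), len = numeric())
    chroms[[c_]] <- build_intra_chrom(c_, genome[[c_]], ev)
  }
  if (!is.null(variants) && nrow(variants)) {
    tra <- variants[variants$class == "translocation", , drop = FALSE]
    for (i in seq_len(nrow(tra))) {
      t_ <- tra[i, ]
      sa <- split_donor_chrom(chroms[[t_$chrom]], t_$chrom, t_$start)
      sb <- split_donor_chrom(chroms[[t_$chrom2]], t_$chrom2, t_$start2)
      der1 <- join_donor(sa$left, sa$left_jn, sb$right, sb$right_jn, t_$id, "A")
      der2 <- join_donor(sb$left, sb$left_jn, sa$right, sa$right_jn, t_$id, "B")
      chroms[[t_$chrom]] <- der1
      chroms[[t_$chrom2]] <- der2
    }
  }
  for (c_ in names(chroms)) {
    b <- chroms[[c_]]$blocks
    b <- b[b$len > 0, , drop = FALSE]
    # reindex junctions after dropping zero-length blocks
    keep_map <- cumsum(chroms[[c_]]$blocks$len > 0)
    jn <- chroms[[c_]]$junctions
    jn$after_block <- keep_map[jn$after_block]
    jn <- jn[jn$after_block >= 1 & jn$after_block < nrow(b), , drop = FALSE]
    b$d_start <- cumsum(c(0, b$len))[seq_len(nrow(b))]
    b$d_end <- b$d_start + b$len
    chroms[[c_]] <- list(blocks = b, junctions = jn)
  }
  lens <- vapply(chroms, function(x) sum(x$blocks$len), 0)
  list(chroms = chroms, lens = lens)
}

# Sample n fragments from a donor; returns a data frame of reference read
# mappings plus a crossing table (pair index, variant_id, side).
sample_donor_pairs <- function(donor, n, cfg) {
  rl <- cfg$read_len
  flo <- max(2 * rl + 2, round(cfg$insert_mean - 4 * cfg$insert_sd))
  fhi <- round(cfg$insert_mean + 4 * cfg$insert_sd)
  cn <- names(donor$lens)
  L <- donor$lens
  out <- data.frame(chrom_f = rep(NA_character_, n), start_f = rep(NA_real_, n),
                    end_f = rep(NA_real_, n), strand_f = rep(NA_character_, n),
                    chrom_r = rep(NA_character_, n), start_r = rep(NA_real_, n),
                    end_r = rep(NA_real_, n), strand_r = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  crossing <- list()
  active <- seq_len(n)
  for (round_ in 1:200) {
    m <- length(active)
    if (!m) break
    ci <- sample.int(length(cn), m, replace = TRUE, prob = L)
    fl <- round(rnorm(m, cfg$insert_mean, cfg$insert_sd))
    st <- floor(runif(m) * pmax(L[ci] - fl + 1, 1))
    ok <- fl >= flo & fl <= fhi & fl <= L[ci]
    done <- logical(m)
    for (cidx in unique(ci)) {
      sel <- which(ci == cidx & ok)
      if (!length(sel)) next
      dc <- donor$chroms[[cn[cidx]]]
      bl <- dc$blocks
      bs <- bl$d_start
      r1s <- st[sel]; r1e <- r1s + rl
      r2s <- st[sel] + fl[sel] - rl; r2e <- r2s + rl
      b1 <- findInterval(r1s, bs)
      b1b <- findInterval(r1e - 1, bs)
      b2 <- findInterval(r2s, bs)
      b2b <- findInterval(r2e - 1, bs)
      good <- b1 == b1b & b2 == b2b &
        !is.na(bl$ref_chrom[b1]) & !is.na(bl$ref_chrom[b2])
      gq <- which(good)
      if (length(gq)) {
        gi <- active[sel[gq]]
        g1 <- b1[gq]; g2 <- b2[gq]
        plus1 <- bl$strand[g1] == "+"
        plus2 <- bl$strand[g2] == "+"
        s1 <- ifelse(plus1, bl$ref_start[g1] + (r1s[gq] - bl$d_start[g1]),
                     bl$ref_end[g1] - (r1s[gq] - bl$d_start[g1]) - rl)
        s2 <- ifelse(plus2, bl$ref_start[g2] + (r2s[gq] - bl$d_start[g2]),
                     bl$ref_end[g2] - (r2s[gq] - bl$d_start[g2]) - rl)
        out$chrom_f[gi] <- bl$ref_chrom[g1]
        out$start_f[gi] <- s1; out$end_f[gi] <- s1 + rl
        out$strand_f[gi] <- ifelse(plus1, "+", "-")
        out$chrom_r[gi] <- bl$ref_chrom[g2]
        out$start_r[gi] <- s2; out$end_r[gi] <- s2 + rl
        out$strand_r[gi] <- ifelse(plus2, "-", "+")
        for (q in which(g2 > g1)) {
          jr <- dc$junctions[dc$junctions$after_block >= g1[q] &
                               dc$junctions$after_block < g2[q], , drop = FALSE]
          if (nrow(jr)) {
            keys <- unique(paste(jr$variant_id, jr$side, sep = ":"))
            # a fragment spanning both edges of an inversion is balanced
            # (consistent) and is evidence for neither junction
            vids <- sub(":[^:]*$", "", keys)
            both_edges <- vids[duplicated(vids)]
            keys <- keys[!(vids %in% both_edges & grepl(":(L|R)$", keys))]
            for (ky in keys)
              crossing[[length(crossing) + 1L]] <- data.frame(
                pair = gi[q], key = ky, stringsAsFactors = FALSE)
          }
        }
        done[sel[gq]] <- TRUE
      }
    }
    active <- active[!done]
  }
  if (length(active))
    stop_param("fragment sampling failed to converge; variants too dense")
  list(pairs = out,
       crossing = if (length(crossing)) do.call(rbind, crossing)
       else data.frame(pair = integer(0), key = character(0)))
}

# Side-ordered read strands at a planted junction: distinguishes the two
# coordinate-coincident junctions of an inversion (L/R) and of a
# reciprocal translocation (A/B after canonical side ordering).
junction_strands <- function(class, side, swapped) {
  switch(class,
         deletion = ,
         insertion = c("+", "-"),
         inversion = if (side == "L") c("+", "+") else c("-", "-"),
         translocation = {
           s <- if (side == "A") c("+", "-") else c("-", "+")
           if (swapped) rev(s) else s
         })
}

# Enumerate truth junction keys and nominal reference coordinates.
truth_junctions <- function(variants) {
  if (is.null(variants) || !nrow(variants))
    return(data.frame(key = character(), id = character(), class = character(),
                      chromA = character(), posA = numeric(),
                      chromB = character(), posB = numeric()))
  rows <- list()
  add <- function(id, side, class, chromA, posA, chromB, posB)
    rows[[length(rows) + 1L]] <<- data.frame(
      key = paste(id, side, sep = ":"), id = id, class = class,
      chromA = chromA, posA = posA, chromB = chromB, posB = posB,
      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    switch(v$class,
           deletion = add(v$id, ".", v$class, v$chrom, v$start, v$chrom, v$end),
           insertion = add(v$id, ".", v$class, v$chrom, v$start, v$chrom, v$start),
           inversion = {
             add(v$id, "L", v$class, v$chrom, v$start, v$chrom, v$end)
             add(v$id, "R", v$class, v$chrom, v$start, v$chrom, v$end)
           },
           translocation = {
             add(v$id, "A", v$class, v$chrom, v$start, v$chrom2, v$start2)
             add(v$id, "B", v$class, v$chrom, v$start, v$chrom2, v$start2)
           })
  }
  do.call(rbind, rows)
}

#' Simulate a mate-pair dataset
#'
#' Samples `n_pairs` fragments from the donor genome (reference or
#' variant-bearing haplotype per `tumor_fraction`), maps both read ends
#' back to reference coordinates and strands -- yielding consistent pairs
#' away from planted variants and the canonical discordant signatures
#' across each planted junction -- then appends clonal duplicates and
#' random chimeric noise pairs. Fragments whose reads would straddle a
#' junction (or land in novel inserted sequence) are resampled, mimicking
#' a uniquely-mapped-read filter. Fully reproducible by seed.
#'
#' @param config A [sim_config].
#' @return A `sim_dataset` list with elements `pairs` (a [mate_pairs]),
#'   `truth` (an [sv_set] of expected breakpoints, one per junction, with
#'   realized spanning-pair counts, spanning pair ids in
#'   `attr(truth, "spanning")`, and the fragment-length truncation bounds
#'   in `attr(truth, "true_bounds")`), and `config`.
#' @export
simulate_mate_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    donor_t <- donor_build(config$genome, config$variants)
    donor_r <- donor_build(config$genome, NULL)
    n <- config$n_pairs
    tumor <- runif(n) < config$tumor_fraction
    idx_t <- which(tumor)
    idx_r <- which(!tumor)
    res_t <- sample_donor_pairs(donor_t, length(idx_t), config)
    res_r <- sample_donor_pairs(donor_r, length(idx_r), config)
    df <- rbind(res_t$pairs, res_r$pairs)
    ord <- c(idx_t, idx_r)
    df <- df[order(ord), , drop = FALSE]
    # either strand of a fragment may be sequenced: swapping the role
    # assignment of the two reads models that and must not change calls
    flip <- runif(n) < 0.5
    fcols <- c("chrom_f", "start_f", "end_f", "strand_f")
    rcols <- c("chrom_r", "start_r", "end_r", "strand_r")
    tmp <- df[flip, fcols]
    df[flip, fcols] <- df[flip, rcols]
    df[flip, rcols] <- tmp
    df$pair_id <- sprintf("s%06d", seq_len(n))
    cross <- res_t$crossing
    cross$pair <- idx_t[cross$pair]

    # noise: random chimeric pairs joining two uniform loci
    n_noise <- round(config$noise_rate * n)
    if (n_noise > 0) {
      pick <- function(m) {
        ci <- sample.int(length(config$genome), m, replace = TRUE,
                         prob = config$genome)
        pos <- floor(runif(m) * (config$genome[ci] - config$read_len))
        list(chrom = names(config$genome)[ci], start = pos)
      }
      a <- pick(n_noise); b <- pick(n_noise)
      noise <- data.frame(
        chrom_f = a$chrom, start_f = a$start, end_f = a$start + config$read_len,
        strand_f = sample(c("+", "-"), n_noise, replace = TRUE),
        chrom_r = b$chrom, start_r = b$start, end_r = b$start + config$read_len,
        strand_r = sample(c("+", "-"), n_noise, replace = TRUE),
        pair_id = sprintf("z%05d", seq_len(n_noise)),
        stringsAsFactors = FALSE)
      df <- rbind(df, noise[, names(df)])
    }

    # clonal duplicates: each pair copied once with probability clonal_rate
    dup <- which(runif(nrow(df)) < config$clonal_rate)
    if (length(dup)) {
      copies <- df[dup, , drop = FALSE]
      copies$pair_id <- paste0(copies$pair_id, "_c1")
      df <- rbind(df, copies)
    }
    pairs <- mate_pairs(df, seqlevels = names(config$genome))

    # truth: one breakpoint per planted junction with realized spanning
    # support and footprints from the spanning reads
    jt <- truth_junctions(config$variants)
    spanning <- stats::setNames(vector("list", nrow(jt)), jt$key)
    tb <- list()
    for (i in seq_len(nrow(jt))) {
      pid <- df$pair_id[cross$pair[cross$key == jt$key[i]]]
      pid <- pid[!duplicated(pid)]
      spanning[[jt$key[i]]] <- pid
      ca <- jt$chromA[i]; pa <- jt$posA[i]
      cb <- jt$chromB[i]; pb <- jt$posB[i]
      # canonical side order
      ra <- chrom_rank(ca, names(config$genome))
      rb <- chrom_rank(cb, names(config$genome))
      swapped <- ra > rb || (ra == rb && pa > pb)
      if (swapped) {
        tmp <- ca; ca <- cb; cb <- tmp
        tmp <- pa; pa <- pb; pb <- tmp
      }
      side <- sub("^[^:]*:", "", jt$key[i])
      str_ <- junction_strands(jt$class[i], side, swapped)
      row <- data.frame(chromA = ca, b1 = pa, e1 = pa, chromB = cb,
                        b2 = pb, e2 = pb, name = jt$key[i],
                        support = length(pid),
                        variant_class = jt$class[i],
                        strand1 = str_[1], strand2 = str_[2],
                        sample = "truth",
                        stringsAsFactors = FALSE)
      if (length(pid)) {
        sp <- pairs[match(pid, pairs$pair_id), , drop = FALSE]
        part <- partition_pairs(sp, names(config$genome))
        row$chromA <- part$chromA[1L]
        row$b1 <- min(part$startA); row$e1 <- max(part$endA)
        row$chromB <- part$chromB[1L]
        row$b2 <- min(part$startB); row$e2 <- max(part$endB)
      }
      tb[[length(tb) + 1L]] <- row
    }
    true_bounds <- c(
      i_min = max(2 * config$read_len + 2,
                  round(config$insert_mean - 4 * config$insert_sd)),
      i_max = round(config$insert_mean + 4 * config$insert_sd))
    tdf <- if (length(tb)) do.call(rbind, tb)
    else data.frame(chromA = character(), b1 = numeric(), e1 = numeric(),
                    chromB = character(), b2 = numeric(), e2 = numeric())
    truth <- sv_set(tdf, name = "truth", i_max = true_bounds[["i_max"]],
                    seqlevels = names(config$genome))
    attr(truth, "spanning") <- spanning
    attr(truth, "true_bounds") <- true_bounds
    attr(truth, "donor_length") <- sum(donor_t$lens)
    structure(list(pairs = pairs, truth = truth, config = config),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d pairs, %d truth junction(s), genome %.3g Mb\n",
              nrow(x$pairs), nrow(x$truth), sum(x$config$genome) / 1e6))
  invisible(x)
}

#' Expected breakpoint-spanning pair counts under the simulation
#'
#' The fragment process is Poisson along the donor; drawing a fragment
#' from the variant haplotype with probability `tumor_fraction` thins it.
#' For each truth junction the expected number of spanning pairs is
#' `n_pairs * tumor_fraction * window / donor_length`, where the window
#' is the mean span the junction allows (`insert_mean - 2 * read_len`,
#' minus the inserted length for insertion junctions, whose novel
#' sequence swallows part of the fragment).
#'
#' @param dataset A `sim_dataset`.
#' @return Named numeric vector of Poisson rates, one per truth junction.
#' @export
expected_spanning_rate <- function(dataset) {
  cfg <- dataset$config
  jt <- truth_junctions(cfg$variants)
  dl <- attr(dataset$truth, "donor_length")
  win <- cfg$insert_mean - 2 * cfg$read_len
  w <- rep(win, nrow(jt))
  if (nrow(jt)) {
    ins <- jt$class == "insertion"
    if (any(ins)) {
      lens <- cfg$variants$len[match(jt$id[ins], cfg$variants$id)]
      w[ins] <- pmax(0, win - lens)
    }
  }
  stats::setNames(cfg$n_pairs * cfg$tumor_fraction * w / dl, jt$key)
}

#' Write mate pairs as SAM
#'
#' Emits a header with the sequence dictionary and one record pair per
#' mate pair with the pairing/strand flags, 1-based positions, MAPQ 60,
#' an all-N placeholder sequence, and the signed outer distance as TLEN.
#' Reading the file back with [read_mate_pairs()] reproduces the
#' coordinates exactly.
#'
#' @param x A [mate_pairs] or `sim_dataset`.
#' @param path Output path.
#' @param genome Named chromosome lengths for the `@SQ` lines; derived
#'   from the data when omitted (simulated datasets carry their genome).
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path, genome = NULL) {
  if (inherits(x, "sim_dataset")) {
    genome <- x$config$genome
    x <- x$pairs
  }
  if (is.null(genome)) {
    chroms <- mp_seqlevels(x)
    genome <- stats::setNames(
      vapply(chroms, function(c_) {
        mx <- max(c(x$end_f[x$chrom_f == c_], x$end_r[x$chrom_r == c_], 1))
        as.numeric(mx)
      }, 0), chroms)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), as.integer(genome)))
  n <- nrow(x)
  lines <- character(0)
  if (n) {
    wf <- x$end_f - x$start_f
    wr <- x$end_r - x$start_r
    same <- x$chrom_f == x$chrom_r
    outer <- ifelse(same, pmax(x$end_f, x$end_r) - pmin(x$start_f, x$start_r), 0)
    tlen_f <- ifelse(!same, 0L, ifelse(x$start_f <= x$start_r, outer, -outer))
    flag_f <- 1L + 64L + ifelse(x$strand_f == "-", 16L, 0L) +
      ifelse(x$strand_r == "-", 32L, 0L)
    flag_r <- 1L + 128L + ifelse(x$strand_r == "-", 16L, 0L) +
      ifelse(x$strand_f == "-", 32L, 0L)
    rec <- function(flag, chrom, start0, w, mate_chrom, mate_start0, tlen) {
      rnext <- ifelse(chrom == mate_chrom, "=", mate_chrom)
      paste(x$pair_id, flag, chrom, as.integer(start0 + 1), 60L,
            paste0(as.integer(w), "M"), rnext, as.integer(mate_start0 + 1),
            as.integer(tlen), strrep("N", as.integer(w)), "*", sep = "\t")
    }
    lf <- rec(flag_f, x$chrom_f, x$start_f, wf, x$chrom_r, x$start_r, tlen_f)
    lr <- rec(flag_r, x$chrom_r, x$start_r, wr, x$chrom_f, x$start_f, -tlen_f)
    lines <- as.vector(rbind(lf, lr))
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
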
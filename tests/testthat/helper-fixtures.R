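# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no stored data files.

# One mate pair from compact arguments (0-based starts, fixed read length).
mk_pair <- function(id, chrom1, s1, strand1, chrom2, s2, strand2, rl = 50) {
  data.frame(pair_id = id,
             chrom_f = chrom1, start_f = s1, end_f = s1 + rl, strand_f = strand1,
             chrom_r = chrom2, start_r = s2, end_r = s2 + rl, strand_r = strand2,
             stringsAsFactors = FALSE)
}

mk_pairs <- function(...) mate_pairs(do.call(rbind, list(...)))

# Concordant intra-chromosomal pairs with the given outer-distance inserts.
concordant_pairs <- function(inserts, chrom = "chr1", anchor = 0, rl = 50,
                             prefix = "p") {
  n <- length(inserts)
  df <- data.frame(pair_id = sprintf("%s%05d", prefix, seq_len(n)),
                   chrom_f = chrom, start_f = anchor + seq_len(n) * 7,
                   strand_f = "+", chrom_r = chrom, strand_r = "-",
                   stringsAsFactors = FALSE)
  df$end_f <- df$start_f + rl
  df$start_r <- df$start_f + inserts - rl
  df$end_r <- df$start_f + inserts
  mate_pairs(df[, c("pair_id", "chrom_f", "start_f", "end_f", "strand_f",
                    "chrom_r", "start_r", "end_r", "strand_r")])
}

# A small valid insert-size model with chosen bounds ("+-" orientation).
mk_model <- function(i_min = 4000, i_max = 6000) {
  insert_size_model(concordant_pairs(c(4800, 5000, 5200)),
                    override = c(i_min, i_max))
}

# A caller bucket (partitioned pair table) from side-A / side-B starts.
mk_bucket <- function(sa, sb, sig = "+-", chromA = "chr1", chromB = "chr2",
                      rl = 50, ids = NULL) {
  n <- length(sa)
  if (is.null(ids)) ids <- sprintf("b%04d", seq_len(n))
  data.frame(pair_id = ids,
             chromA = chromA, startA = sa, endA = sa + rl,
             strandA = substr(sig, 1, 1),
             chromB = chromB, startB = sb, endB = sb + rl,
             strandB = substr(sig, 2, 2),
             sig = sig, key = paste(chromA, chromB, sep = "|"),
             stringsAsFactors = FALSE)
}

# Random breakpoint set on a fixed chromosome pair universe.
rand_svset <- function(n, i_max = 2000, name = "rand",
                       chroms = c("chr1", "chr2", "chr3"), span = 1e6) {
  cA <- sample(chroms, n, replace = TRUE)
  cB <- sample(chroms, n, replace = TRUE)
  swap <- cB < cA
  tmp <- cA[swap]; cA[swap] <- cB[swap]; cB[swap] <- tmp
  b1 <- floor(runif(n) * span)
  b2 <- floor(runif(n) * span)
  same <- cA == cB & b2 < b1
  tmp <- b1[same]; b1[same] <- b2[same]; b2[same] <- tmp
  w1 <- floor(runif(n) * 3000)
  w2 <- floor(runif(n) * 3000)
  sv_set(data.frame(chromA = cA, b1 = b1, e1 = b1 + w1,
                    chromB = cB, b2 = b2, e2 = b2 + w2,
                    support = sample(1:10, n, replace = TRUE)),
         name = name, i_max = i_max, seqlevels = chroms)
}

# Brute-force evaluation of the printed min-of-four-distances overlap
# formula for two breakpoint rows (independent of the package predicate's
# vectorized/indexed path).
brute_overlap1 <- function(a, b, i_max) {
  if (a$chromA != b$chromA || a$chromB != b$chromB) return(FALSE)
  dA <- min(abs(a$b1 - b$b1), abs(a$e1 - b$e1), abs(a$b1 - b$e1), abs(a$e1 - b$b1))
  dB <- min(abs(a$b2 - b$b2), abs(a$e2 - b$e2), abs(a$b2 - b$e2), abs(a$e2 - b$b2))
  dA <= i_max && dB <= i_max
}

# All-pairs brute-force overlap matrix.
brute_overlap_matrix <- function(A, B, i_max) {
  A <- as.data.frame(A); B <- as.data.frame(B)
  m <- matrix(FALSE, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      m[i, j] <- brute_overlap1(A[i, ], B[j, ], i_max)
  m
}

# Vectorized all-pairs oracle for larger instances: direct evaluation of
# the formula with outer products, no interval index.
brute_overlap_outer <- function(A, B, i_max) {
  A <- as.data.frame(A); B <- as.data.frame(B)
  same <- outer(as.character(A$chromA), as.character(B$chromA), "==") &
    outer(as.character(A$chromB), as.character(B$chromB), "==")
  mind <- function(a1, a2, b1, b2) {
    pmin(abs(outer(a1, b1, "-")), abs(outer(a2, b2, "-")),
         abs(outer(a1, b2, "-")), abs(outer(a2, b1, "-")))
  }
  same & mind(A$b1, A$e1, B$b1, B$e1) <= i_max &
    mind(A$b2, A$e2, B$b2, B$e2) <= i_max
}

# Brute-force single-linkage components: BFS over the threshold graph
# with d(p,q) = max(|dA|, |dB|) <= cut.
brute_components <- function(sa, sb, cut) {
  n <- length(sa)
  adj <- outer(sa, sa, function(x, y) abs(x - y)) <= cut &
    outer(sb, sb, function(x, y) abs(x - y)) <= cut
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Partition of indices as a canonical set-of-sets (for comparing
# clusterings regardless of labels).
partition_sets <- function(groups) {
  s <- lapply(unname(groups), function(g) as.integer(sort(g)))
  s[order(vapply(s, function(g) paste(g, collapse = ","), ""))]
}

# Greedy 50-bp thinning oracle mirroring the published diversity rule:
# scan in (sideA, sideB, id) order, keep a member unless both sides fall
# strictly within `spread` of an already-kept member.
thin_count <- function(sa, sb, ids, spread = 50) {
  o <- order(sa, sb, ids, method = "radix")
  ka <- kb <- numeric(0)
  for (i in o) {
    if (!length(ka) || !any(abs(sa[i] - ka) < spread & abs(sb[i] - kb) < spread)) {
      ka <- c(ka, sa[i]); kb <- c(kb, sb[i])
    }
  }
  length(ka)
}

# Small default simulation shared by several tests.
small_sim <- function(seed = 5, n_pairs = 6000, clonal_rate = 0,
                      noise_rate = 0, tumor_fraction = 1, variants = NULL,
                      genome = c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6)) {
  if (is.null(variants))
    variants <- with_seed(seed + 1000,
      random_variants(genome, n_deletion = 2, n_insertion = 1,
                      n_inversion = 1, n_translocation = 1))
  simulate_mate_pairs(sim_config(genome, variants, n_pairs = n_pairs,
                                 clonal_rate = clonal_rate,
                                 noise_rate = noise_rate,
                                 tumor_fraction = tumor_fraction,
                                 seed = seed))
}

# Strand-aware matching of calls to truth junctions: the endpoint-distance
# overlap plus equality of side strands, so the coordinate-coincident
# junction pairs of inversions and reciprocal translocations resolve to
# their own calls.
match_calls_truth <- function(calls, truth, i_max) {
  hits <- svbreaks:::overlap_hits(as.data.frame(calls), as.data.frame(truth), i_max)
  keep <- calls$strand1[hits[, "i"]] == truth$strand1[hits[, "j"]] &
    calls$strand2[hits[, "i"]] == truth$strand2[hits[, "j"]]
  hits[keep, , drop = FALSE]
}

# Truth junctions eligible for calling: spanning pairs after coordinate
# dedup and greedy thinning >= min_support (computed from the simulator's
# truth bookkeeping, independently of the caller).
eligible_junctions <- function(ds, min_support = 3, spread = 50) {
  truth <- ds$truth
  spanning <- attr(truth, "spanning")
  sl <- names(ds$config$genome)
  vapply(names(spanning), function(k) {
    pid <- spanning[[k]]
    if (length(pid) < min_support) return(FALSE)
    sp <- ds$pairs[match(pid, ds$pairs$pair_id), , drop = FALSE]
    key <- paste(sp$chrom_f, sp$start_f, sp$strand_f,
                 sp$chrom_r, sp$start_r, sp$strand_r)
    sp <- sp[!duplicated(key), , drop = FALSE]
    part <- partition_pairs(sp, sl)
    thin_count(part$startA, part$startB, part$pair_id, spread) >= min_support
  }, logical(1))
}
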
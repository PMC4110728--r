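# Breakpoint caller: partitioning, coarse/refined clustering, thinning,
# classification, and whole-pipeline properties.

test_that("partition_pairs buckets by canonical chromosome pair", {
  mp <- mk_pairs(
    mk_pair("a", "chr2", 1000, "+", "chr3", 5000, "-"),
    mk_pair("b", "chr3", 6000, "-", "chr2", 2000, "+"),  # reversed sides
    mk_pair("c", "chr1", 9000, "+", "chr1", 2000, "-"))  # intra, swapped starts
  part <- partition_pairs(mp)
  expect_setequal(unique(part$key), c("chr2|chr3", "chr1|chr1"))
  ab <- part[part$key == "chr2|chr3", ]
  expect_equal(ab$chromA, c("chr2", "chr2"))
  expect_equal(sort(ab$startA), c(1000, 2000))
  intra <- part[part$key == "chr1|chr1", ]
  expect_equal(intra$startA, 2000)  # side A gets the smaller start
  expect_equal(intra$startB, 9000)
  # partition property on random input
  set.seed(21)
  n <- 100
  big <- mate_pairs(mk_pair(sprintf("r%03d", 1:n),
                            sample(c("chr1", "chr2", "chr3"), n, TRUE),
                            sample.int(1e5, n), "+",
                            sample(c("chr1", "chr2", "chr3"), n, TRUE),
                            sample.int(1e5, n) + 2e5, "-"))
  pb <- partition_pairs(big)
  expect_equal(sum(table(pb$key)), n)
  expect_setequal(pb$pair_id, big$pair_id)
  expect_equal(nrow(partition_pairs(big[0, ])), 0L)
})

test_that("coarse clustering follows the window sweep", {
  model <- mk_model(1000, 2400)
  cfg <- caller_config(model, w = 5000)
  b <- mk_bucket(c(10000, 10400, 10900), c(50000, 50300, 50800))
  expect_length(coarse_cluster(b, cfg), 1L)

  b2 <- mk_bucket(c(10000, 10000 + 5000 + 1), c(50000, 50000))
  expect_length(coarse_cluster(b2, cfg), 2L)

  # identical coordinates, opposite signatures: the signature split
  # precedes clustering
  b3 <- rbind(mk_bucket(10000, 50000, sig = "+-", ids = "s1"),
              mk_bucket(10000, 50000, sig = "++", ids = "s2"))
  expect_length(coarse_cluster(b3, cfg), 2L)

  # side-B separation alone also splits
  b4 <- mk_bucket(c(10000, 10100), c(50000, 60000))
  expect_length(coarse_cluster(b4, cfg), 2L)

  # every pair lands in exactly one cluster
  set.seed(31)
  b5 <- mk_bucket(sort(sample.int(1e6, 40)), sample.int(1e6, 40))
  cl <- coarse_cluster(b5, cfg)
  expect_setequal(unlist(lapply(cl, function(x) x$pair_id)), b5$pair_id)
})

test_that("refinement equals brute-force single linkage", {
  model <- mk_model(1000, 2400)
  cfg <- caller_config(model, w = 6000, refine_cut = 1500)

  cl <- mk_bucket(c(1000, 1100, 1200), c(5000, 5100, 5200))
  expect_length(refine_cluster(cl, cfg), 1L)

  # two triples separated by twice the cut on side A
  cl2 <- mk_bucket(c(1000, 1100, 1200, 4200, 4300, 4400),
                   c(5000, 5100, 5200, 5000, 5100, 5200))
  ref <- refine_cluster(cl2, cfg)
  expect_length(ref, 2L)
  expect_equal(unname(sort(vapply(ref, nrow, 1L))), c(3L, 3L))

  set.seed(41)
  for (rep_ in 1:25) {
    n <- 20
    sa <- sample.int(8000, n, replace = TRUE)
    sb <- sample.int(8000, n, replace = TRUE)
    cl3 <- mk_bucket(sa, sb)
    got <- partition_sets(lapply(refine_cluster(cl3, cfg),
                                 function(x) match(x$pair_id, cl3$pair_id)))
    want <- partition_sets(split(seq_len(n), brute_components(sa, sb, cfg$refine_cut)))
    expect_identical(got, want)
  }
})

test_that("diversity thinning drives the support filter", {
  model <- mk_model(4000, 6000)
  cfg <- caller_config(model)

  cl <- mk_bucket(c(1000, 1060, 1120), c(9000, 9070, 9150),
                  chromA = "chr1", chromB = "chr2")
  bp <- cluster_to_breakpoint(cl, cfg, model)
  expect_equal(bp$effective_support, 3L)
  expect_equal(bp$support, 3L)
  expect_equal(bp$variant_class, "translocation")
  expect_equal(bp$b1, 1000); expect_equal(bp$e1, 1170)
  expect_equal(bp$b2, 9000); expect_equal(bp$e2, 9200)

  # five stacked pairs thin to one: no call at min_support 3
  cl2 <- mk_bucket(c(1000, 1002, 1004, 1006, 1008),
                   c(9000, 9001, 9002, 9003, 9004),
                   chromA = "chr1", chromB = "chr2")
  expect_null(cluster_to_breakpoint(cl2, cfg, model))

  # reads exactly min_end_spread apart count as independent evidence
  cl3 <- mk_bucket(c(1000, 1050, 1100), c(9000, 9050, 9100),
                   chromA = "chr1", chromB = "chr2")
  expect_equal(cluster_to_breakpoint(cl3, cfg, model)$effective_support, 3L)

  # veto mode: raw support must clear the bar with at least two diverse pairs
  cfgv <- caller_config(model, end_spread_mode = "veto")
  cl4 <- mk_bucket(c(1000, 1002, 1004), c(9000, 9001, 9060),
                   chromA = "chr1", chromB = "chr2")
  expect_equal(cluster_to_breakpoint(cl4, cfgv, model)$support, 3L)
  expect_null(cluster_to_breakpoint(cl4, cfg, model))  # thinned to 2 under thin mode
})

test_that("defaults carry the published thresholds", {
  cfg <- caller_config(mk_model(4000, 6000))
  expect_equal(cfg$min_support, 3L)
  expect_equal(cfg$min_end_spread, 50)
  expect_equal(cfg$w, 12000)
  expect_equal(cfg$refine_cut, 6000)
  expect_error(caller_config(mk_model(4000, 6000), w = 5000),
               class = "svb_param_error")
})

test_that("variant classes follow the rule table", {
  model <- mk_model(4000, 6000)
  expect_equal(classify_variant("+-", "chr2", "chr3", NA, model), "translocation")
  expect_equal(classify_variant("+-", "chr1", "chr1", 20000, model), "deletion")
  expect_equal(classify_variant("+-", "chr1", "chr1", 2000, model), "insertion")
  expect_equal(classify_variant("++", "chr1", "chr1", 5000, model), "inversion")
  expect_equal(classify_variant("--", "chr1", "chr1", 5000, model), "inversion")
  expect_error(classify_variant("+-", "chr1", "chr1", 5000, model), "internal error")
})

test_that("the pipeline recovers a planted translocation and ignores concordant data", {
  ds <- small_sim(seed = 13, n_pairs = 8000,
                  genome = c(chr1 = 3e6, chr2 = 3e6),
                  variants = data.frame(id = "tra001", class = "translocation",
                                        chrom = "chr1", start = 1.5e6, end = NA,
                                        len = NA, chrom2 = "chr2", start2 = 2e6,
                                        stringsAsFactors = FALSE))
  tb <- attr(ds$truth, "true_bounds")
  model <- insert_size_model(ds$pairs, override = as.numeric(tb))
  calls <- call_breakpoints(ds$pairs, model, sample = "t1")
  expect_true(all(calls$variant_class == "translocation"))
  expect_equal(sort(unique(calls$chromA)), "chr1")
  # reciprocal junctions with >= 3 spanning pairs are found with
  # support counts matching the truth bookkeeping
  want <- ds$truth$support[ds$truth$support >= 3]
  expect_equal(sort(calls$support), sort(want))

  # a dataset with only consistent pairs yields no calls
  ds0 <- small_sim(seed = 14, n_pairs = 1500,
                   variants = data.frame(id = character(), class = character(),
                                         chrom = character(), start = numeric(),
                                         end = numeric(), len = numeric(),
                                         chrom2 = character(), start2 = numeric()))
  model0 <- insert_size_model(ds0$pairs,
                              override = as.numeric(attr(ds0$truth, "true_bounds")))
  expect_equal(nrow(call_breakpoints(ds0$pairs, model0)), 0L)
})

test_that("calling is invariant to record order and batching", {
  ds <- small_sim(seed = 17, n_pairs = 4000, clonal_rate = 0.05)
  tb <- attr(ds$truth, "true_bounds")
  model <- insert_size_model(ds$pairs, override = as.numeric(tb))
  base <- call_breakpoints(ds$pairs, model, sample = "s")
  df <- as.data.frame(ds$pairs)
  set.seed(99)
  perm <- mate_pairs(df[sample(nrow(df)), ], seqlevels = mp_seqlevels(ds$pairs))
  expect_identical(as.data.frame(call_breakpoints(perm, model, sample = "s")),
                   as.data.frame(base))
  # batch decomposition: interleaved thirds reassembled in a new order
  idx <- rep(1:3, length.out = nrow(df))
  batched <- mate_pairs(rbind(df[idx == 3, ], df[idx == 1, ], df[idx == 2, ]),
                        seqlevels = mp_seqlevels(ds$pairs))
  expect_identical(as.data.frame(call_breakpoints(batched, model, sample = "s")),
                   as.data.frame(base))
})

test_that("pair membership is conserved through clustering", {
  ds <- small_sim(seed = 23, n_pairs = 4000)
  tb <- attr(ds$truth, "true_bounds")
  model <- insert_size_model(ds$pairs, override = as.numeric(tb))
  cfg <- caller_config(model)
  dd <- dedup_clonal(ds$pairs)
  cls <- classify_pairs(dd, model)
  incons <- dd[cls$label == "inconsistent", ]
  part <- partition_pairs(incons, mp_seqlevels(ds$pairs))
  total <- 0L
  for (bucket in split(part, part$key))
    for (cl in coarse_cluster(bucket, cfg))
      for (rf in refine_cluster(cl, cfg))
        total <- total + nrow(rf)
  expect_equal(total, nrow(incons))
  # footprint tightness on the resulting calls
  calls <- call_breakpoints(ds$pairs, model)
  for (i in seq_len(nrow(calls)))
    expect_true(calls$e1[i] >= calls$b1[i] && calls$e2[i] >= calls$b2[i])
})

test_that("raising min_support never increases the number of calls", {
  ds <- small_sim(seed = 29, n_pairs = 5000, tumor_fraction = 0.5)
  tb <- attr(ds$truth, "true_bounds")
  model <- insert_size_model(ds$pairs, override = as.numeric(tb))
  counts <- vapply(1:6, function(ms)
    nrow(call_breakpoints(ds$pairs, model,
                          caller_config(model, min_support = ms))), 1L)
  expect_true(all(diff(counts) <= 0))
})
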
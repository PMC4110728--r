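# Permutation enrichment: observed counting, null model, p-value rules,
# matrices, and discriminating-feature selection.

genome3 <- c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7)

# n inter-chromosomal breakpoints at given loci (two windows each).
loci_svset <- function(posA, posB, chromA = "chr1", chromB = "chr2",
                       class = "translocation", name = "bp") {
  sv_set(data.frame(chromA = chromA, b1 = posA, e1 = posA + 100,
                    chromB = chromB, b2 = posB, e2 = posB + 100,
                    variant_class = class),
         name = name, i_max = 5000, seqlevels = names(genome3))
}

test_that("features tiling the whole genome give fold exactly 1", {
  tiles <- feature_track(data.frame(chrom = names(genome3), start = 0,
                                    end = unname(genome3)), "tiles")
  bps <- loci_svset(c(1e6, 5e6), c(2e6, 7e6))
  cfg <- enrichment_config(genome3, radius = 50000, n_perm = 200, seed = 1)
  res <- permutation_enrichment(bps, tiles, cfg)
  expect_equal(nrow(res), 1L)
  expect_equal(res$observed, 4L)  # one incidence per locus window
  expect_equal(res$fold, 1)
  expect_equal(res$p_enrich, 1)
  expect_equal(res$p_deplete, 1)
})

test_that("features planted inside the true windows are detected as enriched", {
  set.seed(2)
  posA <- floor(runif(12) * 9e6)
  posB <- floor(runif(12) * 9e6)
  bps <- loci_svset(posA, posB)
  planted <- feature_track(data.frame(
    chrom = c(rep("chr1", 12), rep("chr2", 12)),
    start = c(posA, posB) + 1000, end = c(posA, posB) + 2000), "planted")
  cfg <- enrichment_config(genome3, radius = 50000, n_perm = 1000, seed = 3)
  res <- permutation_enrichment(bps, planted, cfg)
  expect_gt(res$fold, 1)
  expect_lte(res$p_enrich, 0.05)
  # p-values can never be zero under the add-one rule
  expect_gte(res$p_enrich, 1 / (cfg$n_perm + 1))
  expect_gte(res$p_deplete, 1 / (cfg$n_perm + 1))
  # enrichment and depletion tails cannot both be small
  expect_false(res$p_enrich < 0.5 && res$p_deplete < 0.5)
})

test_that("results are seed-deterministic and input-order independent", {
  set.seed(4)
  bps <- loci_svset(floor(runif(8) * 9e6), floor(runif(8) * 9e6))
  track <- feature_track(data.frame(chrom = sample(names(genome3), 100, TRUE),
                                    start = s <- floor(runif(100) * 9.9e6),
                                    end = s + 5000), "t")
  cfg <- enrichment_config(genome3, n_perm = 300, seed = 11)
  r1 <- permutation_enrichment(bps, track, cfg)
  r2 <- permutation_enrichment(bps, track, cfg)
  expect_identical(r1, r2)
  shuffled <- sv_set(as.data.frame(bps)[sample(nrow(bps)), ], "bp",
                     i_max = 5000, seqlevels = names(genome3))
  expect_identical(permutation_enrichment(shuffled, track, cfg)[
    , c("observed", "null_mean", "p_enrich")],
    r1[, c("observed", "null_mean", "p_enrich")])
  # different seeds: null means within a few standard errors on this fixture
  r3 <- permutation_enrichment(bps, track,
                               enrichment_config(genome3, n_perm = 300, seed = 12))
  se <- r1$null_sd / sqrt(cfg$n_perm)
  expect_lt(abs(r3$null_mean - r1$null_mean), 4 * se)
})

test_that("per-class results are computed separately and empty classes omitted", {
  bps <- sv_set(data.frame(
    chromA = c("chr1", "chr1"), b1 = c(1e6, 2e6), e1 = c(1e6, 2e6) + 100,
    chromB = c("chr2", "chr1"), b2 = c(3e6, 2.2e6), e2 = c(3e6, 2.2e6) + 100,
    variant_class = c("translocation", "deletion")),
    name = "mix", i_max = 5000, seqlevels = names(genome3))
  track <- feature_track(data.frame(chrom = "chr1", start = 999000, end = 1001000))
  cfg <- enrichment_config(genome3, n_perm = 100, seed = 5)
  res <- permutation_enrichment(bps, track, cfg)
  expect_setequal(res$variant_class, c("translocation", "deletion"))
  pooled <- permutation_enrichment(bps, track, cfg, by_class = FALSE)
  expect_equal(pooled$variant_class, "all")
  expect_equal(pooled$n_loci, 4L)
})

test_that("windows near chromosome ends are clipped", {
  g <- c(chrA = 200000)
  bps <- sv_set(data.frame(chromA = "chrA", b1 = 1000, e1 = 1100,
                           chromB = "chrA", b2 = 190000, e2 = 190100,
                           variant_class = "deletion"),
                name = "edge", i_max = 5000, seqlevels = "chrA")
  track <- feature_track(data.frame(chrom = "chrA",
                                    start = c(0, 150000), end = c(500, 150500)))
  # loci at ~1050 and ~190050 with radius 60000: windows clip to
  # [0, 61050) and [130050, 200000); both features are hit once each
  expect_equal(count_features_near(bps, track, 60000, g), 2L)
  # merged-window rule: radius large enough to fuse the two loci
  expect_equal(nrow(svbreaks:::breakpoint_loci(as.data.frame(bps), 100000)), 1L)
  # a chromosome absent from the genome map is a config error
  cfg_bad <- enrichment_config(c(other = 1e6), n_perm = 10)
  expect_error(permutation_enrichment(bps, track, cfg_bad),
               class = "svb_param_error")
})

test_that("unique-feature counting caps multiplicity", {
  g <- c(chr1 = 1e6)
  bps <- sv_set(data.frame(chromA = "chr1", b1 = c(100000, 120000),
                           e1 = c(100100, 120100),
                           chromB = "chr1", b2 = c(500000, 520000),
                           e2 = c(500100, 520100),
                           variant_class = "deletion"),
                name = "m", i_max = 5000, seqlevels = "chr1")
  track <- feature_track(data.frame(chrom = "chr1", start = 110000, end = 111000))
  expect_equal(count_features_near(bps, track, 50000, g), 2L)
  expect_equal(count_features_near(bps, track, 50000, g, unique_features = TRUE), 1L)
})

test_that("enrichment matrices compose per-cell tests deterministically", {
  set.seed(6)
  sA <- loci_svset(floor(runif(10) * 9e6), floor(runif(10) * 9e6), name = "sA")
  sB <- sv_set(as.data.frame(sA), name = "sB", i_max = 5000,
               seqlevels = names(genome3))
  d <- as.data.frame(sA)
  trackX <- feature_track(data.frame(chrom = "chr1", start = d$b1 + 500,
                                     end = d$b1 + 1500), "X")
  cfg <- enrichment_config(genome3, n_perm = 200, seed = 21)
  m <- enrichment_matrix(list(sA = sA, sB = sB), list(X = trackX), cfg)
  # identical breakpoints under different labels give identical columns
  expect_equal(m$fold[, "sA"], m$fold[, "sB"])
  single <- permutation_enrichment(sA, trackX, cfg, by_class = FALSE)
  expect_equal(unname(m$fold["X", "sA"]), single$fold)

  # planted asymmetry: a track hugging sC's breakpoints scores higher there
  sC <- loci_svset(floor(runif(10) * 9e6) , floor(runif(10) * 9e6), name = "sC")
  m2 <- enrichment_matrix(list(sA = sA, sC = sC), list(X = trackX), cfg)
  expect_gt(m2$fold["X", "sA"], m2$fold["X", "sC"])

  path <- tempfile(fileext = ".tsv")
  write_enrichment_matrix(m, path)
  expect_equal(read_enrichment_matrix(path), m$fold)
})

test_that("discriminating features are selected by test, alpha and fold change", {
  base <- matrix(1, nrow = 3, ncol = 10,
                 dimnames = list(c("flat", "shift", "weak"),
                                 paste0("s", 1:10)))
  ga <- paste0("s", 1:5)
  gb <- paste0("s", 6:10)
  base["shift", ga] <- c(3.0, 3.1, 3.2, 3.3, 3.4)
  base["shift", gb] <- c(1.0, 1.1, 1.2, 1.3, 1.4)
  base["weak", ga] <- base["weak", gb] + 0.05
  res <- discriminating_features(base, ga, gb, method = "ranksum",
                                 alpha = 0.05, min_fold_change = 1.25)
  expect_equal(res$track, "shift")
  expect_equal(res$direction, "group_a")
  expect_lt(res$p, 0.05)
  expect_gte(res$fold_ratio, 1.25)

  # identical groups: nothing reported
  expect_equal(nrow(discriminating_features(base[, c(ga, ga)],
                                            paste0("s", 1:5),
                                            paste0("s", 1:5),
                                            method = "ranksum")), 0L)

  # t-test route finds the same planted shift
  res_t <- discriminating_features(base, ga, gb, method = "ttest",
                                   alpha = 0.05, min_fold_change = 1.25)
  expect_equal(res_t$track, "shift")
  # t-test with singleton group is an error; rank-sum warns
  expect_error(discriminating_features(base, "s1", gb, method = "ttest"),
               class = "svb_param_error")
  expect_warning(discriminating_features(base, "s1", gb, method = "ranksum"),
                 "singleton")
})
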
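# Quality scoring, MinHash sketches, ANI estimation, greedy clustering.

test_that("quality_score is completeness minus four times contamination", {
  expect_equal(quality_score(88.5, 3.8), 73.3)
  expect_equal(quality_score(100, 0), 100)
  expect_equal(quality_score(50, 0), 50)
  expect_error(quality_score(101, 0), "completeness")
  expect_error(quality_score(90, -1), "contamination")
})

test_that("quality_filter keeps scores >= 50 inclusively, in order", {
  mags <- helgoland_mags()
  kept <- quality_filter(mags, min_score = 50)
  expect_equal(nrow(kept), 11L)           # all published bins pass
  expect_equal(min(kept$score), 50)       # boundary bin passes inclusively
  expect_equal(kept$mag, mags$mag)

  low <- data.frame(genome = "x", completeness = 60, contamination = 5)
  expect_equal(nrow(quality_filter(low)), 0L)   # score 40
  expect_equal(nrow(quality_filter(low[0, ])), 0L)
})

test_that("sketches are deterministic, canonical, and saturate at s", {
  g <- sim_genome(20000, 0.5, seed = 1, id = "g")
  s1 <- minhash_sketch(g, k = 21, s = 1000)
  s2 <- minhash_sketch(g, k = 21, s = 1000)
  expect_identical(s1$hashes, s2$hashes)
  expect_false(is.unsorted(s1$hashes))
  expect_false(any(duplicated(s1$hashes)))
  expect_length(s1$hashes, 1000L)

  # reverse complement has the identical sketch
  revcomp <- chartr("ACGT", "TGCA", paste(rev(strsplit(g$sequence, "")[[1]]),
                                          collapse = ""))
  s3 <- minhash_sketch(revcomp, k = 21, s = 1000)
  expect_identical(s1$hashes, s3$hashes)

  # a 0.5 Mbp genome fills the default sketch
  big <- sim_genome(5e5, 0.5, seed = 2, id = "big")
  expect_length(minhash_sketch(big)$hashes, 5000L)

  expect_error(minhash_sketch("ACGT", k = 21), "shorter than k")
})

test_that("ani_estimate follows the Mash transform and its edge cases", {
  g <- sim_genome(20000, 0.5, seed = 3, id = "g")
  s <- minhash_sketch(g)
  expect_equal(ani_estimate(s, s), 100)

  # closed form: j = 0.5, k = 21 -> ANI = 100 * (1 - ln(4/3)/21)
  fake <- function(h) structure(list(genome_id = "f", k = 21L, s = 4L,
                                     hashes = as.numeric(h)),
                                class = "minhash_sketch")
  a <- fake(c(1, 2, 3, 4))
  b <- fake(c(1, 2, 7, 8))   # merged bottom-4 {1,2,3,4}: shared 2 -> j = 0.5
  expect_equal(ani_estimate(a, b), 100 * (1 - (-log(2 * 0.5 / 1.5) / 21)),
               tolerance = 1e-12)
  expect_equal(round(ani_estimate(a, b), 2), 98.07)

  # disjoint sketches are below resolution -> sentinel, not a number
  expect_true(is.na(ani_estimate(fake(1:4), fake(11:14))))
  s2 <- minhash_sketch(g, k = 15)
  expect_error(ani_estimate(s, s2), "mismatched")
})

test_that("ani_estimate is symmetric and tracks simulated divergence", {
  g <- sim_genome(2e5, 0.5, seed = 4, id = "g")
  sk <- minhash_sketch(g)
  for (d in c(0.02, 0.05)) {
    rel <- sim_relative(g, d, seed = 40 + round(100 * d), id = "rel")
    skr <- minhash_sketch(rel)
    est <- ani_estimate(sk, skr)
    expect_equal(est, ani_estimate(skr, sk))
    expect_lt(abs(est - 100 * (1 - d)), 0.5)
  }
})

test_that("the Mash transform matches its closed-form expectation up to d = 0.1", {
  # the estimator targets 100*(1 + ln(1-d)); check against that expectation
  g <- sim_genome(2e5, 0.5, seed = 6, id = "g")
  sk <- minhash_sketch(g)
  for (d in c(0.05, 0.08, 0.1)) {
    rel <- sim_relative(g, d, seed = 60 + round(100 * d), id = "rel")
    est <- ani_estimate(sk, minhash_sketch(rel))
    # 0.008 relative ~ 0.7 ANI points: 3 SD of sketch + mutation sampling
    expect_equal(est, 100 * (1 + log(1 - d)), tolerance = 0.008)
  }
})

test_that("realized divergence of derived genomes is binomial", {
  g <- sim_genome(1e5, 0.5, seed = 8, id = "g")
  rel <- sim_relative(g, 0.05, seed = 9, id = "rel")
  mism <- sum(charToRaw(g$sequence) != charToRaw(rel$sequence))
  # exact binomial check: within 4 SD of L*d
  expect_lt(abs(mism - 1e5 * 0.05), 4 * sqrt(1e5 * 0.05 * 0.95))
  ident <- sim_relative(g, 0, id = "same")
  expect_identical(ident$sequence, g$sequence)
})

test_that("greedy clustering recovers truth groups and picks best representatives", {
  dx <- derep_genomes()
  cs <- greedy_cluster(dx$genomes, dx$qualities, ani_threshold = 95)
  expect_equal(length(unique(cs$cluster)), 3L)
  # clusters match the truth partition exactly
  split_truth <- split(names(dx$truth), dx$truth)
  split_est <- split(cs$genome, cs$cluster)
  expect_true(setequal(lapply(split_truth, sort), lapply(split_est, sort)))
  # representative maximizes quality score within each cluster
  for (cl in unique(cs$cluster)) {
    sub <- cs[cs$cluster == cl, ]
    expect_equal(sub$genome[sub$representative],
                 sub$genome[which.max(sub$score)])
  }
  # partition: every genome in exactly one cluster
  expect_setequal(cs$genome, names(dx$genomes))
  expect_equal(anyDuplicated(cs$genome), 0L)
})

test_that("two identical genomes collapse onto the higher-quality one", {
  g <- sim_genome(20000, 0.5, seed = 12, id = "a")
  g2 <- g
  g2$id <- "b"
  qual <- data.frame(genome = c("a", "b"), completeness = c(80, 95),
                     contamination = c(0, 0))
  cs <- greedy_cluster(list(a = g, b = g2), qual, 95)
  expect_equal(unique(cs$cluster), "b")
  expect_true(cs$representative[cs$genome == "b"])
})

test_that("threshold splits and merges follow simulated ANI", {
  g <- sim_genome(60000, 0.5, seed = 13, id = "a")
  rel <- sim_relative(g, 0.03, seed = 14, id = "b")   # true ANI ~97
  qual <- data.frame(genome = c("a", "b"), completeness = c(96, 90),
                     contamination = 0)
  genomes <- list(a = g, b = rel)
  expect_equal(length(unique(greedy_cluster(genomes, qual, 99)$cluster)), 2L)
  expect_equal(length(unique(greedy_cluster(genomes, qual, 95)$cluster)), 1L)
})

test_that("clustering at 99 refines clustering at 95 and counts are monotone", {
  dx <- derep_genomes()
  cs95 <- greedy_cluster(dx$genomes, dx$qualities, 95)
  cs99 <- greedy_cluster(dx$genomes, dx$qualities, 99)
  expect_gte(length(unique(cs99$cluster)), length(unique(cs95$cluster)))
  # refinement: every 99-cluster sits inside one 95-cluster
  map95 <- setNames(cs95$cluster, cs95$genome)
  for (cl in unique(cs99$cluster)) {
    members <- cs99$genome[cs99$cluster == cl]
    expect_equal(length(unique(map95[members])), 1L)
  }
})
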
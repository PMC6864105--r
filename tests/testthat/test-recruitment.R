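# Depth profiles, TAD, identity histograms, cutoff detection, ANIr.

mk_aln <- function(sstart, send, pident = 99, sseqid = "c1",
                   length = abs(send - sstart) + 1L) {
  n <- base::length(sstart)
  data.frame(qseqid = sprintf("r%d", seq_len(n)), sseqid = rep_len(sseqid, n),
             pident = rep_len(pident, n), length = rep_len(length, n),
             mismatch = rep_len(0L, n), gapopen = rep_len(0L, n),
             qstart = rep_len(1L, n), qend = rep_len(length, n),
             sstart = sstart, send = send,
             evalue = rep_len(0, n), bitscore = 2 * rep_len(length, n),
             stringsAsFactors = FALSE)
}

mk_genome <- function(lens, ids = paste0("c", seq_along(lens))) {
  data.frame(id = ids, description = "",
             sequence = vapply(lens, function(L) strrep("A", L), character(1)),
             stringsAsFactors = FALSE)
}

test_that("compute_depth does interval arithmetic per base", {
  g <- mk_genome(20)
  aln <- mk_aln(sstart = c(1L, 6L), send = c(10L, 15L))
  prof <- compute_depth(aln, g)
  expect_equal(prof$depth$c1,
               c(rep(1, 5), rep(2, 5), rep(1, 5), rep(0, 5)))
  # no alignments -> all-zero profile
  empty <- compute_depth(mk_aln(integer(0), integer(0)), g)
  expect_equal(empty$depth$c1, rep(0, 20))
})

test_that("compute_depth rejects unknown contigs and out-of-bounds intervals", {
  g <- mk_genome(20)
  expect_error(compute_depth(mk_aln(1L, 10L, sseqid = "nope"), g),
               "unknown contig.*nope")
  expect_error(compute_depth(mk_aln(5L, 25L), g), "exceeds contig 'c1'")
})

test_that("compute_depth matches a brute-force per-base count", {
  set.seed(42)
  L <- 10000L
  n <- 1000L
  starts <- sample.int(L - 99L, n, replace = TRUE)
  aln <- mk_aln(starts, starts + 99L)
  prof <- compute_depth(aln, mk_genome(L))
  # independent oracle: count covering reads at each base directly
  brute <- vapply(seq_len(L), function(p) {
    sum(starts <= p & p <= starts + 99L)
  }, numeric(1))
  expect_equal(prof$depth$c1, brute)
  expect_equal(mean(prof$depth$c1), n * 100 / L, tolerance = 0.05)
})

test_that("tad trims tails by sort-and-trim and handles edge fractions", {
  expect_equal(tad(rep(7, 100)), 7.0)
  expect_equal(tad(c(0, 0, 1, 1, 1, 1, 1, 1, 100, 100), 0.8), 13.25)
  expect_equal(tad(c(2, 4, 6), central_fraction = 1.0), 4.0)
  expect_error(tad(numeric(0)), "empty")
  expect_error(tad(c(1, 2), central_fraction = 0), "central_fraction")
})

test_that("tad agrees with a brute-force trim oracle on random profiles", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:9999, 1)
    v <- rpois(n, lambda = sample(c(0.5, 5, 50), 1)) * runif(n, 0.5, 1.5)
    # oracle: repeatedly delete the current min and max, floor(n/10) times
    w <- v
    k <- floor(0.1 * n)
    for (j in seq_len(k)) w <- w[-which.min(w)]
    for (j in seq_len(k)) w <- w[-which.max(w)]
    expect_equal(tad(v, 0.8), mean(w))
  }
})

test_that("tad is permutation-invariant, bounded, and scales linearly", {
  set.seed(11)
  v <- rpois(500, 20) + runif(500)
  expect_equal(tad(sample(v)), tad(v))
  expect_gte(tad(v), min(v))
  expect_lte(tad(v), max(v))
  for (c_ in c(0, 0.5, 3)) {
    expect_equal(tad(c_ * v), c_ * tad(v))
  }
})

test_that("multi-contig profiles are concatenated before truncation", {
  g2 <- mk_genome(c(6, 4))
  aln <- rbind(mk_aln(1L, 6L, sseqid = "c1"), mk_aln(1L, 2L, sseqid = "c2"))
  prof <- compute_depth(aln, g2)
  # depths: c1 six 1s, c2 two 1s + two 0s; n=10, drop 1 from each tail
  expect_equal(tad(prof, 0.8), mean(c(0, rep(1, 7))))
})

test_that("identity_histogram applies the edge rules and conserves bases", {
  one <- mk_aln(1L, 100L, pident = 100)
  h <- identity_histogram(one, genome_length = 1000)
  expect_equal(h$depth[h$lower == 99.5], 0.1)
  expect_equal(sum(h$depth), 0.1)

  # pident exactly on an edge goes to the upper bin
  edge <- mk_aln(1L, 100L, pident = 98.0)
  h <- identity_histogram(edge, 1000)
  expect_equal(h$depth[h$lower == 98.0], 0.1)
  expect_equal(h$depth[h$lower == 97.5], 0)

  expect_error(identity_histogram(mk_aln(1L, 10L, pident = 101), 100),
               "identity")
  expect_error(identity_histogram(one, 1000, bin_width = 0.7), "bin_width")
})

test_that("bimodal generator output matches a brute-force tally", {
  sx <- sister_sim()
  aln <- sx$aln
  h <- identity_histogram(aln, 40000)
  # oracle: direct tally per bin
  for (lo in c(91.0, 96.0, 99.5)) {
    hi <- lo + 0.5
    inbin <- if (hi == 100) {
      aln$pident >= lo & aln$pident <= 100
    } else {
      aln$pident >= lo & aln$pident < hi
    }
    expect_equal(h$depth[abs(h$lower - lo) < 1e-9],
                 sum(aln$length[inbin]) / 40000)
  }
  # bimodal: mass near 99.5 and near 92, none near 95
  expect_gt(h$depth[h$lower == 99.5], 10 * h$depth[h$lower == 95.0])
  expect_gt(h$depth[h$lower == 91.5], 10 * h$depth[h$lower == 95.0])
  # conservation over the whole domain
  expect_equal(sum(h$depth) * 40000,
               sum(aln$length[aln$pident >= 70]))
})

test_that("detect_cutoff finds the gap above re-emerging background", {
  h <- identity_histogram(data.frame(pident = 1, length = 1)[0, ], 1)
  h$depth <- 0
  h$depth[h$lower >= 70 & h$lower < 90] <- 2.0      # background taxa
  h$depth[h$lower == 97.5] <- 0.0005                # inside the gap
  h$depth[h$lower == 98.0] <- 6
  h$depth[h$lower == 98.5] <- 40
  h$depth[h$lower == 99.0] <- 300
  h$depth[h$lower == 99.5] <- 800
  res <- detect_cutoff(h, drop_orders = 3)
  expect_true(res$discontinuity_found)
  expect_equal(res$cutoff, 98.0)
  expect_equal(res$peak_depth, 800)
  expect_gte(res$drop_ratio, 1000)
})

test_that("detect_cutoff returns the floor when no discontinuity exists", {
  h <- identity_histogram(data.frame(pident = 1, length = 1)[0, ], 1)
  h$depth <- rep(5, nrow(h))     # uniform recruitment
  res <- detect_cutoff(h)
  expect_false(res$discontinuity_found)
  expect_equal(res$cutoff, 95.0)

  # single isolated spike: a decay to nothing, not a population boundary
  h$depth <- 0
  h$depth[nrow(h)] <- 100
  res <- detect_cutoff(h)
  expect_false(res$discontinuity_found)
  expect_equal(res$cutoff, 95.0)

  h$depth <- 0
  expect_error(detect_cutoff(h), "all-zero")
})

test_that("manual override bypasses detection", {
  h <- identity_histogram(mk_aln(1L, 100L, pident = 99), 1000)
  res <- detect_cutoff(h, manual = 98)
  expect_equal(res$cutoff, 98)
  expect_true(is.na(res$discontinuity_found))
})

test_that("anir filters at the cutoff and weights as requested", {
  aln <- data.frame(pident = c(99.0, 100.0), length = c(100L, 300L))
  expect_equal(anir(aln, cutoff = 98), 99.75)
  expect_equal(anir(aln, cutoff = 98, weighting = "per_read"), 99.5)

  aln <- data.frame(pident = c(97.0, 99.5), length = c(100L, 100L))
  expect_equal(anir(aln, 98), 99.5)
  expect_equal(anir(data.frame(pident = rep(100, 5), length = 50L), 98), 100)
  expect_error(anir(data.frame(pident = 90, length = 100L), 98),
               "no recruited reads")
})

test_that("anir is monotone in the cutoff and bounded by [cutoff, 100]", {
  aln <- clonal_sim()$aln
  cuts <- c(90, 94, 96, 98, 99, 99.5)
  vals <- vapply(cuts, function(ct) anir(aln, ct), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= cuts & vals <= 100))
})

test_that("recruitment matrix marginal equals the identity histogram", {
  sx <- clonal_sim()
  g <- sx$sim$community$genomes[["pop1"]]
  rm_ <- recruitment_matrix(sx$aln, g, position_bin = 1000)
  h <- identity_histogram(sx$aln, 40000)
  expect_equal(colSums(rm_$matrix), h$depth * 40000,
               ignore_attr = TRUE)
  # single read -> exactly one nonzero cell holding its aligned length
  one <- mk_aln(11L, 110L, pident = 99.2)
  m1 <- recruitment_matrix(one, mk_genome(1000), position_bin = 100)
  expect_equal(sum(m1$matrix != 0), 1L)
  expect_equal(sum(m1$matrix), 100)
  # empty alignments -> all-zero matrix
  m0 <- recruitment_matrix(one[0, ], mk_genome(1000), position_bin = 100)
  expect_true(all(m0$matrix == 0))
})
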
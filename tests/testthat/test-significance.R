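test_that("reads are extended from their 5' ends, strand-aware", {
  # BED 100-136 on + -> BED 100-300, i.e. 1-based 101-300
  plus <- gr("chr1", 101, 136, "+")
  expect_equal(ranges(extend_reads(plus, 200)), IRanges(101, 300))
  # BED 500-536 on - -> BED 336-536
  minus <- gr("chr1", 501, 536, "-")
  expect_equal(ranges(extend_reads(minus, 200)), IRanges(337, 536))
  # AGO1-style 350 nt extension
  expect_equal(width(extend_reads(plus, 350)), 350)
  # unstranded read with strand_aware on is an error naming the record
  expect_error(extend_reads(gr("chr1", 101, 136, "*"), 200), "strand")
  # strand-agnostic mode extends rightward regardless
  both <- c(gr("chr1", 101, 136, "*"), gr("chr1", 501, 536, "-"))
  ext <- extend_reads(both, 200, strand_aware = FALSE)
  expect_equal(start(ext), c(101, 501))
  expect_equal(width(ext), c(200, 200))
  # extension shorter than the read is rejected
  expect_error(extend_reads(gr("chr1", 1, 300), 200), "shorter")
})

test_that("extension clips at chromosome bounds when sizes are known", {
  r <- gr("chr1", 901, 936, "+")
  seqlengths(r) <- c(chr1 = 1000)
  expect_equal(end(extend_reads(r, 200)), 1000)
})

test_that("exclusion filtering drops any read overlapping by >= 1 nt", {
  reads <- gr(c("chr1", "chr1", "chr2"), c(11, 500, 11), c(210, 600, 210))
  excl <- gr("chr1", 201, 300)
  kept <- filter_excluded(reads, excl)
  expect_equal(length(kept), 2)              # 10-nt overlap read dropped
  expect_true(all(as.character(seqnames(kept)) %in% c("chr1", "chr2")))
  expect_equal(start(kept), c(500, 11))      # order preserved
  # different chromosome is kept; empty exclusion set is the identity
  expect_equal(length(filter_excluded(reads, GRanges())), 3)
})

test_that("clusters are overlap components with singletons discarded", {
  reads <- c(gr("chr1", 1, 200), gr("chr1", 151, 350), gr("chr1", 1001, 1200))
  cl <- build_clusters(reads)
  expect_equal(length(cl), 1)
  expect_equal(c(start(cl), end(cl)), c(1, 350))
  expect_equal(cl$n_reads, 2)
  # no reads -> empty
  expect_equal(length(build_clusters(GRanges())), 0)
  # a chain of k mutually-overlapping reads is one cluster with n_reads = k
  k <- 7
  chain <- gr("chr1", seq(1, by = 100, length.out = k),
              seq(150, by = 100, length.out = k))
  cl <- build_clusters(chain)
  expect_equal(length(cl), 1)
  expect_equal(cl$n_reads, k)
  # bookended (adjacent, non-overlapping) reads do not merge
  book <- c(gr("chr1", 1, 100), gr("chr1", 101, 200))
  expect_equal(length(build_clusters(book)), 0)
})

test_that("clustering agrees with a brute-force component oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 150
    starts <- sample.int(5000, n)
    reads <- gr(sample(c("chr1", "chr2"), n, replace = TRUE),
                starts, starts + sample(50:300, n, replace = TRUE))
    got <- build_clusters(reads)
    want <- oracle_clusters(reads)
    expect_equal(length(got), length(want))
    if (length(want) > 0) {
      tab <- function(g) {
        d <- data.frame(chrom = as.character(seqnames(g)), start = start(g),
                        end = end(g), n = g$n_reads)
        d[order(d$chrom, d$start), ]
      }
      expect_equal(tab(got), tab(want), ignore_attr = TRUE)
    }
  }
})

test_that("the normalization factor is the mean log2 ratio over background", {
  m <- estimate_cnf(cbind(c(4, 2, 8), c(2, 2, 4)))
  expect_equal(m$cnf_log, 2 / 3)
  expect_equal(m$cnf_linear, 2^(2 / 3))
  expect_equal(m$n_regions, 3)
  # balanced case
  m <- estimate_cnf(cbind(2, 2))
  expect_equal(m$cnf_linear, 1)
  # regions at or above the threshold, or with zero counts, are excluded
  m <- estimate_cnf(cbind(c(4, 10, 4, 0), c(2, 2, 0, 2)))
  expect_equal(m$n_regions, 1)
  expect_equal(m$cnf_log, 1)
  # nothing qualifies -> error
  expect_error(estimate_cnf(cbind(c(20, 0), c(20, 3))), "background")
})

test_that("normalization recovers a planted rate ratio at adequate depth", {
  set.seed(3)
  lambda <- runif(2000, 10, 50)
  counts <- cbind(rpois(2000, 2 * lambda), rpois(2000, lambda))
  m <- estimate_cnf(counts, max_background_reads = 100)
  expect_gt(m$cnf_linear, 2 * 0.95)
  expect_lt(m$cnf_linear, 2 * 1.05)
})

test_that("the significance probability matches the printed formula", {
  expect_equal(bayes_pvalue(0, 0, 1), 0.5)
  expect_equal(bayes_pvalue(1, 0, 1), 0.25)
  # exact direct-arithmetic oracle at small counts
  for (k in c(0.5, 1, 2)) {
    for (ns in c(0, 3, 10)) for (nc in c(0, 2, 7)) {
      expect_equal(bayes_pvalue(ns, nc, k), oracle_bayes(ns, nc, k),
                   tolerance = 1e-12)
    }
  }
  expect_error(bayes_pvalue(1, 1, 0), "cnf_linear")
  expect_error(bayes_pvalue(-1, 0, 1), "non-negative")
})

test_that("the significance probability is a distribution over control counts", {
  for (ns in c(0, 1, 5, 20)) {
    for (k in c(0.25, 1, 4)) {
      total <- sum(bayes_pvalue(ns, 0:(10 * (ns + 10)), k))
      expect_gte(total, 0.999999)
      expect_lte(total, 1 + 1e-12)
    }
  }
})

test_that("swapping sample and control inverts the rate ratio", {
  # P(b | a; 1/k) = k * P(a's role swapped): exact algebraic identity
  for (k in c(0.5, 1, 2)) {
    for (a in c(0, 3, 11, 20)) for (b in c(0, 2, 9, 20)) {
      expect_equal(bayes_pvalue(b, a, 1 / k), k * bayes_pvalue(a, b, k),
                   tolerance = 1e-10)
    }
  }
})

test_that("significant-cluster calling honors the cutoff and the guard", {
  model <- structure(list(cnf_log = 0, cnf_linear = 1, n_regions = 10,
                          max_background_reads = 10),
                     class = "background_model")
  # enriched cluster: 12 reads, control empty under it
  clusters <- gr("chr1", c(1, 2001), c(400, 2400))
  clusters$n_reads <- c(12L, 3L)
  ctrl <- gr("chr1", seq(2001, 2300, by = 30), seq(2100, 2399, by = 30))
  res <- call_significant(clusters, ctrl, model, cutoff = 0.05)
  expect_true(res$clusters$significant[1])
  # depleted cluster (3 sample vs 10 control) has small p but fails the guard
  expect_lt(res$clusters$pvalue[2], 0.05)
  expect_false(res$clusters$significant[2])
  # without the guard the depleted cluster is retained
  res2 <- call_significant(clusters, ctrl, model, cutoff = 0.05,
                           enrichment_guard = FALSE)
  expect_true(res2$clusters$significant[2])
  expect_error(call_significant(clusters, ctrl, model, cutoff = 1.5),
               "cutoff")
})

test_that("enriched clusters are recalled better than background is retained", {
  set.seed(5)
  # 30 enriched regions (12x background) + uniform background, control at 1:2
  chrom <- c(chrA = 4e5)
  bs <- sort(sample.int(399800, 1200))
  bg <- gr("chrA", bs, bs + 199)
  enriched_at <- seq(10000, by = 13000, length.out = 30)
  es <- rep(enriched_at, each = 12) + sample(0:400, 360, replace = TRUE)
  enr <- gr("chrA", es, es + 199)
  reads <- sort(c(granges(bg), granges(enr)))
  cs <- sort(sample.int(399800, 600))
  ctrl <- gr("chrA", cs, cs + 199)
  res <- call_clusters(reads, ctrl, cutoff = 0.01)
  sig <- res$significant
  hit_enriched <- overlapsAny(gr("chrA", enriched_at, enriched_at + 600), sig)
  recall <- mean(hit_enriched)
  retention <- length(sig) / length(res$clusters)
  expect_gt(recall, 0.8)
  expect_gt(recall, retention)
  # only reads overlapping significant clusters are returned
  expect_true(all(overlapsAny(res$reads, sig)))
})
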
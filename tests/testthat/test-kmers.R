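test_that("expected density counts overlapping occurrences per nucleotide", {
  # "AAAAAAAA": two overlapping AAAAAAA in 8 nt -> 0.25
  d0 <- expected_density("AAAAAAAA", k = 7)
  expect_equal(unname(d0["AAAAAAA"]), 2 / 8)
  # absent k-mer has zero density
  expect_equal(unname(d0["ACGTACG"]), 0)
  # counting identity: total density sums to (l - k + 1) / l per strand
  set.seed(71)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  d <- expected_density(s, k = 7)
  expect_equal(sum(d), (5000 - 7 + 1) / 5000)
})

test_that("k-mer counting agrees with a naive scan oracle", {
  set.seed(72)
  for (len in c(300, 2000, 10000)) {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    got <- chromsplice:::kmer_count_matrix(s, 7)
    want <- oracle_kmer_counts(s, 7)
    got_nonzero <- got[1, got[1, ] > 0]
    expect_equal(sort(names(got_nonzero)), sort(names(want)))
    expect_equal(got_nonzero[sort(names(want))], want[sort(names(want))])
  }
  # either orientation folds onto the canonical k-mer
  m <- chromsplice:::kmer_count_matrix(c("GATTACAT", "ATGTAATC"), 7)
  key <- chromsplice:::canonical_kmers("GATTACA")
  expect_equal(unname(m[1, key]), 1)
  expect_equal(unname(m[2, key]), 1)   # reverse complement sequence
})

test_that("the worked Fisher contingency matches the hypergeometric oracle", {
  # 8/10 sample vs 2/10 control indicators
  p <- kmer_fisher(8, 10, 2, 10)
  expect_equal(p, 2126 / 184756, tolerance = 1e-12)
  expect_equal(p, oracle_hyper_tail(8, 10, 2, 10), tolerance = 1e-12)
  # a couple more cells against the exact sum
  expect_equal(kmer_fisher(5, 12, 1, 9), oracle_hyper_tail(5, 12, 1, 9))
  expect_equal(kmer_fisher(0, 10, 0, 10), 1)
  # agreement with R's own one-sided Fisher test
  ft <- fisher.test(matrix(c(8, 2, 2, 8), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(p, ft$p.value, tolerance = 1e-12)
})

test_that("identical sample and control sets are unenriched everywhere", {
  set.seed(73)
  seqs <- vapply(1:15, function(i) {
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  }, character(1))
  res <- kmer_enrichment(seqs, seqs)
  expect_true(all(res$pvalue >= 0.5))
  expect_true(all(res$odds_ratio == 1))
})

test_that("a planted heptamer ranks first and nulls stay calibrated", {
  cfg <- sim_config(seed = 5, motif = "GATTACA", motif_prob = 0.5)
  sim <- simulate_motif_sequences(cfg, n_sample = 150, n_control = 150)
  res <- kmer_enrichment(sim$sample, sim$control)
  key <- chromsplice:::canonical_kmers("GATTACA")
  expect_equal(res$kmer[1], key)
  expect_lt(res$qvalue[1], 1e-6)
  # no insertion: p < 0.05 fraction within binomial tolerance of 0.05
  cfg0 <- sim_config(seed = 6, motif_prob = 0)
  sim0 <- simulate_motif_sequences(cfg0, n_sample = 150, n_control = 150)
  res0 <- kmer_enrichment(sim0$sample, sim0$control)
  frac <- mean(res0$pvalue < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(res0))
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("cluster sequences are kept only with two significant k-mers", {
  genome <- list(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  # plant two distinct significant 7-mers around position 2000, one at 6000
  g <- genome$chr1
  substr(g, 1951, 1957) <- "GATTACA"
  substr(g, 2030, 2036) <- "TTTTGGG"
  substr(g, 5971, 5977) <- "GATTACA"
  genome$chr1 <- g
  clusters <- gr("chr1", c(1901, 5901, 8001), c(2099, 6099, 8199))
  kept <- select_motif_clusters(clusters, c("GATTACA", "TTTTGGG"), genome,
                                min_kmers = 2, width = 200)
  expect_equal(length(kept), 1)
  expect_equal(names(kept), "chr1:1901-2099")
  expect_equal(Biostrings::width(kept), 200)
  # with min_kmers = 1 the single-kmer cluster also qualifies
  kept1 <- select_motif_clusters(clusters, c("GATTACA", "TTTTGGG"), genome,
                                 min_kmers = 1)
  expect_equal(length(kept1), 2)
})

test_that("the PFM stacks oriented k-mer occurrences", {
  # single occurrence of a single k-mer: one-hot core plus flank counts
  s <- Biostrings::DNAStringSet("AACCGATTACAGGTT")
  pfm <- build_pfm(s, "GATTACA", width = 11)
  expect_equal(pfm$n_sites, 1)
  expect_equal(sum(pfm$counts), 11)
  core <- pfm$counts[, 3:9]
  ri <- match(c("G", "A", "T", "T", "A", "C", "A"), rownames(core))
  expect_equal(unname(core[cbind(ri, 1:7)]), rep(1, 7))
  expect_equal(substr(pfm$consensus, 3, 9), "GATTACA")
  # the reverse-complement sequence gives the identical PFM
  s_rc <- Biostrings::reverseComplement(s)
  pfm_rc <- build_pfm(s_rc, "GATTACA", width = 11)
  expect_equal(pfm_rc$counts, pfm$counts)
  # column sums are equal across fully-covered positions
  expect_true(all(colSums(pfm$counts) == 1))
})

test_that("a PFM built from planted sites recovers the planted consensus", {
  set.seed(74)
  motif <- "GCGTAAC"   # no 7-mer shared with its reverse complement
  seqs <- vapply(1:40, function(i) {
    bg <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    at <- sample(10:40, 1)
    s <- paste(bg, collapse = "")
    substr(s, at, at + nchar(motif) - 1) <- motif
    s
  }, character(1))
  ctl <- vapply(1:40, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  res <- kmer_enrichment(seqs, ctl)
  expect_equal(res$kmer[1], motif)
  pfm <- build_pfm(Biostrings::DNAStringSet(seqs), res$kmer[1], width = 11)
  # the planted heptamer (or its reverse complement) forms the consensus
  # core; the two random flank columns degenerate
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  hit <- grepl(motif, pfm$consensus, fixed = TRUE) ||
    grepl(rc, pfm$consensus, fixed = TRUE)
  expect_true(hit)
  expect_gte(pfm$n_sites, 40)
  # MEME minimal export is parseable and sums to one per row
  path <- tempfile(fileext = ".meme")
  write_meme(pfm, path)
  txt <- readLines(path)
  expect_true(any(grepl("^MOTIF ", txt)))
  rows <- txt[grepl("^[0-9]", txt)]
  expect_equal(length(rows), pfm$width)
  sums <- vapply(strsplit(rows, " +"),
                 function(rr) sum(as.numeric(rr)), numeric(1))
  expect_equal(sums, rep(1, pfm$width), tolerance = 1e-4)
})

test_that("motif density profiles peak at planted positions", {
  set.seed(76)
  bg <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
              collapse = "")
  mids <- seq(3000, 57000, by = 3000)
  for (m in mids) substr(bg, m - 3, m + 3) <- "GATTACA"
  genome <- list(chr1 = bg)
  clusters <- gr("chr1", mids - 100, mids + 100)
  prof <- motif_density_profile("GATTACA", list(planted = clusters), genome,
                                flank = 300)
  pos <- as.integer(colnames(prof))
  expect_equal(pos[which.max(prof["planted", ])], -3)
  # far from the planted sites the density is at background level
  expect_lt(mean(prof[, abs(pos) > 50]), 0.05)
  expect_error(motif_density_profile("GATTACA", list(), genome), "empty")
})
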
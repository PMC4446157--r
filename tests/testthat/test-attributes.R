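toy_event_table <- function() {
  # six events: two regulated pass all filters, two fail one filter each,
  # one overlaps a non-regulated event, one non-regulated control
  ev <- do.call(rbind, lapply(1:6, function(i) {
    make_event(event_id = sprintf("e%d", i), e1_start = 5000 + 10000 * i)
  }))
  ev$label <- c("inclusion", "skipping", "inclusion", "skipping",
                "inclusion", "non_regulated")
  ev$fold_change <- c(3.0, 2.5, 1.2, 3.0, 2.0, 1.1)   # e3 fails fold-change
  ev$expr_pvalue <- c(0.5, 0.9, 0.5, 0.005, 0.5, 0.8) # e4 fails expression
  ev$overlaps_nonreg <- c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  ev
}

test_that("event selection applies the array filters and balances classes", {
  ev <- toy_event_table()
  sel <- select_events(ev)
  # hand-applied filters: e1 and e2 survive, one per class; e6 is the
  # non-regulated control
  expect_setequal(sel$regulated$event_id, c("e1", "e2"))
  expect_equal(nrow(sel$non_regulated), 1)
  expect_equal(sel$non_regulated$event_id, "e6")
  # all below fold-change -> empty regulated set
  ev2 <- ev
  ev2$fold_change[ev2$label != "non_regulated"] <- 1.2
  sel2 <- select_events(ev2, n_per_class = 0)
  expect_equal(nrow(sel2$regulated), 0)
  # requesting more than available errors with counts
  expect_error(select_events(ev, n_per_class = 5), "inclusion")
})

test_that("majority-class subsampling is balanced and seed-deterministic", {
  set.seed(99)
  ev <- do.call(rbind, lapply(1:30, function(i) {
    make_event(event_id = sprintf("e%02d", i), e1_start = 5000 + 10000 * i,
               label = if (i <= 20) "skipping" else "inclusion")
  }))
  s1 <- select_events(ev, seed = 7)
  s2 <- select_events(ev, seed = 7)
  s3 <- select_events(ev, seed = 8)
  expect_equal(as.vector(table(s1$regulated$label)), c(10, 10))
  expect_identical(s1$regulated$event_id, s2$regulated$event_id)
  expect_false(identical(s1$regulated$event_id, s3$regulated$event_id))
})

fake_reads <- function(signals, conditions = c("A", "B")) {
  out <- list()
  set.seed(17)
  for (s in signals) {
    out[[s]] <- list()
    for (cond in conditions) {
      starts <- sort(sample.int(200000, 250))
      out[[s]][[cond]] <- gr("chr1", starts, starts + 199)
    }
  }
  out
}

test_that("the attribute matrix is signals x 15 windows wide", {
  signals <- c("AGO1", "CTCF", "H3K27me3", "H3K9me2", "H3K36me3",
               "RNAPII", "HP1", "5metC")
  ev <- rbind(make_event("e1", e1_start = 15001),
              make_event("e2", e1_start = 55001, label = "skipping"))
  am <- build_attribute_matrix(ev, fake_reads(signals))
  expect_equal(ncol(am$x), 120)
  expect_equal(nrow(am$x), 2)
  expect_true(all(c("HP1-w5", "CTCF-I2", "AGO1-J2", "5metC-E3")
                  %in% colnames(am$x)))
  expect_true(all(is.finite(am$x)))
  # one signal -> 15 columns
  am1 <- build_attribute_matrix(ev, fake_reads("HP1"))
  expect_equal(ncol(am1$x), 15)
  # zero events -> empty matrix with the full header
  am0 <- build_attribute_matrix(ev[0, ], fake_reads(signals))
  expect_equal(dim(am0$x), c(0, 120))
  # missing condition is an error naming the signal
  broken <- fake_reads(signals)
  broken$HP1$B <- NULL
  expect_error(build_attribute_matrix(ev, broken), "HP1")
})

test_that("correlation summaries flag cross-signal pairs only", {
  set.seed(31)
  n <- 400
  base <- rnorm(n)
  x <- cbind(`HP1-w5` = base + rnorm(n, sd = 0.6),
             `CTCF-I2` = 0.8 * base + rnorm(n, sd = 0.6),
             `HP1-w1` = base + rnorm(n, sd = 0.3),
             `AGO1-w5` = rnorm(n))
  am <- list(x = x, labels = factor(rep("inclusion", n)))
  res <- pairwise_correlations(am, high = 0.6, low = -0.5)
  expect_equal(diag(res$cor), rep(1, 4), ignore_attr = TRUE)
  # planted rho = 0.8-ish cross-signal pair is recovered near its value
  got <- res$flagged[res$flagged$attr_a == "HP1-w5" &
                       res$flagged$attr_b == "CTCF-I2", ]
  expect_equal(nrow(got), 1)
  expect_lt(abs(got$r - cor(x[, 1], x[, 2])), 1e-12)
  # the strong HP1-w5 / HP1-w1 pair is same-signal, hence not flagged
  expect_false(any(res$flagged$attr_a == "HP1-w5" &
                     res$flagged$attr_b == "HP1-w1"))
  # an attribute against its own negation is perfectly anti-correlated
  x2 <- cbind(`A-w1` = base, `B-w1` = -base)
  res2 <- pairwise_correlations(list(x = x2, labels = am$labels))
  expect_equal(res2$cor["A-w1", "B-w1"], -1)
  expect_equal(nrow(res2$flagged), 1)
})

test_that("density profiles anchor at the 5' splice site of E2", {
  ev <- make_event(e1_start = 5001, exon = 100, intron = 800)
  # anchor = E2 donor at 6000; plant reads 200 nt downstream
  reads <- gr("chr1", rep(6181, 40), rep(6220, 40))
  prof <- density_profile(reads, ev, flank = 600)
  peak <- as.integer(colnames(prof)[which.max(prof[1, ])])
  expect_gte(peak, 181); expect_lte(peak, 220)
  # uniform coverage gives a flat profile
  flat <- gr("chr1", 1, 20000)
  pf <- density_profile(flat, ev, flank = 600)
  expect_true(all(pf == 1))
  # reads strictly downstream leave the upstream half empty
  expect_true(all(prof[1, as.integer(colnames(prof)) < 180] == 0))
  # minus-strand events are reported in transcript orientation
  evm <- make_event(strand = "-")
  anchor_m <- evm$E2_start  # genomic start = transcript donor on minus
  reads_m <- gr("chr1", rep(anchor_m - 220, 40), rep(anchor_m - 181, 40))
  prof_m <- density_profile(reads_m, evm, flank = 600)
  peak_m <- as.integer(colnames(prof_m)[which.max(prof_m[1, ])])
  expect_gte(peak_m, 181); expect_lte(peak_m, 220)
})

test_that("first/second-exon events are excluded from profiles when flagged", {
  ev <- rbind(make_event("e1"), make_event("e2", e1_start = 50001))
  ev$first_or_second <- c(FALSE, TRUE)
  reads <- gr("chr1", 1, 100000)
  prof <- density_profile(reads, ev, flank = 100,
                          groups = factor(c("g", "g")))
  # only e1 contributes: mean stays 1 (not diluted by absent group rows)
  expect_true(all(prof == 1))
})

test_that("attribute matrices round-trip through TSV and export to ARFF", {
  ev <- rbind(make_event("e1", e1_start = 15001),
              make_event("e2", e1_start = 55001, label = "skipping"))
  am <- build_attribute_matrix(ev, fake_reads(c("HP1", "CTCF")))
  tsv <- tempfile(fileext = ".tsv")
  write_attribute_matrix(am, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(as.matrix(back[, -(1:2)]), am$x, ignore_attr = TRUE)
  arff <- tempfile(fileext = ".arff")
  write_arff(am, arff)
  txt <- readLines(arff)
  expect_true(any(grepl("@relation", txt)))
  expect_equal(sum(grepl("@attribute", txt)), 31)  # 30 features + class
})
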
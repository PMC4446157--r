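test_that("MDL discretization cuts separated classes and resists noise", {
  set.seed(51)
  # well-separated bimodal attribute: exactly one cut, in the gap;
  # brute-force entropy check that the gap is the best single cut
  v <- c(rnorm(60, 0), rnorm(60, 6))
  y <- rep(c("inclusion", "skipping"), each = 60)
  cuts <- discretize_mdl(v, y)
  expect_equal(length(cuts), 1)
  expect_gt(cuts, max(v[1:60]) - 1e-9)
  expect_lt(cuts, min(v[61:120]) + 1e-9)
  # brute force: entropy of the 2-bin split at every midpoint
  sv <- sort(v)
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  ent <- vapply(mids, function(m) {
    left <- table(factor(y[v < m], levels = unique(y)))
    right <- table(factor(y[v >= m], levels = unique(y)))
    (sum(left) * chromsplice:::entropy_counts(left) +
       sum(right) * chromsplice:::entropy_counts(right)) / length(v)
  }, numeric(1))
  expect_equal(cuts, mids[which.min(ent)])
  # labels independent of values: no accepted cut
  set.seed(52)
  v2 <- rnorm(200); y2 <- sample(rep(c("inclusion", "skipping"), 100))
  expect_equal(length(discretize_mdl(v2, y2)), 0)
  # constant attribute: no cut possible
  expect_equal(length(discretize_mdl(rep(1, 50),
                                     rep(c("a", "b"), 25))), 0)
  expect_error(discretize_mdl(rnorm(10), rep("a", 10)), "two classes")
})

test_that("information gain matches hand entropy computations", {
  # balanced binary labels with a perfect 2-bin separator: 1 bit
  y <- rep(c("inclusion", "skipping"), each = 50)
  bins <- rep(c(1, 2), each = 50)
  expect_equal(information_gain(bins, y), 1.0)
  # independent attribute: 0 bits
  expect_equal(information_gain(rep(1, 100), y), 0)
  # counts [[8,2],[2,8]] by bin: hand-computed conditional entropy
  bins2 <- rep(c(1, 2), each = 10)
  y2 <- c(rep("a", 8), rep("b", 2), rep("a", 2), rep("b", 8))
  h <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  want <- h(c(0.5, 0.5)) - (0.5 * h(c(0.8, 0.2)) + 0.5 * h(c(0.2, 0.8)))
  expect_equal(information_gain(bins2, y2), want)
  # IG is invariant under strictly monotone transforms of the attribute
  set.seed(53)
  v <- rnorm(200); y3 <- ifelse(v + rnorm(200, sd = 0.5) > 0, "a", "b")
  ig1 <- information_gain(chromsplice:::apply_cuts(v, discretize_mdl(v, y3)), y3)
  v_t <- exp(v)  # monotone
  ig2 <- information_gain(chromsplice:::apply_cuts(v_t, discretize_mdl(v_t, y3)), y3)
  expect_equal(ig1, ig2)
})

test_that("IG ranking breaks ties lexicographically", {
  set.seed(54)
  x <- cbind(zeta = rnorm(100), alpha = rnorm(100),
             sig = c(rnorm(50, 0), rnorm(50, 4)))
  y <- rep(c("inclusion", "skipping"), each = 50)
  r <- rank_information_gain(x, y)
  expect_equal(r$attribute[r$ig_rank == 1], "sig")
  # both noise attributes have IG 0; alpha ranks before zeta
  expect_equal(r$ig_rank[r$attribute == "alpha"], 2)
  expect_equal(r$ig_rank[r$attribute == "zeta"], 3)
})

test_that("the CFS merit equals the printed formula on a 3-attribute toy", {
  r_cf <- c(0.8, 0.6, 0.4)
  r_ff <- 0.3
  k <- 3
  want <- k * mean(r_cf) / sqrt(k + k * (k - 1) * r_ff)
  expect_equal(cfs_merit(r_cf, r_ff), want)
  expect_equal(cfs_merit(0.7), 0.7)      # singleton: no redundancy term
  expect_equal(cfs_merit(numeric(0)), 0)
})

fs_matrix <- function(n = 120, seed = 55, informative = TRUE) {
  set.seed(seed)
  y <- rep(c("inclusion", "skipping"), each = n / 2)
  x <- matrix(rnorm(n * 10), ncol = 10,
              dimnames = list(NULL, sprintf("S%d-w%d", rep(1:2, 5), 1:5)))
  if (informative) x[, 1] <- ifelse(y == "inclusion", 1.6, -1.6) + rnorm(n)
  list(x = x, y = y)
}

test_that("CFS frequency finds a planted predictive attribute", {
  d <- fs_matrix()
  freq <- cfs_select(d$x, d$y, folds = 10, seed = 2)
  expect_equal(freq$cfs_freq[1], 1.0)
  expect_true(all(freq$cfs_freq[-1] <= 0.3))
  # two identical predictive attributes: the pair is redundant, so the
  # combined frequency stays high but both together are rarely kept
  d2 <- fs_matrix()
  d2$x[, 2] <- d2$x[, 1]
  freq2 <- cfs_select(d2$x, d2$y, folds = 10, seed = 2)
  expect_gte(max(freq2$cfs_freq[1:2]), 0.5)
  # pure noise: nothing selected often
  d3 <- fs_matrix(informative = FALSE)
  freq3 <- cfs_select(d3$x, d3$y, folds = 10, seed = 2)
  expect_true(all(freq3$cfs_freq <= 0.5))
})

test_that("wrapper selection is seeded-deterministic and finds the signal", {
  d <- fs_matrix(n = 60, seed = 56)
  w1 <- wse_select(d$x, d$y, folds = 5, inner_folds = 3, rounds = 3,
                   ga = list(pop = 10, generations = 5, p_cross = 0.6,
                             p_mut = 0.033), seed = 4)
  w2 <- wse_select(d$x, d$y, folds = 5, inner_folds = 3, rounds = 3,
                   ga = list(pop = 10, generations = 5, p_cross = 0.6,
                             p_mut = 0.033), seed = 4)
  expect_identical(w1, w2)
  expect_gte(w1$wse_freq[1], 0.8)
})

test_that("combining the selectors applies thresholds and redundancy pruning", {
  scores <- data.frame(
    attribute = c("HP1-w5", "HP1-I2", "CTCF-w1", "AGO1-E2", "RNAPII-J1"),
    ig = c(0.5, 0.3, 0.2, 0.15, 0.01),
    ig_rank = 1:5,
    cfs_freq = c(0.9, 0.8, 0.6, 0.4, 0.9),
    wse_freq = c(0.8, 0.7, 0.4, 0.9, 0.9))
  res <- combine_selection(scores, freq_min = 0.5, ig_top = 0.5)
  sel <- res$attribute[res$selected]
  # HP1-w5 passes everything; HP1-I2 passes but its window overlaps w5's
  # for the same signal and has lower IG, so it is pruned
  expect_true("HP1-w5" %in% sel)
  expect_false("HP1-I2" %in% sel)
  # CTCF-w1 fails wse, AGO1-E2 fails cfs, RNAPII-J1 fails the IG-top rule
  # (rank 5 of 5 > ceiling(0.5 * 5) = 3)
  expect_false(any(c("CTCF-w1", "AGO1-E2", "RNAPII-J1") %in% sel))
  # same signal, non-overlapping windows: both survive
  scores2 <- data.frame(
    attribute = c("HP1-w5", "HP1-w1", "A-x", "B-x"),
    ig = c(0.5, 0.4, 0, 0), ig_rank = 1:4,
    cfs_freq = c(1, 1, 0, 0), wse_freq = c(1, 1, 0, 0))
  res2 <- combine_selection(scores2)
  expect_setequal(res2$attribute[res2$selected], c("HP1-w5", "HP1-w1"))
})

test_that("the canonical window-overlap map reflects the geometry", {
  m <- window_overlap_map()
  expect_true(m["w5", "I2"]); expect_true(m["I2", "w5"])
  expect_true(m["J2", "E2"]); expect_true(m["J2", "I1"])
  expect_true(m["E2", "E2"])
  expect_false(m["w5", "I1"]); expect_false(m["E1", "E3"])
  expect_false(m["w1", "I1"])
  expect_true(isSymmetric(m))
})
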
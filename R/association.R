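#' One-sided overlap proportions between two cluster sets
#'
#' Fraction of A clusters touching (>= 1 nt) at least one B cluster, and
#' the converse.  The two proportions are independent quantities: a small
#' set A can lie almost entirely inside a large set B while only a tiny
#' fraction of B is covered by A.
#'
#' @param set_a,set_b `GRanges` cluster sets.
#' @return list with `prop_a_in_b` and `prop_b_in_a`.
#' @export
overlap_proportion <- function(set_a, set_b) {
  list(
    prop_a_in_b = if (length(set_a) == 0) 0 else
      mean(overlapsAny(set_a, set_b, ignore.strand = TRUE)),
    prop_b_in_a = if (length(set_b) == 0) 0 else
      mean(overlapsAny(set_b, set_a, ignore.strand = TRUE)))
}

#' Block-bootstrap z-score of the overlap between two annotations
#'
#' The observed statistic is the total base-pair overlap of sets A and B
#' within the given regions (or, with `stat = "count"`, the number of A
#' clusters touching B).  The null distribution is obtained by `n`
#' bootstrap replicates in which, within each region independently, A's
#' occupancy track is resampled in contiguous blocks spanning a fraction
#' `r` of the region (preserving A's local clustering structure while
#' breaking its alignment with B).  The z-score is the number of null
#' standard deviations the observation lies above the null mean.
#'
#' @param set_a,set_b `GRanges`; both are restricted to `regions`.
#' @param regions `GRanges` of mappable regions within which the
#'   resampling is done.
#' @param r block fraction of each region (default 0.1).
#' @param n number of bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param stat `"bp"` (base-pair overlap, default) or `"count"`.
#' @return list with `zscore`, `observed`, `null_mean`, `null_sd`, `n`,
#'   `r`.
#' @export
block_bootstrap_z <- function(set_a, set_b, regions, r = 0.1, n = 10000,
                              seed = 1L, stat = c("bp", "count")) {
  stat <- match.arg(stat)
  if (n < 2) stop("need at least 2 bootstrap replicates for a defined sd")
  set.seed(seed)
  null_stats <- matrix(0, nrow = n, ncol = length(regions))
  observed <- 0
  for (ri in seq_along(regions)) {
    reg <- regions[ri]
    a <- occupancy_vector(set_a, reg)
    b <- occupancy_vector(set_b, reg)
    if (stat == "bp") {
      observed <- observed + sum(a & b)
    } else {
      observed <- observed + count_runs_hit(a, b)
    }
    bl <- max(1L, as.integer(round(r * width(reg))))
    boot <- block_boot_region_cpp(a, b, bl, n, stat == "count")
    null_stats[, ri] <- if (stat == "bp") boot$bp else boot$count
  }
  null_tot <- rowSums(null_stats)
  null_sd <- sd(null_tot)
  if (is.na(null_sd) || null_sd == 0) {
    stop("degenerate null distribution (sd = 0); ",
         "enlarge the regions or the cluster sets")
  }
  list(zscore = (observed - mean(null_tot)) / null_sd,
       observed = observed, null_mean = mean(null_tot),
       null_sd = null_sd, n = n, r = r, stat = stat)
}

# 0/1 occupancy of gr over a single region, as an integer vector.
occupancy_vector <- function(gr, region) {
  L <- width(region)
  v <- integer(L)
  hits <- restrict_to_region(gr, region)
  if (length(hits) > 0) {
    s <- pmax(start(hits) - start(region) + 1L, 1L)
    e <- pmin(end(hits) - start(region) + 1L, L)
    for (i in seq_along(s)) v[s[i]:e[i]] <- 1L
  }
  v
}

restrict_to_region <- function(gr, region) {
  gr <- gr[seqnames(gr) == as.character(seqnames(region))]
  gr[start(gr) <= end(region) & end(gr) >= start(region)]
}

# number of maximal runs of a that touch >= 1 base of b
count_runs_hit <- function(a, b) {
  r <- rle(a)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values == 1L)
  sum(vapply(runs, function(q) any(b[starts[q]:ends[q]] == 1L), logical(1)))
}

#' Randomize cluster positions within chromosomes
#'
#' Relocates each cluster to a uniformly random position on its own
#' chromosome, preserving its length, avoiding the exclusion regions and
#' any overlap with previously placed random clusters.  Placement is
#' rejected-and-retried; an error names the first cluster that cannot be
#' placed.
#'
#' @param clusters `GRanges`.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param exclusions `GRanges` of regions to avoid (may be empty).
#' @param seed RNG seed.
#' @param max_retries retries per cluster before giving up (default 1000).
#' @return `GRanges` of relocated clusters (same order, same widths).
#' @export
randomize_clusters <- function(clusters, chrom_sizes,
                               exclusions = GRanges(), seed = 1L,
                               max_retries = 1000) {
  set.seed(seed)
  chroms <- as.character(seqnames(clusters))
  widths <- width(clusters)
  ex_chrom <- as.character(seqnames(exclusions))
  ex_s <- start(exclusions); ex_e <- end(exclusions)
  # per-chromosome bookkeeping in plain vectors for speed
  placed_s <- list(); placed_e <- list()
  out_start <- integer(length(clusters))
  for (i in seq_along(clusters)) {
    chr <- chroms[i]; w <- widths[i]
    if (!chr %in% names(chrom_sizes)) stop("no size for chromosome ", chr)
    L <- chrom_sizes[[chr]]
    if (w > L) stop("cluster ", i, " longer than its chromosome")
    exi <- which(ex_chrom == chr)
    ps <- placed_s[[chr]]; pe <- placed_e[[chr]]
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      s <- sample.int(L - w + 1L, 1L)
      e <- s + w - 1L
      if (length(exi) > 0 && any(s <= ex_e[exi] & ex_s[exi] <= e)) next
      if (length(ps) > 0 && any(s <= pe & ps <= e)) next
      placed_s[[chr]] <- c(ps, s); placed_e[[chr]] <- c(pe, e)
      out_start[i] <- s
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("could not place randomized cluster ", i, " (", chr, ", width ",
           w, ") after ", max_retries, " retries")
    }
  }
  GRanges(seqnames(clusters), IRanges(out_start, width = widths),
          strand = strand(clusters))
}

#' Mean density of one cluster set around the midpoints of another
#'
#' Per-position mean coverage of the query clusters in a window centered
#' at each anchor-cluster midpoint, together with the same profile for a
#' randomized relocation of the query set (the null).
#'
#' @param query,anchors `GRanges` cluster sets.
#' @param flank half-window in nt (default 1000).
#' @param chrom_sizes named lengths, required for the randomized null.
#' @param exclusions passed to [randomize_clusters()].
#' @param seed seed for the null relocation.
#' @param null compute the randomized-null profile too (default `TRUE`).
#' @return list with `position` (-flank..flank), `observed` and
#'   (optionally) `randomized` mean-coverage vectors.
#' @export
cluster_density_profile <- function(query, anchors, flank = 1000,
                                    chrom_sizes = NULL,
                                    exclusions = GRanges(), seed = 1L,
                                    null = TRUE) {
  if (length(anchors) == 0) stop("empty anchor set")
  prof <- midpoint_profile(query, anchors, flank)
  out <- list(position = seq(-flank, flank), observed = prof)
  if (null) {
    if (is.null(chrom_sizes)) stop("chrom_sizes required for the null")
    rnd <- randomize_clusters(query, chrom_sizes, exclusions, seed)
    out$randomized <- midpoint_profile(rnd, anchors, flank)
  }
  out
}

midpoint_profile <- function(query, anchors, flank) {
  cov <- coverage(query)
  mids <- floor((start(anchors) + end(anchors)) / 2)
  acc <- numeric(2 * flank + 1)
  for (i in seq_along(anchors)) {
    chr <- as.character(seqnames(anchors[i]))
    prof <- numeric(2 * flank + 1)
    if (chr %in% names(cov)) {
      v <- cov[[chr]]
      idx <- seq(mids[i] - flank, mids[i] + flank)
      ok <- idx >= 1 & idx <= length(v)
      prof[ok] <- as.numeric(v[idx[ok]])
    }
    acc <- acc + prof
  }
  acc / length(anchors)
}

#' Pairwise association report for several cluster sets
#'
#' Overlap proportions and block-bootstrap z-scores for every ordered
#' pair of cluster sets, in a long table.
#'
#' @param cluster_sets named list of `GRanges`.
#' @param regions mappable regions for [block_bootstrap_z()].
#' @param r,n,seed bootstrap parameters.
#' @return `data.frame` with `set_a`, `set_b`, `prop_a_in_b`,
#'   `prop_b_in_a`, `zscore`.
#' @export
association_report <- function(cluster_sets, regions, r = 0.1, n = 10000,
                               seed = 1L) {
  nm <- names(cluster_sets)
  pairs <- which(outer(seq_along(nm), seq_along(nm), "<"), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(q) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    pr <- overlap_proportion(cluster_sets[[i]], cluster_sets[[j]])
    z <- block_bootstrap_z(cluster_sets[[i]], cluster_sets[[j]], regions,
                           r = r, n = n, seed = seed + q)
    data.frame(set_a = nm[i], set_b = nm[j],
               prop_a_in_b = pr$prop_a_in_b, prop_b_in_a = pr$prop_b_in_a,
               zscore = z$zscore)
  })
  do.call(rbind, rows)
}
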
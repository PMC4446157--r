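#' Configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator with defaults emulating the
#' statistical structure of a two-cell-line ChIP-Seq / splicing-array
#' comparison: per-window read-density enrichment that differs by
#' splicing class, sample-versus-control coverage with a known
#' enrichment ratio, co-located versus independent cluster sets, and
#' sequences with planted heptamers.
#'
#' The default planted chromatin code mirrors the directionality of the
#' real one: HP1 (windows w5 and w1) and CTCF (intron I2) gain signal in
#' condition A on inclusion events; AGO1 (w5), RNAPII (w6) and H3K36me3
#' (exon-flanking w3/w4) gain signal in condition A on skipping events.
#'
#' @param seed integer seed; every generator takes its randomness from
#'   the configuration, so outputs are reproducible.
#' @param chrom_sizes named integer vector of chromosome lengths; by
#'   default sized to hold `n_inclusion + n_skipping + n_nonreg` events.
#' @param n_inclusion,n_skipping,n_nonreg events per class (defaults
#'   442, 442 and 1970).
#' @param exon_len,intron_len ranges (min, max) of exon and intron
#'   lengths in nt.
#' @param spacing_len range of the gap between consecutive events.
#' @param signals character vector of ChIP-Seq signal names (default the
#'   eight modelled signals).
#' @param conditions the two condition names (first = enriched side of
#'   positive z-scores).
#' @param background_rate background read rate, reads per kb per
#'   library (default 5, a typical genome-wide ChIP coverage).
#' @param read_len raw read length before extension (default 36 nt).
#' @param effects `data.frame` of planted effects with columns `signal`,
#'   `window`, `class`, `fold` — the condition-A rate multiplier applied
#'   in that window for events of that class; default
#'   [default_effects()].
#' @param cnf_ratio true sample:control rate ratio (default 2).
#' @param motif planted heptamer for sequence simulation.
#' @param motif_prob fraction of sample sequences carrying the motif.
#' @param colocation fraction of A clusters centered on B clusters in
#'   [simulate_cluster_pair()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = NULL,
                       n_inclusion = 442L, n_skipping = 442L,
                       n_nonreg = 1970L,
                       exon_len = c(100L, 250L),
                       intron_len = c(800L, 3000L),
                       spacing_len = c(2000L, 5000L),
                       signals = c("AGO1", "CTCF", "H3K27me3", "H3K9me2",
                                   "H3K36me3", "RNAPII", "HP1", "5metC"),
                       conditions = c("A", "B"),
                       background_rate = 5,
                       read_len = 36L,
                       effects = default_effects(),
                       cnf_ratio = 2,
                       motif = "GATTACA",
                       motif_prob = 0.5,
                       colocation = 0.4) {
  n_events <- n_inclusion + n_skipping + n_nonreg
  if (is.null(chrom_sizes)) {
    # room for all events at maximal geometry, split over two chromosomes
    per_event <- 3 * exon_len[2] + 2 * intron_len[2] + spacing_len[2]
    half <- ceiling(n_events / 2) * per_event + 10000
    chrom_sizes <- c(chr1 = half, chr2 = half)
  }
  structure(list(seed = seed, chrom_sizes = chrom_sizes,
                 n_inclusion = n_inclusion, n_skipping = n_skipping,
                 n_nonreg = n_nonreg, exon_len = exon_len,
                 intron_len = intron_len, spacing_len = spacing_len,
                 signals = signals, conditions = conditions,
                 background_rate = background_rate, read_len = read_len,
                 effects = effects, cnf_ratio = cnf_ratio,
                 motif = motif, motif_prob = motif_prob,
                 colocation = colocation),
            class = "sim_config")
}

#' Default planted chromatin-code effects
#'
#' @param fold rate multiplier in condition A for the affected class
#'   (default 4).
#' @return `data.frame` with columns `signal`, `window`, `class`, `fold`.
#' @export
default_effects <- function(fold = 4) {
  data.frame(
    signal = c("HP1", "HP1", "CTCF", "AGO1", "RNAPII", "H3K36me3", "H3K36me3"),
    window = c("w5", "w1", "I2", "w5", "w6", "w3", "w4"),
    class = c("inclusion", "inclusion", "inclusion",
              "skipping", "skipping", "skipping", "skipping"),
    fold = fold,
    stringsAsFactors = FALSE)
}

#' Simulate a cassette-event table
#'
#' Places non-overlapping exon triplets along the configured chromosomes
#' on alternating strands and fills the array-statistic columns
#' consistently with the labels: regulated events get a fold-change
#' above 1.5 and an expression p-value above 0.01; non-regulated events
#' get a fold-change at or below 1.5.
#'
#' @param config a [sim_config()].
#' @return event `data.frame` as accepted by the pipeline (1-based
#'   closed coordinates; see [read_events()]).
#' @export
simulate_events <- function(config) {
  set.seed(config$seed)
  n <- config$n_inclusion + config$n_skipping + config$n_nonreg
  labels <- sample(c(rep("inclusion", config$n_inclusion),
                     rep("skipping", config$n_skipping),
                     rep("non_regulated", config$n_nonreg)))
  chroms <- names(config$chrom_sizes)
  chrom <- chroms[rep_len(seq_along(chroms), n)]
  rint <- function(rng, m) {
    if (rng[1] == rng[2]) rep(rng[1], m) else
      sample(seq(rng[1], rng[2]), m, replace = TRUE)
  }
  e_len <- matrix(rint(config$exon_len, 3 * n), ncol = 3)
  i_len <- matrix(rint(config$intron_len, 2 * n), ncol = 2)
  gap <- rint(config$spacing_len, n)
  ev <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    idx <- which(chrom == chroms[ci])
    # leave room upstream for flanking windows
    cursor <- cumsum(c(1000, (rowSums(e_len) + rowSums(i_len) + gap)[idx]))
    s1 <- cursor[seq_along(idx)]
    ev[[ci]] <- data.frame(
      i = idx,
      E1_start = s1,
      E1_end = s1 + e_len[idx, 1] - 1L,
      E2_start = s1 + e_len[idx, 1] + i_len[idx, 1],
      E2_end = s1 + e_len[idx, 1] + i_len[idx, 1] + e_len[idx, 2] - 1L,
      E3_start = s1 + e_len[idx, 1] + i_len[idx, 1] + e_len[idx, 2] +
        i_len[idx, 2],
      E3_end = s1 + e_len[idx, 1] + i_len[idx, 1] + e_len[idx, 2] +
        i_len[idx, 2] + e_len[idx, 3] - 1L)
  }
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$i), , drop = FALSE]
  if (any(ev$E3_end > config$chrom_sizes[chrom])) {
    stop("chromosomes too short for the requested number of events")
  }
  reg <- labels != "non_regulated"
  out <- data.frame(
    event_id = sprintf("ev%05d", seq_len(n)),
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = chrom,
    strand = rep_len(c("+", "-"), n),
    ev[, -1],
    label = labels,
    fold_change = ifelse(reg, 1.5 + rexp(n, rate = 1), runif(n, 1, 1.5)),
    expr_pvalue = runif(n, 0.02, 1),
    first_or_second = FALSE,
    overlaps_nonreg = FALSE,
    stringsAsFactors = FALSE)
  validate_events(out)
  out
}

# Uniform background reads over the chromosomes at `rate` reads per kb.
poisson_reads <- function(chrom_sizes, rate, read_len) {
  per_chrom <- rpois(length(chrom_sizes), chrom_sizes / 1000 * rate)
  starts <- unlist(lapply(seq_along(chrom_sizes), function(ci) {
    sample.int(max(1L, chrom_sizes[[ci]] - read_len + 1L), per_chrom[ci],
               replace = TRUE)
  }))
  GRanges(rep(names(chrom_sizes), per_chrom),
          IRanges(starts, width = read_len),
          strand = sample(c("+", "-"), sum(per_chrom), replace = TRUE))
}

# Extra reads within given windows at `rate` reads per kb of window.
window_reads <- function(windows, rate, read_len) {
  m <- rpois(length(windows), width(windows) / 1000 * rate)
  tot <- sum(m)
  if (tot == 0) {
    return(GRanges())
  }
  wi <- rep(seq_along(windows), m)
  off <- floor(runif(tot) * pmax(1, width(windows)[wi] - read_len + 1))
  GRanges(seqnames(windows)[wi],
          IRanges(start(windows)[wi] + off, width = read_len),
          strand = sample(c("+", "-"), tot, replace = TRUE))
}

#' Simulate per-signal read sets with a planted chromatin code
#'
#' Background coverage is Poisson and uniform genome-wide in every
#' library.  For each planted effect `(signal, window, class, fold)` the
#' condition-A rate inside that window is multiplied by `fold` for
#' events of the target class.  Each condition also gets a control
#' library whose rate is the background rate divided by the true
#' normalization ratio `cnf_ratio`.
#'
#' @param events event table (typically [simulate_events()]).
#' @param config a [sim_config()].
#' @return nested list: `reads[[signal]][[condition]]` and
#'   `controls[[condition]]`, all `GRanges` of raw (unextended) reads,
#'   plus `totals[[signal]][[condition]]` library sizes.
#' @export
simulate_reads <- function(events, config) {
  set.seed(config$seed + 1L)
  win <- define_windows(events)
  reads <- list(); totals <- list()
  for (s in config$signals) {
    reads[[s]] <- list()
    totals[[s]] <- list()
    eff <- config$effects[config$effects$signal == s, , drop = FALSE]
    for (cond in config$conditions) {
      gr <- poisson_reads(config$chrom_sizes, config$background_rate,
                          config$read_len)
      if (cond == config$conditions[1] && nrow(eff) > 0) {
        for (q in seq_len(nrow(eff))) {
          target <- win[win$window == eff$window[q] &
                          win$event_id %in%
                          events$event_id[events$label == eff$class[q]]]
          extra <- window_reads(target,
                                (eff$fold[q] - 1) * config$background_rate,
                                config$read_len)
          if (length(extra) > 0) gr <- c(gr, extra)
        }
      }
      reads[[s]][[cond]] <- sort(gr)
      totals[[s]][[cond]] <- length(gr)
    }
  }
  controls <- list()
  for (cond in config$conditions) {
    controls[[cond]] <- sort(poisson_reads(
      config$chrom_sizes, config$background_rate / config$cnf_ratio,
      config$read_len))
  }
  list(reads = reads, controls = controls, totals = totals)
}

#' Simulate two cluster sets with controlled co-location
#'
#' Set B is placed uniformly on the chromosomes; a fraction
#' `config$colocation` of the A clusters is centered on randomly chosen
#' B clusters and the remainder placed uniformly and independently.
#'
#' @param config a [sim_config()].
#' @param n_a,n_b cluster counts.
#' @param width_a,width_b cluster widths in nt.
#' @return list of `GRanges` `a` and `b`.
#' @export
simulate_cluster_pair <- function(config, n_a = 200L, n_b = 500L,
                                  width_a = 400L, width_b = 400L) {
  set.seed(config$seed + 2L)
  sizes <- config$chrom_sizes
  place <- function(m, w) {
    chr <- sample(names(sizes), m, replace = TRUE,
                  prob = sizes / sum(sizes))
    s <- floor(runif(m) * (sizes[chr] - w)) + 1L
    GRanges(chr, IRanges(s, width = w))
  }
  b <- place(n_b, width_b)
  n_co <- rbinom(1, n_a, config$colocation)
  a_unif <- place(n_a - n_co, width_a)
  host <- sample.int(n_b, n_co, replace = TRUE)
  mid <- floor((start(b[host]) + end(b[host])) / 2)
  a_co <- GRanges(seqnames(b[host]),
                  IRanges(pmax(1L, mid - floor(width_a / 2)),
                          width = width_a))
  list(a = sort(c(a_unif, a_co)), b = sort(b))
}

#' Simulate sample and control sequence sets with a planted motif
#'
#' Background sequences are i.i.d. uniform over ACGT; the configured
#' motif is inserted at a uniform position in a fraction `motif_prob` of
#' the sample sequences.  The control set carries no insertion.
#'
#' @param config a [sim_config()].
#' @param n_sample,n_control sequence counts.
#' @param length sequence length in nt.
#' @return list of `DNAStringSet`s `sample` and `control`, plus
#'   `planted` (logical, which sample sequences carry the motif).
#' @export
simulate_motif_sequences <- function(config, n_sample = 200L,
                                     n_control = 200L, length = 200L) {
  set.seed(config$seed + 3L)
  rand_seq <- function(m) {
    vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
  }
  smp <- rand_seq(n_sample)
  ctl <- rand_seq(n_control)
  planted <- runif(n_sample) < config$motif_prob
  mlen <- nchar(config$motif)
  for (i in which(planted)) {
    at <- sample.int(length - mlen + 1L, 1L)
    substr(smp[i], at, at + mlen - 1L) <- config$motif
  }
  list(sample = Biostrings::DNAStringSet(smp),
       control = Biostrings::DNAStringSet(ctl),
       planted = planted)
}

#' Write a simulated dataset to disk
#'
#' Events as TSV, reads and controls as BED6, chromosome sizes as TSV
#' and the configuration snapshot as YAML, for provenance.
#'
#' @param sim result of [simulate_reads()].
#' @param events event table.
#' @param config the [sim_config()] used.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, events, config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(events, file.path(dir, "events.tsv"))
  for (s in names(sim$reads)) {
    for (cond in names(sim$reads[[s]])) {
      write_bed(sim$reads[[s]][[cond]],
                file.path(dir, sprintf("reads_%s_%s.bed", s, cond)))
    }
  }
  for (cond in names(sim$controls)) {
    write_bed(sim$controls[[cond]],
              file.path(dir, sprintf("control_%s.bed", cond)))
  }
  write.table(data.frame(names(config$chrom_sizes), config$chrom_sizes),
              file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cfg <- config
  cfg$effects <- as.list(cfg$effects)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Simulate an attribute matrix with planted informative attributes
#'
#' Generates the z-score matrix directly, bypassing the read level: all
#' attributes are standard-normal noise except the planted ones, which
#' are shifted by `+delta` for inclusion events and `-delta` for
#' skipping events.  A per-event separation of `2 * delta = 1.5` is
#' comparable to what the read-level generator's four-fold window
#' effects produce after cluster restriction and z-scoring.  Used to
#' calibrate the feature-selection stage, where effects confined to
#' exactly one attribute are needed (read-level planting necessarily
#' bleeds into genomically overlapping windows).
#'
#' @param n_events events (balanced inclusion/skipping; default 120).
#' @param planted attribute names carrying signal (default three
#'   attributes of three different signals in non-overlapping windows).
#' @param delta per-class mean shift (default 0.75).
#' @param signals signal names for the column naming (8 signals x 15
#'   windows = 120 attributes).
#' @param permute_labels permute the labels after planting (the
#'   negative control; default `FALSE`).
#' @param seed RNG seed.
#' @return list with `x` (matrix) and `labels` (factor).
#' @export
simulate_attribute_matrix <- function(n_events = 120,
                                      planted = c("HP1-w5", "CTCF-I2",
                                                  "AGO1-w1"),
                                      delta = 0.75,
                                      signals = c("AGO1", "CTCF",
                                                  "H3K27me3", "H3K9me2",
                                                  "H3K36me3", "RNAPII",
                                                  "HP1", "5metC"),
                                      permute_labels = FALSE, seed = 1L) {
  set.seed(seed)
  wins <- c(paste0("w", 1:6), paste0("J", 1:4), "E1", "E2", "E3",
            "I1", "I2")
  cols <- as.vector(t(outer(signals, wins, paste, sep = "-")))
  stopifnot(all(planted %in% cols), n_events %% 2 == 0)
  x <- matrix(rnorm(n_events * length(cols)), ncol = length(cols),
              dimnames = list(NULL, cols))
  y <- rep(c("inclusion", "skipping"), each = n_events / 2)
  for (a in planted) {
    x[, a] <- x[, a] + ifelse(y == "inclusion", delta, -delta)
  }
  if (permute_labels) y <- sample(y)
  list(x = x, labels = factor(y), planted = planted)
}
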
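#' Select and label cassette events from array statistics
#'
#' Applies the array-based filters that define the regulated event set:
#' average probe fold-change above `fold_change_min` in either direction,
#' host gene not changing expression (expression log2-fold-change p-value
#' above `expr_pvalue_min`), and no overlap with a non-regulated event.
#' The two regulated classes are then balanced by seeded subsampling of
#' the majority class.  Non-regulated events are exon triplets from the
#' same host genes that are array-negative and do not overlap regulated
#' events.
#'
#' @param events event `data.frame` with columns `label` (`inclusion`,
#'   `skipping` or `non_regulated`), `fold_change` (linear, `>= 1`),
#'   `expr_pvalue`, and optionally `overlaps_nonreg` (logical).
#' @param fold_change_min minimum array fold-change for a regulated event
#'   (default 1.5, exclusive).
#' @param expr_pvalue_min events in genes with expression-change p-value
#'   at or below this are dropped (default 0.01, i.e. only stably
#'   expressed genes are kept).
#' @param n_per_class events per regulated class after balancing; default
#'   the minority class size.
#' @param seed seed for the majority-class subsample.
#' @return list with `regulated` (balanced, labels `inclusion`/`skipping`)
#'   and `non_regulated` event `data.frame`s.
#' @export
select_events <- function(events, fold_change_min = 1.5,
                          expr_pvalue_min = 0.01, n_per_class = NULL,
                          seed = 1L) {
  need <- c("label", "fold_change", "expr_pvalue")
  miss <- setdiff(need, names(events))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  nonreg <- events[events$label == "non_regulated", , drop = FALSE]
  reg <- events[events$label %in% c("inclusion", "skipping"), , drop = FALSE]
  keep <- reg$fold_change > fold_change_min & reg$expr_pvalue > expr_pvalue_min
  if ("overlaps_nonreg" %in% names(reg)) keep <- keep & !reg$overlaps_nonreg
  reg <- reg[keep, , drop = FALSE]
  counts <- table(factor(reg$label, levels = c("inclusion", "skipping")))
  if (is.null(n_per_class)) n_per_class <- min(counts)
  if (any(counts < n_per_class)) {
    stop(sprintf(
      "cannot balance to %d per class: %d inclusion, %d skipping available",
      n_per_class, counts[["inclusion"]], counts[["skipping"]]))
  }
  set.seed(seed)
  pick <- unlist(lapply(c("inclusion", "skipping"), function(cl) {
    idx <- which(reg$label == cl)
    if (length(idx) > n_per_class) sort(sample(idx, n_per_class)) else idx
  }))
  list(regulated = reg[sort(pick), , drop = FALSE], non_regulated = nonreg)
}

#' Build the event-by-attribute z-score matrix
#'
#' For every ChIP-Seq signal and every one of the fifteen windows of each
#' event, densities in the two conditions are converted to a
#' relative-enrichment z-score ([enrichment_zscore()]); the background set
#' for standardization is the full collection of (event, window) pairs of
#' that signal.  With `s` signals this yields `s * 15` attributes per
#' event, named `"SIGNAL-window"` (e.g. `"HP1-w5"`, `"CTCF-I2"`).
#'
#' @param events event `data.frame`.
#' @param reads nested list `reads[[signal]][[condition]]` of `GRanges`;
#'   every signal must have both conditions.  Typically these are the
#'   reads restricted to significant clusters ([call_significant()]).
#' @param conditions character vector of the two condition names
#'   (default the names found in the first signal); z-scores are oriented
#'   so positive means enriched in `conditions[1]`.
#' @param totals optional list `totals[[signal]][[condition]]` of library
#'   sizes; default is the number of reads supplied (restricting reads to
#'   significant clusters does not change the library size, so pass the
#'   original totals when available).
#' @param flank,junction_half window geometry, see [define_windows()].
#' @param pseudocount see [enrichment_zscore()].
#' @return object of class `attribute_matrix`: list with `x` (numeric
#'   matrix, events by attributes), `events` (the event table), `labels`
#'   (factor, from `events$label`), `signals`, and `windows` (the
#'   per-event window `GRanges`).
#' @export
build_attribute_matrix <- function(events, reads, conditions = NULL,
                                   totals = NULL, flank = 300,
                                   junction_half = 100, pseudocount = 1) {
  stopifnot(nrow(events) >= 0, length(reads) >= 1)
  signals <- names(reads)
  if (is.null(conditions)) conditions <- names(reads[[1]])
  if (length(conditions) != 2) stop("exactly two conditions required")
  for (s in signals) {
    miss <- setdiff(conditions, names(reads[[s]]))
    if (length(miss) > 0) {
      stop("signal ", s, " lacks condition(s): ", paste(miss, collapse = ", "))
    }
  }
  win <- define_windows(events, flank = flank, junction_half = junction_half)
  wnames <- levels(win$window)
  cols <- as.vector(t(outer(signals, wnames, paste, sep = "-")))
  x <- matrix(0, nrow = nrow(events), ncol = length(cols),
              dimnames = list(events$event_id, cols))
  if (nrow(events) > 0) {
    for (s in signals) {
      tot_a <- if (!is.null(totals)) totals[[s]][[conditions[1]]] else
        max(1, length(reads[[s]][[conditions[1]]]))
      tot_b <- if (!is.null(totals)) totals[[s]][[conditions[2]]] else
        max(1, length(reads[[s]][[conditions[2]]]))
      da <- window_density(reads[[s]][[conditions[1]]], win, tot_a)
      db <- window_density(reads[[s]][[conditions[2]]], win, tot_b)
      z <- enrichment_zscore(da, db, pseudocount = pseudocount)
      # win is ordered window-major (15 blocks of n events)
      zm <- matrix(z, nrow = nrow(events))   # columns = windows
      x[, paste(s, wnames, sep = "-")] <- zm
    }
  }
  labels <- if ("label" %in% names(events)) {
    factor(events$label)
  } else {
    factor(rep(NA_character_, nrow(events)))
  }
  structure(list(x = x, events = events, labels = labels,
                 signals = signals, windows = win,
                 conditions = conditions),
            class = "attribute_matrix")
}

#' @export
print.attribute_matrix <- function(x, ...) {
  cat(sprintf("attribute matrix: %d events x %d attributes (%d signals x %d windows)\n",
              nrow(x$x), ncol(x$x), length(x$signals),
              nlevels(x$windows$window)))
  if (any(!is.na(x$labels))) print(table(x$labels))
  invisible(x)
}

#' Pairwise Pearson correlations between attributes
#'
#' Computes the symmetric Pearson correlation matrix of the attribute
#' z-scores for one class of events and flags the strongly (anti-)
#' correlated pairs involving two different ChIP-Seq signals.
#'
#' @param am `attribute_matrix`.
#' @param class optional label (e.g. `"inclusion"`); default all events.
#' @param high flag pairs with `R >= high` (default 0.6).
#' @param low flag pairs with `R <= low` (default -0.5).
#' @return list with `cor` (matrix) and `flagged` (`data.frame` of
#'   attribute pairs from different signals passing either threshold).
#' @export
pairwise_correlations <- function(am, class = NULL, high = 0.6, low = -0.5) {
  x <- am$x
  if (!is.null(class)) x <- x[am$labels == class, , drop = FALSE]
  cm <- suppressWarnings(cor(x))
  sig_of <- sub("-[^-]+$", "", colnames(cm))
  idx <- which(upper.tri(cm) & (cm >= high | cm <= low), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    keep <- sig_of[idx[, 1]] != sig_of[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
  }
  flagged <- data.frame(
    attr_a = colnames(cm)[idx[, 1]],
    attr_b = colnames(cm)[idx[, 2]],
    r = cm[idx])
  flagged <- flagged[is.finite(flagged$r), , drop = FALSE]
  list(cor = cm, flagged = flagged[order(-abs(flagged$r)), , drop = FALSE])
}

#' Mean read-density profile around 5' splice sites
#'
#' Per-base mean coverage of reads in a window around the donor site
#' (5'ss) of the alternative exon, in transcript orientation, averaged
#' within event groups (e.g. inclusion / skipping / non-regulated).
#' Events overlapping a transcript's first or second exon can be excluded
#' to avoid transcription-start-site bias.
#'
#' @param reads `GRanges` of (extended) reads.
#' @param events event `data.frame`; the anchor is the 5'ss of E2.
#' @param flank half-width of the profile in nt (default 600).
#' @param groups factor splitting events (default `events$label`).
#' @param drop_first_second drop events flagged `first_or_second`
#'   (default `TRUE` when the column exists).
#' @return matrix of mean coverage, rows = groups, columns = positions
#'   `-flank ... flank`.
#' @export
density_profile <- function(reads, events, flank = 600, groups = NULL,
                            drop_first_second = TRUE) {
  if (is.null(groups)) {
    groups <- if ("label" %in% names(events)) events$label else
      rep("all", nrow(events))
  }
  groups <- factor(groups)
  if (drop_first_second && "first_or_second" %in% names(events)) {
    keep <- !events$first_or_second
    events <- events[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  e2 <- event_part(events, "E2")
  anchor <- ifelse(events$strand == "+", end(e2), start(e2))
  pos <- seq(-flank, flank)
  cov <- coverage(reads)
  out <- matrix(0, nrow = nlevels(groups), ncol = length(pos),
                dimnames = list(levels(groups), pos))
  counts <- setNames(integer(nlevels(groups)), levels(groups))
  for (i in seq_len(nrow(events))) {
    chr <- events$chrom[i]
    if (!chr %in% names(cov)) next
    v <- cov[[chr]]
    win_start <- anchor[i] - flank
    idx <- seq(win_start, anchor[i] + flank)
    ok <- idx >= 1 & idx <= length(v)
    prof <- numeric(length(idx))
    prof[ok] <- as.numeric(v[idx[ok]])
    if (events$strand[i] == "-") prof <- rev(prof)
    g <- as.character(groups[i])
    out[g, ] <- out[g, ] + prof
    counts[g] <- counts[g] + 1L
  }
  sweep(out, 1, pmax(counts, 1L), "/")
}

#' Export an attribute matrix as ARFF
#'
#' Writes the z-score matrix plus the class label in the
#' attribute-relation file format used by machine-learning toolkits.
#'
#' @param am `attribute_matrix`.
#' @param path output `.arff` path.
#' @return `path`, invisibly.
#' @export
write_arff <- function(am, path) {
  df <- as.data.frame(am$x)
  # ARFF attribute names must not contain '-'
  names(df) <- gsub("-", "_", names(df))
  df$class <- am$labels
  foreign::write.arff(df, path)
  invisible(path)
}

#' Export an attribute matrix as TSV
#'
#' @param am `attribute_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attribute_matrix <- function(am, path) {
  df <- data.frame(event_id = rownames(am$x), label = am$labels,
                   am$x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
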
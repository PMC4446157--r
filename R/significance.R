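#' Extend reads from their 5' ends
#'
#' ChIP-Seq reads are short sequenced ends of longer immunoprecipitated
#' fragments; to approximate fragment occupancy each read is replaced by an
#' interval of fixed length anchored at its 5' end and extended in the 5'
#' to 3' direction (rightward on the plus strand, leftward on the minus
#' strand).
#'
#' @param reads `GRanges` of mapped reads.  Strand must be `+` or `-` for
#'   every read when `strand_aware = TRUE`.
#' @param length target fragment length in nt (e.g. 200 for most samples;
#'   350 is typical for AGO1 given its larger sonication fragments).  Must
#'   be at least the read length.
#' @param strand_aware extend with respect to strand (default) or always
#'   rightward.
#' @return `GRanges` of extended reads, clipped at chromosome bounds when
#'   `seqlengths` are set.
#' @export
extend_reads <- function(reads, length, strand_aware = TRUE) {
  if (base::length(reads) == 0) return(reads)
  if (any(width(reads) > length)) {
    stop("extension length ", length, " is shorter than some reads")
  }
  if (strand_aware) {
    str <- as.character(strand(reads))
    bad <- which(!str %in% c("+", "-"))
    if (base::length(bad) > 0) {
      nm <- if (!is.null(names(reads))) names(reads)[bad[1]] else bad[1]
      stop("read ", nm, " has no strand; required for strand-aware extension")
    }
    out <- suppressWarnings(resize(reads, width = length, fix = "start"))
  } else {
    str0 <- strand(reads)
    strand(reads) <- "+"
    out <- suppressWarnings(resize(reads, width = length, fix = "start"))
    strand(out) <- str0
  }
  trim(out)
}

#' Drop reads overlapping exclusion regions
#'
#' Reads overlapping (by at least 1 nt) centromeres, assembly gaps,
#' satellites or other low-mappability regions are removed before
#' clustering.  Order of the surviving reads is preserved; an empty
#' exclusion set is the identity.
#'
#' @param reads `GRanges`.
#' @param exclusions `GRanges` of regions to avoid (strand ignored).
#' @return filtered `GRanges`.
#' @export
filter_excluded <- function(reads, exclusions) {
  if (length(exclusions) == 0 || length(reads) == 0) return(reads)
  hit <- overlapsAny(reads, exclusions, ignore.strand = TRUE)
  reads[!hit]
}

#' Merge overlapping reads into clusters
#'
#' Clusters are the connected components of the "overlaps by at least
#' 1 nt" relation on the extended reads, ignoring strand; each cluster's
#' interval is the union span of its reads.  Clusters supported by a
#' single read are discarded.
#'
#' @param reads extended `GRanges`.
#' @param min_reads minimum reads per cluster (default 2, i.e. singleton
#'   clusters are dropped).
#' @return `GRanges` of clusters with metadata column `n_reads`.
#' @export
build_clusters <- function(reads, min_reads = 2L) {
  cl <- reduce(granges(reads), min.gapwidth = 0L, ignore.strand = TRUE)
  n <- countOverlaps(cl, reads, ignore.strand = TRUE)
  cl$n_reads <- n
  cl[n >= min_reads]
}

#' Estimate the ChIP-to-control normalization factor
#'
#' Sequencing depth differs between a ChIP sample and its control, so read
#' counts cannot be compared directly.  Low-coverage regions where sample
#' and control clusters overlap are taken as background, and the average
#' log2 sample/control count ratio over those regions defines the
#' normalization factor:
#' \deqn{CNF = \frac{1}{N}\sum_{i=1}^{N} \log_2\!\left(n_i^{(s)} / n_i^{(c)}\right)}
#'
#' A region qualifies as background when both counts are below
#' `max_background_reads` and both are positive (the log ratio is undefined
#' at zero).  The linearized factor \eqn{2^{CNF}} is the rate ratio used by
#' [bayes_pvalue()].
#'
#' Note that the mean-log estimator is consistent for the planted rate
#' ratio only when background counts are not dominated by small-count
#' log bias; at single-digit counts it is biased toward 1.
#'
#' @param paired_counts two-column matrix or data.frame of per-region
#'   counts `(n_s, n_c)` for regions where sample and control clusters
#'   overlap.
#' @param max_background_reads regions with this many reads or more (in
#'   either track) are considered signal, not background (default 10).
#' @return an object of class `background_model` with elements `cnf_log`
#'   (the mean log2 ratio), `cnf_linear` (`2^cnf_log`), `n_regions` and
#'   `max_background_reads`.
#' @export
estimate_cnf <- function(paired_counts, max_background_reads = 10) {
  pc <- as.matrix(paired_counts)
  if (ncol(pc) != 2) stop("paired_counts must have two columns (n_s, n_c)")
  n_s <- pc[, 1]; n_c <- pc[, 2]
  keep <- n_s < max_background_reads & n_c < max_background_reads &
    n_s > 0 & n_c > 0
  if (!any(keep)) {
    stop("no qualifying background regions (need 0 < counts < ",
         max_background_reads, " in both tracks)")
  }
  cnf_log <- mean(log2(n_s[keep] / n_c[keep]))
  structure(
    list(cnf_log = cnf_log, cnf_linear = 2^cnf_log,
         n_regions = sum(keep), max_background_reads = max_background_reads),
    class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("ChIP/control background model\n")
  cat(sprintf("  CNF (mean log2 ratio): %.4f\n", x$cnf_log))
  cat(sprintf("  linear rate ratio 2^CNF: %.4f\n", x$cnf_linear))
  cat(sprintf("  background regions: %d (count threshold < %g)\n",
              x$n_regions, x$max_background_reads))
  invisible(x)
}

#' Control-normalized Bayesian cluster significance
#'
#' Probability of observing the control read count given the sample read
#' count in the same region under the background model with rate ratio
#' `k` (the linearized normalization factor):
#' \deqn{P(n_c \mid n_s) = k^{n_c}\,
#'   \frac{(n_c+n_s)!}{n_c!\,n_s!\,(1+k)^{n_c+n_s+1}}}
#' This is the negative-binomial predictive mass; for fixed `n_s` it sums
#' to 1 over all `n_c`.  A small value for an enriched cluster (large
#' `n_s`, small `n_c`) flags it as significant.  Computed in log space so
#' large counts do not overflow.
#'
#' @param n_s sample read count(s), non-negative integers (vectorized).
#' @param n_c control read count(s), non-negative integers (vectorized).
#' @param cnf_linear background rate ratio, `> 0` (a `background_model`
#'   is also accepted).
#' @return probabilities in `(0, 1]`.
#' @export
bayes_pvalue <- function(n_s, n_c, cnf_linear) {
  if (is(cnf_linear, "background_model")) cnf_linear <- cnf_linear$cnf_linear
  if (any(cnf_linear <= 0)) stop("cnf_linear must be > 0")
  if (any(n_s < 0) || any(n_c < 0)) stop("counts must be non-negative")
  k <- cnf_linear
  exp(n_c * log(k) + lchoose(n_c + n_s, n_c) - (n_c + n_s + 1) * log1p(k))
}

#' Select significant clusters and restrict reads to them
#'
#' Assigns each cluster the control read count over its union span,
#' computes [bayes_pvalue()] under the background model, and keeps
#' clusters below the cut-off.  Because the probability is small for
#' strong depletion as well as strong enrichment, an enrichment guard
#' (default on) additionally requires `n_s > cnf_linear * n_c`.
#'
#' Per-sample cut-offs in the original design ranged from 0.05 (AGO1,
#' H3K9me2) through 0.01 (H3K27me3, H3, H3K36me3) to 1e-3 (HP1, 5metC,
#' RNAPII, CTCF); see [default_cutoffs()].
#'
#' @param clusters `GRanges` from [build_clusters()] (metadata `n_reads`).
#' @param control_reads `GRanges` of (extended) control reads.
#' @param model `background_model` from [estimate_cnf()] for the same
#'   sample/control pair.
#' @param cutoff retain clusters with `pvalue < cutoff`; must lie in (0,1).
#' @param enrichment_guard require sample enrichment (default `TRUE`);
#'   set `FALSE` to reproduce the formula-only behaviour.
#' @param reads optional `GRanges` of the sample's extended reads; when
#'   given, the reads overlapping significant clusters are returned too.
#' @return list with `clusters` (all clusters, with `n_control`, `pvalue`
#'   and `significant` metadata), `significant` (the retained subset) and,
#'   when `reads` was supplied, `reads` restricted to significant clusters.
#' @export
call_significant <- function(clusters, control_reads, model, cutoff = 0.05,
                             enrichment_guard = TRUE, reads = NULL) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  n_c <- countOverlaps(clusters, control_reads, ignore.strand = TRUE)
  p <- bayes_pvalue(clusters$n_reads, n_c, model$cnf_linear)
  sig <- p < cutoff
  if (enrichment_guard) {
    sig <- sig & clusters$n_reads > model$cnf_linear * n_c
  }
  clusters$n_control <- n_c
  clusters$pvalue <- p
  clusters$significant <- sig
  out <- list(clusters = clusters, significant = clusters[sig])
  if (!is.null(reads)) {
    out$reads <- reads[overlapsAny(reads, out$significant,
                                   ignore.strand = TRUE)]
  }
  out
}

#' Default per-sample significance cut-offs
#'
#' The cluster-significance cut-off that maximizes the usable cluster set
#' differs between antibodies; these defaults follow the original design.
#'
#' @return named numeric vector of p-value cut-offs.
#' @export
default_cutoffs <- function() {
  c(AGO1 = 0.05, H3K9me2 = 0.05,
    H3K27me3 = 0.01, H3 = 0.01, H3K36me3 = 0.01,
    HP1 = 1e-3, `5metC` = 1e-3, RNAPII = 1e-3, CTCF = 1e-3)
}

#' Call significant clusters for one sample/control pair
#'
#' Convenience wrapper running the whole significance stage: cluster the
#' extended sample reads, estimate the background normalization factor
#' from regions where sample and control clusters overlap, and select
#' significant clusters.
#'
#' @param reads extended sample reads (`GRanges`).
#' @param control_reads extended control reads (`GRanges`).
#' @param cutoff p-value cut-off (see [default_cutoffs()]).
#' @param max_background_reads background threshold for [estimate_cnf()].
#' @param enrichment_guard see [call_significant()].
#' @return list as from [call_significant()] plus the `background_model`.
#' @export
call_clusters <- function(reads, control_reads, cutoff = 0.05,
                          max_background_reads = 10,
                          enrichment_guard = TRUE) {
  clusters <- build_clusters(reads)
  ctrl_clusters <- build_clusters(control_reads)
  # background = regions where sample and control clusters overlap
  ov <- findOverlaps(clusters, ctrl_clusters, ignore.strand = TRUE)
  if (length(ov) == 0) stop("sample and control clusters do not overlap")
  counts <- cbind(n_s = clusters$n_reads[queryHits(ov)],
                  n_c = ctrl_clusters$n_reads[subjectHits(ov)])
  model <- estimate_cnf(counts, max_background_reads)
  out <- call_significant(clusters, control_reads, model, cutoff,
                          enrichment_guard, reads = reads)
  out$model <- model
  out
}

#' Write a cluster table
#'
#' Writes clusters as BED6 (score column `-log10(pvalue)`, capped at 1000)
#' and a companion TSV with read counts, control counts, p-values and the
#' significance flag.
#'
#' @param clusters annotated `GRanges` from [call_significant()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the TSV `data.frame`.
#' @export
write_clusters <- function(clusters, bed_path = NULL, tsv_path = NULL) {
  tab <- data.frame(
    chrom = as.character(seqnames(clusters)),
    start = start(clusters) - 1L,
    end = end(clusters),
    n_reads = clusters$n_reads,
    n_control = clusters$n_control,
    pvalue = clusters$pvalue,
    significant = clusters$significant)
  if (!is.null(bed_path)) {
    out <- granges(clusters)
    out$name <- sprintf("cluster_%d", seq_along(clusters))
    out$score <- pmin(1000, -log10(pmax(clusters$pvalue, 1e-300)))
    write_bed(out, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(tab)
}
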
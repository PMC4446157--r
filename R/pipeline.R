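#' Run the full chromatin-splicing pipeline on a simulated dataset
#'
#' Orchestrates the stages end to end on data produced by the synthetic
#' generator (or on pre-loaded objects of the same shape): read
#' extension, exclusion filtering, cluster significance calling per
#' signal and condition, restriction of reads to significant clusters,
#' attribute-matrix construction, optional three-way feature selection,
#' and cross-validated classification.  All randomness is governed by
#' the seeds in the arguments, so two runs with the same inputs are
#' identical.
#'
#' @param events event `data.frame`.
#' @param reads nested list `reads[[signal]][[condition]]` of raw reads.
#' @param controls list `controls[[condition]]` of raw control reads.
#' @param config `sim_config` (used for conditions, chromosome sizes and
#'   extension bookkeeping).
#' @param extension named extension lengths per signal in nt; default
#'   200 for every signal except AGO1 (350).
#' @param cutoffs named per-signal p-value cut-offs
#'   (default [default_cutoffs()], falling back to 0.05).
#' @param exclusions `GRanges` of excluded regions (default empty).
#' @param select_features run [cfs_select()], [wse_select()] and
#'   [combine_selection()] and refit on the selected attributes
#'   (default `FALSE`; the wrapper search dominates the run time).
#' @param rounds,cv_folds,seed classifier settings.
#' @param out_dir optional directory; when given, clusters, the
#'   attribute matrix (TSV and ARFF), scores, per-event predictions and
#'   a JSON summary are written there.
#' @return list with `matrix` (the `attribute_matrix`), `clusters`
#'   (per signal/condition significance calls), `cv`
#'   (the [adtree_cv()] result on all attributes), and when
#'   `select_features` is `TRUE` also `scores`, `selected` and
#'   `cv_selected`; plus `summary`, a flat list of headline numbers.
#' @export
run_pipeline <- function(events, reads, controls, config,
                         extension = NULL, cutoffs = default_cutoffs(),
                         exclusions = GRanges(), select_features = FALSE,
                         rounds = 10, cv_folds = 10, seed = 1L,
                         out_dir = NULL) {
  conditions <- config$conditions
  signals <- names(reads)
  if (is.null(extension)) {
    extension <- setNames(rep(200L, length(signals)), signals)
    if ("AGO1" %in% signals) extension[["AGO1"]] <- 350L
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ext_controls <- stage("extend-controls", lapply(controls, function(g) {
    filter_excluded(extend_reads(g, 200L), exclusions)
  }))
  clusters <- list(); sig_reads <- list(); totals <- list()
  for (s in signals) {
    clusters[[s]] <- list(); sig_reads[[s]] <- list(); totals[[s]] <- list()
    cut <- if (s %in% names(cutoffs)) cutoffs[[s]] else 0.05
    for (cond in conditions) {
      ext <- stage(paste0("extend-", s, "-", cond), {
        filter_excluded(extend_reads(reads[[s]][[cond]], extension[[s]]),
                        exclusions)
      })
      cl <- stage(paste0("clusters-", s, "-", cond), {
        call_clusters(ext, ext_controls[[cond]], cutoff = cut)
      })
      clusters[[s]][[cond]] <- cl
      sig_reads[[s]][[cond]] <- cl$reads
      totals[[s]][[cond]] <- length(ext)
    }
  }
  am <- stage("attributes", {
    build_attribute_matrix(events, sig_reads, conditions = conditions,
                           totals = totals)
  })
  cv <- stage("cross-validation", {
    adtree_cv(am$x, am$labels, k = cv_folds, rounds = rounds, seed = seed)
  })
  out <- list(matrix = am, clusters = clusters, cv = cv)
  if (select_features) {
    out$scores <- stage("feature-selection", {
      ig <- rank_information_gain(am$x, am$labels)
      cfs <- cfs_select(am$x, am$labels, seed = seed)
      wse <- wse_select(am$x, am$labels, seed = seed)
      combine_selection(merge(merge(ig, cfs, by = "attribute"),
                              wse, by = "attribute"))
    })
    out$selected <- out$scores$attribute[out$scores$selected]
    if (length(out$selected) > 0) {
      out$cv_selected <- stage("cross-validation-selected", {
        adtree_cv(am$x[, out$selected, drop = FALSE], am$labels,
                  k = cv_folds, rounds = rounds, seed = seed)
      })
    }
  }
  out$summary <- list(
    n_events = nrow(events),
    n_signals = length(signals),
    n_attributes = ncol(am$x),
    selected = if (select_features) out$selected else NULL,
    roc_area = cv$roc_area,
    precision = cv$precision,
    recall = cv$recall,
    n_correct = cv$n_correct)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in signals) {
      for (cond in conditions) {
        write_clusters(clusters[[s]][[cond]]$clusters,
                       tsv_path = file.path(out_dir,
                         sprintf("clusters_%s_%s.tsv", s, cond)))
      }
    }
    write_attribute_matrix(am, file.path(out_dir, "attributes.tsv"))
    write_arff(am, file.path(out_dir, "attributes.arff"))
    pred <- data.frame(event_id = rownames(am$x), score = cv$score,
                       predicted = cv$predicted, true = cv$label)
    write.table(pred, file.path(out_dir, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (select_features) {
      write.table(out$scores, file.path(out_dir, "attribute_scores.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
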
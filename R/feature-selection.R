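# Entropy of a count vector, in bits.
entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Entropy-based supervised discretization (recursive MDL)
#'
#' Fayyad-Irani discretization: the cut point minimizing class-label
#' entropy is applied recursively, with the minimum-description-length
#' criterion as stopping rule.  Attributes for which no cut is accepted
#' collapse to a single bin (and thus have zero information gain).
#'
#' @param values numeric attribute values.
#' @param labels class labels (factor or coercible); at least two classes
#'   present.
#' @return numeric vector of cut points (possibly empty), sorted.
#' @export
discretize_mdl <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least two classes")
  y <- as.integer(labels)
  k_all <- nlevels(labels)
  ord <- order(values)
  v <- values[ord]; yy <- y[ord]

  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2) return()
    vs <- v[lo:hi]; ys <- yy[lo:hi]
    tot <- tabulate(ys, nbins = k_all)
    # cumulative class counts at each prefix
    ind <- matrix(0L, nrow = n, ncol = k_all)
    ind[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(ind, 2, cumsum)
    cand <- which(vs[-n] < vs[-1])        # boundaries between distinct values
    if (length(cand) == 0) return()
    row_h <- function(cm) {
      ns <- rowSums(cm)
      p <- cm / pmax(ns, 1)
      lp <- p * log2(p); lp[!is.finite(lp)] <- 0
      -rowSums(lp)
    }
    cl <- cum[cand, , drop = FALSE]
    cr <- sweep(-cl, 2, tot, "+")
    n1 <- rowSums(cl); n2 <- rowSums(cr)
    h1 <- row_h(cl); h2 <- row_h(cr)
    hs <- entropy_counts(tot)
    e <- (n1 * h1 + n2 * h2) / n
    best <- which.min(e)
    gain <- hs - e[best]
    k  <- sum(tot > 0)
    k1 <- sum(cl[best, ] > 0); k2 <- sum(cr[best, ] > 0)
    delta <- log2(3^k - 2) - (k * hs - k1 * h1[best] - k2 * h2[best])
    if (gain <= (log2(n - 1) + delta) / n) return()
    cut_at <- lo + cand[best] - 1
    cuts <<- c(cuts, (v[cut_at] + v[cut_at + 1]) / 2)
    recurse(lo, cut_at)
    recurse(cut_at + 1, hi)
  }
  recurse(1, length(v))
  sort(cuts)
}

# Bin a numeric attribute by cut points (1-based bin index).
apply_cuts <- function(values, cuts) {
  findInterval(values, cuts) + 1L
}

#' Information gain of a discretized attribute
#'
#' Expected reduction in class entropy caused by partitioning the
#' examples by the attribute's bins:
#' \eqn{IG = H(Y) - \sum_v p(v) H(Y \mid v)}, in bits.
#'
#' @param bins discrete attribute values (bin indices or factor).
#' @param labels class labels.
#' @return information gain in bits (non-negative up to rounding).
#' @export
information_gain <- function(bins, labels) {
  labels <- factor(labels)
  tab <- table(bins, labels)
  n <- sum(tab)
  hy <- entropy_counts(colSums(tab))
  hcond <- sum(apply(tab, 1, function(r) sum(r) / n * entropy_counts(r)))
  hy - hcond
}

#' Information-gain ranking of all attributes
#'
#' Each attribute is MDL-discretized ([discretize_mdl()]) and scored by
#' [information_gain()]; ties in the ranking are broken lexicographically
#' by attribute name so the ranking is reproducible.
#'
#' @param x numeric matrix (instances by attributes, named columns).
#' @param labels class labels.
#' @return `data.frame` with `attribute`, `ig`, `ig_rank` (1 = best), in
#'   column order of `x`.
#' @export
rank_information_gain <- function(x, labels) {
  ig <- vapply(seq_len(ncol(x)), function(j) {
    cuts <- discretize_mdl(x[, j], labels)
    if (length(cuts) == 0) return(0)
    information_gain(apply_cuts(x[, j], cuts), labels)
  }, numeric(1))
  ord <- order(-ig, colnames(x))
  rank <- integer(ncol(x)); rank[ord] <- seq_len(ncol(x))
  data.frame(attribute = colnames(x), ig = ig, ig_rank = rank,
             stringsAsFactors = FALSE)
}

# Symmetrical uncertainty between two discrete vectors, in [0,1].
symmetrical_uncertainty <- function(a, b) {
  tab <- table(a, b)
  ha <- entropy_counts(rowSums(tab))
  hb <- entropy_counts(colSums(tab))
  hab <- entropy_counts(as.vector(tab))
  if (ha + hb == 0) return(0)
  2 * (ha + hb - hab) / (ha + hb)
}

#' Correlation-based feature selection merit
#'
#' Merit of an attribute subset: average attribute-class correlation
#' balanced against average attribute-attribute redundancy,
#' \deqn{M_S = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\bar r_{ff}}}}
#' with symmetrical-uncertainty correlations.
#'
#' @param r_cf attribute-class correlations of the subset's members.
#' @param r_ff_mean mean pairwise attribute-attribute correlation within
#'   the subset (0 for singleton subsets).
#' @return the merit value.
#' @export
cfs_merit <- function(r_cf, r_ff_mean = 0) {
  k <- length(r_cf)
  if (k == 0) return(0)
  k * mean(r_cf) / sqrt(k + k * (k - 1) * r_ff_mean)
}

# Best-first forward search maximizing CFS merit.  su_cf: vector of
# class correlations; su_ff(i, j): lazily computed pair correlations.
cfs_best_first <- function(su_cf, su_ff_get, max_stale = 5) {
  p <- length(su_cf)
  merit_of <- function(sel) {
    k <- length(sel)
    if (k == 0) return(0)
    rff <- if (k < 2) 0 else {
      pairs <- utils::combn(sel, 2)
      mean(su_ff_get(pairs[1, ], pairs[2, ]))
    }
    cfs_merit(su_cf[sel], rff)
  }
  best_sel <- integer(0); best_merit <- 0
  frontier <- list(list(sel = integer(0), merit = 0))
  visited <- new.env(hash = TRUE)
  stale <- 0
  while (length(frontier) > 0 && stale < max_stale) {
    merits <- vapply(frontier, `[[`, numeric(1), "merit")
    i <- which.max(merits)
    node <- frontier[[i]]; frontier[[i]] <- NULL
    improved <- FALSE
    for (j in setdiff(seq_len(p), node$sel)) {
      sel <- sort(c(node$sel, j))
      key <- paste(sel, collapse = ",")
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      m <- merit_of(sel)
      frontier[[length(frontier) + 1]] <- list(sel = sel, merit = m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best_sel <- sel; improved <- TRUE
      }
    }
    stale <- if (improved) 0 else stale + 1
    # keep frontier bounded
    if (length(frontier) > 50) {
      merits <- vapply(frontier, `[[`, numeric(1), "merit")
      frontier <- frontier[order(-merits)[1:50]]
    }
  }
  best_sel
}

#' Correlation-based feature selection with fold frequencies
#'
#' For each of `folds` stratified cross-validation folds, the training
#' portion is MDL-discretized and a best-first search selects the
#' attribute subset maximizing the CFS merit ([cfs_merit()]); an
#' attribute's `cfs_freq` is the fraction of folds whose subset contains
#' it.
#'
#' @param x numeric matrix (instances by attributes).
#' @param labels class labels.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return `data.frame` with `attribute` and `cfs_freq`.
#' @export
cfs_select <- function(x, labels, folds = 10, seed = 1L) {
  labels <- factor(labels)
  fold_id <- stratified_folds(labels, folds, seed)
  p <- ncol(x)
  count <- setNames(numeric(p), colnames(x))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xt <- x[tr, , drop = FALSE]; yt <- droplevels(labels[tr])
    disc <- lapply(seq_len(p), function(j) {
      apply_cuts(xt[, j], discretize_mdl(xt[, j], yt))
    })
    su_cf <- vapply(disc, symmetrical_uncertainty, numeric(1), b = yt)
    su_ff <- matrix(NA_real_, p, p)
    su_ff_get <- function(ii, jj) {
      vapply(seq_along(ii), function(q) {
        i <- ii[q]; j <- jj[q]
        if (is.na(su_ff[i, j])) {
          v <- symmetrical_uncertainty(disc[[i]], disc[[j]])
          su_ff[i, j] <<- v; su_ff[j, i] <<- v
        }
        su_ff[i, j]
      }, numeric(1))
    }
    sel <- cfs_best_first(su_cf, su_ff_get)
    count[sel] <- count[sel] + 1
  }
  data.frame(attribute = colnames(x), cfs_freq = unname(count) / folds,
             stringsAsFactors = FALSE)
}

#' Wrapper subset evaluation with genetic search
#'
#' For each of `folds` stratified outer folds, a genetic algorithm
#' searches attribute-subset bitmasks; each subset is scored by the
#' inner cross-validated accuracy of an alternating decision tree
#' ([adtree()]) trained on the fold's training portion restricted to the
#' subset.  An attribute's `wse_freq` is the fraction of outer folds
#' whose best subset contains it.  All randomness is seeded, so repeated
#' runs with the same seed give identical output.
#'
#' @param x numeric matrix (instances by attributes).
#' @param labels class labels (two classes).
#' @param folds outer folds (default 10).
#' @param ga genetic-search parameters: population size, generations,
#'   crossover and per-bit mutation probabilities, plus the sparse
#'   initialization rate `p_init` (default 0.1).
#' @param inner_folds folds of the inner accuracy estimate (default 3;
#'   nested inside each outer fold).
#' @param rounds boosting rounds of the evaluating classifier (default
#'   5: the wrapper only ranks subsets, and a shallower evaluator picks
#'   the same top attributes at a fraction of the cost).
#' @param seed RNG seed.
#' @return `data.frame` with `attribute` and `wse_freq`.
#' @export
wse_select <- function(x, labels, folds = 10,
                       ga = list(pop = 20, generations = 20,
                                 p_cross = 0.6, p_mut = 0.033,
                                 p_init = 0.1),
                       inner_folds = 3, rounds = 5, seed = 1L) {
  labels <- factor(labels)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- ncol(x)
  fold_id <- stratified_folds(labels, folds, seed)
  count <- setNames(numeric(p), colnames(x))
  set.seed(seed + 1L)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xt <- x[tr, , drop = FALSE]; yt <- droplevels(labels[tr])
    inner_id <- stratified_folds(yt, inner_folds, seed + f)
    pos <- if ("inclusion" %in% levels(yt)) "inclusion" else levels(yt)[1]
    yi <- ifelse(yt == pos, 1L, -1L)
    # per-inner-fold training/held-out matrices and per-column sort
    # orders, computed once; the genetic search then evaluates thousands
    # of subsets against these without re-sorting
    folds_pre <- lapply(seq_len(inner_folds), function(g) {
      tr <- inner_id != g
      xtr <- xt[tr, , drop = FALSE]
      list(xtr = xtr, ytr = yi[tr],
           ord = apply(xtr, 2, order),
           xte = xt[!tr, , drop = FALSE], yte = yi[!tr])
    })
    n_t <- length(yt)
    fx <- lapply(folds_pre, `[[`, "xtr")
    fy <- lapply(folds_pre, `[[`, "ytr")
    fo <- lapply(folds_pre, `[[`, "ord")
    fxe <- lapply(folds_pre, `[[`, "xte")
    fye <- lapply(folds_pre, `[[`, "yte")
    memo <- new.env(hash = TRUE)
    majority <- max(table(yt)) / n_t
    # scores a whole generation in one compiled call, memoizing subsets
    fitness_batch <- function(masks) {
      keys <- vapply(masks, function(m) paste(which(m), collapse = ","),
                     character(1))
      vals <- vapply(keys, function(k) {
        if (k == "") return(NA_real_)
        v <- memo[[k]]
        if (is.null(v)) NA_real_ else v
      }, numeric(1))
      todo <- which(is.na(vals) & keys != "")
      vals[keys == ""] <- majority
      if (length(todo) > 0) {
        acc <- adtree_wse_batch_cpp(fx, fy, fo, fxe, fye,
                                    lapply(masks[todo], which), rounds)
        for (q in seq_along(todo)) {
          memo[[keys[todo[q]]]] <- acc[q]
          vals[todo[q]] <- acc[q]
        }
      }
      unname(vals)
    }
    best <- genetic_search(p, fitness_batch, ga)
    count[best] <- count[best] + 1
  }
  data.frame(attribute = colnames(x), wse_freq = unname(count) / folds,
             stringsAsFactors = FALSE)
}

# Simple generational GA over bitmasks with elitism of one.
# Returns the indices of the best subset ever evaluated.  The population
# starts at sparse subsets (each attribute on with probability p_init),
# reflecting the expectation that informative sets are small; mutation
# and crossover let the search grow them as needed.
genetic_search <- function(p, fitness_batch, ga) {
  p_init <- if (is.null(ga$p_init)) 0.1 else ga$p_init
  pop <- lapply(seq_len(ga$pop), function(i) runif(p) < p_init)
  fit <- fitness_batch(pop)
  best_mask <- pop[[which.max(fit)]]; best_fit <- max(fit)
  for (gen in seq_len(ga$generations)) {
    # fitness-proportionate selection
    w <- fit - min(fit) + 1e-6
    idx <- sample.int(ga$pop, ga$pop, replace = TRUE, prob = w)
    nxt <- pop[idx]
    # single-point crossover on consecutive pairs
    for (i in seq(1, ga$pop - 1, by = 2)) {
      if (runif(1) < ga$p_cross && p > 1) {
        cut <- sample.int(p - 1, 1)
        a <- nxt[[i]]; b <- nxt[[i + 1]]
        nxt[[i]] <- c(a[1:cut], b[(cut + 1):p])
        nxt[[i + 1]] <- c(b[1:cut], a[(cut + 1):p])
      }
    }
    # bit mutation
    nxt <- lapply(nxt, function(m) xor(m, runif(p) < ga$p_mut))
    nxt[[1]] <- best_mask                      # elitism
    pop <- nxt
    fit <- fitness_batch(pop)
    if (max(fit) > best_fit) {
      best_fit <- max(fit); best_mask <- pop[[which.max(fit)]]
    }
  }
  which(best_mask)
}

#' Combine the three selectors into a final attribute set
#'
#' An attribute is selected when its CFS and WSE selection frequencies
#' are both at least `freq_min` and its information-gain rank lies in the
#' top `ig_top` fraction.  Among selected attributes of the same
#' ChIP-Seq signal whose windows genomically overlap (for the canonical
#' event geometry), only the one with the highest information gain is
#' kept, giving a minimal non-redundant set.
#'
#' @param scores `data.frame` with columns `attribute` (named
#'   `"SIGNAL-window"`), `ig`, `ig_rank`, `cfs_freq`, `wse_freq`
#'   (merge of [rank_information_gain()], [cfs_select()],
#'   [wse_select()]).
#' @param freq_min minimum CFS/WSE frequency (default 0.5).
#' @param ig_top fraction of the IG ranking considered informative
#'   (default 0.5).
#' @param overlap 15x15 logical window-overlap matrix; default
#'   [window_overlap_map()].
#' @return `scores` with a logical `selected` column.
#' @export
combine_selection <- function(scores, freq_min = 0.5, ig_top = 0.5,
                              overlap = window_overlap_map()) {
  p <- nrow(scores)
  sel <- scores$cfs_freq >= freq_min & scores$wse_freq >= freq_min &
    scores$ig_rank <= ceiling(ig_top * p)
  # redundancy pruning within signals over overlapping windows
  sig <- sub("-[^-]+$", "", scores$attribute)
  win <- sub("^.*-", "", scores$attribute)
  for (s in unique(sig[sel])) {
    idx <- which(sel & sig == s)
    if (length(idx) < 2) next
    # connected components under window overlap
    comp <- seq_along(idx)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a < b && overlap[win[idx[a]], win[idx[b]]]) {
        comp[comp == comp[b]] <- comp[a]
      }
    }
    for (cc in unique(comp)) {
      members <- idx[comp == cc]
      if (length(members) < 2) next
      keep <- members[order(-scores$ig[members],
                            scores$attribute[members])][1]
      sel[setdiff(members, keep)] <- FALSE
    }
  }
  scores$selected <- sel
  scores
}

#' Which of the fifteen windows overlap genomically?
#'
#' Computed from [define_windows()] on a canonical plus-strand event
#' (150-nt exons, `intron_len`-nt introns); used by the redundancy rule
#' of [combine_selection()].
#'
#' @param flank,junction_half window geometry.
#' @param exon_len,intron_len canonical event geometry in nt.
#' @return 15x15 logical matrix, dimnames = window names.
#' @export
window_overlap_map <- function(flank = 300, junction_half = 100,
                               exon_len = 150, intron_len = 1500) {
  e1s <- 10000L
  ev <- data.frame(
    event_id = "canon", gene_id = "g", chrom = "chrC", strand = "+",
    E1_start = e1s, E1_end = e1s + exon_len - 1L,
    E2_start = e1s + exon_len + intron_len,
    E2_end = e1s + 2L * exon_len + intron_len - 1L,
    E3_start = e1s + 2L * (exon_len + intron_len),
    E3_end = e1s + 3L * exon_len + 2L * intron_len - 1L)
  w <- define_windows(ev, flank, junction_half)
  ov <- as.matrix(findOverlaps(w, w, ignore.strand = TRUE))
  m <- matrix(FALSE, 15, 15,
              dimnames = list(levels(w$window), levels(w$window)))
  m[cbind(as.character(w$window[ov[, 1]]),
          as.character(w$window[ov[, 2]]))] <- TRUE
  m
}

# Stratified fold assignment: within each class, a seeded random
# permutation is dealt round-robin into folds.
stratified_folds <- function(labels, folds, seed) {
  labels <- factor(labels)
  set.seed(seed)
  id <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    id[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  id
}
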
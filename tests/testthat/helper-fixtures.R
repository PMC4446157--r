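# Shared fixtures and independent oracles for the test suite.
# Coordinates in helpers are 1-based closed (GRanges convention) unless a
# name says "bed".

library(GenomicRanges)

gr <- function(chrom, start, end, strand = "*") {
  GRanges(chrom, IRanges(start, end), strand = strand)
}

# one well-spaced cassette event; coordinates chosen so no window is
# clipped (introns 800 nt, exons 100 nt)
make_event <- function(event_id = "e1", chrom = "chr1", strand = "+",
                       e1_start = 5001, exon = 100, intron = 800,
                       label = "inclusion", fold_change = 3,
                       expr_pvalue = 0.5) {
  data.frame(
    event_id = event_id, gene_id = paste0("g_", event_id),
    chrom = chrom, strand = strand,
    E1_start = e1_start, E1_end = e1_start + exon - 1,
    E2_start = e1_start + exon + intron,
    E2_end = e1_start + 2 * exon + intron - 1,
    E3_start = e1_start + 2 * (exon + intron),
    E3_end = e1_start + 3 * exon + 2 * intron - 1,
    label = label, fold_change = fold_change, expr_pvalue = expr_pvalue,
    first_or_second = FALSE, overlaps_nonreg = FALSE,
    stringsAsFactors = FALSE)
}

# O(n^2) connected-components clustering oracle: union-find over the
# pairwise >=1 nt overlap relation, singletons dropped.
oracle_clusters <- function(reads) {
  n <- length(reads)
  if (n == 0) return(GRanges())
  chrom <- as.character(seqnames(reads))
  s <- start(reads); e <- end(reads)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (chrom[i] == chrom[j] && s[i] <= e[j] && s[j] <= e[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  keep <- as.integer(names(which(table(comp) >= 2)))
  if (length(keep) == 0) return(GRanges())
  out <- lapply(keep, function(cc) {
    idx <- which(comp == cc)
    GRanges(chrom[idx[1]], IRanges(min(s[idx]), max(e[idx])),
            n_reads = length(idx))
  })
  sort(suppressWarnings(do.call(c, out)))
}

# direct-arithmetic oracle for the cluster significance probability,
# valid for small counts (no log-space tricks)
oracle_bayes <- function(n_s, n_c, k) {
  k^n_c * choose(n_c + n_s, n_c) / (1 + k)^(n_c + n_s + 1)
}

# exhaustive path-enumeration scorer for an adtree model: walks every
# rule, tracking satisfaction of every path explicitly
oracle_adtree_score <- function(model, x) {
  vapply(seq_len(nrow(x)), function(i) {
    m <- nrow(model$rules)
    sat <- c(TRUE, rep(FALSE, 2 * m))
    s <- model$root
    if (m > 0) for (r in seq_len(m)) {
      pre <- model$rules$path[r] + 1
      if (!sat[pre]) next
      left <- x[i, model$rules$attr_index[r]] < model$rules$threshold[r]
      s <- s + if (left) model$rules$left[r] else model$rules$right[r]
      sat[2 * r] <- left
      sat[2 * r + 1] <- !left
    }
    s
  }, numeric(1))
}

# naive O(l*k) overlapping k-mer counter folding a k-mer with its
# reverse complement
oracle_kmer_counts <- function(sequence, k) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  counts <- list()
  for (i in seq_len(nchar(sequence) - k + 1)) {
    km <- substr(sequence, i, i + k - 1)
    if (grepl("[^ACGT]", km)) next
    rc <- revcomp(km)
    key <- if (km <= rc) km else rc
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact hypergeometric upper-tail sum, as a ratio of binomial products
oracle_hyper_tail <- function(x, N, c, N0) {
  K <- x + c          # total successes
  tot <- N + N0
  sum(vapply(x:min(K, N), function(q) {
    choose(K, q) * choose(tot - K, N - q)
  }, numeric(1))) / choose(tot, N)
}
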
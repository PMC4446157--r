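# Canonical k-mer key: the lexicographic minimum of a k-mer and its
# reverse complement, so occurrences on either strand fold together.
canonical_kmers <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# Per-sequence canonical k-mer count matrix.  A canonical k-mer's count
# is the number of occurrences of the k-mer or its reverse complement in
# the forward-strand scan (overlapping occurrences; N-containing windows
# yield no k-mer), so a motif is found in either orientation without
# being double-counted.
kmer_count_matrix <- function(sequences, k) {
  seqs <- as_dna(sequences)
  if (min(Biostrings::width(seqs)) < k) {
    stop("k = ", k, " exceeds the shortest sequence length")
  }
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = k)
  key <- canonical_kmers(colnames(counts))
  t(rowsum(t(counts), group = key))
}

as_dna <- function(sequences) {
  if (is(sequences, "DNAStringSet")) return(sequences)
  Biostrings::DNAStringSet(toupper(sequences))
}

#' Expected per-nucleotide k-mer density from a control set
#'
#' For each (canonical) k-mer, the total number of occurrences in the
#' control sequences (overlapping occurrences, both strands) divided by
#' the total control sequence length:
#' \deqn{d^{(0)}_a = \sum_i n^{(0)}_{i,a} \Big/ \sum_i l^{(0)}_i}
#'
#' @param control_sequences character vector or `DNAStringSet`.
#' @param k k-mer length (default 7).
#' @return named numeric vector of expected densities (occurrences per
#'   nt), over the canonical k-mers present in the alphabet.
#' @export
expected_density <- function(control_sequences, k = 7) {
  if (k <= 0) stop("k must be positive")
  m <- kmer_count_matrix(control_sequences, k)
  tot_len <- sum(Biostrings::width(as_dna(control_sequences)))
  colSums(m) / tot_len
}

#' Heptamer (k-mer) enrichment between sample and control sequences
#'
#' For every k-mer `a`, each sample sequence `i` contributes an indicator
#' \eqn{d_{i,a} = 1} when its observed count \eqn{n_{i,a}} exceeds the
#' expected count \eqn{d^{(0)}_a l_i} under the control density; control
#' sequences contribute analogous indicators against their own lengths.
#' The per-k-mer 2x2 table of indicator sums versus set sizes is tested
#' with a one-tailed Fisher exact test (enrichment direction); the odds
#' ratio is the k-mer score and k-mers are ranked by raw p-value.
#' Benjamini-Hochberg q-values are reported alongside for transparency.
#'
#' @param sample_sequences,control_sequences character vectors or
#'   `DNAStringSet`s (uppercase ACGTN; N positions yield no k-mers).
#' @param k k-mer length (default 7).
#' @return `data.frame` (one row per canonical k-mer, ranked by p-value):
#'   `kmer`, `d0` (expected density), `sample_hits`, `control_hits`,
#'   `odds_ratio`, `pvalue`, `qvalue`.
#' @export
kmer_enrichment <- function(sample_sequences, control_sequences, k = 7) {
  s <- as_dna(sample_sequences); ctl <- as_dna(control_sequences)
  if (length(s) == 0 || length(ctl) == 0) stop("empty sequence set")
  ms <- kmer_count_matrix(s, k)
  mc <- kmer_count_matrix(ctl, k)
  d0 <- colSums(mc) / sum(Biostrings::width(ctl))
  ls <- Biostrings::width(s); lc <- Biostrings::width(ctl)
  exp_s <- outer(ls, d0)       # expected counts per (sequence, kmer)
  exp_c <- outer(lc, d0)
  hits_s <- colSums(ms > exp_s)
  hits_c <- colSums(mc > exp_c)
  N <- length(s); N0 <- length(ctl)
  p <- kmer_fisher(hits_s, N, hits_c, N0)
  or <- (hits_s / pmax(N - hits_s, 1e-300)) /
    pmax(hits_c / pmax(N0 - hits_c, 1e-300), 1e-300)
  or[hits_c == 0 & hits_s > 0] <- Inf
  or[hits_c == 0 & hits_s == 0] <- 1
  out <- data.frame(kmer = colnames(ms), d0 = d0[colnames(ms)],
                    sample_hits = hits_s, control_hits = hits_c,
                    odds_ratio = or, pvalue = p,
                    qvalue = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$pvalue, -out$odds_ratio, out$kmer), , drop = FALSE]
}

#' One-tailed Fisher exact test for k-mer indicator sums
#'
#' Enrichment-direction Fisher test on the 2x2 table of
#' more-than-expected indicator sums versus set sizes,
#' `[[x, N - x], [c, N0 - c]]`, computed as the hypergeometric upper
#' tail `P(X >= x)`.  Vectorized over `x` and `c`.
#'
#' @param x sample sequences with more k-mer occurrences than expected.
#' @param N sample set size.
#' @param c control sequences with more occurrences than expected.
#' @param N0 control set size.
#' @return one-tailed p-value(s) in `(0, 1]`.
#' @export
kmer_fisher <- function(x, N, c, N0) {
  phyper(x - 1, m = x + c, n = N + N0 - x - c, k = N, lower.tail = FALSE)
}

#' Extract cluster-centered sequences containing significant k-mers
#'
#' For each cluster, the `width`-bp sequence centered at the cluster
#' midpoint is extracted from the genome; clusters whose centered
#' sequence contains at least `min_kmers` distinct significant k-mers
#' (on either strand) are kept.
#'
#' @param clusters `GRanges`.
#' @param significant_kmers character vector of k-mers (canonicalized
#'   internally).
#' @param genome named list or `DNAStringSet` of chromosome sequences.
#' @param min_kmers minimum distinct significant k-mers (default 2).
#' @param width extracted width in bp (default 200).
#' @return `DNAStringSet` of qualifying centered sequences, named by
#'   cluster coordinate.
#' @export
select_motif_clusters <- function(clusters, significant_kmers, genome,
                                  min_kmers = 2, width = 200) {
  genome <- as_dna_list(genome)
  mids <- floor((start(clusters) + end(clusters)) / 2)
  half <- floor(width / 2)
  seqs <- character(length(clusters))
  keep <- logical(length(clusters))
  sig <- unique(canonical_kmers(toupper(significant_kmers)))
  k <- nchar(sig[1])
  for (i in seq_along(clusters)) {
    chr <- as.character(seqnames(clusters[i]))
    if (!chr %in% names(genome)) next
    s <- max(1L, mids[i] - half)
    e <- min(length(genome[[chr]]), s + width - 1L)
    if (e - s + 1L < k) next
    seqs[i] <- as.character(Biostrings::subseq(genome[[chr]], s, e))
  }
  nonempty <- which(nchar(seqs) >= k)
  if (length(nonempty) > 0) {
    counts <- kmer_count_matrix(seqs[nonempty], k)
    present <- counts[, intersect(colnames(counts), sig), drop = FALSE] > 0
    keep[nonempty] <- rowSums(present) >= min_kmers
  }
  out <- Biostrings::DNAStringSet(seqs[keep])
  names(out) <- sprintf("%s:%d-%d", seqnames(clusters)[keep],
                        start(clusters)[keep], end(clusters)[keep])
  out
}

as_dna_list <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    out <- as.list(genome)
    return(lapply(out, Biostrings::DNAString))
  }
  lapply(genome, function(s) {
    if (is(s, "DNAString")) s else Biostrings::DNAString(toupper(s))
  })
}

#' Build a position frequency matrix from top-ranked k-mers
#'
#' All occurrences of the top k-mers in the sequences (both strands;
#' minus-strand occurrences are reverse-complemented onto the plus
#' strand) are extended symmetrically to `width` and stacked into
#' per-position nucleotide counts.  The consensus string takes the
#' majority base per column, degenerating to the IUPAC code of the top
#' two bases when the majority falls below `majority`.
#'
#' @param sequences `DNAStringSet` (e.g. from [select_motif_clusters()]).
#' @param top_kmers character vector of k-mers, best first (e.g. the top
#'   10 by enrichment p-value).
#' @param width motif width (default 12).
#' @param majority consensus majority threshold (default 0.6).
#' @return object of class `pfm`: list with `counts` (4 x width matrix
#'   over ACGT), `consensus`, `n_sites`, `kmers`.
#' @export
build_pfm <- function(sequences, top_kmers, width = 12, majority = 0.6) {
  seqs <- as_dna(sequences)
  k <- nchar(top_kmers[1])
  if (width < k) stop("width must be at least the k-mer length")
  pad_l <- floor((width - k) / 2)
  pad_r <- width - k - pad_l
  counts <- matrix(0L, nrow = 4, ncol = width,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  n_sites <- 0L
  add_site <- function(site) {
    ri <- match(strsplit(site, "")[[1]], rownames(counts))
    # skip sites running off the sequence end or containing N
    if (length(ri) != width || anyNA(ri)) return(FALSE)
    idx <- cbind(ri, seq_len(width))
    counts[idx] <<- counts[idx] + 1L
    TRUE
  }
  for (km in top_kmers) {
    pat <- Biostrings::DNAString(toupper(km))
    rc <- Biostrings::reverseComplement(pat)
    for (i in seq_along(seqs)) {
      sq <- seqs[[i]]
      for (on_rc in c(FALSE, TRUE)) {
        hits <- Biostrings::matchPattern(if (on_rc) rc else pat, sq)
        for (h in seq_len(length(hits))) {
          # pad so that flipping a minus-strand site re-centers the k-mer
          s <- start(hits)[h] - (if (on_rc) pad_r else pad_l)
          e <- end(hits)[h] + (if (on_rc) pad_l else pad_r)
          if (s < 1 || e > length(sq)) next
          site <- as.character(Biostrings::subseq(sq, s, e))
          if (on_rc) {
            site <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(site)))
          }
          if (add_site(site)) n_sites <- n_sites + 1L
        }
      }
    }
  }
  structure(list(counts = counts, consensus = pfm_consensus(counts, majority),
                 n_sites = n_sites, kmers = top_kmers, width = width),
            class = "pfm")
}

# IUPAC two-base degeneracy codes
iupac2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

pfm_consensus <- function(counts, majority = 0.6) {
  paste(apply(counts, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) return("N")
    ord <- order(-col, names(col))
    if (col[ord[1]] / tot >= majority) return(names(col)[ord[1]])
    pair <- paste(sort(names(col)[ord[1:2]]), collapse = "")
    iupac2[[pair]]
  }), collapse = "")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("position frequency matrix, width %d, %d sites from %d k-mers\n",
              x$width, x$n_sites, length(x$kmers)))
  cat("consensus:", x$consensus, "\n")
  print(x$counts)
  invisible(x)
}

#' Write a PFM in MEME minimal motif format
#'
#' @param pfm a [build_pfm()] result.
#' @param path output path.
#' @param name motif name (default the consensus).
#' @return `path`, invisibly.
#' @export
write_meme <- function(pfm, path, name = pfm$consensus) {
  n <- max(1L, pfm$n_sites)
  probs <- t(pfm$counts) / pmax(colSums(pfm$counts), 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       pfm$width, n)), con)
  writeLines(apply(probs, 1, function(rr)
    paste(sprintf("%.6f", rr), collapse = " ")), con)
  invisible(path)
}

#' Motif match-density profile around cluster midpoints
#'
#' Per-position density of motif matches (exact matches of any of the
#' k-mers, on either strand, or PFM log-odds matches above a fraction of
#' the maximum achievable score) in a window around the midpoint of each
#' cluster, one curve per cluster set.
#'
#' @param motif character vector of k-mers or a `pfm`.
#' @param cluster_sets named list of `GRanges`.
#' @param genome named list or `DNAStringSet` of chromosome sequences.
#' @param flank half-window in bp (default 500).
#' @param score_min PFM score threshold as a fraction of the maximum
#'   log-odds score (default 0.6); ignored for k-mer motifs.
#' @return matrix, rows = cluster sets, columns = positions
#'   `-flank ... flank` (match start positions relative to midpoint).
#' @export
motif_density_profile <- function(motif, cluster_sets, genome, flank = 500,
                                  score_min = 0.6) {
  if (length(cluster_sets) == 0) stop("empty cluster set list")
  genome <- as_dna_list(genome)
  pos <- seq(-flank, flank)
  out <- matrix(0, nrow = length(cluster_sets), ncol = length(pos),
                dimnames = list(names(cluster_sets), pos))
  for (si in seq_along(cluster_sets)) {
    cl <- cluster_sets[[si]]
    if (length(cl) == 0) stop("empty cluster set: ", names(cluster_sets)[si])
    mids <- floor((start(cl) + end(cl)) / 2)
    acc <- numeric(length(pos))
    n_used <- 0L
    for (i in seq_along(cl)) {
      chr <- as.character(seqnames(cl)[i])
      if (!chr %in% names(genome)) next
      L <- length(genome[[chr]])
      s <- mids[i] - flank; e <- mids[i] + flank
      if (s < 1 || e > L) next
      win <- Biostrings::subseq(genome[[chr]], s, e)
      hit <- motif_hit_starts(motif, win, score_min)
      acc[hit] <- acc[hit] + 1
      n_used <- n_used + 1L
    }
    out[si, ] <- acc / max(1L, n_used)
  }
  out
}

# start positions (1-based within window) of motif matches on either strand
motif_hit_starts <- function(motif, window, score_min) {
  if (is(motif, "pfm")) {
    pwm <- log2((motif$counts + 1) / rep(colSums(motif$counts + 1), each = 4) / 0.25)
    hits <- c(start(Biostrings::matchPWM(pwm, window, min.score = paste0(round(100 * score_min), "%"))),
              start(Biostrings::matchPWM(Biostrings::reverseComplement(pwm), window,
                                         min.score = paste0(round(100 * score_min), "%"))))
    return(unique(hits))
  }
  kms <- unique(toupper(motif))
  hits <- integer(0)
  for (km in kms) {
    pat <- Biostrings::DNAString(km)
    hits <- c(hits, start(Biostrings::matchPattern(pat, window)),
              start(Biostrings::matchPattern(Biostrings::reverseComplement(pat), window)))
  }
  unique(hits)
}
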
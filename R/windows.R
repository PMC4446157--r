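#' The fifteen windows of a cassette-exon event
#'
#' Each exon-triplet event (upstream exon E1, alternative exon E2,
#' downstream exon E3, introns I1 and I2) is covered by fifteen windows,
#' all expressed in transcript orientation:
#'
#' * `w1 ... w6`: 300-nt windows flanking the exons (w1/w2 flank E1,
#'   w3/w4 flank E2, w5/w6 flank E3; odd numbers upstream of their exon,
#'   even numbers downstream).  Intron-internal flanks (w2, w3, w4, w5)
#'   are clipped to their intron and never cross into an exon, so on
#'   short introns they may overlap each other.
#' * `J1 ... J4`: 200-nt junction windows covering 100 nt on either side
#'   of the four intron-adjacent exon boundaries, ordered 5' to 3'
#'   (E1 donor, E2 acceptor, E2 donor, E3 acceptor).
#' * `E1`, `E2`, `E3`: the entire exons.
#' * `I1`, `I2`: the entire introns.
#'
#' On minus-strand events the scheme is mirror-imaged so that "upstream"
#' always means 5' in the transcript.
#'
#' @param events event `data.frame` (see [read_events()]); geometry is
#'   validated.
#' @param flank outer flank window length in nt (default 300).
#' @param junction_half half-width of junction windows in nt (default 100).
#' @return `GRanges` with one range per (event, window), metadata columns
#'   `event_id` and `window` (factor with the 15 window names).
#' @export
define_windows <- function(events, flank = 300, junction_half = 100) {
  validate_events(events)
  n <- nrow(events)
  plus <- events$strand == "+"
  chrom <- events$chrom; str <- events$strand; id <- events$event_id

  # transcript-orientation exon bounds, expressed as genomic coordinates:
  # on + strand, t_start = genomic start; on -, t_start = genomic end.
  # Work in genomic coordinates throughout and mirror the arithmetic.
  E <- list(E1 = event_part(events, "E1"),
            E2 = event_part(events, "E2"),
            E3 = event_part(events, "E3"),
            I1 = event_part(events, "I1"),
            I2 = event_part(events, "I2"))

  # helper: interval upstream (5') of a genomic position, length len,
  # in transcript orientation; pos is the first base of the exon.
  out <- vector("list", 15)
  names(out) <- c(paste0("w", 1:6), paste0("J", 1:4),
                  "E1", "E2", "E3", "I1", "I2")

  rng <- function(s, e) IRanges(pmin(s, e), pmax(s, e))
  # exon boundary coordinates in transcript orientation
  s1 <- ifelse(plus, start(E$E1), end(E$E1))   # E1 acceptor-side end
  e1 <- ifelse(plus, end(E$E1), start(E$E1))   # E1 donor (5'ss of I1)
  s2 <- ifelse(plus, start(E$E2), end(E$E2))   # E2 acceptor
  e2 <- ifelse(plus, end(E$E2), start(E$E2))   # E2 donor
  s3 <- ifelse(plus, start(E$E3), end(E$E3))   # E3 acceptor
  e3 <- ifelse(plus, end(E$E3), start(E$E3))   # E3 donor-side end
  dir <- ifelse(plus, 1L, -1L)                 # transcript direction

  clip_to <- function(ir, intron) {
    IRanges(pmax(start(ir), start(intron)), pmin(end(ir), end(intron)))
  }

  # outer flanks (unclipped except at chromosome bounds, handled by trim
  # later if seqlengths are attached)
  out$w1 <- rng(s1 - dir, s1 - dir * flank)            # upstream of E1
  out$w6 <- rng(e3 + dir, e3 + dir * flank)            # downstream of E3
  # intron-internal flanks, clipped to their intron
  out$w2 <- clip_to(rng(e1 + dir, e1 + dir * flank), ranges(E$I1))
  out$w3 <- clip_to(rng(s2 - dir, s2 - dir * flank), ranges(E$I1))
  out$w4 <- clip_to(rng(e2 + dir, e2 + dir * flank), ranges(E$I2))
  out$w5 <- clip_to(rng(s3 - dir, s3 - dir * flank), ranges(E$I2))
  # junction windows: junction_half nt on either side of the boundary
  jwin <- function(donor_pos) {
    # covers the last junction_half exonic nt and first junction_half
    # intronic nt (or vice versa); symmetric about the boundary.
    rng(donor_pos - dir * (junction_half - 1L), donor_pos + dir * junction_half)
  }
  out$J1 <- jwin(e1)
  out$J2 <- rng(s2 + dir * (junction_half - 1L), s2 - dir * junction_half)
  out$J3 <- jwin(e2)
  out$J4 <- rng(s3 + dir * (junction_half - 1L), s3 - dir * junction_half)
  out$E1 <- ranges(E$E1); out$E2 <- ranges(E$E2); out$E3 <- ranges(E$E3)
  out$I1 <- ranges(E$I1); out$I2 <- ranges(E$I2)

  win <- rep(names(out), each = n)
  ir <- do.call(c, unname(out))
  # clamp at the chromosome start (outer flanks of events near the origin)
  ir <- IRanges(pmax(1L, start(ir)), pmax(1L, end(ir)))
  gr <- GRanges(rep(chrom, 15), ir, strand = rep(str, 15))
  gr$event_id <- rep(id, 15)
  gr$window <- factor(win, levels = names(out))
  gr
}

#' Read density of a window in RPKM
#'
#' Reads per kilobase of window per million mapped reads:
#' `count * 1e9 / (width * total_mapped_reads)`, where `count` is the
#' number of (extended) reads overlapping the window by at least 1 nt.
#'
#' @param reads `GRanges` of reads.
#' @param windows `GRanges` of windows (vectorized).
#' @param total_mapped_reads library size used for normalization; `> 0`.
#' @return numeric RPKM per window.
#' @export
window_density <- function(reads, windows, total_mapped_reads) {
  if (total_mapped_reads <= 0) stop("total_mapped_reads must be > 0")
  if (any(width(windows) == 0)) stop("zero-length window")
  n <- countOverlaps(windows, reads, ignore.strand = TRUE)
  n * 1e9 / (width(windows) * total_mapped_reads)
}

#' Normalize a density by the total-H3 density
#'
#' Optional nucleosome-occupancy correction for histone-modification
#' signals: the ratio `(density + pc) / (h3_density + pc)`.  The default
#' pipeline does not apply it, as it does not change the attribute
#' behaviour, but it is provided for sensitivity analyses.
#'
#' @param density,h3_density RPKM vectors.
#' @param pseudocount positive stabilizer (default 1).
#' @return normalized densities.
#' @export
h3_normalize <- function(density, h3_density, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  (density + pseudocount) / (h3_density + pseudocount)
}

#' Relative-enrichment z-score between two conditions
#'
#' For each window the log ratio `M = log2((a+pc)/(b+pc))` and mean
#' intensity `A = 0.5*log2((a+pc)(b+pc))` are computed; `M` is then
#' standardized within intensity deciles of a background set of window
#' pairs, which controls the strong dependence of log-ratio variance on
#' coverage.  Positive z means enriched in condition A.
#'
#' Windows with zero density in both conditions carry no evidence and get
#' `z = 0`.  A decile whose `M` standard deviation is zero (or that holds
#' a single pair) falls back to the global standard deviation with a
#' warning; if even the global standard deviation is zero the z-scores of
#' that bin are 0.
#'
#' @param density_a,density_b RPKM vectors for conditions A and B.
#' @param background_a,background_b matched background window pairs used
#'   for the decile standardization (at least 30 pairs); default: the
#'   input densities themselves.
#' @param pseudocount added to both densities before taking logs
#'   (default 1 RPKM).
#' @param n_bins number of intensity bins (default 10); automatically
#'   reduced so every bin holds at least ~30 background pairs.
#' @return numeric z-scores, one per window.
#' @export
enrichment_zscore <- function(density_a, density_b,
                              background_a = density_a,
                              background_b = density_b,
                              pseudocount = 1, n_bins = 10) {
  if (length(background_a) < 30) {
    stop("need at least 30 background window pairs for standardization")
  }
  pc <- pseudocount
  M <- log2((density_a + pc) / (density_b + pc))
  A <- 0.5 * log2((density_a + pc) * (density_b + pc))
  Mb <- log2((background_a + pc) / (background_b + pc))
  Ab <- 0.5 * log2((background_a + pc) * (background_b + pc))
  # intensity deciles on the background set; fewer bins when the
  # background is small so each keeps a stable sd estimate
  n_bins <- max(1, min(n_bins, length(Ab) %/% 30))
  br <- unique(quantile(Ab, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) br <- range(Ab) + c(-1, 1)
  bin_b <- findInterval(Ab, br, rightmost.closed = TRUE, all.inside = TRUE)
  bin <- findInterval(A, br, rightmost.closed = TRUE, all.inside = TRUE)
  mu <- tapply(Mb, bin_b, mean)
  sig <- tapply(Mb, bin_b, sd)
  glob <- sd(Mb)
  bad <- is.na(sig) | sig == 0
  if (any(bad[as.character(bin)] %in% TRUE)) {
    warning("degenerate intensity bin; falling back to global sd")
  }
  sig[bad] <- glob
  mu_i <- mu[as.character(bin)]
  sig_i <- sig[as.character(bin)]
  mu_i[is.na(mu_i)] <- mean(Mb)
  sig_i[is.na(sig_i)] <- glob
  z <- (M - mu_i) / sig_i
  z[!is.finite(z)] <- 0
  z[density_a == 0 & density_b == 0] <- 0
  unname(z)
}
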
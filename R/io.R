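#' Read genomic intervals from a BED file
#'
#' Thin wrapper around [rtracklayer::import.bed()] returning a `GRanges`.
#' BED is 0-based half-open on disk; the returned object is 1-based closed
#' as usual for Bioconductor.
#'
#' @param path path to a BED3/BED6 file.
#' @param chrom_sizes optional named integer vector of chromosome lengths
#'   (as from [read_chrom_sizes()]); when given, it is attached as
#'   `seqlengths` so downstream operations can clip at chromosome bounds.
#' @return a `GRanges`.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(chrom_sizes)) {
    gr <- set_chrom_sizes(gr, chrom_sizes)
  }
  gr
}

#' Write genomic intervals to a BED file
#'
#' @param gr a `GRanges`; metadata columns `name` and `score` are written
#'   when present (BED6), otherwise only the coordinates (BED3 plus strand
#'   when any strand is set).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "size"),
                    colClasses = c("character", "integer"))
  setNames(tab$size, tab$chrom)
}

# Attach seqlengths, expanding seqlevels as needed.
set_chrom_sizes <- function(gr, chrom_sizes) {
  miss <- setdiff(seqlevels(gr), names(chrom_sizes))
  if (length(miss) > 0) {
    stop("no chromosome size given for: ", paste(miss, collapse = ", "))
  }
  seqlengths(gr) <- chrom_sizes[seqlevels(gr)]
  gr
}

#' Read a cassette-event table
#'
#' The table is tab-separated with one row per exon-triplet event and
#' columns `event_id`, `gene_id`, `chrom`, `strand`, the six exon
#' coordinates `E1_start`, `E1_end`, `E2_start`, `E2_end`, `E3_start`,
#' `E3_end` (BED convention, 0-based half-open, in *genomic* order;
#' `E1`/`E3` denote the upstream/downstream exon in transcript
#' orientation), and optionally `label`, `fold_change`, `expr_pvalue`,
#' `first_or_second` and `overlaps_nonreg`.  Coordinates are converted to
#' 1-based closed on read.
#'
#' @param path path to the TSV.
#' @return a `data.frame` of events with 1-based closed coordinates.
#' @export
read_events <- function(path) {
  ev <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  needed <- c("event_id", "gene_id", "chrom", "strand",
              "E1_start", "E1_end", "E2_start", "E2_end",
              "E3_start", "E3_end")
  miss <- setdiff(needed, names(ev))
  if (length(miss) > 0) {
    stop("event table lacks columns: ", paste(miss, collapse = ", "))
  }
  for (col in c("E1_start", "E2_start", "E3_start")) {
    ev[[col]] <- ev[[col]] + 1L
  }
  validate_events(ev)
  ev
}

#' Write a cassette-event table
#'
#' Inverse of [read_events()]: starts are converted back to the 0-based BED
#' convention.
#'
#' @param events event `data.frame` (1-based closed coordinates).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  ev <- events
  for (col in c("E1_start", "E2_start", "E3_start")) {
    ev[[col]] <- ev[[col]] - 1L
  }
  write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Geometry sanity checks on an event table (1-based closed coordinates,
# exons in genomic order).  Introns must be at least 1 nt.
validate_events <- function(events) {
  with(events, {
    if (any(E1_start > E1_end | E2_start > E2_end | E3_start > E3_end)) {
      stop("malformed exon coordinates (start > end)")
    }
    if (any(E1_end + 1 >= E2_start) || any(E2_end + 1 >= E3_start)) {
      bad <- which(E1_end + 1 >= E2_start | E2_end + 1 >= E3_start)
      stop("intron shorter than 1 nt in event(s): ",
           paste(head(events$event_id[bad], 5), collapse = ", "))
    }
    if (!all(strand %in% c("+", "-"))) {
      stop("event strand must be '+' or '-'")
    }
  })
  invisible(events)
}

# Exon/intron GRanges accessors for an event table.  `part` is one of
# "E1","I1","E2","I2","E3" named in transcript orientation: on the minus
# strand E1 is the genomically rightmost exon.
event_part <- function(events, part) {
  plus <- events$strand == "+"
  # genomic-order part per row: for minus-strand events, transcript E1 is
  # genomic E3 and I1 is I2.
  flip <- c(E1 = "E3", I1 = "I2", E2 = "E2", I2 = "I1", E3 = "E1")
  gpart <- ifelse(plus, part, flip[[part]])
  start <- integer(nrow(events)); end <- integer(nrow(events))
  pick <- function(rows, s, e) {
    start[rows] <<- events[[s]][rows]; end[rows] <<- events[[e]][rows]
  }
  for (gp in unique(gpart)) {
    rows <- which(gpart == gp)
    switch(gp,
      E1 = pick(rows, "E1_start", "E1_end"),
      E2 = pick(rows, "E2_start", "E2_end"),
      E3 = pick(rows, "E3_start", "E3_end"),
      I1 = { start[rows] <- events$E1_end[rows] + 1L
             end[rows]   <- events$E2_start[rows] - 1L },
      I2 = { start[rows] <- events$E2_end[rows] + 1L
             end[rows]   <- events$E3_start[rows] - 1L })
  }
  GRanges(events$chrom, IRanges(start, end), strand = events$strand,
          event_id = events$event_id)
}
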
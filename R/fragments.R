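#' Restriction fragment map
#'
#' Ordered restriction fragments of one chromosome, the coordinate authority
#' for every track in the package. Coordinates are 0-based half-open (BED
#' convention) throughout.
#'
#' @param chrom chromosome name.
#' @param start,end integer vectors of fragment bounds (0-based half-open).
#' @return a `fragment_map`: a data.frame with columns `start`, `end`,
#'   `length`, `mid` and attribute `chrom`.
#' @export
fragment_map <- function(chrom, start, end) {
  if (length(start) != length(end)) stop("start and end differ in length")
  if (length(start) == 0L) stop("a fragment map needs at least one fragment")
  o <- order(start)
  start <- as.numeric(start[o]); end <- as.numeric(end[o])
  if (any(end <= start)) stop("every fragment length must be > 0")
  if (any(start[-1L] < end[-length(end)]))
    stop("fragments overlap; a fragment map must be non-overlapping")
  if (any(start[-1L] > end[-length(end)]))
    warning("fragment map has gaps between fragments")
  fm <- data.frame(start = start, end = end,
                   length = end - start, mid = (start + end) / 2)
  attr(fm, "chrom") <- as.character(chrom)
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

#' @export
print.fragment_map <- function(x, ...) {
  cat(sprintf("Fragment map: %d fragments on %s, span [%d, %d), median length %d bp\n",
              nrow(x), attr(x, "chrom"), as.integer(min(x$start)),
              as.integer(max(x$end)), as.integer(stats::median(x$length))))
  invisible(x)
}

#' In-silico restriction digestion
#'
#' Cuts a DNA sequence at every occurrence of the enzyme recognition site.
#' The cut position is the site start, so each fragment (except the first)
#' carries the recognition site at its 5' end. Overlapping site occurrences
#' are resolved left to right, non-overlapping.
#'
#' @param sequence DNA sequence: a single character string (A/C/G/T/N) or a
#'   `Biostrings::DNAString`.
#' @param recognition_site recognition sequence, e.g. `"AAGCTT"` for HindIII.
#' @param chrom chromosome name recorded in the output.
#' @return a [fragment_map] tiling `[0, nchar(sequence))`.
#' @export
digest_sequence <- function(sequence, recognition_site, chrom = "chr") {
  sequence <- toupper(as.character(sequence))
  recognition_site <- toupper(as.character(recognition_site))
  if (nchar(sequence) == 0L) stop("sequence is empty")
  if (nchar(recognition_site) == 0L) stop("recognition site is empty")
  if (nchar(recognition_site) >= nchar(sequence))
    stop("recognition site must be shorter than the sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside A/C/G/T/N")
  if (grepl("[^ACGTN]", recognition_site))
    stop("recognition site contains characters outside A/C/G/T/N")
  m <- gregexpr(recognition_site, sequence, fixed = TRUE)[[1L]]
  cuts <- if (m[1L] == -1L) integer(0) else as.integer(m) - 1L  # 0-based starts
  cuts <- cuts[cuts > 0L]
  bounds <- unique(c(0L, cuts, nchar(sequence)))
  fragment_map(chrom, bounds[-length(bounds)], bounds[-1L])
}

#' Digest the first sequence of a FASTA file
#'
#' @param fasta path to an (uncompressed) FASTA file.
#' @inheritParams digest_sequence
#' @return a [fragment_map].
#' @export
digest_fasta <- function(fasta, recognition_site) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequence in ", fasta)
  digest_sequence(as.character(seqs[[1L]]), recognition_site,
                  chrom = sub("\\s.*$", "", names(seqs)[1L]))
}

#' Read / write a fragment map as BED
#'
#' @param path file path.
#' @return `read_fragment_bed` returns a [fragment_map].
#' @export
read_fragment_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  fragment_map(b[[1L]][1L], b[[2L]], b[[3L]])
}

#' @rdname read_fragment_bed
#' @param fm a [fragment_map].
#' @export
write_fragment_bed <- function(fm, path) {
  utils::write.table(
    data.frame(attr(fm, "chrom"), as.integer(fm$start), as.integer(fm$end)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Viewpoint definitions
#'
#' A viewpoint is the anchored restriction fragment (or contiguous run of
#' fragments) whose genome-wide contacts one 4C experiment measures. The
#' viewpoint length enters the biased-contact-probability normalization.
#'
#' @param id character ids.
#' @param start,end viewpoint intervals, 0-based half-open bp.
#' @param chrom chromosome name.
#' @return a `viewpoint_set` data.frame with columns `id`, `start`, `end`,
#'   `length`, `mid`.
#' @export
viewpoint_set <- function(id, start, end, chrom = "chr") {
  if (anyDuplicated(id)) stop("viewpoint ids must be unique")
  vp <- data.frame(id = as.character(id), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (any(vp$end <= vp$start)) stop("viewpoint length must be > 0")
  vp$length <- vp$end - vp$start
  vp$mid <- (vp$start + vp$end) / 2
  attr(vp, "chrom") <- chrom
  class(vp) <- c("viewpoint_set", "data.frame")
  vp
}

#' Read a capture-count table
#'
#' Reads tab-delimited per-fragment capture counts and aligns them to a
#' fragment map. Columns `chrom`, `start`, `end`, `count` are required;
#' optional `viewpoint`, `replicate`, `condition` columns carry the
#' experiment layout (defaults can be supplied instead). Rows are matched to
#' fragments by exact interval; with `midpoint_fallback = TRUE` a row whose
#' interval midpoint falls inside a single fragment is accepted too. Rows
#' matching no fragment are returned in a rejects report, never silently
#' dropped.
#'
#' @param path TSV file with a header line.
#' @param fragment_map a [fragment_map].
#' @param viewpoint,replicate,condition defaults used when the file lacks the
#'   corresponding column.
#' @param midpoint_fallback logical; allow midpoint containment matching.
#' @return a `capture_table`: data.frame with columns `viewpoint`, `fragment`
#'   (index into the fragment map), `replicate`, `condition`, `count`, and a
#'   `rejects` attribute holding unmatched rows.
#' @export
read_capture_table <- function(path, fragment_map, viewpoint = NA,
                               replicate = "1", condition = "WT",
                               midpoint_fallback = FALSE) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) return(capture_table_empty())
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(raw)))
    stop("capture table needs columns: ", paste(need, collapse = ", "))
  if (!"viewpoint" %in% names(raw)) raw$viewpoint <- viewpoint
  if (!"replicate" %in% names(raw)) raw$replicate <- replicate
  if (!"condition" %in% names(raw)) raw$condition <- condition
  idx <- match_fragments(raw$start, raw$end, fragment_map, midpoint_fallback)
  ok <- !is.na(idx)
  ct <- capture_table(viewpoint = raw$viewpoint[ok], fragment = idx[ok],
                      replicate = raw$replicate[ok],
                      condition = raw$condition[ok], count = raw$count[ok])
  attr(ct, "rejects") <- raw[!ok, , drop = FALSE]
  ct
}

match_fragments <- function(start, end, fm, midpoint_fallback = FALSE) {
  i <- match(paste(start, end), paste(fm$start, fm$end))
  if (midpoint_fallback && anyNA(i)) {
    mid <- (start + end) / 2
    j <- findInterval(mid, fm$start)
    hit <- j >= 1L & mid < fm$end[pmax(j, 1L)]
    i[is.na(i) & hit] <- j[is.na(i) & hit]
  }
  i
}

#' Capture-count container
#'
#' @param viewpoint,fragment,replicate,condition,count parallel vectors; one
#'   row per (viewpoint, fragment, replicate, condition) observation.
#' @return a `capture_table` data.frame.
#' @export
capture_table <- function(viewpoint, fragment, replicate, condition, count) {
  count <- as.numeric(count)
  if (any(count < 0) || any(count != floor(count)))
    stop("counts must be non-negative integers")
  ct <- data.frame(viewpoint = as.character(viewpoint),
                   fragment = as.integer(fragment),
                   replicate = as.character(replicate),
                   condition = as.character(condition),
                   count = count, stringsAsFactors = FALSE)
  class(ct) <- c("capture_table", "data.frame")
  ct
}

capture_table_empty <- function() {
  ct <- capture_table(character(0), integer(0), character(0), character(0),
                      numeric(0))
  attr(ct, "rejects") <- data.frame()
  ct
}

#' Write / read numeric genomic tracks
#'
#' Serializes per-interval values as bedGraph (chrom/start/end/value, 0-based
#' half-open) or as TSV with a header. Intervals with NA/NaN values are
#' omitted on writing, so only finite-valued intervals appear on disk.
#'
#' @param track data.frame with columns `start`, `end`, `value` (bp, 0-based
#'   half-open).
#' @param path output file.
#' @param chrom chromosome name for the first column.
#' @param format `"bedGraph"` or `"tsv"`.
#' @param digits significant digits written (values round-trip at this
#'   precision).
#' @return the path, invisibly.
#' @export
write_track <- function(track, path, chrom = "chr",
                        format = c("bedGraph", "tsv"), digits = 10) {
  format <- match.arg(format)
  keep <- is.finite(track$value)
  out <- data.frame(chrom = chrom, start = as.integer(track$start[keep]),
                    end = as.integer(track$end[keep]),
                    value = signif(track$value[keep], digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = identical(format, "tsv"))
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path, format = c("bedGraph", "tsv")) {
  format <- match.arg(format)
  tr <- utils::read.table(path, sep = "\t", header = identical(format, "tsv"),
                          stringsAsFactors = FALSE)
  names(tr) <- c("chrom", "start", "end", "value")[seq_along(tr)]
  tr
}

#' Grid helper: interval bounds for grid-centred windows
#'
#' @param pos grid-point centres (bp).
#' @param step grid spacing (bp).
#' @keywords internal
grid_track <- function(pos, value, step) {
  data.frame(start = pos - step / 2, end = pos + step / 2, value = value)
}
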
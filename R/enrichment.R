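#' Interval set on one chromosome
#'
#' @param start,end 0-based half-open intervals in bp.
#' @param chrom chromosome name.
#' @return an `interval_set` data.frame, sorted by start; within-set overlaps
#'   are allowed but flagged via the `overlapping` attribute.
#' @export
interval_set <- function(start, end, chrom = "chr") {
  if (length(start) != length(end)) stop("start and end differ in length")
  if (any(end <= start)) stop("intervals must have positive length")
  o <- order(start)
  x <- data.frame(start = as.numeric(start[o]), end = as.numeric(end[o]))
  attr(x, "chrom") <- chrom
  attr(x, "overlapping") <- nrow(x) > 1L &&
    any(x$start[-1L] < x$end[-nrow(x)])
  class(x) <- c("interval_set", "data.frame")
  x
}

#' Read a BED file as an interval set
#' @param path BED path (first three columns used).
#' @export
read_interval_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  interval_set(b[[2L]], b[[3L]], chrom = b[[1L]][1L])
}

as_iranges <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

#' Base-pair overlap between two interval sets
#'
#' Total length of the intersection of the two (merged) sets, plus the count
#' of query intervals touching the annotation.
#'
#' @param a,b `interval_set`s (or data.frames with `start`/`end`).
#' @return list with `bp` (intersection length) and `n_query` (intervals of
#'   `a` overlapping `b`).
#' @export
overlap_bp <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(list(bp = 0, n_query = 0L))
  ra <- IRanges::reduce(as_iranges(a))
  rb <- IRanges::reduce(as_iranges(b))
  list(bp = sum(IRanges::width(IRanges::intersect(ra, rb))),
       n_query = sum(IRanges::overlapsAny(as_iranges(a), rb)))
}

#' Permutation (random-sampling) enrichment test
#'
#' Tests whether a query set (e.g. DIRs) overlaps an annotation set (e.g.
#' CTCF/Smc1 binding sites) more than expected by chance. The null model
#' re-places the annotation intervals uniformly and independently within the
#' domain (lengths preserved, excluded regions such as a deletion honored)
#' while the query is held fixed. The empirical upper-tail p-value is
#' (1 + #\{null >= observed\}) / (n_perm + 1), so the minimum attainable p
#' with 999 permutations is 0.001.
#'
#' @param query,annotation `interval_set`s.
#' @param domain_length chromosome (domain) length in bp.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param exclude optional `interval_set` of regions where annotation
#'   intervals may not be placed.
#' @param statistic `"bp"` (intersection length, primary) or `"count"`
#'   (overlapping query intervals).
#' @return an `overlap_stat`: list with `observed`, `null` (vector), `p`,
#'   `n_perm`, `seed`, `statistic`.
#' @export
permutation_enrichment <- function(query, annotation, domain_length,
                                   n_perm = 999, seed = NULL, exclude = NULL,
                                   statistic = c("bp", "count")) {
  statistic <- match.arg(statistic)
  if (n_perm < 100) stop("use at least 100 permutations")
  if (nrow(annotation) == 0L) stop("annotation set is empty")
  stat <- function(ann) {
    ov <- overlap_bp(query, ann)
    if (statistic == "bp") ov$bp else ov$n_query
  }
  lens <- annotation$end - annotation$start
  gaps <- placement_gaps(domain_length, exclude)
  if (max(lens) > max(gaps$end - gaps$start))
    stop("an annotation interval is longer than the largest placeable gap")
  if (!is.null(seed)) set.seed(seed)
  observed <- stat(annotation)
  null <- vapply(seq_len(n_perm), function(i) {
    st <- place_uniform(lens, gaps)
    stat(data.frame(start = st, end = st + lens))
  }, numeric(1))
  structure(list(observed = observed, null = null,
                 p = (1 + sum(null >= observed)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, statistic = statistic),
            class = "overlap_stat")
}

placement_gaps <- function(domain_length, exclude = NULL) {
  if (is.null(exclude) || nrow(exclude) == 0L)
    return(data.frame(start = 0, end = domain_length))
  r <- IRanges::reduce(as_iranges(exclude))
  g <- IRanges::gaps(r, start = 1L, end = as.integer(domain_length))
  data.frame(start = IRanges::start(g) - 1, end = IRanges::end(g))
}

# uniform independent placement of intervals of the given lengths into gaps,
# each start uniform over all feasible positions
place_uniform <- function(lens, gaps) {
  vapply(lens, function(l) {
    w <- pmax(0, (gaps$end - gaps$start) - l + 1)
    if (sum(w) == 0) stop("interval of length ", l, " does not fit")
    g <- sample.int(nrow(gaps), 1L, prob = w)
    gaps$start[g] + floor(stats::runif(1) * w[g])
  }, numeric(1))
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("Permutation enrichment (%s statistic): observed %.4g, null mean %.4g, p = %.4g (%d permutations)\n",
              x$statistic, x$observed, mean(x$null), x$p, x$n_perm))
  invisible(x)
}

#' Running-coverage density track
#'
#' Fraction of each window covered by annotation base pairs, evaluated on a
#' uniform grid (the running average used to display binding-site footprint
#' density alongside DIRs).
#'
#' @param annotation an `interval_set`.
#' @param domain_length domain length in bp.
#' @param window window size in bp (default 20 kb).
#' @param grid_step grid spacing (default = window).
#' @return data.frame with `pos` (window centres) and `density` in \[0, 1\].
#' @export
density_track <- function(annotation, domain_length, window = 20000,
                          grid_step = window) {
  if (window <= 0) stop("window must be positive")
  pos <- seq(window / 2, domain_length, by = grid_step)
  if (nrow(annotation) == 0L)
    return(data.frame(pos = pos, density = rep(0, length(pos))))
  r <- IRanges::reduce(as_iranges(annotation))
  st <- IRanges::start(r) - 1; en <- IRanges::end(r)
  cum <- c(0, cumsum(en - st))
  covered_upto <- function(x) {
    i <- findInterval(x, st)
    j <- pmax(i, 1L)
    v <- cum[j] + pmin(pmax(x - st[j], 0), (en - st)[j])
    v[i == 0L] <- 0
    v
  }
  lo <- pmax(pos - window / 2, 0)
  hi <- pmin(pos + window / 2, domain_length)
  data.frame(pos = pos,
             density = (covered_upto(hi) - covered_upto(lo)) / (hi - lo))
}
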
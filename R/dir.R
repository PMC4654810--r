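#' Differential relative contact probability (DRCP)
#'
#' DRCP = (log P_test - log P_ref) / |log P_ref| on the smoothed CPP grid.
#' Dividing by |log P_ref| (rather than the signed log, which is negative for
#' probabilities below 1) makes positive DRCP mean increased contact
#' probability in the test condition. Before comparison the test profile is
#' rescaled by a common factor so that its mean over the shared covered grid
#' points matches the reference, removing residual experiment scale. Grid
#' points where either profile is missing, or where the reference carries
#' only pseudo-count floor data, are masked.
#'
#' @param p_test,p_ref `smoothed_cpp` tracks on the same grid (test =
#'   e.g. deletion, ref = wild type).
#' @param rescale match the test profile's mean to the reference over shared
#'   covered grid points (default TRUE).
#' @return a `drcp_track` data.frame with columns `pos`, `drcp`.
#' @export
compute_drcp <- function(p_test, p_ref, rescale = TRUE) {
  if (nrow(p_test) != nrow(p_ref) || any(p_test$pos != p_ref$pos))
    stop("test and reference tracks are on different grids")
  ok <- is.finite(p_test$value) & is.finite(p_ref$value) &
    p_test$value > 0 & p_ref$value > 0
  v_test <- p_test$value
  if (rescale && any(ok)) {
    v_test <- v_test * mean(p_ref$value[ok]) / mean(p_test$value[ok])
  }
  use <- ok & p_ref$informative
  drcp <- rep(NA_real_, nrow(p_test))
  drcp[use] <- (log(v_test[use]) - log(p_ref$value[use])) /
    abs(log(p_ref$value[use]))
  tr <- data.frame(pos = p_test$pos, drcp = drcp)
  attr(tr, "window") <- attr(p_test, "window")
  attr(tr, "viewpoint") <- attr(p_test, "viewpoint")
  class(tr) <- c("drcp_track", "data.frame")
  tr
}

#' Windowed Mann-Whitney test on raw CPP values
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test comparing the raw,
#' unsmoothed per-fragment CPP values of the two conditions inside a window.
#' Windows with fewer than `min_n` fragments on either side are untestable
#' and return NA rather than raising.
#'
#' @param raw_test,raw_ref numeric vectors of raw CPP values in the window.
#' @param min_n minimum fragments per side (default 3).
#' @return two-sided p-value, or NA when untestable.
#' @export
test_window <- function(raw_test, raw_ref, min_n = 3) {
  if (length(raw_test) < min_n || length(raw_ref) < min_n) return(NA_real_)
  suppressWarnings(stats::wilcox.test(raw_test, raw_ref)$p.value)
}

#' Call differentially interacting regions (DIRs)
#'
#' Seeds are grid points where |DRCP| exceeds the signal threshold with
#' consistent sign in both biological replicates (a same-sign seed within the
#' window size in the other replicate counts as support), and where the
#' windowed Mann-Whitney test on the raw CPPs rejects in both replicates.
#' Each significant seed contributes its bracketing window; overlapping or
#' adjacent same-sign windows are merged into maximal intervals. Grid points
#' inside a declared deletion are excluded.
#'
#' @param drcp list of two `drcp_track`s (replicates 1, 2) for the same
#'   test-vs-reference comparison.
#' @param raw_test,raw_ref lists of two `cpp_profile`s (raw, per replicate).
#' @param signal_threshold minimum |DRCP| (default 0.05, i.e. 5 %).
#' @param alpha per-window significance level in each replicate (default
#'   0.05).
#' @param window test window size in bp, equal to the smoothing filter size
#'   (default 80 kb).
#' @param deletion optional `c(start, end)`; grid points inside are masked.
#' @return a `dir_calls` data.frame: `start`, `end`, `direction`
#'   (`"increase"`/`"decrease"`), `max_drcp` (signed, extreme over member
#'   seeds and replicates), `p_rep1`, `p_rep2` (minimum window p-values over
#'   member seeds).
#' @export
call_dirs <- function(drcp, raw_test, raw_ref, signal_threshold = 0.05,
                      alpha = 0.05, window = 80000, deletion = NULL) {
  if (length(drcp) != 2L || length(raw_test) != 2L || length(raw_ref) != 2L)
    stop("DIR calling is defined on exactly two biological replicates")
  if (any(drcp[[1L]]$pos != drcp[[2L]]$pos))
    stop("replicate DRCP tracks are on different grids")
  pos <- drcp[[1L]]$pos
  v1 <- drcp[[1L]]$drcp; v2 <- drcp[[2L]]$drcp
  seed1 <- !is.na(v1) & abs(v1) >= signal_threshold
  seed2 <- !is.na(v2) & abs(v2) >= signal_threshold
  if (!is.null(deletion)) {
    inside <- pos >= deletion[1L] & pos < deletion[2L]
    seed1[inside] <- FALSE
    seed2[inside] <- FALSE
  }
  supported <- function(g, sgn, seed_o, v_o) {
    near <- abs(pos - pos[g]) <= window & seed_o & sign(v_o) == sgn
    any(near)
  }
  cand <- which(seed1 | seed2)
  calls <- list()
  half <- window / 2
  for (g in cand) {
    sgn <- sign(if (seed1[g]) v1[g] else v2[g])
    ok1 <- seed1[g] && sign(v1[g]) == sgn || supported(g, sgn, seed1, v1)
    ok2 <- seed2[g] && sign(v2[g]) == sgn || supported(g, sgn, seed2, v2)
    if (!(ok1 && ok2)) next
    p1 <- window_p(raw_test[[1L]], raw_ref[[1L]], pos[g], half)
    if (is.na(p1) || p1 >= alpha) next
    p2 <- window_p(raw_test[[2L]], raw_ref[[2L]], pos[g], half)
    if (is.na(p2) || p2 >= alpha) next
    calls[[length(calls) + 1L]] <-
      data.frame(start = pos[g] - half, end = pos[g] + half,
                 direction = if (sgn > 0) "increase" else "decrease",
                 max_drcp = c(v1[g], v2[g])[which.max(abs(c(v1[g], v2[g])))],
                 p_rep1 = p1, p_rep2 = p2)
  }
  out <- merge_calls(calls)
  attr(out, "signal_threshold") <- signal_threshold
  attr(out, "alpha") <- alpha
  attr(out, "window") <- window
  class(out) <- c("dir_calls", "data.frame")
  out
}

# window test on raw CPPs; fragments carrying only the pseudo-count are
# missing data, not observations, and are excluded from the ranks
window_p <- function(raw_test, raw_ref, centre, half) {
  floor_t <- if ("at_floor" %in% names(raw_test)) raw_test$at_floor else FALSE
  floor_r <- if ("at_floor" %in% names(raw_ref)) raw_ref$at_floor else FALSE
  it <- abs(raw_test$mid - centre) <= half & !raw_test$self & !floor_t
  ir <- abs(raw_ref$mid - centre) <= half & !raw_ref$self & !floor_r
  test_window(raw_test$P[it], raw_ref$P[ir])
}

merge_calls <- function(calls) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      direction = character(0), max_drcp = numeric(0),
                      p_rep1 = numeric(0), p_rep2 = numeric(0))
  if (length(calls) == 0L) return(empty)
  x <- do.call(rbind, calls)
  out <- lapply(split(x, x$direction), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    grp <- cumsum(c(1, d$start[-1L] > cummax(d$end[-nrow(d)])))
    do.call(rbind, lapply(split(d, grp), function(m) {
      data.frame(start = min(m$start), end = max(m$end),
                 direction = m$direction[1L],
                 max_drcp = m$max_drcp[which.max(abs(m$max_drcp))],
                 p_rep1 = min(m$p_rep1), p_rep2 = min(m$p_rep2))
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read DIR calls
#'
#' BED6+ output: name encodes the call index and direction, score is
#' 1000 * min(1, |max DRCP|); the extra columns round-trip the full call.
#'
#' @param calls a `dir_calls` data.frame.
#' @param path output path.
#' @param chrom chromosome name.
#' @export
write_dirs <- function(calls, path, chrom = "chr") {
  if (nrow(calls) == 0L) {
    writeLines(paste(c("chrom", "start", "end", "name", "score", "strand",
                       "direction", "max_drcp", "p_rep1", "p_rep2"),
                     collapse = "\t"), path)
    return(invisible(path))
  }
  for (d in unique(calls$direction)) {
    sub <- calls[calls$direction == d, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping same-direction calls; merge upstream")
  }
  out <- data.frame(chrom = chrom, start = as.integer(calls$start),
                    end = as.integer(calls$end),
                    name = sprintf("DIR_%d_%s", seq_len(nrow(calls)),
                                   calls$direction),
                    score = as.integer(round(1000 * pmin(1, abs(calls$max_drcp)))),
                    strand = ".",
                    direction = calls$direction,
                    max_drcp = calls$max_drcp,
                    p_rep1 = calls$p_rep1, p_rep2 = calls$p_rep2)
  out <- out[order(out$start), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dirs
#' @export
read_dirs <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  out <- x[, c("start", "end", "direction", "max_drcp", "p_rep1", "p_rep2")]
  out$start <- as.numeric(out$start); out$end <- as.numeric(out$end)
  class(out) <- c("dir_calls", "data.frame")
  out
}
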
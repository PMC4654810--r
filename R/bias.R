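#' Biased contact probability (BCP) profiles
#'
#' Phase 1 length normalization: each capture count is divided by the product
#' of viewpoint length and fragment length, giving the biased contact
#' probability F (count per bp^2). Genomic separations s are midpoint-to-
#' midpoint distances; for a condition carrying a heterozygous deletion the
#' separation of a pair straddling the deletion is shortened by the deleted
#' length, so decay fits see the distances of the rearranged chromosome.
#'
#' @param counts a [capture_table].
#' @param viewpoints a [viewpoint_set].
#' @param frags a [fragment_map].
#' @param deletion optional `c(start, end)` deletion interval in reference bp.
#' @param deletion_conditions condition labels whose chromosomes carry the
#'   deletion (separations adjusted for those only).
#' @return a list of `bcp_profile` objects, one per (viewpoint, condition,
#'   replicate) present in `counts`, named `"vp|condition|replicate"`. Each is
#'   a data.frame with columns `fragment`, `mid`, `s`, `count`, `F`, `self`
#'   and attributes `viewpoint`, `vp_length`, `condition`, `replicate`,
#'   `span`, `chrom`.
#' @export
compute_bcp <- function(counts, viewpoints, frags, deletion = NULL,
                        deletion_conditions = NULL) {
  if (any(frags$length <= 0)) stop("zero-length fragment in fragment map")
  key <- paste(counts$viewpoint, counts$condition, counts$replicate, sep = "|")
  lapply(split(seq_len(nrow(counts)), key), function(rows) {
    sub <- counts[rows, , drop = FALSE]
    vp <- viewpoints[match(sub$viewpoint[1L], viewpoints$id), ]
    if (is.na(vp$id)) stop("unknown viewpoint: ", sub$viewpoint[1L])
    del <- if (!is.null(deletion) &&
               sub$condition[1L] %in% deletion_conditions) deletion
    bcp_profile(sub$count, sub$fragment, frags, vp,
                condition = sub$condition[1L], replicate = sub$replicate[1L],
                deletion = del)
  })
}

#' Build a single BCP profile
#'
#' @param count counts aligned to `fragment` indices.
#' @param fragment fragment indices into `frags`.
#' @inheritParams compute_bcp
#' @param vp one row of a [viewpoint_set].
#' @param condition,replicate labels stored as attributes.
#' @export
bcp_profile <- function(count, fragment, frags, vp, condition = "WT",
                        replicate = "1", deletion = NULL) {
  if (vp$length <= 0) stop("viewpoint length must be > 0")
  if (!is.null(deletion)) {
    # fragments inside the deletion do not exist on this chromosome
    keep <- frags$mid[fragment] < deletion[1L] | frags$mid[fragment] >= deletion[2L]
    count <- count[keep]; fragment <- fragment[keep]
  }
  mid <- frags$mid[fragment]
  s <- deletion_separation(vp$mid, mid, deletion)
  self <- frags$start[fragment] < vp$end & frags$end[fragment] > vp$start
  pr <- data.frame(fragment = fragment, mid = mid, s = s,
                   count = as.numeric(count),
                   F = count / (vp$length * frags$length[fragment]),
                   self = self)
  attr(pr, "viewpoint") <- vp$id
  attr(pr, "vp_length") <- vp$length
  attr(pr, "vp_mid") <- vp$mid
  attr(pr, "condition") <- condition
  attr(pr, "replicate") <- replicate
  attr(pr, "span") <- c(min(frags$start), max(frags$end))
  attr(pr, "chrom") <- attr(frags, "chrom")
  class(pr) <- c("bcp_profile", "data.frame")
  pr
}

# separation between two reference coordinates, in deleted coordinates when
# the pair straddles a deletion interval
deletion_separation <- function(a, b, deletion = NULL) {
  s <- abs(a - b)
  if (is.null(deletion)) return(s)
  dl <- deletion[2L] - deletion[1L]
  straddle <- (pmin(a, b) < deletion[1L]) & (pmax(a, b) >= deletion[2L])
  s[straddle] <- s[straddle] - dl
  s
}

#' Smoothing-spline fit of the log-log contact decay
#'
#' Fits log F against log s with a smoothing spline (GCV-selected smoothing),
#' the Phase 1/4 workhorse. Only positive, non-self observations inside the
#' fit range contribute; the fitted curve and its analytic derivative are
#' evaluable at arbitrary separations.
#'
#' @param profile a `bcp_profile` (or any data.frame with columns `s`, `F`
#'   and optionally `self`).
#' @param fit_range bp interval used for fitting; the decay is typically
#'   linear in log-log between 10 kb and 10 Mb.
#' @param min_points minimum usable observations.
#' @param df_floor lower bound on effective degrees of freedom of the spline.
#' @return a `decay_fit` with elements `spline`, `support` (log-s range),
#'   `n`, `viewpoint`.
#' @export
fit_loglog_decay <- function(profile, fit_range = c(1e4, 1e7),
                             min_points = 30, df_floor = 4) {
  self <- if ("self" %in% names(profile)) profile$self else FALSE
  use <- profile$F > 0 & !self & profile$s >= fit_range[1L] &
    profile$s <= fit_range[2L] & profile$s > 0
  vp <- attr(profile, "viewpoint")
  if (sum(use) < min_points)
    stop(sprintf("too few positive observations (%d < %d) to fit decay for viewpoint %s",
                 sum(use), min_points, if (is.null(vp)) "?" else vp))
  x <- log(profile$s[use]); y <- log(profile$F[use])
  fit <- tryCatch(stats::smooth.spline(x, y, keep.data = FALSE),
                  error = function(e) stats::smooth.spline(x, y, df = df_floor,
                                                           keep.data = FALSE))
  if (fit$df < df_floor)
    fit <- stats::smooth.spline(x, y, df = df_floor, keep.data = FALSE)
  structure(list(spline = fit, support = range(x), n = sum(use),
                 fit_range = fit_range, viewpoint = vp),
            class = "decay_fit")
}

#' Evaluate a decay fit
#'
#' @param fit a `decay_fit`.
#' @param s separations in bp.
#' @return `predict_decay`: fitted F (natural scale); `decay_slope`: d log F /
#'   d log s at `s`.
#' @export
predict_decay <- function(fit, s) {
  exp(stats::predict(fit$spline, log(s))$y)
}

#' @rdname predict_decay
#' @export
decay_slope <- function(fit, s) {
  stats::predict(fit$spline, log(s), deriv = 1)$y
}

#' Inter-viewpoint BCP matrix from smoothed decays
#'
#' The average BCP between viewpoints I and J is read off viewpoint I's
#' smoothed decay at separation s_IJ, deliberately not off the raw captures at
#' J's fragments, which may be dominated by specific biological interactions.
#'
#' @param fits named list of `decay_fit`s, one per viewpoint, in chromosomal
#'   order.
#' @param viewpoints a [viewpoint_set] (same order as `fits`).
#' @param deletion optional deletion interval applied to pair separations.
#' @return a `pair_matrix`: list with `F` (n x n, diagonal NA), `s` (symmetric
#'   separations), `extrapolated` (logical matrix, TRUE where s_IJ fell
#'   outside the fit support).
#' @export
interviewpoint_bcp <- function(fits, viewpoints, deletion = NULL) {
  n <- length(fits)
  if (n != nrow(viewpoints)) stop("one decay fit per viewpoint required")
  mids <- viewpoints$mid
  s <- outer(mids, mids, function(a, b) deletion_separation(a, b, deletion))
  F <- matrix(NA_real_, n, n, dimnames = list(viewpoints$id, viewpoints$id))
  extra <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    j <- setdiff(seq_len(n), i)
    F[i, j] <- predict_decay(fits[[i]], s[i, j])
    extra[i, j] <- log(s[i, j]) < fits[[i]]$support[1L] |
      log(s[i, j]) > fits[[i]]$support[2L]
  }
  structure(list(F = F, s = s, extrapolated = extra, ids = viewpoints$id),
            class = "pair_matrix")
}

#' Solve viewpoint and experiment bias factors
#'
#' The bias model is F_IJ = C_I C_J K_I P_IJ with P_IJ symmetric: C are
#' viewpoint-sequence bias factors, K experiment bias factors. In log space
#' the antisymmetric part of the selected equations, log F_IJ - log F_JI =
#' log K_I - log K_J, determines K up to gauge; the symmetrized sums together
#' with a power-law model for P over the selected pairs determine C; the
#' corrected symmetric P_IJ is then implied for all pairs, not only the
#' fitted ones. Gauge convention: geometric mean of C and of K is 1.
#'
#' @param pair_matrix a `pair_matrix` from [interviewpoint_bcp] (or any list
#'   with positive matrix `F` and separations `s`).
#' @param pair_selection `"nn2"` restricts the fit to nearest and
#'   next-nearest viewpoint pairs in chromosomal order (the default, as in
#'   the underlying method); `"all"` uses every pair.
#' @return a `bias_factors` object: `C`, `K` (named positive vectors),
#'   `P` (corrected symmetric pair matrix), `Fhat` (reconstructed biased
#'   matrix), `residual` (RMS log residual of the reconstruction on selected
#'   pairs), `model_residual` (RMS residual of the power-law P model, a
#'   diagnostic only), `gauge`, `pairs`.
#' @export
solve_bias_factors <- function(pair_matrix, pair_selection = c("nn2", "all")) {
  pair_selection <- match.arg(pair_selection)
  F <- pair_matrix$F; s <- pair_matrix$s
  n <- nrow(F)
  if (n < 4L)
    stop("bias factors are not identifiable with fewer than 4 viewpoints (got ",
         n, ")")
  pairs <- utils::combn(n, 2L)
  if (pair_selection == "nn2")
    pairs <- pairs[, pairs[2L, ] - pairs[1L, ] <= 2L, drop = FALSE]
  I <- pairs[1L, ]; J <- pairs[2L, ]
  fij <- F[cbind(I, J)]; fji <- F[cbind(J, I)]
  if (any(!is.finite(fij) | !is.finite(fji) | fij <= 0 | fji <= 0)) {
    bad <- which(!is.finite(fij) | !is.finite(fji) | fij <= 0 | fji <= 0)[1L]
    stop(sprintf("non-positive BCP for selected viewpoint pair (%d, %d)",
                 I[bad], J[bad]))
  }
  m <- ncol(pairs)

  ## K from antisymmetric part, gauge sum(log K) = 0
  Xk <- matrix(0, m, n)
  Xk[cbind(seq_len(m), I)] <- 1
  Xk[cbind(seq_len(m), J)] <- -1
  dk <- log(fij) - log(fji)
  kap <- qr.solve(rbind(Xk, rep(1, n)), c(dk, 0))

  ## C jointly with power-law P = exp(a + b log s) from symmetrized sums,
  ## gauge sum(log C) = 0
  msum <- (log(fij) + log(fji)) / 2 - (kap[I] + kap[J]) / 2
  Xc <- matrix(0, m, n + 2L)
  Xc[cbind(seq_len(m), I)] <- 1
  Xc[cbind(seq_len(m), J)] <- 1
  Xc[, n + 1L] <- 1
  Xc[, n + 2L] <- log(s[cbind(I, J)])
  sol <- qr.solve(rbind(Xc, c(rep(1, n), 0, 0)), c(msum, 0))
  cc <- sol[seq_len(n)]
  model_residual <- sqrt(mean((msum - Xc %*% sol)^2))

  ## corrected symmetric P for all pairs
  lF <- log(F)
  msym <- (lF + t(lF)) / 2
  P <- exp(msym - outer(kap, kap, "+") / 2 - outer(cc, cc, "+"))
  diag(P) <- NA_real_
  Fhat <- exp(log(P) + outer(cc, cc, "+") + matrix(kap, n, n))
  resid <- sqrt(mean((log(Fhat[cbind(I, J)]) - log(fij))^2 +
                     (log(Fhat[cbind(J, I)]) - log(fji))^2) / 2)
  ids <- pair_matrix$ids
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(C = stats::setNames(exp(cc), ids),
                 K = stats::setNames(exp(kap), ids),
                 P = P, Fhat = Fhat, residual = resid,
                 model_residual = model_residual,
                 gauge = "geometric mean of C = geometric mean of K = 1",
                 pairs = t(pairs), pair_selection = pair_selection),
            class = "bias_factors")
}

#' @export
print.bias_factors <- function(x, ...) {
  cat(sprintf("Bias factors for %d viewpoints (%s pairs; %s)\n",
              length(x$C), x$pair_selection, x$gauge))
  print(round(rbind(C = x$C, K = x$K), 4))
  cat(sprintf("RMS log residual: %.3g (P power-law model: %.3g)\n",
              x$residual, x$model_residual))
  invisible(x)
}

#' Relative asymmetry matrix
#'
#' |M_IJ - M_JI| / (M_IJ + M_JI), the Phase 1 diagnostic: large values flag
#' viewpoint/experiment biases, values near zero a symmetric contact matrix.
#' Entries where both M_IJ and M_JI are zero (or missing) are NA.
#'
#' @param M square matrix with positive off-diagonal entries.
#' @return symmetric matrix of values in \[0, 1\], diagonal NA.
#' @export
relative_asymmetry <- function(M) {
  if (nrow(M) != ncol(M)) stop("M must be square")
  den <- M + t(M)
  A <- abs(M - t(M)) / den
  A[!is.finite(den) | den == 0] <- NA_real_
  diag(A) <- NA_real_
  A
}

#' Median off-diagonal relative asymmetry
#' @param M square positive matrix.
#' @export
median_asymmetry <- function(M) {
  A <- relative_asymmetry(M)
  stats::median(A[upper.tri(A)], na.rm = TRUE)
}
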
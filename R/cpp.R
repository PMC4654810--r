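#' Read-count thresholding and pseudo-counts
#'
#' Counts at or below the threshold are zeroed to suppress Poisson noise in
#' sparsely captured fragments, then the pseudo-count is added to every
#' fragment so missing data cannot generate spurious differential signals.
#' The order is fixed: threshold first, pseudo-count second, so the floor
#' value equals `pseudo`.
#'
#' @param counts non-negative integer vector.
#' @param threshold reads per restriction fragment at or below which a count
#'   is treated as missing (default 5).
#' @param pseudo pseudo-count added to all fragments (default 1).
#' @return integer vector, minimum value `pseudo`.
#' @export
threshold_and_pseudocount <- function(counts, threshold = 5, pseudo = 1) {
  if (threshold < 0) stop("threshold must be non-negative")
  if (pseudo < 0) stop("pseudo-count must be non-negative")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts[counts <= threshold] <- 0
  counts + pseudo
}

#' Unbiased contact probability profile (raw CPP)
#'
#' Phase 2: P = F / (C_I K_I), dividing the biased contact probability by the
#' viewpoint and experiment bias factors of the profile's viewpoint.
#'
#' @param bcp a `bcp_profile` (built from thresholded + pseudo-counted
#'   counts for downstream differential analysis).
#' @param factors a `bias_factors` object, or a list with named vectors `C`
#'   and `K`.
#' @param floor_count counts equal to this value are flagged `at_floor`
#'   (pseudo-count-only fragments); NULL disables the flag.
#' @return a `cpp_profile` data.frame with columns `fragment`, `mid`, `s`,
#'   `P`, `self`, `at_floor`, carrying the bcp profile's attributes.
#' @export
compute_cpp <- function(bcp, factors, floor_count = NULL) {
  vp <- attr(bcp, "viewpoint")
  if (!vp %in% names(factors$C) || !vp %in% names(factors$K))
    stop("no bias factors for viewpoint ", vp)
  P <- bcp$F / (factors$C[[vp]] * factors$K[[vp]])
  pr <- data.frame(fragment = bcp$fragment, mid = bcp$mid, s = bcp$s, P = P,
                   self = bcp$self,
                   at_floor = if (is.null(floor_count)) FALSE
                              else bcp$count <= floor_count)
  for (a in c("viewpoint", "vp_length", "vp_mid", "condition", "replicate",
              "span", "chrom"))
    attr(pr, a) <- attr(bcp, a)
  class(pr) <- c("cpp_profile", "data.frame")
  pr
}

#' Gaussian-kernel smoothing of a raw CPP onto a uniform grid
#'
#' Nadaraya-Watson kernel regression over restriction fragment midpoints,
#' with a Gaussian kernel of standard deviation `sigma` truncated at a total
#' filter size `window` (i.e. +/- window/2 around each grid point). Working
#' on the irregular midpoints, each fragment contributing once, avoids
#' aliasing from variable fragment sizes; length bias was already removed in
#' the BCP. Grid points with no fragment inside the window are missing, not
#' zero. The smoothing scale is the genomic resolution of the measurement,
#' hence the default grid step equals sigma.
#'
#' @param profile a `cpp_profile` (any data.frame with `mid` and `P`, plus
#'   optionally `at_floor`).
#' @param sigma kernel standard deviation, bp (default 20 kb).
#' @param window total filter size, bp (default 80 kb = 4 sigma).
#' @param grid_step grid spacing, bp (default = sigma).
#' @param grid optional explicit grid-point vector (bp); overrides
#'   `grid_step`/span.
#' @return a `smoothed_cpp` data.frame with columns `pos`, `value`, `n_frag`
#'   (fragments in window), `informative` (any contributing fragment above
#'   the pseudo-count floor), and attributes `sigma`, `window`, `grid_step`
#'   plus those of the input profile.
#' @export
smooth_cpp <- function(profile, sigma = 20000, window = 80000,
                       grid_step = sigma, grid = NULL) {
  if (nrow(profile) < 1L) stop("need at least one raw CPP value")
  if (sigma <= 0) stop("sigma must be positive")
  if (window < 2 * sigma) stop("window must be at least 2*sigma")
  if (is.null(grid)) {
    span <- attr(profile, "span")
    if (is.null(span)) span <- range(profile$mid)
    grid <- seq(span[1L] + grid_step / 2, span[2L], by = grid_step)
  }
  o <- order(profile$mid)
  mid <- profile$mid[o]; P <- profile$P[o]
  at_floor <- if ("at_floor" %in% names(profile)) profile$at_floor[o]
              else rep(FALSE, length(mid))
  half <- window / 2
  lo <- findInterval(grid - half, mid) + 1L
  hi <- findInterval(grid + half, mid)
  value <- rep(NA_real_, length(grid))
  n_frag <- hi - lo + 1L
  informative <- rep(FALSE, length(grid))
  for (g in which(n_frag > 0L)) {
    i <- lo[g]:hi[g]
    w <- exp(-(mid[i] - grid[g])^2 / (2 * sigma^2))
    value[g] <- sum(w * P[i]) / sum(w)
    informative[g] <- any(!at_floor[i])
  }
  n_frag[n_frag < 0L] <- 0L
  sm <- data.frame(pos = grid, value = value, n_frag = n_frag,
                   informative = informative)
  for (a in c("viewpoint", "condition", "replicate", "chrom", "span"))
    attr(sm, a) <- attr(profile, a)
  attr(sm, "sigma") <- sigma
  attr(sm, "window") <- window
  attr(sm, "grid_step") <- grid_step
  class(sm) <- c("smoothed_cpp", "data.frame")
  sm
}
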
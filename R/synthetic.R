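#' Generalized Gaussian bead-on-string chain
#'
#' The null model of the package: beads i = 1..N at spatial positions x_i
#' with joint density prod_i (k_i/2 pi)^(3/2) exp(-k_i (x_i - x_{i+1})^2 / 2),
#' i.e. successive displacements are independent 3D Gaussians with per-axis
#' variance 1/k_{i,i+1}. Spring constants follow the local scaling law
#' k_{i,i+1} = (s_{i,i+1}/s_ref)^(2 nu / 3); for uniform nu = -3/2 this is
#' the pure Gaussian chain with k proportional to 1/s and contact probability
#' scaling as s^(-3/2). Model-length units are arbitrary; only exponents and
#' ratios are compared to theory.
#'
#' @param n_beads number of beads N.
#' @param seg_lengths segment lengths s_{i,i+1} in bp: scalar or vector of
#'   length N-1.
#' @param nu per-region scaling exponent(s): scalar or vector of length N-1.
#' @param s_ref reference segment length fixing the model-length unit
#'   (default: median segment).
#' @return a `gaussian_chain`: list with `n`, `seg`, `k`, `nu`, `pos` (bead
#'   genomic coordinates, bp, bead 1 at 0), `ref_pos` (coordinates on the
#'   reference genome; differs from `pos` after a deletion), `s_ref`,
#'   `deletion` (reference interval removed, or NULL).
#' @export
gaussian_chain <- function(n_beads, seg_lengths = 10000, nu = -1.5,
                           s_ref = NULL) {
  if (n_beads < 2L) stop("a chain needs at least 2 beads")
  seg <- rep_len(as.numeric(seg_lengths), n_beads - 1L)
  if (any(seg <= 0)) stop("segment lengths must be positive")
  nu <- rep_len(as.numeric(nu), n_beads - 1L)
  if (is.null(s_ref)) s_ref <- stats::median(seg)
  k <- (seg / s_ref)^(2 * nu / 3)
  pos <- cumsum(c(0, seg))
  structure(list(n = as.integer(n_beads), seg = seg, k = k, nu = nu,
                 pos = pos, ref_pos = pos, s_ref = s_ref, deletion = NULL),
            class = "gaussian_chain")
}

#' @export
print.gaussian_chain <- function(x, ...) {
  cat(sprintf("Gaussian chain: %d beads, %.3g Mb, nu in [%.2f, %.2f]%s\n",
              x$n, x$pos[x$n] / 1e6, min(x$nu), max(x$nu),
              if (is.null(x$deletion)) "" else
                sprintf(", deletion [%g, %g) in reference coordinates",
                        x$deletion[1L], x$deletion[2L])))
  invisible(x)
}

#' Fragment map of a chain
#'
#' One fragment per bead, with fragment boundaries midway between adjacent
#' beads (reference coordinates), so fragment midpoint distances approximate
#' bead separations.
#'
#' @param chain a `gaussian_chain`.
#' @param chrom chromosome name.
#' @return a [fragment_map] with `nrow == chain$n`.
#' @export
as_fragment_map <- function(chain, chrom = "chrS") {
  p <- chain$ref_pos
  half <- c(p[1L], (p[-1L] + p[-chain$n]) / 2, p[chain$n] + chain$seg[1L] / 2)
  # extend the terminal fragments symmetrically
  half[1L] <- p[1L] - (half[2L] - p[1L])
  off <- -half[1L]
  fragment_map(chrom, half[-length(half)] + off, half[-1L] + off)
}

#' Sample chain configurations
#'
#' Draws independent spatial configurations of the chain: bead 1 at the
#' origin, successive displacements independent 3D Gaussians with per-axis
#' variance 1/k.
#'
#' @param chain a `gaussian_chain`.
#' @param n_config number of configurations.
#' @param seed optional integer seed (same seed, identical configurations).
#' @return a `chain_configs`: list of matrices `x`, `y`, `z` of dimension
#'   `n_beads x n_config`.
#' @export
sample_chain <- function(chain, n_config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- chain$n
  sd <- sqrt(1 / chain$k)
  axis <- function() {
    if (n_config == 0L) return(matrix(numeric(0), n, 0))
    d <- matrix(stats::rnorm((n - 1L) * n_config, sd = sd), n - 1L, n_config)
    # column-wise cumulative sums via one global cumsum, correcting each
    # column by the running total of the preceding columns
    m <- matrix(cumsum(d), n - 1L, n_config)
    m <- m - rep(c(0, m[n - 1L, -n_config]), each = n - 1L)
    rbind(0, m)
  }
  structure(list(x = axis(), y = axis(), z = axis(), chain = chain),
            class = "chain_configs")
}

#' Monte-Carlo contact probabilities
#'
#' Fraction of configurations in which two beads lie within the capture
#' radius (hard-sphere contact definition).
#'
#' @param configs a `chain_configs`.
#' @param radius capture radius in model-length units (see [contact_radius]).
#' @param beads optional bead indices to use as viewpoints; the default uses
#'   all beads pairwise (quadratic in N - intended for small chains).
#' @return with `beads`: matrix `length(beads) x N` of contact frequencies
#'   (rows named by bead index); without: symmetric `N x N` matrix with unit
#'   diagonal.
#' @export
contact_probabilities <- function(configs, radius, beads = NULL) {
  if (radius <= 0) stop("capture radius must be positive")
  n <- nrow(configs$x)
  if (ncol(configs$x) < 1L) stop("need at least one configuration")
  r2 <- radius^2
  one <- function(v) {
    d2 <- (configs$x - matrix(configs$x[v, ], n, ncol(configs$x), byrow = TRUE))^2 +
          (configs$y - matrix(configs$y[v, ], n, ncol(configs$y), byrow = TRUE))^2 +
          (configs$z - matrix(configs$z[v, ], n, ncol(configs$z), byrow = TRUE))^2
    rowMeans(d2 < r2)
  }
  idx <- if (is.null(beads)) seq_len(n) else as.integer(beads)
  out <- t(vapply(idx, one, numeric(n)))
  rownames(out) <- idx
  out
}

#' Default capture radius
#'
#' Radius at which two adjacent beads (at the median spring constant) are in
#' contact in a given fraction of configurations; the default 0.5 keeps the
#' radius small relative to typical distances at larger separations, inside
#' the scaling regime.
#'
#' @param chain a `gaussian_chain`.
#' @param p_adjacent target adjacent-bead contact frequency.
#' @export
contact_radius <- function(chain, p_adjacent = 0.5) {
  sqrt(stats::qchisq(p_adjacent, df = 3) / stats::median(chain$k))
}

#' Closed-form contact profile of the generalized chain
#'
#' The pairwise distance distribution of the generalized model: the
#' separation of the viewpoint bead and a bead at genomic distance s is 3D
#' Gaussian with per-axis variance v(s) = (1/k_loc) (s/s_loc)^(-2 nu/3),
#' anchored at the viewpoint's adjacent segment (length s_loc, spring
#' k_loc), so the hard-sphere contact probability is
#' pchisq(radius^2 / v(s), 3) which scales as s^nu at small radius. For a
#' uniform chain at nu = -3/2 this reduces exactly to the additive-variance
#' Gaussian chain sampled by [sample_chain] (v = s/s_loc segments' worth of
#' variance); for other exponents it is the model's effective pairwise form
#' - a strict chain of independent springs is always diffusive, so local
#' exponents other than -3/2 exist only in this pairwise sense.
#'
#' @param chain a `gaussian_chain`.
#' @param bead viewpoint bead index.
#' @param radius capture radius.
#' @return vector of contact probabilities over all beads (1 at the
#'   viewpoint itself).
#' @export
theoretical_contact_profile <- function(chain, bead, radius) {
  i_loc <- min(bead, chain$n - 1L)
  s_loc <- chain$seg[i_loc]
  k_loc <- chain$k[i_loc]
  nu <- chain$nu[i_loc]
  s <- abs(chain$pos - chain$pos[bead])
  v <- (1 / k_loc) * (s / s_loc)^(-2 * nu / 3)
  p <- stats::pchisq(radius^2 / v, df = 3)
  p[bead] <- 1
  p
}

#' Remove beads from a chain (heterozygous deletion)
#'
#' Deletes a bead range strictly inside the chain and rejoins the flanking
#' beads with a new spring whose genomic length is the sum of the two severed
#' half-segments, with k from the same scaling law. Reference coordinates of
#' the retained beads are kept so deleted-chromosome profiles can be compared
#' against the reference genome, and the removed reference interval is
#' recorded.
#'
#' @param chain a `gaussian_chain`.
#' @param bead_range `c(from, to)` bead indices to remove (inclusive), or
#'   NULL/empty for the identity.
#' @return a new `gaussian_chain` with `n - m` beads.
#' @export
apply_deletion <- function(chain, bead_range) {
  if (is.null(bead_range) || length(bead_range) == 0L) return(chain)
  from <- bead_range[1L]; to <- bead_range[length(bead_range)]
  if (from > to) return(chain)
  if (from <= 1L || to >= chain$n)
    stop("deletion range must lie strictly inside the chain")
  keep <- setdiff(seq_len(chain$n), from:to)
  s_new <- chain$seg[from - 1L] / 2 + chain$seg[to] / 2
  nu_new <- chain$nu[from - 1L]
  k_new <- (s_new / chain$s_ref)^(2 * nu_new / 3)
  seg <- c(chain$seg[seq_len(from - 2L)], s_new,
           if (to + 1L <= chain$n - 1L) chain$seg[(to + 1L):(chain$n - 1L)])
  k <- c(chain$k[seq_len(from - 2L)], k_new,
         if (to + 1L <= chain$n - 1L) chain$k[(to + 1L):(chain$n - 1L)])
  nu <- c(chain$nu[seq_len(from - 2L)], nu_new,
          if (to + 1L <= chain$n - 1L) chain$nu[(to + 1L):(chain$n - 1L)])
  del_ref <- c(chain$ref_pos[from - 1L] + chain$seg[from - 1L] / 2,
               chain$ref_pos[to] + chain$seg[to] / 2)
  structure(list(n = length(keep), seg = seg, k = k, nu = nu,
                 pos = cumsum(c(0, seg)), ref_pos = chain$ref_pos[keep],
                 s_ref = chain$s_ref, deletion = del_ref),
            class = "gaussian_chain")
}

#' Sample FISH probe-pair distances from the model
#'
#' i.i.d. draws of |r| for a 3D Gaussian separation with per-axis variance
#' 1/k, i.e. the Maxwell-type density [fish_density].
#'
#' @param k spring constant (1/um^2).
#' @param n sample size.
#' @param seed optional integer seed.
#' @return numeric vector of distances.
#' @export
sample_fish_distances <- function(k, n, seed = NULL) {
  if (k <= 0) stop("spring constant must be positive")
  if (!is.null(seed)) set.seed(seed)
  sqrt(stats::rchisq(n, df = 3) / k)
}

#' Synthetic capture counts with multiplicative biases
#'
#' Realizes the bias model forward: the expected biased contact probability
#' of experiment I at fragment alpha is C_I * K_I * C_alpha * P_I(alpha)
#' (with C_alpha the fragment-level bias, 1 except at other viewpoints'
#' fragments, and injected interaction spikes multiplied into P). Counts are
#' independent Poisson draws of the expectation scaled so that an unbiased
#' experiment (C = K = 1) totals `depth` reads, converted back to raw counts
#' via the viewpoint x fragment length product.
#'
#' @param P matrix of true contact probabilities, one row per viewpoint,
#'   columns aligned to `frags`.
#' @param frags a [fragment_map] aligned to the columns of `P`.
#' @param viewpoints a [viewpoint_set], rows aligned to rows of `P`.
#' @param C,K per-viewpoint and per-experiment bias factors (named or in
#'   viewpoint order).
#' @param depth expected total reads per unbiased experiment.
#' @param condition,replicate labels stamped on the output.
#' @param seed optional integer seed.
#' @return a [capture_table].
#' @export
generate_capture_counts <- function(P, frags, viewpoints, C = 1, K = 1,
                                    depth = 1e6, condition = "WT",
                                    replicate = "1", seed = NULL) {
  if (depth < 0) stop("depth must be non-negative")
  nvp <- nrow(viewpoints)
  C <- rep_len(C, nvp); K <- rep_len(K, nvp)
  if (!is.null(seed)) set.seed(seed)
  # fragment-level bias: other viewpoints' fragments carry their C
  C_frag <- rep(1, nrow(frags))
  vp_frag <- match_fragments(viewpoints$start, viewpoints$end, frags,
                             midpoint_fallback = TRUE)
  C_frag[vp_frag[!is.na(vp_frag)]] <- C[!is.na(vp_frag)]
  out <- lapply(seq_len(nvp), function(i) {
    w <- P[i, ] * frags$length
    lambda <- depth * C[i] * K[i] * C_frag * P[i, ] * frags$length / sum(w)
    capture_table(viewpoint = viewpoints$id[i],
                  fragment = seq_len(nrow(frags)),
                  replicate = replicate, condition = condition,
                  count = stats::rpois(nrow(frags), lambda))
  })
  ct <- do.call(rbind, out)
  class(ct) <- c("capture_table", "data.frame")
  ct
}

#' Inject an interaction spike into contact profiles
#'
#' Multiplies the contact probability between each viewpoint inside the
#' anchor region and every fragment of the target region by `fold` (and vice
#' versa), emulating a specific biological interaction on top of the entropic
#' background.
#'
#' @param P viewpoint x fragment contact matrix.
#' @param frags a [fragment_map] aligned to columns of `P`.
#' @param viewpoints a [viewpoint_set] aligned to rows of `P`.
#' @param anchor,target `c(start, end)` bp intervals.
#' @param fold fold-change > 0.
#' @export
inject_spike <- function(P, frags, viewpoints, anchor, target, fold) {
  if (fold <= 0) stop("fold-change must be positive")
  in_int <- function(mid, int) mid >= int[1L] & mid < int[2L]
  vp_anchor <- in_int(viewpoints$mid, anchor)
  vp_target <- in_int(viewpoints$mid, target)
  fr_anchor <- in_int(frags$mid, anchor)
  fr_target <- in_int(frags$mid, target)
  P[vp_anchor, fr_target] <- P[vp_anchor, fr_target] * fold
  P[vp_target, fr_anchor] <- P[vp_target, fr_anchor] * fold
  P
}

#' Simulate a two-condition, two-replicate 4C study
#'
#' The package's synthetic study: a Gaussian chain chromosome, viewpoints
#' placed around and inside a heterozygous deletion (two upstream, a block
#' inside, two downstream, mirroring a deletion-flanking design), log-uniform
#' viewpoint and experiment biases, Poisson counts at the given depth, an
#' optional specific-interaction spike present only in the deletion
#' condition, and the deletion condition measured on the rejoined chain with
#' only the viewpoints outside the deletion.
#'
#' @param seed integer seed; all randomness derives from it.
#' @param n_beads,seg_length,nu chain geometry (defaults 2000 beads of 10 kb,
#'   nu = -3/2).
#' @param deletion_beads bead range removed in the deletion condition, or
#'   NULL for a no-deletion study (both conditions share the chain; only an
#'   injected spike, if any, distinguishes them).
#' @param n_viewpoints total viewpoints (default 12).
#' @param depth expected reads per experiment (default 1e6).
#' @param replicates biological replicates per condition (default 2).
#' @param C_range,K_range log-uniform ranges for the true bias factors.
#' @param spike NULL, the string `"standard"`, or list(anchor=, target=,
#'   fold=) in reference bp, injected into the test (deletion) condition
#'   only. The standard spike doubles the contact probability between the
#'   last viewpoint and a 300 kb block 0.65-0.95 Mb upstream of it: at the
#'   study depth the 5 % DRCP reporting threshold makes a 2-fold change
#'   detectable only up to about 2 Mb separation (DRCP = log fold / |log P|),
#'   so the block sits inside the method's sensitive regime.
#' @param p_adjacent adjacent-bead contact frequency fixing the capture
#'   radius.
#' @return a `synthetic_study` list: `chain`, `chain_del`, `frags`,
#'   `viewpoints` (all, with `outside` flag), `counts` (a [capture_table]
#'   over conditions WT/del and replicates), `truth` (C, K per condition),
#'   `deletion` (reference interval), `radius`, `spike`, `depth`.
#' @export
simulate_study <- function(seed = 1, n_beads = 2000, seg_length = 10000,
                           nu = -1.5, deletion_beads = c(800, 1230),
                           n_viewpoints = 12, depth = 1e6, replicates = 2,
                           C_range = c(0.5, 2), K_range = c(0.5, 2),
                           spike = NULL, p_adjacent = 0.5) {
  set.seed(seed)
  chain <- gaussian_chain(n_beads, seg_length, nu)
  chain_del <- apply_deletion(chain, deletion_beads)
  frags <- as_fragment_map(chain)
  radius <- contact_radius(chain, p_adjacent)

  ## viewpoint beads: 2 upstream, rest inside, 2 downstream of the deletion
  ## (evenly spread when there is no deletion)
  if (is.null(deletion_beads)) {
    beads <- round(seq(0.1, 0.9, length.out = n_viewpoints) * n_beads)
  } else {
    n_in <- max(n_viewpoints - 4L, 0L)
    up <- round(seq(deletion_beads[1L] * 0.55, deletion_beads[1L] * 0.9,
                    length.out = 2L))
    dn <- round(seq(deletion_beads[2L] + 0.1 * (n_beads - deletion_beads[2L]),
                    deletion_beads[2L] + 0.6 * (n_beads - deletion_beads[2L]),
                    length.out = 2L))
    ins <- if (n_in > 0L) round(seq(deletion_beads[1L] + 20,
                                    deletion_beads[2L] - 20,
                                    length.out = n_in)) else integer(0)
    beads <- sort(unique(c(up, ins, dn)))
  }
  vps <- viewpoint_set(id = sprintf("vp%02d", seq_along(beads)),
                       start = frags$start[beads], end = frags$end[beads],
                       chrom = attr(frags, "chrom"))
  vps$bead <- beads
  outside <- if (is.null(deletion_beads)) rep(TRUE, length(beads))
             else beads < deletion_beads[1L] | beads > deletion_beads[2L]

  C <- exp(stats::runif(length(beads), log(C_range[1L]), log(C_range[2L])))
  K_wt <- exp(stats::runif(length(beads), log(K_range[1L]), log(K_range[2L])))
  K_del <- exp(stats::runif(length(beads), log(K_range[1L]), log(K_range[2L])))

  P_wt <- t(vapply(beads, function(b)
    theoretical_contact_profile(chain, b, radius), numeric(n_beads)))

  ## deletion chain: retained beads only, mapped back to reference fragments
  keep <- if (is.null(deletion_beads)) seq_len(n_beads)
          else setdiff(seq_len(n_beads), deletion_beads[1L]:deletion_beads[2L])
  bead_del <- match(beads[outside], keep)
  P_del_sub <- t(vapply(bead_del, function(b)
    theoretical_contact_profile(chain_del, b, radius),
    numeric(chain_del$n)))
  P_del <- matrix(0, nrow = sum(outside), ncol = n_beads)
  P_del[, keep] <- P_del_sub
  if (identical(spike, "standard")) {
    last <- vps[nrow(vps), ]
    spike <- list(anchor = c(last$start - 5e4, last$end + 5e4),
                  target = c(last$mid - 9.5e5, last$mid - 6.5e5),
                  fold = 2)
  }
  if (!is.null(spike))
    P_del <- inject_spike(P_del, frags, vps[outside, ], spike$anchor,
                          spike$target, spike$fold)

  counts <- list()
  for (r in seq_len(replicates)) {
    counts[[length(counts) + 1L]] <- generate_capture_counts(
      P_wt, frags, vps, C = C, K = K_wt, depth = depth,
      condition = "WT", replicate = as.character(r))
    counts[[length(counts) + 1L]] <- generate_capture_counts(
      P_del, frags, vps[outside, ], C = C[outside], K = K_del[outside],
      depth = depth, condition = "del", replicate = as.character(r))
  }
  counts <- do.call(rbind, counts)
  class(counts) <- c("capture_table", "data.frame")

  ## deletion interval in fragment-map coordinates
  del_ref <- if (is.null(deletion_beads)) NULL
             else c(frags$start[deletion_beads[1L]],
                    frags$end[deletion_beads[2L]])

  structure(list(chain = chain, chain_del = chain_del, frags = frags,
                 viewpoints = vps, outside = outside, counts = counts,
                 truth = list(C = stats::setNames(C, vps$id),
                              K_WT = stats::setNames(K_wt, vps$id),
                              K_del = stats::setNames(K_del, vps$id)),
                 deletion = del_ref, radius = radius, spike = spike,
                 depth = depth, seed = seed, replicates = replicates),
            class = "synthetic_study")
}
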
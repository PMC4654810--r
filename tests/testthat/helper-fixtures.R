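# Shared fixture builders. Everything is generated in code; no data files.

# random DNA sequence
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# noiseless power-law BCP profile sampled at log-spaced separations
power_law_profile <- function(nu = -1.5, n = 200, s_range = c(1e4, 1e7),
                              amplitude = 1) {
  s <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n))
  pr <- data.frame(fragment = seq_len(n), mid = s, s = s,
                   count = NA_real_, F = amplitude * s^nu,
                   self = rep(FALSE, n))
  class(pr) <- c("bcp_profile", "data.frame")
  pr
}

# direct noiseless pair matrix F_IJ = C_I C_J K_I P(s_IJ)
make_pair_matrix <- function(C, K, nu = -1.5, seed = 1, noise_counts = NULL) {
  n <- length(C)
  set.seed(seed)
  pos <- cumsum(runif(n, 4e5, 8e5))
  s <- outer(pos, pos, function(a, b) abs(a - b))
  P <- s^nu
  F <- exp(log(P) + outer(log(C), log(C), "+") + matrix(log(K), n, n))
  if (!is.null(noise_counts)) {
    # observe each F_IJ through a Poisson count with expectation
    # noise_counts at the median entry (realistic sequencing depth)
    scale <- noise_counts / stats::median(F[upper.tri(F)])
    lam <- F * scale; lam[!is.finite(lam)] <- 0
    F <- matrix(rpois(n * n, lam), n, n) / scale
  }
  diag(F) <- NA
  list(F = F, s = s, ids = as.character(seq_len(n)))
}

# minimal smoothed-track data.frame for compute_drcp
fake_smoothed <- function(pos, value, informative = TRUE) {
  sm <- data.frame(pos = pos, value = value,
                   n_frag = 1L, informative = informative)
  class(sm) <- c("smoothed_cpp", "data.frame")
  sm
}
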
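#' Local chromatin compaction exponent
#'
#' Fits a smoothing spline to log contact probability against log genomic
#' separation and reports its analytic slope at the evaluation scale
#' (default 100 kb) as the local scaling exponent nu. For an ideal Gaussian
#' chain nu = -3/2; more negative values mean less compact chromatin.
#' Observations outside the fit range (where the scaling form breaks down at
#' short distances and in the contact-starved far tail) are excluded.
#'
#' @param profile a `cpp_profile` or `bcp_profile`: needs columns `s` and
#'   `P` (or `F`), plus optionally `self`.
#' @param eval_scale bp separation at which the slope is evaluated (default
#'   100 kb, inside the typically linear 10 kb - 10 Mb region).
#' @param fit_range bp interval retained for fitting.
#' @param min_points minimum positive observations in range.
#' @return a `compaction_estimate`: list with `nu`, `eval_scale`, `df`
#'   (effective degrees of freedom of the spline), `n`, `viewpoint`,
#'   `condition`, `replicate`, `fit` (the underlying `decay_fit`).
#' @export
fit_scaling_exponent <- function(profile, eval_scale = 1e5,
                                 fit_range = c(1e4, 1e7), min_points = 30) {
  if (!"F" %in% names(profile) && "P" %in% names(profile)) {
    profile$F <- profile$P
  }
  use <- profile$F > 0 & profile$s >= fit_range[1L] & profile$s <= fit_range[2L]
  if (sum(use) >= min_points) {
    span <- range(profile$s[use & profile$s > 0])
    if (span[2L] / span[1L] < 10)
      stop("observations span less than one decade of separation")
  }
  fit <- fit_loglog_decay(profile, fit_range = fit_range,
                          min_points = min_points)
  structure(list(nu = decay_slope(fit, eval_scale),
                 eval_scale = eval_scale, fit_range = fit_range,
                 df = fit$spline$df, n = fit$n,
                 viewpoint = attr(profile, "viewpoint"),
                 condition = attr(profile, "condition"),
                 replicate = attr(profile, "replicate"),
                 fit = fit),
            class = "compaction_estimate")
}

#' @export
print.compaction_estimate <- function(x, ...) {
  cat(sprintf("Compaction exponent nu = %.3f at %g kb (viewpoint %s, n = %d, spline df = %.1f)\n",
              x$nu, x$eval_scale / 1000,
              if (is.null(x$viewpoint)) "?" else x$viewpoint, x$n, x$df))
  invisible(x)
}

#' Tabulate compaction estimates
#'
#' @param estimates list of `compaction_estimate`s.
#' @return data.frame with columns `viewpoint`, `condition`, `replicate`,
#'   `nu`.
#' @export
compaction_table <- function(estimates) {
  estimates <- Filter(Negate(is.null), estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(viewpoint = if (is.null(e$viewpoint)) NA else e$viewpoint,
               condition = if (is.null(e$condition)) NA else e$condition,
               replicate = if (is.null(e$replicate)) NA else e$replicate,
               nu = e$nu)
  }))
}

#' Compare compaction between two conditions
#'
#' Per-viewpoint difference of mean exponents with a standard error pooled
#' from the spread across biological replicates; the difference is flagged
#' significant when |delta nu| exceeds `z` pooled standard errors. Less
#' compact chromatin has the more negative nu, so a negative delta means the
#' first condition is less compact.
#'
#' @param a,b data.frames as from [compaction_table] (or lists of
#'   `compaction_estimate`s), each with >= 2 replicates per viewpoint.
#' @param z significance multiplier (default 1.96).
#' @return data.frame with `viewpoint`, `nu_a`, `nu_b`, `delta`, `se`,
#'   `significant`.
#' @export
compare_compaction <- function(a, b, z = 1.96) {
  if (!is.data.frame(a)) a <- compaction_table(a)
  if (!is.data.frame(b)) b <- compaction_table(b)
  vps <- intersect(unique(a$viewpoint), unique(b$viewpoint))
  out <- lapply(vps, function(v) {
    na <- a$nu[a$viewpoint == v]; nb <- b$nu[b$viewpoint == v]
    if (length(na) < 2L || length(nb) < 2L)
      stop("need >= 2 replicate estimates per side for viewpoint ", v,
           "; pool replicates first if only one is available")
    se <- sqrt(stats::var(na) / length(na) + stats::var(nb) / length(nb))
    data.frame(viewpoint = v, nu_a = mean(na), nu_b = mean(nb),
               delta = mean(na) - mean(nb), se = se,
               significant = abs(mean(na) - mean(nb)) > z * se)
  })
  do.call(rbind, out)
}
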
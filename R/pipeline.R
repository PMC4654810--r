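#' Run the four-phase analysis pipeline
#'
#' Orchestrates Phase 1 (bias correction), Phase 2 (thresholding,
#' pseudo-counts, smoothed CPPs), Phase 3 (DRCP and DIR calling) and Phase 4
#' (compaction exponents) from a single configuration, and persists every
#' intermediate to the output directory. All tunables default to the method's
#' standard values; the run is deterministic given the configuration.
#'
#' The configuration is a named list (or a YAML file path) with entries:
#' \describe{
#'   \item{counts / frags / viewpoints}{paths: a counts TSV (columns chrom,
#'     start, end, count, viewpoint, replicate, condition), a fragment BED
#'     and a viewpoint TSV (columns id, start, end). Alternatively
#'     `simulate:` a list of [simulate_study] arguments, in which case the
#'     study is generated in memory.}
#'   \item{test_condition / ref_condition}{condition labels compared in
#'     Phase 3 (defaults `"del"` and `"WT"`).}
#'   \item{deletion}{`c(start, end)` reference interval carried by the test
#'     condition's chromosomes, or NULL.}
#'   \item{sigma, window, grid_step, threshold, pseudo, signal_threshold,
#'     alpha, eval_scale, fit_range}{tunables; defaults 20 kb, 80 kb, 20 kb,
#'     5, 1, 0.05, 0.05, 100 kb, c(10 kb, 10 Mb).}
#'   \item{out}{output directory.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return (invisibly) a `pipeline_result` list with `factors` (per
#'   condition x replicate), `asymmetry` (median relative asymmetry of F and
#'   of corrected P per experiment set), `smoothed`, `drcp`, `dirs`,
#'   `compaction`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- pipeline_defaults(config)

  ## ---- inputs -------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    study <- do.call(simulate_study, cfg$simulate)
    frags <- study$frags
    vps <- study$viewpoints
    counts <- study$counts
    if (is.null(cfg$deletion)) cfg$deletion <- study$deletion
  } else {
    for (p in c("counts", "frags", "viewpoints"))
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        stop("missing input: ", p, " (", cfg[[p]], ")")
    frags <- read_fragment_bed(cfg$frags)
    vtab <- utils::read.table(cfg$viewpoints, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    vps <- viewpoint_set(vtab$id, vtab$start, vtab$end,
                         chrom = attr(frags, "chrom"))
    counts <- read_capture_table(cfg$counts, frags)
  }
  if (!is.null(cfg$deletion)) cfg$deletion <- as.numeric(cfg$deletion)
  del_conds <- if (is.null(cfg$deletion)) NULL else cfg$test_condition

  out <- cfg$out
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ## ---- phase 1: bias factors per (condition, replicate) -------------
  bcp_raw <- compute_bcp(counts, vps, frags, deletion = cfg$deletion,
                         deletion_conditions = del_conds)
  sets <- unique(data.frame(condition = counts$condition,
                            replicate = counts$replicate))
  factors <- list(); asym <- list()
  for (i in seq_len(nrow(sets))) {
    cond <- sets$condition[i]; rep <- sets$replicate[i]
    ids <- unique(counts$viewpoint[counts$condition == cond &
                                   counts$replicate == rep])
    vsub <- vps[match(ids, vps$id), , drop = FALSE]
    vsub <- vsub[order(vsub$mid), , drop = FALSE]
    if (nrow(vsub) < 4L)
      stop("bias correction needs at least 4 viewpoints; condition ",
           cond, " replicate ", rep, " has ", nrow(vsub))
    fits <- lapply(vsub$id, function(v)
      fit_loglog_decay(bcp_raw[[paste(v, cond, rep, sep = "|")]],
                       fit_range = cfg$fit_range))
    del <- if (cond %in% del_conds) cfg$deletion
    pm <- interviewpoint_bcp(fits, vsub, deletion = del)
    bf <- solve_bias_factors(pm, pair_selection = cfg$pair_selection)
    key <- paste(cond, rep, sep = "|")
    factors[[key]] <- bf
    asym[[key]] <- c(F = median_asymmetry(pm$F), P = median_asymmetry(bf$P))
  }

  ## ---- phase 2: thresholded, corrected, smoothed CPPs ---------------
  counts_f <- counts
  counts_f$count <- threshold_and_pseudocount(counts_f$count,
                                              cfg$threshold, cfg$pseudo)
  bcp_f <- compute_bcp(counts_f, vps, frags, deletion = cfg$deletion,
                       deletion_conditions = del_conds)
  grid <- seq(min(frags$start) + cfg$grid_step / 2, max(frags$end),
              by = cfg$grid_step)
  cpp_raw <- list(); smoothed <- list()
  for (nm in names(bcp_f)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1L]]
    key <- paste(parts[2L], parts[3L], sep = "|")
    if (is.null(factors[[key]]) || !parts[1L] %in% names(factors[[key]]$C))
      next
    cpp_raw[[nm]] <- compute_cpp(bcp_f[[nm]], factors[[key]],
                                 floor_count = cfg$pseudo)
    smoothed[[nm]] <- smooth_cpp(cpp_raw[[nm]], sigma = cfg$sigma,
                                 window = cfg$window,
                                 grid_step = cfg$grid_step, grid = grid)
  }

  ## ---- phase 3: DRCP and DIRs per viewpoint -------------------------
  reps <- sort(unique(counts$replicate))
  test_vps <- unique(counts$viewpoint[counts$condition == cfg$test_condition])
  drcp <- list(); dirs <- list()
  for (v in test_vps) {
    keys_t <- paste(v, cfg$test_condition, reps, sep = "|")
    keys_r <- paste(v, cfg$ref_condition, reps, sep = "|")
    if (!all(c(keys_t, keys_r) %in% names(smoothed))) next
    dr <- lapply(seq_along(reps), function(r)
      compute_drcp(smoothed[[keys_t[r]]], smoothed[[keys_r[r]]]))
    drcp[[v]] <- dr
    dirs[[v]] <- call_dirs(dr,
                           raw_test = cpp_raw[keys_t],
                           raw_ref = cpp_raw[keys_r],
                           signal_threshold = cfg$signal_threshold,
                           alpha = cfg$alpha, window = cfg$window,
                           deletion = cfg$deletion)
  }

  ## ---- phase 4: compaction ------------------------------------------
  compaction <- compaction_table(lapply(names(cpp_raw), function(nm)
    tryCatch(fit_scaling_exponent(cpp_raw[[nm]], eval_scale = cfg$eval_scale,
                                  fit_range = cfg$fit_range),
             error = function(e) NULL)))

  res <- structure(list(factors = factors, asymmetry = asym,
                        smoothed = smoothed, drcp = drcp, dirs = dirs,
                        compaction = compaction, config = cfg,
                        viewpoints = vps, frags = frags),
                   class = "pipeline_result")
  if (!is.null(out)) write_pipeline_outputs(res, out)
  invisible(res)
}

pipeline_defaults <- function(config) {
  def <- list(sigma = 20000, window = 80000, grid_step = 20000,
              threshold = 5, pseudo = 1, signal_threshold = 0.05,
              alpha = 0.05, eval_scale = 1e5, fit_range = c(1e4, 1e7),
              pair_selection = "nn2", test_condition = "del",
              ref_condition = "WT", deletion = NULL, out = NULL)
  for (nm in names(config)) def[[nm]] <- config[[nm]]
  def
}

write_pipeline_outputs <- function(res, out) {
  cfg <- res$config
  chrom <- attr(res$frags, "chrom")
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(out, "config.yaml"))
  ftab <- do.call(rbind, lapply(names(res$factors), function(k) {
    bf <- res$factors[[k]]
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    data.frame(condition = parts[1L], replicate = parts[2L],
               viewpoint = names(bf$C), C = unname(bf$C), K = unname(bf$K))
  }))
  utils::write.table(ftab, file.path(out, "factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  atab <- do.call(rbind, lapply(names(res$asymmetry), function(k)
    data.frame(set = k, median_asym_F = res$asymmetry[[k]][["F"]],
               median_asym_P = res$asymmetry[[k]][["P"]])))
  utils::write.table(atab, file.path(out, "asymmetry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(res$smoothed)) {
    sm <- res$smoothed[[nm]]
    write_track(grid_track(sm$pos, sm$value, attr(sm, "grid_step")),
                file.path(out, paste0("cpp_", gsub("\\|", "_", nm),
                                      ".bedGraph")), chrom = chrom)
  }
  for (v in names(res$drcp))
    for (r in seq_along(res$drcp[[v]])) {
      tr <- res$drcp[[v]][[r]]
      write_track(grid_track(tr$pos, tr$drcp, cfg$grid_step),
                  file.path(out, sprintf("drcp_%s_rep%d.bedGraph", v, r)),
                  chrom = chrom)
    }
  all_dirs <- do.call(rbind, lapply(names(res$dirs), function(v) {
    d <- res$dirs[[v]]
    if (nrow(d) == 0L) return(NULL)
    cbind(viewpoint = v, d)
  }))
  if (is.null(all_dirs))
    all_dirs <- data.frame(viewpoint = character(0), start = numeric(0),
                           end = numeric(0), direction = character(0),
                           max_drcp = numeric(0), p_rep1 = numeric(0),
                           p_rep2 = numeric(0))
  utils::write.table(all_dirs, file.path(out, "dirs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (v in names(res$dirs))
    write_dirs(res$dirs[[v]], file.path(out, sprintf("dirs_%s.bed", v)),
               chrom = chrom)
  if (!is.null(res$compaction))
    utils::write.table(res$compaction, file.path(out, "nu.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("poly4C %s", as.character(utils::packageVersion("poly4C"))),
               sprintf("R %s", as.character(getRversion())),
               paste("parameters:",
                     paste(sprintf("%s=%s",
                                   names(cfg)[!vapply(cfg, is.null, logical(1)) &
                                              !vapply(cfg, is.list, logical(1))],
                                   vapply(cfg[!vapply(cfg, is.null, logical(1)) &
                                              !vapply(cfg, is.list, logical(1))],
                                          function(x) paste(x, collapse = ","),
                                          character(1))),
                           collapse = " "))),
             file.path(out, "run_log.txt"))
  invisible(out)
}

#' Summarize a pipeline run
#'
#' DIR counts and size statistics (minimum/median/maximum span), the
#' compaction table, and the median relative asymmetry before and after bias
#' correction.
#'
#' @param res a `pipeline_result` from [run_pipeline].
#' @return a `pipeline_report` list with `n_dirs`, `dir_sizes`
#'   (min/median/max, bp), `total_dir_bp`, `compaction`, `asymmetry`.
#' @export
make_report <- function(res) {
  dirs <- do.call(rbind, lapply(res$dirs, function(d)
    d[, c("start", "end", "direction")]))
  sizes <- if (is.null(dirs) || nrow(dirs) == 0L) numeric(0)
           else dirs$end - dirs$start
  merged_bp <- if (length(sizes) == 0L) 0 else
    overlap_bp(interval_set(dirs$start, dirs$end),
               interval_set(dirs$start, dirs$end))$bp
  structure(list(n_dirs = length(sizes),
                 dir_sizes = if (length(sizes) == 0L)
                   c(min = NA_real_, median = NA_real_, max = NA_real_)
                 else c(min = min(sizes), median = stats::median(sizes),
                        max = max(sizes)),
                 total_dir_bp = merged_bp,
                 compaction = res$compaction,
                 asymmetry = res$asymmetry),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("DIRs: %d", x$n_dirs))
  if (x$n_dirs > 0)
    cat(sprintf(" (size min/median/max: %g/%g/%g kb; %g kb total)",
                x$dir_sizes[["min"]] / 1000, x$dir_sizes[["median"]] / 1000,
                x$dir_sizes[["max"]] / 1000, x$total_dir_bp / 1000))
  cat("\nMedian relative asymmetry (F -> corrected P):\n")
  for (k in names(x$asymmetry))
    cat(sprintf("  %s: %.3f -> %.3f\n", k, x$asymmetry[[k]][["F"]],
                x$asymmetry[[k]][["P"]]))
  if (!is.null(x$compaction) && nrow(x$compaction) > 0) {
    cat("Compaction exponents (mean over replicates):\n")
    agg <- stats::aggregate(nu ~ viewpoint + condition, x$compaction, mean)
    print(utils::head(agg, 24))
  }
  invisible(x)
}
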
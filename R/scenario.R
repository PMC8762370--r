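## The scenario grid: every combination of sub-sampling stage (none /
## pre-ASV / post-ASV), processing mode (sample-wise / pooled) and prior use
## (none / from baseline), 3 x 2 x 2 = 12 scenarios. The engine runs all
## twelve from one raw read set, applies the shared sample-retention rule,
## and summarises per-scenario richness and its correlation with the
## ORIGINAL (full-data) sequencing depth.

#' Enumerate the twelve processing scenarios
#'
#' Deterministic sub-sampling-major order over
#' `{none, pre_asv, post_asv} x {samplewise, pooled} x {none, from_baseline}`.
#'
#' @return a data frame with columns `label`, `subsampling`, `pooling`,
#'   `prior`; exactly 12 distinct rows.
#' @export
enumerate_scenarios <- function() {
  grid <- expand.grid(
    prior = c("none", "from_baseline"),
    pooling = c("samplewise", "pooled"),
    subsampling = c("none", "pre_asv", "post_asv"),
    stringsAsFactors = FALSE
  )[, c("subsampling", "pooling", "prior")]
  grid$label <- paste(grid$subsampling, grid$pooling, grid$prior, sep = ".")
  rownames(grid) <- NULL
  grid[, c("label", "subsampling", "pooling", "prior")]
}

#' Restrict a count table to a set of samples
#'
#' @param table a `count_table`.
#' @param sample_ids sample identifiers to keep (must all be present).
#' @return the restricted `count_table` with empty ASV columns dropped.
#' @export
restrict_samples <- function(table, sample_ids) {
  stopifnot(inherits(table, "count_table"))
  missing <- setdiff(sample_ids, rownames(table))
  abort_if(length(missing) > 0, "samples not in table: ",
           paste(missing, collapse = ", "))
  drop_empty_asvs(structure_count_table(
    unclass(table)[sample_ids, , drop = FALSE]))
}

#' Correlation of richness with original sequencing depth
#'
#' Always computed against the FULL-data depths, even for sub-sampled
#' scenarios whose realised depths are constant: the question is whether
#' the processed richness still carries a signal of how deeply each sample
#' was originally sequenced.
#'
#' @param richness per-sample richness (or any index) values.
#' @param original_depths per-sample full-data depths, same order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return the correlation coefficient, or an undefined marker when either
#'   vector is constant.
#' @export
depth_correlation <- function(richness, original_depths,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  abort_if(length(richness) != length(original_depths),
           "`richness` and `original_depths` differ in length")
  abort_if(length(richness) < 3, "need at least 3 samples")
  if (stats::sd(richness) == 0 || stats::sd(original_depths) == 0) {
    return(undefined_value("constant input: correlation undefined"))
  }
  stats::cor(richness, original_depths, method = method)
}

run_one_scenario <- function(scen, reads, full_table, depth, config, priors) {
  prior_set <- if (scen$prior == "from_baseline") priors[[scen$pooling]]
  spec <- filter_spec(scen$pooling, min_count = config$min_count,
                      min_total = config$min_total, prior = prior_set)
  # one sub-sample draw per stage, shared by all processing variants: the
  # raw data is rarefied once and then fed to each pipeline setup, so
  # pooled/unpooled and prior/no-prior comparisons see the same reads
  seed <- derive_seed(config$seed, "scenario", scen$subsampling)
  switch(scen$subsampling,
         none = apply_filter(full_table, spec),
         # post-ASV: denoise first, then rarefy the derived counts
         post_asv = subsample_counts(apply_filter(full_table, spec),
                                     depth, seed),
         # pre-ASV: rarefy raw reads, then denoise the shallower sample --
         # sub-sampling-induced singletons are destroyed on this path
         pre_asv = apply_filter(tabulate_reads(
           subsample_reads(reads, depth, seed)), spec),
         stop("unknown subsampling stage: ", scen$subsampling, call. = FALSE))
}

#' Run the full twelve-scenario grid
#'
#' From one raw read set: (1) filters the full table sample-wise and pooled
#' with no prior (the baselines); (2) extracts the prior list of each
#' pooling mode from its baseline; (3) runs all 12 scenarios (pre-ASV:
#' sub-sample reads, tabulate, filter; post-ASV: filter, sub-sample
#' counts); (4) keeps only samples retained in every scenario and above the
#' configured depth thresholds; (5) computes the diversity profile and the
#' correlation of observed richness with original depth per scenario.
#' Fully deterministic given `config$seed`.
#'
#' @param reads a `read_table` of raw (pre-ASV) reads.
#' @param config an [analysis_config()].
#' @return a `grid_result` list with elements `scenarios`, `tables` (named
#'   list of retained `count_table`s), `diversity` (named list of profile
#'   data frames), `summary` (one row per scenario), `retained_samples`,
#'   `original_depths`, `subsample_depth`, and `config`.
#' @export
run_grid <- function(reads, config = analysis_config()) {
  stopifnot(inherits(reads, "read_table"), inherits(config, "analysis_config"))
  full_table <- tabulate_reads(reads)
  full_depths <- sample_depths(full_table)

  eligible <- full_depths >= config$min_full_depth
  depth <- if (identical(config$subsample_depth, "auto")) {
    abort_if(!any(eligible), "no sample reaches min_full_depth = ",
             config$min_full_depth)
    min(full_depths[eligible])
  } else config$subsample_depth

  priors <- list(
    samplewise = extract_prior(filter_samplewise(full_table,
                                                 config$min_count)),
    pooled = extract_prior(filter_pooled(full_table, config$min_total))
  )

  scenarios <- enumerate_scenarios()
  tables <- lapply(seq_len(nrow(scenarios)), function(i) {
    run_one_scenario(scenarios[i, ], reads, full_table, depth, config, priors)
  })
  names(tables) <- scenarios$label

  retained <- retention_filter(full_table, tables,
                               min_full = config$min_full_depth,
                               min_sub = config$min_sub_depth)
  if (length(retained) == 0) {
    n_full <- sum(!eligible)
    stop(sprintf(paste0("no sample retained across all 12 scenarios ",
                        "(%d below min_full_depth = %d; check min_sub_depth ",
                        "and subsample_depth)"),
                 n_full, config$min_full_depth), call. = FALSE)
  }

  tables <- lapply(tables, restrict_samples, sample_ids = retained)
  diversity <- lapply(tables, diversity_profile,
                      rare_threshold = config$rare_threshold)
  depths_retained <- full_depths[retained]

  summary_rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    div <- diversity[[scenarios$label[i]]]
    if (nrow(div) >= 3) {
      rho_s <- depth_correlation(div$observed_richness, depths_retained,
                                 "spearman")
      rho_p <- depth_correlation(div$observed_richness, depths_retained,
                                 "pearson")
    } else {
      rho_s <- rho_p <- undefined_value("fewer than 3 retained samples")
    }
    data.frame(
      label = scenarios$label[i],
      subsampling = scenarios$subsampling[i],
      pooling = scenarios$pooling[i],
      prior = scenarios$prior[i],
      n_samples = nrow(div),
      rho_spearman = as.numeric(rho_s),
      rho_pearson = as.numeric(rho_p),
      mean_richness = mean(div$observed_richness),
      sd_richness = stats::sd(div$observed_richness),
      mean_singletons = mean(div$singletons),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  structure(list(scenarios = scenarios,
                 tables = tables,
                 diversity = diversity,
                 summary = summary,
                 retained_samples = retained,
                 original_depths = depths_retained,
                 subsample_depth = depth,
                 config = config),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf(paste0("grid_result: 12 scenarios, %d retained samples, ",
                     "sub-sampling depth %d\n"),
              length(x$retained_samples), x$subsample_depth))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Scenario-grid summary table
#'
#' One row per scenario: depth-richness correlation (Spearman and Pearson),
#' mean and SD of observed richness, mean per-sample singleton count, and
#' the retained sample count.
#'
#' @param object a `grid_result`.
#' @param ... unused.
#' @return the summary data frame.
#' @export
summary.grid_result <- function(object, ...) object$summary

#' Write the grid summary as a TSV file
#'
#' Numeric columns are serialised with full precision via a fixed format,
#' so identical grids produce byte-identical files.
#'
#' @param grid a `grid_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_summary <- function(grid, path) {
  stopifnot(inherits(grid, "grid_result"))
  df <- grid$summary
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write all grid outputs under a run directory
#'
#' Writes `summary.tsv`, a long-format `diversity_long.tsv` (sample, index,
#' value per scenario), per-scenario rarefaction `curves.tsv`, and a
#' `manifest.json`-style YAML manifest recording the configuration, the
#' resolved sub-sampling depth and the retained samples.
#'
#' @param grid a `grid_result`.
#' @param dir output directory (created if missing).
#' @param grid_points depths per rarefaction curve.
#' @return named character vector of written paths, invisibly.
#' @export
write_grid_outputs <- function(grid, dir, grid_points = 20L) {
  stopifnot(inherits(grid, "grid_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(summary = file.path(dir, "summary.tsv"),
             diversity = file.path(dir, "diversity_long.tsv"),
             curves = file.path(dir, "curves.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  write_grid_summary(grid, paths[["summary"]])

  long <- do.call(rbind, lapply(names(grid$diversity), function(lab) {
    div <- grid$diversity[[lab]]
    idx <- setdiff(names(div), c("sample_id", "ace_defined",
                                 "margalef_defined"))
    do.call(rbind, lapply(idx, function(ix) {
      data.frame(scenario = lab, sample_id = div$sample_id, index = ix,
                 value = as.numeric(div[[ix]]), stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(long, paths[["diversity"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  curves <- do.call(rbind, lapply(names(grid$tables), function(lab) {
    cv <- rarefaction_curve(grid$tables[[lab]], grid_points)
    cbind(scenario = lab, as.data.frame(cv))
  }))
  utils::write.table(curves, paths[["curves"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  yaml::write_yaml(list(config = unclass(grid$config),
                        subsample_depth = grid$subsample_depth,
                        retained_samples = grid$retained_samples),
                   paths[["manifest"]])
  invisible(paths)
}
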
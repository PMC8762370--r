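## Synthetic ASV communities. The generator is built so that, by
## construction, true per-sample richness carries no depth signal: any
## depth-richness correlation seen downstream is attributable to the
## processing pipeline, not to the community.

#' Parameters of the synthetic community generator
#'
#' A regional pool of `pool_size` true ASVs receives lognormal relative
#' abundances (the classic species-abundance distribution with a long rare
#' tail). Each sample contains a Bernoulli(`occupancy`) subset of the pool,
#' renormalised to sum to one. Per-sample sequencing depths are log-uniform
#' on `[depth_low, depth_high]`, emulating the technical depth spread of
#' real runs. Each sequenced read is independently corrupted with
#' probability `error_rate` into a globally unique spurious identifier, so
#' error reads are exact singletons in the uncorrected table -- the premise
#' under which denoisers treat singletons as presumptive errors.
#'
#' Defaults are the package's headline study conditions: 60 samples, a
#' 2000-ASV pool at 60% occupancy, depths on \[10^4, 10^5\], and a 0.5%
#' per-read error rate.
#'
#' @param pool_size number of true ASVs in the regional pool.
#' @param abundance_logmean,abundance_logsd lognormal SAD parameters.
#' @param occupancy probability in (0, 1] that a pool ASV occurs in a sample.
#' @param depth_low,depth_high bounds of the log-uniform depth distribution.
#' @param error_rate per-read corruption probability in \[0, 1).
#' @param n_samples number of samples.
#' @param seed master integer seed.
#' @return a `community_model` object.
#' @export
community_model <- function(pool_size = 2000L,
                            abundance_logmean = 0,
                            abundance_logsd = 1.5,
                            occupancy = 0.6,
                            depth_low = 10000L,
                            depth_high = 100000L,
                            error_rate = 0.005,
                            n_samples = 60L,
                            seed = 1L) {
  abort_if(pool_size < 1, "`pool_size` must be at least 1")
  abort_if(occupancy <= 0 || occupancy > 1, "`occupancy` must be in (0, 1]")
  abort_if(depth_low > depth_high, "`depth_low` must not exceed `depth_high`")
  abort_if(depth_low < 1, "depths must be positive")
  abort_if(error_rate < 0 || error_rate >= 1, "`error_rate` must be in [0, 1)")
  abort_if(n_samples < 1, "`n_samples` must be at least 1")
  structure(list(pool_size = as.integer(pool_size),
                 abundance_logmean = abundance_logmean,
                 abundance_logsd = abundance_logsd,
                 occupancy = occupancy,
                 depth_low = as.integer(depth_low),
                 depth_high = as.integer(depth_high),
                 error_rate = error_rate,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "community_model")
}

sample_names <- function(n) sprintf("s%03d", seq_len(n))

pool_names <- function(n) sprintf("asv%06d", seq_len(n))

#' Draw per-sample true relative abundances
#'
#' The regional lognormal abundances are drawn once from a dedicated random
#' stream; each sample then draws its own presence mask (at least one ASV is
#' always present) from a per-sample stream, so adding samples never changes
#' existing ones. Present abundances are renormalised to sum to one.
#'
#' @param model a [community_model()].
#' @return numeric matrix (`n_samples` x `pool_size`) of relative
#'   abundances; absent ASVs hold zero and every row sums to one.
#' @export
draw_community <- function(model) {
  stopifnot(inherits(model, "community_model"))
  pool <- with_seed(derive_seed(model$seed, "pool"),
                    stats::rlnorm(model$pool_size,
                                  meanlog = model$abundance_logmean,
                                  sdlog = model$abundance_logsd))
  m <- matrix(0, nrow = model$n_samples, ncol = model$pool_size,
              dimnames = list(sample_names(model$n_samples),
                              pool_names(model$pool_size)))
  for (i in seq_len(model$n_samples)) {
    present <- with_seed(derive_seed(model$seed, "presence", i), {
      p <- stats::runif(model$pool_size) < model$occupancy
      if (!any(p)) p[sample.int(model$pool_size, 1)] <- TRUE
      p
    })
    m[i, present] <- pool[present] / sum(pool[present])
  }
  m
}

#' Draw per-sample sequencing depths
#'
#' Depths are log-uniform on `[depth_low, depth_high]`, rounded to integers,
#' drawn from per-sample streams.
#'
#' @param model a [community_model()].
#' @return named integer vector of depths.
#' @export
draw_depths <- function(model) {
  stopifnot(inherits(model, "community_model"))
  d <- vapply(seq_len(model$n_samples), function(i) {
    with_seed(derive_seed(model$seed, "depth", i), {
      u <- stats::runif(1, log(model$depth_low), log(model$depth_high))
      max(1L, as.integer(round(exp(u))))
    })
  }, integer(1))
  names(d) <- sample_names(model$n_samples)
  d
}

#' Simulate an ASV count table from true abundances
#'
#' For each sample, the number of error reads is Binomial(`N`, `error_rate`)
#' and the remaining reads are multinomial over that sample's true
#' abundances -- together exactly equivalent to corrupting each of `N`
#' drawn reads independently with probability `error_rate`. Every corrupted
#' read becomes a fresh identifier (`err-sXXX-YYYYYY`) never shared with any
#' other read, so spurious ASVs are exact singletons in the returned table.
#'
#' @param abundances matrix of per-sample relative abundances (rows sum to 1).
#' @param depths named integer vector of per-sample depths.
#' @param error_rate per-read corruption probability.
#' @param seed integer seed.
#' @return a `count_table` with row sums equal to `depths`.
#' @export
simulate_counts <- function(abundances, depths, error_rate = 0, seed = 1L) {
  abort_if(!is.matrix(abundances), "`abundances` must be a matrix")
  abort_if(length(depths) != nrow(abundances),
           "`depths` must have one entry per abundance row")
  abort_if(any(depths < 1), "depths must be positive")
  abort_if(any(abs(rowSums(abundances) - 1) > 1e-9),
           "abundance rows must sum to 1")
  if (is.null(names(depths))) names(depths) <- rownames(abundances)
  samples <- rownames(abundances)
  true_counts <- matrix(0L, nrow = length(samples), ncol = ncol(abundances),
                        dimnames = list(samples, colnames(abundances)))
  err_cols <- list()
  for (i in seq_along(samples)) {
    s <- samples[i]
    n <- as.integer(depths[[s]])
    with_seed(derive_seed(seed, "reads", i), {
      n_err <- stats::rbinom(1, n, error_rate)
      p <- abundances[i, ]
      true_counts[i, ] <- as.integer(stats::rmultinom(1, n - n_err, p))
      if (n_err > 0) {
        err_cols[[s]] <- sprintf("err-%s-%06d", s, seq_len(n_err))
      }
    })
  }
  err_ids <- unlist(err_cols, use.names = FALSE)
  if (length(err_ids)) {
    err <- matrix(0L, nrow = length(samples), ncol = length(err_ids),
                  dimnames = list(samples, err_ids))
    for (s in names(err_cols)) err[s, err_cols[[s]]] <- 1L
    m <- cbind(true_counts, err)
  } else {
    m <- true_counts
  }
  drop_empty_asvs(structure_count_table(m))
}

#' Simulate raw reads from true abundances
#'
#' Same sampling law as [simulate_counts()] (and the same draws under the
#' same seed), expanded into a per-sample read multiset so that pre-ASV
#' sub-sampling can act at the read level.
#'
#' @inheritParams simulate_counts
#' @return a `read_table`; `tabulate_reads()` of it equals
#'   `simulate_counts()` under the same arguments.
#' @export
simulate_reads <- function(abundances, depths, error_rate = 0, seed = 1L) {
  expand_reads(simulate_counts(abundances, depths, error_rate, seed))
}

#' Simulate a full synthetic dataset
#'
#' Convenience wrapper: draws the community and depths from the model and
#' simulates the uncorrected count table (and optionally the raw reads).
#'
#' @param model a [community_model()].
#' @param reads also materialise the `read_table` (needed for pre-ASV
#'   sub-sampling; skip for count-level-only analyses).
#' @return list with elements `model`, `abundances`, `depths`, `table`, and
#'   (if requested) `reads`.
#' @export
simulate_dataset <- function(model, reads = TRUE) {
  stopifnot(inherits(model, "community_model"))
  abund <- draw_community(model)
  depths <- draw_depths(model)
  tab <- simulate_counts(abund, depths, model$error_rate, model$seed)
  out <- list(model = model, abundances = abund, depths = depths, table = tab)
  if (reads) out$reads <- expand_reads(tab)
  out
}
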
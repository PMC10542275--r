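# Empirical-null power and false-positive-rate estimation.
#
# Power: the fraction of selection-simulated replicates whose statistic falls
# in the 5% one-sided tail of a simulated neutral null distribution. FPR: the
# same fraction for neutrally simulated data (the null-generating demography
# may deliberately differ from the data-generating one). Undefined statistic
# values count as non-significant among the data replicates and are excluded
# (with a recorded count) from the null.
#
# Null construction differs by statistic family: the SFS statistics use
# unconditioned neutral replicates, while the haplotype statistics use
# neutral replicates whose focal variant is frequency-matched (bin width
# 0.05) to each data replicate, because the EHH-based statistics depend
# strongly on the core-allele frequency. Comparing the unstandardized iHS
# to its frequency-matched null is tail-equivalent to bin-wise
# standardization.

.stat_family <- function(stat) {
  if (stat %in% c("D", "H")) "sfs" else if (stat %in% c("rEHH", "iHS")) "hap"
  else stop("unknown statistic: ", stat)
}

#' Wilson score interval
#'
#' @param k successes.
#' @param n trials.
#' @param conf confidence level.
#' @return named vector \code{c(lo, hi)}.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

# frequency bin of width w containing f, clipped to the polymorphic lattice
# range of a population of size N0 (used to condition neutral nulls)
.freq_bin <- function(f, w, N0) {
  lo <- floor(f / w + 1e-12) * w
  if (lo >= 1) lo <- 1 - w
  hi <- lo + w
  lo <- max(lo, 1 / (2 * N0))
  hi <- min(hi, 1 - 1 / (4 * N0))
  c(lo, hi)
}

.bin_key <- function(bin) sprintf("%.6f-%.6f", bin[1], bin[2])

# Generate n_null neutral replicates under null_model and compute the given
# statistics on each; returns a list of numeric vectors (NAs removed, sorted)
# plus exclusion counts. Cached per (family, conditioning) in cache_env.
.null_values <- function(stats, null_model, region, conditioning, n_null,
                         cache_env, opts) {
  family <- .stat_family(stats[1])
  key <- paste(family, null_model$label, region$L, region$n,
               if (is.null(conditioning)) "none" else .bin_key(conditioning),
               n_null, sep = "|")
  if (!is.null(cache_env) && !is.null(cache_env[[key]])) return(cache_env[[key]])
  fam_stats <- if (family == "sfs") c("D", "H") else c("rEHH", "iHS")
  vals <- matrix(NA_real_, nrow = n_null, ncol = length(fam_stats),
                 dimnames = list(NULL, fam_stats))
  for (i in seq_len(n_null)) {
    smp <- simulate_neutral_sample(null_model, region, condition_focal = conditioning)
    for (st in fam_stats)
      vals[i, st] <- compute_stat(smp, st, ehh_distance = opts$ehh_distance,
                                  truncation = opts$truncation,
                                  include_focal = opts$include_focal)$value
  }
  out <- lapply(fam_stats, function(st) {
    v <- vals[, st]
    n_excl <- sum(is.na(v))
    if (n_excl > n_null / 2)
      stop(sprintf("more than 50%% of null replicates undefined for %s %s(conditioning misconfigured?)",
                   st, if (is.null(conditioning)) "" else paste0("in bin ", .bin_key(conditioning), " ")))
    list(values = sort(v[!is.na(v)]), n_excluded = n_excl)
  })
  names(out) <- fam_stats
  if (!is.null(cache_env)) cache_env[[key]] <- out
  out
}

#' Build an empirical null distribution for one statistic
#'
#' Simulates \code{n_null} neutral replicates under \code{null_model} (with
#' the focal variant frequency-matched to \code{conditioning} for the
#' haplotype statistics), computes the statistic, and stores the sorted
#' defined values together with the rejection tail.
#'
#' @param stat statistic name (\code{"D"}, \code{"H"}, \code{"rEHH"},
#'   \code{"iHS"}).
#' @param null_model a \code{demographic_model}.
#' @param region a \code{region_config}.
#' @param conditioning optional length-2 frequency bin for the focal variant.
#' @param n_null number of null replicates (>= 200).
#' @param ehh_distance,truncation,include_focal statistic options.
#' @return an object of class \code{null_distribution}.
#' @export
build_null <- function(stat, null_model, region, conditioning = NULL,
                       n_null = 1000, ehh_distance = 25000, truncation = 0.05,
                       include_focal = TRUE) {
  if (n_null < 200) stop("n_null must be >= 200")
  opts <- list(ehh_distance = ehh_distance, truncation = truncation,
               include_focal = include_focal)
  nv <- .null_values(stat, null_model, region, conditioning, n_null,
                     cache_env = NULL, opts = opts)[[stat]]
  structure(
    list(stat = stat, values = nv$values, tail = stat_tail(stat),
         conditioning = conditioning, n_null = length(nv$values),
         n_excluded = nv$n_excluded, model_label = null_model$label),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution for %s (%s tail): %d values (%d undefined excluded), model %s\n",
              x$stat, x$tail, x$n_null, x$n_excluded, x$model_label))
  invisible(x)
}

#' Empirical one-sided threshold of a null distribution
#'
#' The order statistic at rank \code{ceiling(alpha * n)} from the rejection
#' tail.
#'
#' @param null a \code{null_distribution}, or a sorted numeric vector.
#' @param alpha significance level.
#' @param tail \code{"lower"} or \code{"upper"} (taken from the object when
#'   a \code{null_distribution} is given).
#' @export
null_threshold <- function(null, alpha = 0.05, tail = NULL) {
  if (inherits(null, "null_distribution")) {
    v <- null$values
    tail <- null$tail
  } else {
    v <- sort(null)
    if (is.null(tail)) stop("tail required for a bare vector")
  }
  n <- length(v)
  r <- max(1L, ceiling(alpha * n))
  if (tail == "lower") v[r] else v[n + 1L - r]
}

.is_significant <- function(value, thr, tail) {
  if (is.na(value)) return(FALSE)
  if (tail == "lower") value <= thr else value >= thr
}

# simulate one data replicate for a cell; scenario NULL => neutral data
.sim_data_sample <- function(model, scenario, region, data_bin = NULL) {
  if (is.null(scenario)) {
    return(simulate_neutral_sample(model, region, condition_focal = data_bin))
  }
  traj <- switch(scenario$mode,
    SDN = simulate_sdn(model, s = scenario$s, t_age = scenario$t_age,
                       h = scenario$h, condition = scenario$condition),
    SSV = simulate_ssv(model, s = scenario$s, p1 = scenario$p1,
                       t_sel = scenario$t_sel, h = scenario$h,
                       condition = scenario$condition),
    CURRENT_FREQ = simulate_current_freq(model, scenario$bin, s = scenario$s,
                                         h = scenario$h,
                                         t_max = scenario$t_max),
    stop("unknown scenario mode: ", scenario$mode))
  simulate_sweep_sample(model, traj, region)
}

#' Estimate power (or FPR) for one scenario cell
#'
#' Simulates \code{n_reps} data replicates (selection scenario, or neutral
#' when \code{scenario} is \code{NULL}), compares each statistic with the
#' empirical one-sided threshold of its simulated neutral null under
#' \code{null_model}, and returns one \code{power_estimate} per statistic.
#' Undefined statistic values count as non-significant.
#'
#' @param model data-generating \code{demographic_model}.
#' @param scenario a \code{selection_scenario}, or \code{NULL} for neutral
#'   data (FPR estimation).
#' @param region a \code{region_config}.
#' @param stats character vector of statistic names (one family per call:
#'   \code{c("D","H")} with an SFS region, or \code{c("rEHH","iHS")} with a
#'   haplotype region).
#' @param n_reps data replicates per cell (default 200).
#' @param alpha one-sided significance level.
#' @param null_model null-generating demography (defaults to \code{model};
#'   set to a standard-neutral model to study demographic misspecification).
#' @param n_null null replicates for the SFS statistics.
#' @param n_null_bin null replicates per frequency bin for the haplotype
#'   statistics.
#' @param bin_width frequency-matching bin width.
#' @param data_bin focal-frequency bin for neutral haplotype-family data
#'   (required when \code{scenario} is \code{NULL} and the family is
#'   \code{"hap"}).
#' @param ehh_distance,truncation,include_focal statistic options.
#' @param null_cache optional environment reused across calls to share null
#'   simulations.
#' @param seed optional seed (set once at entry).
#' @return a data.frame with one row per statistic: counts, power, Wilson
#'   interval, and the mean present-day derived-allele frequency.
#' @export
estimate_power <- function(model, scenario, region, stats,
                           n_reps = 200, alpha = 0.05,
                           null_model = model,
                           n_null = 1000, n_null_bin = 200,
                           bin_width = 0.05, data_bin = NULL,
                           ehh_distance = 25000, truncation = 0.05,
                           include_focal = TRUE,
                           null_cache = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  family <- unique(vapply(stats, .stat_family, ""))
  if (length(family) != 1)
    stop("all statistics in one call must belong to the same family")
  if (is.null(null_cache)) null_cache <- new.env(parent = emptyenv())
  opts <- list(ehh_distance = ehh_distance, truncation = truncation,
               include_focal = include_focal)
  N0_null <- size_at(null_model, 0)

  values <- matrix(NA_real_, nrow = n_reps, ncol = length(stats),
                   dimnames = list(NULL, stats))
  freqs <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    smp <- .sim_data_sample(model, scenario, region, data_bin)
    freqs[i] <- if (isTRUE(smp$focal$present)) smp$focal$freq else NA_real_
    for (st in stats)
      values[i, st] <- compute_stat(smp, st, ehh_distance = ehh_distance,
                                    truncation = truncation,
                                    include_focal = include_focal)$value
  }

  out <- vector("list", length(stats))
  for (k in seq_along(stats)) {
    st <- stats[k]
    tail <- stat_tail(st)
    v <- values[, st]
    n_undef <- sum(is.na(v))
    if (family == "sfs") {
      nv <- .null_values(st, null_model, region, NULL, n_null, null_cache, opts)[[st]]
      thr <- null_threshold(nv$values, alpha, tail)
      sig <- vapply(v, .is_significant, TRUE, thr = thr, tail = tail)
    } else {
      sig <- logical(n_reps)
      def <- which(!is.na(v))
      if (length(def) > 0) {
        bins <- vapply(freqs[def], function(f) .freq_bin(f, bin_width, N0_null)[1],
                       numeric(1))
        for (b in unique(bins)) {
          bin <- .freq_bin(b + bin_width / 2, bin_width, N0_null)
          nv <- .null_values(st, null_model, region, bin, n_null_bin,
                             null_cache, opts)[[st]]
          thr <- null_threshold(nv$values, alpha, tail)
          in_b <- def[bins == b]
          sig[in_b] <- vapply(v[in_b], .is_significant, TRUE, thr = thr, tail = tail)
        }
      }
    }
    n_sig <- sum(sig)
    ci <- wilson_ci(n_sig, n_reps)
    out[[k]] <- data.frame(
      stat = st, n_reps = n_reps, n_sig = n_sig, n_undefined = n_undef,
      power = n_sig / n_reps, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
      mean_final_freq = mean(freqs), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the false-positive rate for one cell
#'
#' Power of neutrally generated data against a (possibly mismatched) null:
#' \code{estimate_power} with \code{scenario = NULL}. The data-generating
#' demography may differ from the null demography to study the effect of
#' ignoring population expansion or bottlenecks.
#'
#' @inheritParams estimate_power
#' @export
estimate_fpr <- function(model, region, stats, n_reps = 200, alpha = 0.05,
                         null_model = model, n_null = 1000, n_null_bin = 200,
                         bin_width = 0.05, data_bin = NULL,
                         ehh_distance = 25000, truncation = 0.05,
                         include_focal = TRUE, null_cache = NULL, seed = NULL) {
  estimate_power(model, scenario = NULL, region = region, stats = stats,
                 n_reps = n_reps, alpha = alpha, null_model = null_model,
                 n_null = n_null, n_null_bin = n_null_bin,
                 bin_width = bin_width, data_bin = data_bin,
                 ehh_distance = ehh_distance, truncation = truncation,
                 include_focal = include_focal, null_cache = null_cache,
                 seed = seed)
}

# ------------------------------------------------------------- grid running

.model_from_cfg <- function(x) {
  if (inherits(x, "demographic_model")) return(x)
  tu <- if (is.null(x$time_unit)) "generations" else x$time_unit
  refN <- if (is.null(x$reference_N)) NA_real_ else as.numeric(x$reference_N)
  ts <- vapply(x$epochs, function(e) as.numeric(e$t_start), numeric(1))
  sz <- vapply(x$epochs, function(e) as.numeric(e$size), numeric(1))
  if (tu == "scaled_N") ts <- ts * refN
  if (!is.finite(refN)) refN <- sz[1]
  demographic_model(ts, sz, reference_N = refN,
                    label = if (is.null(x$label)) "" else x$label)
}

.region_from_cfg <- function(kind, n, L = NULL, focal = NULL) {
  if (identical(kind, "sfs")) return(sfs_region(n))
  if (identical(kind, "hap")) return(hap_region(n))
  if (is.list(kind)) {
    return(region_config(L = kind$L,
                         mu = if (is.null(kind$mu)) 1e-8 else kind$mu,
                         r = if (is.null(kind$r)) 1e-8 else kind$r,
                         n = if (is.null(kind$n)) n else as.integer(kind$n),
                         focal_pos = if (is.null(kind$focal_pos)) 0 else kind$focal_pos))
  }
  region_config(L, n = n, focal_pos = focal)
}

.cell_scenario <- function(cell) {
  if (identical(cell$mode, "NEUTRAL") || is.null(cell$mode)) return(NULL)
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  h <- if (is.null(cell$h)) 0.5 else as.numeric(cell$h)
  cond <- if (is.null(cell$condition)) "non_lost" else cell$condition
  switch(cell$mode,
    SDN = selection_scenario("SDN", s = num(cell$s), h = h,
                             t_age = num(cell$t_age), condition = cond),
    SSV = selection_scenario("SSV", s = num(cell$s), h = h, p1 = num(cell$p1),
                             t_sel = num(cell$t_sel), condition = cond),
    CURRENT_FREQ = selection_scenario("CURRENT_FREQ", s = num(cell$s), h = h,
                                      bin = num(unlist(cell$bin)),
                                      t_max = num(cell$t_max),
                                      condition = cond),
    stop("unknown cell mode: ", cell$mode))
}

#' Run a grid of power / FPR cells from an experiment configuration
#'
#' The configuration (a list, or a YAML file path) has global fields
#' \code{label}, \code{model}, optional \code{null_model}, \code{sample_n},
#' \code{alpha}, \code{n_reps}, \code{n_null}, \code{n_null_bin},
#' \code{ehh_distance}, \code{seed}, and a list \code{cells}. Each cell
#' gives \code{name}, \code{mode} (\code{SDN}, \code{SSV},
#' \code{CURRENT_FREQ}, or \code{NEUTRAL} for FPR rows), its scenario
#' parameters, \code{stats}, and \code{region} (\code{"sfs"} or
#' \code{"hap"}). Null simulations are shared across cells through one
#' cache. Partial failures are flagged in the \code{error} column and the
#' run continues.
#'
#' @param config list or YAML file path.
#' @param seed overrides the config seed.
#' @return long-format data.frame of results, one row per (cell, statistic).
#' @export
run_grid <- function(config, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  model <- .model_from_cfg(config$model)
  null_model <- if (is.null(config$null_model)) model
                else .model_from_cfg(config$null_model)
  n <- if (is.null(config$sample_n)) 120L else as.integer(config$sample_n)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  n_reps <- if (is.null(config$n_reps)) 200L else as.integer(config$n_reps)
  n_null <- if (is.null(config$n_null)) 1000L else as.integer(config$n_null)
  n_null_bin <- if (is.null(config$n_null_bin)) 200L else as.integer(config$n_null_bin)
  ehh_distance <- if (is.null(config$ehh_distance)) 25000 else config$ehh_distance
  cache <- new.env(parent = emptyenv())
  rows <- list()
  for (cell in config$cells) {
    res <- tryCatch({
      region <- .region_from_cfg(cell$region, n, cell$L, cell$focal_pos)
      scen <- .cell_scenario(cell)
      data_bin <- if (!is.null(cell$data_bin)) unlist(cell$data_bin) else NULL
      estimate_power(model, scen, region, stats = unlist(cell$stats),
                     n_reps = n_reps, alpha = alpha, null_model = null_model,
                     n_null = n_null, n_null_bin = n_null_bin,
                     data_bin = data_bin, ehh_distance = ehh_distance,
                     null_cache = cache)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cell$name, mode = if (is.null(cell$mode)) "NEUTRAL" else cell$mode,
        stat = paste(unlist(cell$stats), collapse = ","),
        n_reps = NA_integer_, n_sig = NA_integer_, n_undefined = NA_integer_,
        power = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        mean_final_freq = NA_real_,
        error = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    res$cell <- cell$name
    res$mode <- if (is.null(cell$mode)) "NEUTRAL" else cell$mode
    res$error <- NA_character_
    rows[[length(rows) + 1L]] <-
      res[, c("cell", "mode", "stat", "n_reps", "n_sig", "n_undefined",
              "power", "ci_lo", "ci_hi", "mean_final_freq", "error")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write grid results as TSV
#'
#' @param results data.frame from \code{\link{run_grid}}.
#' @param path output file.
#' @export
write_grid_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
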
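# Piecewise-constant diploid demographic models.
#
# Internal time unit: generations before present. Epochs are half-open
# [t_start, t_end) looking backward, so a size change at time t applies to
# all times >= t. Config files may give times in units of reference_N
# generations; they are converted on parsing.

#' Construct a piecewise-constant demographic model
#'
#' @param t_start numeric vector of epoch start times in generations before
#'   present, ascending, first element 0. Each epoch extends to the start of
#'   the next (the oldest is unbounded).
#' @param size diploid population sizes, one per epoch (all >= 2).
#' @param reference_N diploid size used to convert N-scaled times in configs
#'   and scenario definitions.
#' @param label free-text label.
#' @return an object of class \code{demographic_model}.
#' @export
demographic_model <- function(t_start, size, reference_N = size[1], label = "") {
  t_start <- as.numeric(t_start)
  size <- as.numeric(size)
  if (length(t_start) != length(size) || length(size) < 1)
    stop("t_start and size must have equal positive length")
  if (t_start[1] != 0)
    stop("the first epoch must begin at t_start = 0")
  if (length(t_start) > 1 && any(diff(t_start) <= 0))
    stop("epoch start times must be strictly increasing (gap or overlap in epochs)")
  if (any(size < 2))
    stop("population sizes must be >= 2")
  if (any(!is.finite(size)) || any(!is.finite(t_start)))
    stop("non-finite epoch parameters")
  structure(
    list(t_start = t_start, size = size,
         reference_N = as.numeric(reference_N), label = as.character(label)),
    class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model", if (nzchar(x$label)) paste0("'", x$label, "'") else "",
      "\n", sep = " ")
  ends <- c(x$t_start[-1], Inf)
  for (i in seq_along(x$size))
    cat(sprintf("  [%g, %g) generations: N = %g\n", x$t_start[i], ends[i], x$size[i]))
  cat(sprintf("  reference_N = %g\n", x$reference_N))
  invisible(x)
}

#' Population size at a time in the past
#'
#' @param model a \code{demographic_model}.
#' @param t time in generations before present (vectorised, all >= 0).
#' @return diploid size of the epoch containing each \code{t}.
#' @export
size_at <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"))
  if (any(t < 0)) stop("t must be non-negative")
  idx <- findInterval(t, model$t_start)
  model$size[idx]
}

#' Constant-size model
#'
#' @param N0 diploid population size.
#' @param label model label.
#' @return a single-epoch \code{demographic_model}.
#' @export
make_constant <- function(N0, label = sprintf("constant N=%g", N0)) {
  if (N0 <= 0) stop("N0 must be positive")
  demographic_model(0, N0, reference_N = N0, label = label)
}

#' Instantaneous-expansion model
#'
#' The current population of size \code{ratio * N1} arose by an instantaneous
#' expansion at time \code{t1} from an ancestral population of size \code{N1}.
#'
#' @param ratio current/ancestral size ratio (N0/N1).
#' @param N1 ancestral diploid size.
#' @param t1 expansion time. Interpreted in units of \code{reference_N}
#'   generations when \code{scaled_time = TRUE} (the convention of the model
#'   grids this package ships), otherwise in generations.
#' @param reference_N diploid size that scales \code{t1}; defaults to 5000,
#'   the common effective size of the basic model grid.
#' @param scaled_time whether \code{t1} is in units of \code{reference_N}
#'   generations.
#' @param label model label.
#' @export
make_expansion <- function(ratio, N1, t1, reference_N = 5000,
                           scaled_time = TRUE,
                           label = sprintf("expansion N1=%g t1=%g", N1, t1)) {
  if (ratio <= 0 || N1 <= 0 || t1 <= 0) stop("expansion parameters must be positive")
  t1g <- if (scaled_time) t1 * reference_N else t1
  demographic_model(c(0, t1g), c(ratio * N1, N1),
                    reference_N = reference_N, label = label)
}

#' Bottleneck model
#'
#' Looking backward: the current population of size \code{N0} passed through
#' a bottleneck of size \code{Nb} that ended \code{tb} before present and
#' lasted \code{duration} generations; before the bottleneck the population
#' had the ancestral size \code{N0} again (current/bottleneck ratio
#' \code{N0/Nb}).
#'
#' @param N0 current (and ancestral) diploid size.
#' @param Nb diploid size during the bottleneck.
#' @param tb time the bottleneck ended. In units of \code{reference_N}
#'   generations when \code{scaled_time = TRUE}, else generations.
#' @param duration bottleneck duration in generations.
#' @param reference_N diploid size that scales \code{tb}.
#' @param scaled_time whether \code{tb} is N-scaled.
#' @param N_anc pre-bottleneck diploid size (defaults to \code{N0}).
#' @param label model label.
#' @export
make_bottleneck <- function(N0, Nb, tb, duration = 500, reference_N = 5000,
                            scaled_time = TRUE, N_anc = N0,
                            label = sprintf("bottleneck Nb=%g tb=%g", Nb, tb)) {
  if (N0 <= 0 || Nb <= 0 || tb <= 0 || duration <= 0 || N_anc <= 0)
    stop("bottleneck parameters must be positive")
  tbg <- if (scaled_time) tb * reference_N else tb
  demographic_model(c(0, tbg, tbg + duration), c(N0, Nb, N_anc),
                    reference_N = reference_N, label = label)
}

#' Read a demographic model from a YAML config
#'
#' The config has fields \code{label}, \code{reference_N},
#' \code{time_unit} (\code{"generations"} or \code{"scaled_N"}) and
#' \code{epochs}, a list of \code{{t_start, size}} records ordered from the
#' present backward.
#'
#' @param path file path, or a YAML string.
#' @return a \code{demographic_model}.
#' @export
read_demography_config <- function(path) {
  cfg <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  if (is.null(cfg$epochs) || length(cfg$epochs) == 0)
    stop("config must list at least one epoch")
  tu <- if (is.null(cfg$time_unit)) "generations" else cfg$time_unit
  if (!tu %in% c("generations", "scaled_N"))
    stop("time_unit must be 'generations' or 'scaled_N'")
  refN <- if (is.null(cfg$reference_N)) NA_real_ else as.numeric(cfg$reference_N)
  ts <- vapply(cfg$epochs, function(e) as.numeric(e$t_start), numeric(1))
  sz <- vapply(cfg$epochs, function(e) as.numeric(e$size), numeric(1))
  if (tu == "scaled_N") {
    if (!is.finite(refN)) stop("scaled_N times require a reference_N field")
    ts <- ts * refN
  }
  if (!is.finite(refN)) refN <- sz[1]
  demographic_model(ts, sz, reference_N = refN,
                    label = if (is.null(cfg$label)) "" else cfg$label)
}

#' Write a demographic model to a YAML config
#'
#' Times are written in generations, so
#' \code{read_demography_config(write_demography_config(m))} reproduces
#' \code{m} exactly.
#'
#' @param model a \code{demographic_model}.
#' @param path output file; when \code{NULL} the YAML text is returned.
#' @export
write_demography_config <- function(model, path = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  cfg <- list(
    label = model$label,
    reference_N = model$reference_N,
    time_unit = "generations",
    epochs = lapply(seq_along(model$size), function(i)
      list(t_start = model$t_start[i], size = model$size[i])))
  txt <- yaml::as.yaml(cfg)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
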
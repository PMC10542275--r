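# Wright-Fisher derived-allele frequency trajectories under selection.
#
# Genotype fitnesses are 1 : 1+2hs : 1+2s, so with the default h = 0.5 the
# heterozygote advantage equals s (the additive, per-allele convention of
# forward sweep simulators; Ns is then the usual selection-strength
# parameter). A trajectory is stored present-first: freqs[1] is the
# present-day frequency, freqs[origin_gen + 1] the frequency at the origin.

.traj_new <- function(freqs, scenario, model, attempts = NA_real_) {
  structure(
    list(freqs = as.numeric(freqs),
         origin_gen = length(freqs) - 1L,
         final_freq = freqs[1],
         scenario = scenario,
         model_label = model$label,
         attempts = attempts),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Trajectory: mode=%s s=%g h=%g | origin %d generations ago, final frequency %.4g\n",
              sc$mode, sc$s, sc$h, x$origin_gen, x$final_freq))
  invisible(x)
}

#' Selection scenario descriptor
#'
#' @param mode one of \code{"SDN"} (selection on a de novo mutation),
#'   \code{"SSV"} (selection on standing variation), or
#'   \code{"CURRENT_FREQ"} (conditioning on the present-day frequency).
#' @param s selection coefficient per allele (genotype fitnesses
#'   1 : 1+2hs : 1+2s); \code{s = 0} gives neutral trajectories.
#' @param h dominance coefficient; 0.5 (semidominant / additive) by default.
#' @param t_age allele age in generations (SDN).
#' @param p1 derived-allele frequency when selection started (SSV).
#' @param t_sel onset of selection in generations before present (SSV).
#' @param bin length-2 frequency interval in (0, 1] (CURRENT_FREQ).
#' @param t_max origin-time window in generations for CURRENT_FREQ forward
#'   rejection (default \code{8 * reference_N} at simulation time).
#' @param condition \code{"non_lost"} (frequency > 0 at present; fixation
#'   allowed) or \code{"segregating"}.
#' @export
selection_scenario <- function(mode = c("SDN", "SSV", "CURRENT_FREQ"),
                               s, h = 0.5, t_age = NULL, p1 = NULL,
                               t_sel = NULL, bin = NULL, t_max = NULL,
                               condition = c("non_lost", "segregating")) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  if (s < 0) stop("s must be non-negative")
  if (mode == "SDN" && (is.null(t_age) || t_age < 1)) stop("SDN requires t_age >= 1")
  if (mode == "SSV") {
    if (is.null(p1) || p1 <= 0 || p1 >= 1) stop("SSV requires 0 < p1 < 1")
    if (is.null(t_sel) || t_sel < 1) stop("SSV requires t_sel >= 1")
  }
  if (mode == "CURRENT_FREQ") {
    if (is.null(bin) || length(bin) != 2 || bin[1] <= 0 || bin[2] > 1 || bin[1] > bin[2])
      stop("CURRENT_FREQ requires a frequency bin within (0, 1]")
  }
  structure(list(mode = mode, s = s, h = h, t_age = t_age, p1 = p1,
                 t_sel = t_sel, bin = bin, t_max = t_max,
                 condition = condition),
            class = "selection_scenario")
}

.epochs <- function(model) list(t = model$t_start, N = model$size)

#' One Wright-Fisher generation, forward in time
#'
#' Applies deterministic selection (fitnesses 1 : 1+2hs : 1+2s) and then
#' binomial drift with \code{2 * N_child} trials.
#'
#' @param p parental derived-allele frequency in [0, 1].
#' @param N_child diploid size of the offspring generation.
#' @param s,h selection and dominance coefficients.
#' @return the offspring frequency, a lattice value k / (2 N_child).
#' @export
wf_step_forward <- function(p, N_child, s, h = 0.5) {
  cpp_wf_step(p, N_child, s, h)
}

#' Expected post-selection frequency
#'
#' The deterministic part of \code{\link{wf_step_forward}}:
#' \eqn{p^* = [p^2(1+2s) + p(1-p)(1+2hs)] / \bar w}.
#'
#' @inheritParams wf_step_forward
#' @export
selection_pstar <- function(p, s, h = 0.5) {
  w2 <- 1 + 2 * s; w1 <- 1 + 2 * h * s
  num <- p^2 * w2 + p * (1 - p) * w1
  num / (num + p * (1 - p) * w1 + (1 - p)^2)
}

#' Trajectory for selection on a de novo mutation
#'
#' The derived allele is introduced at frequency 1/(2N) \code{t_age}
#' generations before present and followed forward to the present;
#' trajectories violating the survival condition are rejected and redrawn.
#'
#' @param model a \code{demographic_model}.
#' @param s,h selection and dominance coefficients.
#' @param t_age allele age in generations (>= 1).
#' @param condition \code{"non_lost"} or \code{"segregating"}.
#' @param max_attempts rejection-sampling guard.
#' @return a \code{trajectory}.
#' @export
simulate_sdn <- function(model, s, t_age, h = 0.5,
                         condition = c("non_lost", "segregating"),
                         max_attempts = 1e6) {
  condition <- match.arg(condition)
  ep <- .epochs(model)
  res <- cpp_sdn_trajectory(ep$t, ep$N, s, h, as.integer(t_age),
                            condition == "segregating", max_attempts)
  sc <- selection_scenario("SDN", s = s, h = h, t_age = t_age, condition = condition)
  .traj_new(res$freqs, sc, model, res$attempts)
}

#' Trajectory conditioned on the current allele frequency
#'
#' Baseline (\code{method = "forward"}, valid under any demography): forward
#' simulation from a de novo mutation at an origin time drawn uniformly on
#' [1, t_max], rejected until the present-day frequency falls in \code{bin}.
#' Constant-model accelerator (\code{method = "backward"}): the present-day
#' lattice frequency is drawn uniformly in \code{bin} and the path is
#' extended into the past by binomial resampling with reversed fitness
#' weights until the origin (paths reaching fixation backward are rejected).
#' \code{method = "auto"} uses the accelerator for single-epoch models when
#' \code{bin[2] < 1}.
#'
#' @param model a \code{demographic_model}.
#' @param bin length-2 frequency interval within (0, 1].
#' @param s,h selection and dominance coefficients (\code{s = 0} for the
#'   neutral trajectories used in frequency-matched null distributions).
#' @param method \code{"auto"}, \code{"forward"} or \code{"backward"}.
#' @param t_max origin-time window for the forward baseline; defaults to
#'   \code{8 * reference_N} generations.
#' @param max_attempts rejection guard.
#' @param max_len cap on backward path length.
#' @return a \code{trajectory}.
#' @export
simulate_current_freq <- function(model, bin, s = 0, h = 0.5,
                                  method = c("auto", "forward", "backward"),
                                  t_max = NULL, max_attempts = 1e6,
                                  max_len = 4e6) {
  method <- match.arg(method)
  sc <- selection_scenario("CURRENT_FREQ", s = s, h = h, bin = bin)
  ep <- .epochs(model)
  constant <- length(model$size) == 1
  if (method == "auto")
    method <- if (constant && bin[2] < 1) "backward" else "forward"
  if (method == "backward") {
    if (!constant) stop("the backward accelerator requires a constant-size model")
    if (bin[2] >= 1) stop("the backward accelerator requires bin[2] < 1")
    res <- cpp_current_freq_backward(model$size[1], s, h, bin[1], bin[2],
                                     max_attempts, max_len)
  } else {
    if (is.null(t_max)) t_max <- 8 * model$reference_N
    res <- cpp_current_freq_forward(ep$t, ep$N, s, h, bin[1], bin[2],
                                    as.integer(t_max), max_attempts)
  }
  .traj_new(res$freqs, sc, model, res$attempts)
}

#' Trajectory for selection on standing variation
#'
#' Selection with coefficient \code{s} begins \code{t_sel} generations before
#' present, when the (neutral) derived allele is at frequency \code{p1}. The
#' ancestral segment (older than \code{t_sel}) is generated by neutral
#' backward binomial resampling until absorption at zero, rejecting paths
#' that fix backward; the recent segment is a forward selected path from
#' \code{p1}, rejected on the survival condition. The two are spliced at
#' \code{t_sel}.
#'
#' @param model a \code{demographic_model}.
#' @param s,h selection and dominance coefficients.
#' @param p1 frequency at the onset of selection, in (0, 1).
#' @param t_sel onset time in generations before present.
#' @param condition survival condition for the forward segment.
#' @param max_attempts rejection guard.
#' @param max_len cap on the backward segment length.
#' @return a \code{trajectory}.
#' @export
simulate_ssv <- function(model, s, p1, t_sel, h = 0.5,
                         condition = c("non_lost", "segregating"),
                         max_attempts = 1e6, max_len = 4e6) {
  condition <- match.arg(condition)
  ep <- .epochs(model)
  res <- cpp_ssv_trajectory(ep$t, ep$N, s, h, p1, as.integer(t_sel),
                            condition == "segregating", max_attempts, max_len)
  sc <- selection_scenario("SSV", s = s, h = h, p1 = p1, t_sel = t_sel,
                           condition = condition)
  .traj_new(res$freqs, sc, model, res$attempts_forward)
}

#' De novo survival probability by direct simulation
#'
#' Fraction of \code{n_attempts} de novo trajectories (arising \code{t_age}
#' generations ago) that satisfy the survival condition at present; for
#' \code{t_age} much larger than 4N this approximates the fixation
#' probability of a new mutant.
#'
#' @inheritParams simulate_sdn
#' @param n_attempts number of simulated trajectories.
#' @export
sdn_acceptance_probability <- function(model, s, t_age, h = 0.5,
                                       condition = c("non_lost", "segregating"),
                                       n_attempts = 1e4) {
  condition <- match.arg(condition)
  ep <- .epochs(model)
  acc <- cpp_sdn_acceptance(ep$t, ep$N, s, h, as.integer(t_age),
                            condition == "segregating", n_attempts)
  acc / n_attempts
}

#' Write a trajectory to a plain-text file
#'
#' Header lines start with \code{#} and carry the scenario metadata; data
#' lines have two columns, generation before present and frequency, written
#' at full precision so that \code{\link{read_trajectory}} is lossless.
#'
#' @param traj a \code{trajectory}.
#' @param path output file.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  sc <- traj$scenario
  hdr <- c(
    sprintf("#mode=%s s=%.17g h=%.17g condition=%s", sc$mode, sc$s, sc$h, sc$condition),
    sprintf("#origin_gen=%d final_freq=%.17g", traj$origin_gen, traj$final_freq),
    sprintf("#model=%s", traj$model_label))
  gens <- seq.int(0L, traj$origin_gen)
  lines <- c(hdr, sprintf("%d\t%.17g", gens, traj$freqs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory written by \code{\link{write_trajectory}}
#'
#' @param path input file.
#' @return a \code{trajectory} (scenario metadata restored from the header).
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  dat <- lines[!startsWith(lines, "#")]
  parts <- strsplit(dat, "\t", fixed = TRUE)
  gens <- as.integer(vapply(parts, `[`, "", 1))
  freqs <- as.numeric(vapply(parts, `[`, "", 2))
  o <- order(gens)
  gens <- gens[o]; freqs <- freqs[o]
  if (!identical(gens, seq.int(0L, length(gens) - 1L)))
    stop("trajectory file must contain one line per generation from 0")
  get_field <- function(name, ln) {
    m <- regmatches(ln, regexpr(paste0(name, "=[^ ]+"), ln))
    if (length(m) == 0) return(NA_character_)
    sub(paste0(name, "="), "", m[1])
  }
  h1 <- if (length(hdr) >= 1) hdr[1] else ""
  sc <- list(mode = get_field("mode", h1),
             s = as.numeric(get_field("s", h1)),
             h = as.numeric(get_field("h", h1)),
             condition = get_field("condition", h1))
  class(sc) <- "selection_scenario"
  model_label <- if (length(hdr) >= 3) sub("^#model=", "", hdr[3]) else ""
  .traj_new(freqs, sc, list(label = model_label))
}
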
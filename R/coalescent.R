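# Haplotype-sample generation: a structured coalescent with recombination
# conditioned on a derived-allele frequency trajectory (the selected site
# partitions lineages into derived and ancestral allelic classes whose sizes
# follow the trajectory), plus the unconditioned neutral coalescent used for
# null distributions. Infinite-sites mutations are dropped on the genealogy
# afterwards.

#' Region configuration
#'
#' @param L region length in bp.
#' @param mu mutation rate per site per generation.
#' @param r recombination rate per site per generation.
#' @param n sample size in chromosomes (2..128).
#' @param focal_pos bp coordinate of the selected site in [0, L].
#' @return an object of class \code{region_config}.
#' @export
region_config <- function(L, mu = 1e-8, r = 1e-8, n = 120, focal_pos = 0) {
  L <- as.numeric(L); mu <- as.numeric(mu); r <- as.numeric(r)
  focal_pos <- as.numeric(focal_pos)
  if (anyNA(c(L, mu, r, focal_pos))) stop("non-numeric region parameter")
  if (L <= 0) stop("L must be positive")
  if (mu < 0 || r < 0) stop("mu and r must be non-negative")
  if (n < 2) stop("n must be >= 2")
  if (focal_pos < 0 || focal_pos > L) stop("focal_pos must lie in [0, L]")
  structure(list(L = as.numeric(L), mu = mu, r = r, n = as.integer(n),
                 focal_pos = as.numeric(focal_pos)),
            class = "region_config")
}

#' 10-kb region with a central target, for the SFS-based tests
#' @param n sample size in chromosomes.
#' @export
sfs_region <- function(n = 120) region_config(1e4, 1e-8, 1e-8, n, focal_pos = 5e3)

#' 500-kb region with the target at the edge, for the haplotype-based tests
#' @param n sample size in chromosomes.
#' @export
hap_region <- function(n = 120) region_config(5e5, 1e-8, 1e-8, n, focal_pos = 0)

#' Sample focal-allele counts from the population frequency
#'
#' @param n chromosomes sampled.
#' @param final_freq population frequency of the derived allele at sampling.
#' @return named integer vector \code{c(n_derived, n_ancestral)}.
#' @export
sample_allele_counts <- function(n, final_freq) {
  if (final_freq < 0 || final_freq > 1) stop("final_freq must lie in [0, 1]")
  nd <- rbinom(1L, n, final_freq)
  c(n_derived = nd, n_ancestral = n - nd)
}

#' Trajectory-conditioned structured genealogy
#'
#' Runs the backward-in-time structured coalescent with recombination. While
#' the focal allele is polymorphic in the look-back population, lineages are
#' partitioned into derived and ancestral classes whose sizes track the
#' trajectory; coalescence happens within classes, and recombination moves
#' the fragment not containing the focal site to a background drawn by the
#' current frequency. At the trajectory origin all derived lineages merge
#' (the focal mutation event) and a single-class neutral coalescent continues
#' until every bp position has reached its MRCA. With \code{traj = NULL} the
#' engine is the ordinary neutral coalescent with recombination.
#'
#' @param traj a \code{trajectory}, or \code{NULL} for the neutral engine.
#' @param model a \code{demographic_model}.
#' @param counts output of \code{\link{sample_allele_counts}} (ignored when
#'   \code{traj} is \code{NULL}: all \code{region$n} lineages are unlabelled).
#' @param region a \code{region_config}.
#' @param max_generations safety cap on simulated generations.
#' @return an object of class \code{genealogy} holding edge records: each
#'   record spans a time interval and carries the bp intervals (with their
#'   descendant-leaf sets) the lineage transmitted.
#' @export
simulate_structured_genealogy <- function(traj, model, counts, region,
                                          max_generations = NULL) {
  stopifnot(inherits(model, "demographic_model"), inherits(region, "region_config"))
  has_focal <- !is.null(traj)
  if (has_focal) {
    stopifnot(inherits(traj, "trajectory"))
    nd <- as.integer(counts[["n_derived"]])
    na <- as.integer(counts[["n_ancestral"]])
    if (nd + na != region$n) stop("counts must sum to the sample size")
    if (nd > 0 && traj$final_freq <= 0)
      stop("derived chromosomes sampled but the trajectory is lost at present")
    if (na > 0 && traj$final_freq >= 1)
      stop("ancestral chromosomes sampled but the trajectory is fixed at present")
    fr <- traj$freqs
  } else {
    nd <- 0L
    na <- region$n
    fr <- numeric(0)
  }
  if (is.null(max_generations))
    max_generations <- 400 * max(model$size) + length(fr) + 1e5
  eng <- cpp_structured_genealogy(model$t_start, model$size, fr, nd, na,
                                  region$L, region$r, region$focal_pos,
                                  max_generations)
  structure(
    list(engine = eng, n = region$n, L = region$L, region = region,
         model_label = model$label,
         focal = list(present = has_focal,
                      pos = region$focal_pos,
                      n_der = nd,
                      freq = if (has_focal) traj$final_freq else NA_real_),
         end_time = eng$end_time),
    class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Structured genealogy: n=%d, L=%g bp, %d edge records, depth %.1f generations\n",
              x$n, x$L, length(x$engine$rec_t0), x$end_time))
  invisible(x)
}

# decode a 128-bit leaf mask (four int32 words) into 1-based leaf indices
.mask_leaves <- function(w1, w2, w3, w4, n) {
  bits <- c(as.integer(intToBits(w1)), as.integer(intToBits(w2)),
            as.integer(intToBits(w3)), as.integer(intToBits(w4)))
  which(bits[seq_len(n)] == 1L)
}

#' Total genealogy branch length at a bp position
#'
#' Sum of edge-record durations covering \code{x}; under neutrality and
#' \code{r = 0} its expectation is \eqn{4N \sum_{i<n} 1/i}.
#'
#' @param gen a \code{genealogy}.
#' @param x bp position.
#' @export
total_tree_length <- function(gen, x) {
  e <- gen$engine
  cover <- e$seg_l <= x & x < e$seg_r
  sum((e$rec_t1 - e$rec_t0)[e$seg_rec[cover]])
}

#' Time to the most recent common ancestor at a bp position
#' @param gen a \code{genealogy}.
#' @param x bp position.
#' @export
tmrca_at <- function(gen, x) {
  e <- gen$engine
  cover <- e$seg_l <= x & x < e$seg_r
  if (!any(cover)) return(0)
  max(e$rec_t1[e$seg_rec[cover]])
}

#' Drop infinite-sites mutations on a genealogy
#'
#' Each edge record receives Poisson(mu x duration x carried bp) mutations at
#' uniform positions within its intervals; the derived state is assigned to
#' the record's descendant leaves. Monomorphic columns cannot arise because
#' fully-resolved material is pruned during simulation. When the focal allele
#' is polymorphic in the sample, the focal site itself is included as a
#' column (the derived class carries allele 1).
#'
#' @param gen a \code{genealogy}.
#' @param mu mutation rate per site per generation (defaults to the region's).
#' @return an object of class \code{haplotype_sample}: a 0/1 matrix (rows =
#'   chromosomes, columns = segregating sites), relative positions, and the
#'   focal-site annotation.
#' @export
drop_mutations <- function(gen, mu = NULL) {
  stopifnot(inherits(gen, "genealogy"))
  if (is.null(mu)) mu <- gen$region$mu
  e <- gen$engine
  n <- gen$n
  L <- gen$L
  pos <- numeric(0)
  leaf_sets <- list()
  if (length(e$seg_rec) > 0 && mu > 0) {
    dur <- (e$rec_t1 - e$rec_t0)[e$seg_rec]
    len <- e$seg_r - e$seg_l
    nm <- rpois(length(len), mu * dur * len)
    tot <- sum(nm)
    if (tot > 0) {
      idx <- rep.int(seq_along(nm), nm)
      pos <- runif(tot, e$seg_l[idx], e$seg_r[idx])
      useg <- unique(idx)
      cache <- lapply(useg, function(j)
        .mask_leaves(e$seg_w1[j], e$seg_w2[j], e$seg_w3[j], e$seg_w4[j], n))
      names(cache) <- as.character(useg)
      leaf_sets <- cache[as.character(idx)]
    }
  }
  focal <- gen$focal
  focal_col_leaves <- NULL
  if (isTRUE(focal$present) && focal$n_der > 0 && focal$n_der < n) {
    pos <- c(pos, focal$pos)
    focal_col_leaves <- seq_len(focal$n_der)
    leaf_sets <- c(leaf_sets, list(focal_col_leaves))
    is_focal <- c(rep(FALSE, length(pos) - 1), TRUE)
  } else {
    is_focal <- rep(FALSE, length(pos))
  }
  o <- order(pos)
  pos <- pos[o]
  leaf_sets <- leaf_sets[o]
  is_focal <- is_focal[o]
  S <- length(pos)
  mat <- matrix(0L, nrow = n, ncol = S)
  for (j in seq_len(S)) mat[leaf_sets[[j]], j] <- 1L
  haplotype_sample(mat, rel_pos = pos / L, L = L,
                   focal = list(present = isTRUE(focal$present),
                                pos = focal$pos,
                                freq = focal$freq,
                                n_der = focal$n_der,
                                col = if (any(is_focal)) which(is_focal) else NA_integer_))
}

#' Haplotype sample container
#'
#' @param mat n x S matrix of 0 (ancestral) / 1 (derived).
#' @param rel_pos site positions as fractions of the region length, strictly
#'   increasing (canonical representation, also used by the ms-format I/O).
#' @param L region length in bp.
#' @param focal focal-site annotation: \code{present}, \code{pos} (bp),
#'   \code{freq} (population frequency at sampling), \code{n_der} (derived
#'   chromosomes in the sample), \code{col} (column index or NA).
#' @export
haplotype_sample <- function(mat, rel_pos, L,
                             focal = list(present = FALSE, pos = NA_real_,
                                          freq = NA_real_, n_der = NA_integer_,
                                          col = NA_integer_)) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (ncol(mat) != length(rel_pos)) stop("one position per column required")
  if (length(rel_pos) > 1 && any(diff(rel_pos) < 0)) stop("positions must be sorted")
  structure(list(mat = mat, rel_pos = as.numeric(rel_pos),
                 positions = as.numeric(rel_pos) * L, L = as.numeric(L),
                 n = nrow(mat), S = ncol(mat), focal = focal),
            class = "haplotype_sample")
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf("Haplotype sample: n=%d chromosomes, S=%d segregating sites, L=%g bp\n",
              x$n, x$S, x$L))
  if (isTRUE(x$focal$present))
    cat(sprintf("  focal site at %g bp, population frequency %.4g, %d derived in sample\n",
                x$focal$pos, x$focal$freq, x$focal$n_der))
  invisible(x)
}

#' Simulate a haplotype sample under a sweep trajectory
#'
#' Convenience wrapper: binomial sampling of focal-allele counts, the
#' structured genealogy, then mutation dropping.
#'
#' @param model a \code{demographic_model}.
#' @param traj a \code{trajectory}.
#' @param region a \code{region_config}.
#' @return a \code{haplotype_sample}.
#' @export
simulate_sweep_sample <- function(model, traj, region) {
  counts <- sample_allele_counts(region$n, traj$final_freq)
  gen <- simulate_structured_genealogy(traj, model, counts, region)
  drop_mutations(gen)
}

#' Simulate a neutral haplotype sample
#'
#' Without conditioning this is the ordinary neutral coalescent with
#' recombination (used for the null distributions of the SFS-based tests).
#' With \code{condition_focal} set to a frequency bin, a neutral trajectory
#' conditioned on its present-day frequency drives the structured engine, so
#' the sample carries a neutral focal variant at a matched frequency (the
#' null construction for the haplotype-based tests).
#'
#' @param model a \code{demographic_model}.
#' @param region a \code{region_config}.
#' @param condition_focal optional length-2 frequency bin in (0, 1).
#' @param method trajectory method passed to \code{\link{simulate_current_freq}}.
#' @return a \code{haplotype_sample}.
#' @export
simulate_neutral_sample <- function(model, region, condition_focal = NULL,
                                    method = "auto") {
  if (is.null(condition_focal)) {
    gen <- simulate_structured_genealogy(NULL, model, NULL, region)
    return(drop_mutations(gen))
  }
  traj <- simulate_current_freq(model, condition_focal, s = 0, method = method)
  simulate_sweep_sample(model, traj, region)
}
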
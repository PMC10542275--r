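# The four neutrality statistics. SFS-based: Tajima's D and (unnormalized)
# Fay & Wu's H, both from the unfolded spectrum (ancestral states are known
# by construction). Haplotype-based: EHH/rEHH at a fixed distance from the
# focal site, and the unstandardized iHS with one-sided integration (the
# focal site sits at the region edge in the simulated design). Statistics
# that cannot be computed return an UNDEFINED result carrying the reason;
# significance always comes from simulated empirical nulls, so no analytic
# normalization is applied anywhere.

#' Statistic result
#'
#' @param name one of \code{"D"}, \code{"H"}, \code{"rEHH"}, \code{"iHS"}.
#' @param value numeric value, or \code{NA} when undefined.
#' @param reason cause when undefined: one of
#'   \code{"no-segregating-sites"}, \code{"no-ancestral-haplotype"},
#'   \code{"core-class-too-small"}, \code{"zero-integral"}.
#' @export
stat_result <- function(name, value, reason = NA_character_) {
  structure(list(name = name, value = value, reason = reason),
            class = "stat_result")
}

#' Is a statistic result undefined?
#' @param x a \code{stat_result}.
#' @export
is_undefined <- function(x) is.na(x$value)

#' @export
print.stat_result <- function(x, ...) {
  if (is_undefined(x)) cat(sprintf("%s: UNDEFINED (%s)\n", x$name, x$reason))
  else cat(sprintf("%s = %.6g\n", x$name, x$value))
  invisible(x)
}

.sample_counts <- function(sample, include_focal = TRUE) {
  m <- sample$mat
  if (!include_focal && isTRUE(sample$focal$present) && !is.na(sample$focal$col))
    m <- m[, -sample$focal$col, drop = FALSE]
  colSums(m)
}

#' Unfolded site-frequency spectrum
#'
#' @param sample a \code{haplotype_sample} (ancestral states known; 1 =
#'   derived).
#' @param include_focal whether the focal column (a genuine segregating site
#'   when polymorphic) enters the spectrum. Default TRUE.
#' @return an object of class \code{sfs}: counts \eqn{\xi_i} for
#'   \eqn{i = 1..n-1}.
#' @export
unfolded_sfs <- function(sample, include_focal = TRUE) {
  n <- sample$n
  cnt <- .sample_counts(sample, include_focal)
  cnt <- cnt[cnt > 0 & cnt < n]  # defensive; columns are polymorphic by construction
  xi <- tabulate(cnt, nbins = n - 1)
  structure(list(xi = xi, n = n, S = sum(xi)), class = "sfs")
}

#' Tajima's D
#'
#' \eqn{D = (\pi - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}} with the usual
#' constants; \eqn{\pi} is the mean pairwise difference. Undefined when
#' there are no segregating sites.
#'
#' @param sample a \code{haplotype_sample} (n >= 4).
#' @param include_focal include the focal column (default TRUE).
#' @return a \code{stat_result}.
#' @export
tajimas_d <- function(sample, include_focal = TRUE) {
  n <- sample$n
  if (n < 4) stop("Tajima's D requires n >= 4")
  sfs <- unfolded_sfs(sample, include_focal)
  S <- sfs$S
  if (S == 0) return(stat_result("D", NA_real_, "no-segregating-sites"))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  pi_ <- sum(sfs$xi * i * (n - i)) * 2 / (n * (n - 1))
  d <- (pi_ - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  stat_result("D", d)
}

#' Fay & Wu's H (unnormalized)
#'
#' \eqn{H = \theta_\pi - \theta_H} with
#' \eqn{\theta_\pi = \sum_i \xi_i \, 2i(n-i)/(n(n-1))} and
#' \eqn{\theta_H = \sum_i \xi_i \, 2i^2/(n(n-1))}; requires the unfolded
#' spectrum. Negative values indicate an excess of high-frequency derived
#' alleles. By convention H = 0 when S = 0 (both estimators vanish).
#'
#' @inheritParams tajimas_d
#' @return a \code{stat_result}.
#' @export
fay_wu_h <- function(sample, include_focal = TRUE) {
  n <- sample$n
  sfs <- unfolded_sfs(sample, include_focal)
  i <- seq_len(n - 1)
  theta_pi <- sum(sfs$xi * 2 * i * (n - i)) / (n * (n - 1))
  theta_h <- sum(sfs$xi * 2 * i^2) / (n * (n - 1))
  stat_result("H", theta_pi - theta_h)
}

#' Extended haplotype homozygosity
#'
#' Among the carriers of \code{core_allele} at column \code{core_col}, group
#' haplotypes by identity over every polymorphic column between the core and
#' \code{target_pos} (boundary columns included); EHH is the probability
#' that two random carriers fall in the same group:
#' \eqn{\sum_h \binom{m_h}{2} / \binom{n_c}{2}}.
#'
#' @param sample a \code{haplotype_sample}.
#' @param core_col column index of the core site.
#' @param core_allele 0 or 1.
#' @param target_pos bp coordinate the homozygosity is evaluated at.
#' @return EHH in [0, 1], or \code{NA} (fewer than 2 carriers).
#' @export
ehh <- function(sample, core_col, core_allele, target_pos) {
  carriers <- which(sample$mat[, core_col] == core_allele)
  nc <- length(carriers)
  if (nc < 2) return(NA_real_)
  core_pos <- sample$positions[core_col]
  lo <- min(core_pos, target_pos)
  hi <- max(core_pos, target_pos)
  cols <- which(sample$positions >= lo & sample$positions <= hi)
  if (length(cols) == 0) return(1)
  key <- apply(sample$mat[carriers, cols, drop = FALSE], 1, paste, collapse = "")
  m <- table(key)
  sum(choose(m, 2)) / choose(nc, 2)
}

# incremental EHH decay away from the core for one allelic class:
# returns (distance from core in bp, EHH) at the core (distance 0, EHH 1)
# and at each successive polymorphic column moving outward, truncated at the
# first marker where EHH < trunc (that marker included).
.ehh_decay <- function(sample, core_col, core_allele, trunc = 0) {
  carriers <- which(sample$mat[, core_col] == core_allele)
  nc <- length(carriers)
  if (nc < 2) return(NULL)
  core_pos <- sample$positions[core_col]
  dist <- abs(sample$positions - core_pos)
  ord <- order(dist)
  ord <- ord[ord != core_col]
  denom <- choose(nc, 2)
  g <- rep(1L, nc)
  xs <- 0
  es <- 1
  for (j in ord) {
    key <- g * 2L + sample$mat[carriers, j]
    g <- match(key, unique(key))
    e <- sum(choose(tabulate(g), 2)) / denom
    xs <- c(xs, dist[j])
    es <- c(es, e)
    if (e < trunc) break
  }
  list(dist = xs, ehh = es)
}

#' Relative extended haplotype homozygosity at a fixed distance
#'
#' \eqn{rEHH = EHH_{derived} / EHH_{ancestral}} evaluated \code{distance} bp
#' from the focal site (toward the interior of the region). Undefined when
#' either allelic class has fewer than 2 carriers or the ancestral EHH is 0 -
#' in particular when the derived allele is fixed in the sample, the
#' mechanism that robs the haplotype tests of power after fixation.
#'
#' @param sample a \code{haplotype_sample} with a focal column.
#' @param distance evaluation distance in bp (0.025 cM = 25,000 bp at the
#'   rates simulated here).
#' @return a \code{stat_result}.
#' @export
rehh_stat <- function(sample, distance = 25000) {
  f <- sample$focal
  if (!isTRUE(f$present) || is.na(f$col))
    return(stat_result("rEHH", NA_real_,
                       if (isTRUE(f$present) && isTRUE(f$n_der == sample$n))
                         "no-ancestral-haplotype" else "core-class-too-small"))
  core <- f$col
  nd <- sum(sample$mat[, core])
  na_ <- sample$n - nd
  if (na_ < 2)
    return(stat_result("rEHH", NA_real_, "no-ancestral-haplotype"))
  if (nd < 2)
    return(stat_result("rEHH", NA_real_, "core-class-too-small"))
  core_pos <- sample$positions[core]
  target <- if (core_pos <= sample$L / 2) core_pos + distance else core_pos - distance
  e_d <- ehh(sample, core, 1L, target)
  e_a <- ehh(sample, core, 0L, target)
  if (is.na(e_a) || e_a == 0)
    return(stat_result("rEHH", NA_real_, "zero-integral"))
  stat_result("rEHH", e_d / e_a)
}

#' Unstandardized integrated haplotype score
#'
#' For each allelic class at the focal site, \eqn{iHH} is the trapezoidal
#' integral of the EHH decay curve over bp distance from the core, moving
#' outward across the region and truncated at the first marker where EHH
#' drops below \code{truncation} (that marker's contribution included). The
#' statistic is \eqn{\ln(iHH_A / iHH_D)}: large negative values mean
#' unusually long derived haplotypes. Comparison against a
#' frequency-matched empirical null replaces the usual genome-wide
#' standardization.
#'
#' @param sample a \code{haplotype_sample} with a focal column.
#' @param truncation EHH truncation threshold (default 0.05).
#' @return a \code{stat_result}.
#' @export
ihs_unstandardized <- function(sample, truncation = 0.05) {
  f <- sample$focal
  if (!isTRUE(f$present) || is.na(f$col))
    return(stat_result("iHS", NA_real_,
                       if (isTRUE(f$present) && isTRUE(f$n_der == sample$n))
                         "no-ancestral-haplotype" else "core-class-too-small"))
  core <- f$col
  nd <- sum(sample$mat[, core])
  na_ <- sample$n - nd
  if (na_ < 2)
    return(stat_result("iHS", NA_real_, "no-ancestral-haplotype"))
  if (nd < 2)
    return(stat_result("iHS", NA_real_, "core-class-too-small"))
  ihh <- function(allele) {
    d <- .ehh_decay(sample, core, allele, trunc = truncation)
    if (is.null(d) || length(d$dist) < 2) return(0)
    sum(diff(d$dist) * (d$ehh[-1] + d$ehh[-length(d$ehh)]) / 2)
  }
  ihh_d <- ihh(1L)
  ihh_a <- ihh(0L)
  if (ihh_d <= 0 || ihh_a <= 0)
    return(stat_result("iHS", NA_real_, "zero-integral"))
  stat_result("iHS", log(ihh_a / ihh_d))
}

#' Compute a named statistic on a sample
#'
#' Dispatch helper used by the power pipeline and the command-line tool.
#'
#' @param sample a \code{haplotype_sample}.
#' @param stat one of \code{"D"}, \code{"H"}, \code{"rEHH"}, \code{"iHS"}.
#' @param ehh_distance rEHH evaluation distance in bp.
#' @param truncation iHS truncation threshold.
#' @param include_focal include the focal column in the SFS statistics.
#' @return a \code{stat_result}.
#' @export
compute_stat <- function(sample, stat, ehh_distance = 25000,
                         truncation = 0.05, include_focal = TRUE) {
  switch(stat,
         D = tajimas_d(sample, include_focal),
         H = fay_wu_h(sample, include_focal),
         rEHH = rehh_stat(sample, ehh_distance),
         iHS = ihs_unstandardized(sample, truncation),
         stop("unknown statistic: ", stat))
}

#' Rejection tail for each statistic under positive selection
#'
#' Sweeps push Tajima's D and Fay & Wu's H down (excess rare and
#' high-frequency-derived variants), rEHH up (long derived haplotypes
#' relative to ancestral), and ln(iHH_A/iHH_D) down.
#'
#' @param stat statistic name.
#' @return \code{"lower"} or \code{"upper"}.
#' @export
stat_tail <- function(stat) {
  switch(stat, D = "lower", H = "lower", rEHH = "upper", iHS = "lower",
         stop("unknown statistic: ", stat))
}

#' Write statistic results as TSV
#'
#' @param results data.frame with columns replicate, stat, value, reason.
#' @param path output file.
#' @export
write_stat_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
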
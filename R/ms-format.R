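# ms-format text I/O for haplotype samples.
#
# Layout per replicate block:
#   //
#   #region L=<bp>                      (comment, ours)
#   #focal pos=<fraction> freq=<float> col=<index|NA>   (comment, ours)
#   segsites: S
#   positions: p1 p2 ... pS             (fractions of L)
#   <n lines of 0/1 characters>
#
# Positions are written with 17 significant digits from the sample's
# canonical relative positions, so write -> read -> write round-trips
# byte-identically. Files from other ms-compatible simulators (no comment
# lines) are read too; the region length then comes from the L argument.

#' Write haplotype samples in ms format
#'
#' @param samples a \code{haplotype_sample} or list of them.
#' @param path output file.
#' @param header optional first line (defaults to an ms-style command echo).
#' @export
write_ms <- function(samples, path, header = NULL) {
  if (inherits(samples, "haplotype_sample")) samples <- list(samples)
  n <- samples[[1]]$n
  if (is.null(header))
    header <- sprintf("ms %d %d", n, length(samples))
  lines <- c(header, "")
  for (s in samples) {
    stopifnot(inherits(s, "haplotype_sample"))
    blk <- c("//", sprintf("#region L=%.17g", s$L))
    if (isTRUE(s$focal$present)) {
      blk <- c(blk, sprintf("#focal pos=%.17g freq=%.17g col=%s",
                            s$focal$pos / s$L, s$focal$freq,
                            if (is.na(s$focal$col)) "NA" else as.character(s$focal$col)))
    }
    blk <- c(blk, sprintf("segsites: %d", s$S))
    if (s$S > 0) {
      blk <- c(blk,
               paste("positions:", paste(sprintf("%.17g", s$rel_pos), collapse = " ")),
               apply(s$mat, 1, paste, collapse = ""))
    }
    lines <- c(lines, blk, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read ms-format haplotype samples
#'
#' @param path input file.
#' @param L region length in bp; only used for blocks without a
#'   \code{#region} comment line.
#' @return a list of \code{haplotype_sample} objects.
#' @export
read_ms <- function(path, L = 1) {
  lines <- readLines(path)
  starts <- which(lines == "//")
  if (length(starts) == 0) stop("no '//' replicate blocks found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    blk <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    blk <- blk[nzchar(blk)]
    Lb <- L
    focal <- list(present = FALSE, pos = NA_real_, freq = NA_real_,
                  n_der = NA_integer_, col = NA_integer_)
    reg <- grep("^#region ", blk, value = TRUE)
    if (length(reg) > 0)
      Lb <- as.numeric(sub("^#region L=", "", reg[1]))
    foc <- grep("^#focal ", blk, value = TRUE)
    rel_focal <- NA_real_
    if (length(foc) > 0) {
      gv <- function(nm) {
        m <- regmatches(foc[1], regexpr(paste0(nm, "=[^ ]+"), foc[1]))
        sub(paste0(nm, "="), "", m)
      }
      rel_focal <- as.numeric(gv("pos"))
      focal <- list(present = TRUE, pos = rel_focal * Lb,
                    freq = as.numeric(gv("freq")),
                    n_der = NA_integer_,
                    col = suppressWarnings(as.integer(gv("col"))))
    }
    ssl <- grep("^segsites:", blk, value = TRUE)
    if (length(ssl) == 0) stop("block ", b, " has no segsites line")
    S <- as.integer(sub("^segsites: *", "", ssl[1]))
    if (S == 0) {
      out[[b]] <- haplotype_sample(matrix(0L, 0, 0), numeric(0), Lb, focal)
      # sample size unknown for an empty block; leave 0 rows
      next
    }
    pl <- grep("^positions:", blk, value = TRUE)
    rel <- as.numeric(strsplit(sub("^positions: *", "", pl[1]), " +")[[1]])
    rows <- blk[!startsWith(blk, "#") & !grepl("^(segsites|positions):", blk)]
    mat <- do.call(rbind, lapply(strsplit(rows, ""), function(ch) as.integer(ch)))
    smp <- haplotype_sample(mat, rel, Lb, focal)
    if (isTRUE(focal$present)) {
      smp$focal$n_der <- if (!is.na(smp$focal$col)) sum(mat[, smp$focal$col])
                         else NA_integer_
    }
    out[[b]] <- smp
  }
  out
}
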
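#' Folded site frequency spectrum from called genotypes
#'
#' Sites with any missing genotype in the focal group are skipped (and
#' counted); at each scored site the minor allele count is
#' `min(a, n - a)` with `n = 2 * group size` alleles. Bins run from 0 to
#' `floor(n / 2)`; monomorphic sites fall in bin 0. Folding makes the
#' spectrum invariant to ref/alt relabeling.
#'
#' @param m a [cohort_matrix()].
#' @param group group label.
#' @return list of class `folded_sfs`: `group`, `n_alleles`, `bins` (named
#'   integer vector `0..n/2`), `n_sites_scored`, `n_sites_skipped`.
#' @export
folded_sfs <- function(m, group) {
  dos <- group_dosages(m, group)
  n <- 2L * nrow(dos)
  full <- colSums(is.na(dos)) == 0L
  a <- colSums(dos[, full, drop = FALSE])
  minor <- pmin(a, n - a)
  half <- n %/% 2L
  bins <- tabulate(minor + 1L, nbins = half + 1L)
  names(bins) <- 0:half
  structure(list(group = group, n_alleles = n, bins = bins,
                 n_sites_scored = sum(full),
                 n_sites_skipped = sum(!full)),
            class = "folded_sfs")
}

#' Tajima (1989) constants for a sample of n haplotypes
#'
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i in 1..n-1`, and the derived
#' b1, b2, c1, c2, e1, e2 used by the D variance estimate.
#'
#' @param n haplotype sample size (>= 2).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Sliding-window Tajima's D
#'
#' Windows of `window_bp` advancing by `step_bp`, anchored at position 1; a
#' site contributes to every window covering it. Sites with any missing
#' genotype in the group are excluded throughout. Per window: `S` the count
#' of segregating sites, `theta_pi` the mean pairwise difference total
#' (`sum a(n-a)/choose(n,2)`), `theta_w = S/a1`, and
#' `D = (theta_pi - theta_w) / sqrt(e1 S + e2 S (S - 1))`, undefined (`NA`)
#' when `S = 0`. Computed from allele counts, which equals the
#' haplotype-pair computation regardless of phase.
#'
#' @param m a [cohort_matrix()].
#' @param group group label (>= 2 diploids; a warning is issued for n < 4
#'   haplotypes where the variance formula is unstable).
#' @param window_bp,step_bp window geometry in bp.
#' @return data.frame: chrom, start, end, n_sites, S, theta_pi, theta_w,
#'   tajima_d.
#' @export
tajima_windows <- function(m, group, window_bp = 50000, step_bp = 10000) {
  dos <- group_dosages(m, group)
  if (nrow(dos) < 2L) stop("need >= 2 diploids")
  n <- 2L * nrow(dos)
  if (n < 4L) warning("n < 4 haplotypes: D variance formula unstable")
  k <- tajima_constants(n)
  full <- colSums(is.na(dos)) == 0L
  a <- colSums(dos)  # valid where full
  res <- list()
  for (ch in unique(m$sites$chrom)) {
    si <- which(m$sites$chrom == ch & full)
    if (!length(si)) next
    pos <- m$sites$pos[si]
    last <- max(m$sites$pos[m$sites$chrom == ch])
    starts <- seq(1, last, by = step_bp)
    rows <- lapply(starts, function(s) {
      inw <- si[pos >= s & pos < s + window_bp]
      aw <- a[inw]
      nseg <- sum(aw > 0L & aw < n)
      tp <- sum(aw * (n - aw)) / (n * (n - 1) / 2)
      tw <- nseg / k$a1
      dv <- k$e1 * nseg + k$e2 * nseg * (nseg - 1)
      data.frame(chrom = ch, start = s, end = s + window_bp - 1,
                 n_sites = length(inw), S = nseg,
                 theta_pi = tp, theta_w = tw,
                 tajima_d = if (nseg > 0 && dv > 0) (tp - tw) / sqrt(dv)
                 else NA_real_,
                 stringsAsFactors = FALSE)
    })
    res[[ch]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
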
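#' Windowed nucleotide diversity (pi) with invariant-site denominators
#'
#' Per site, the number of mismatching unordered pairs of called haplotypes
#' within the group is `a * (n - a)` and the number of pairs is
#' `choose(n, 2)`, where `n` is the count of called alleles and `a` the count
#' of alternate alleles; this allele-count algebra is exact for unphased
#' diploids. Window pi is the ratio of summed mismatches to summed pairs over
#' all sites in the window (invariant sites contribute pairs, lowering pi --
#' the reason the matrix must retain them). Sites with fewer than 2 called
#' haplotypes contribute nothing; a window whose pair total is 0 gets `NA`,
#' never 0.
#'
#' Windows are half-open, tiled from position 1 on each chromosome up to the
#' last site present; the final partial window is kept and flagged.
#'
#' @param m a [cohort_matrix()] containing variant and invariant sites.
#' @param group group label (requires `m$groups`).
#' @param window_bp window size in bp.
#' @return data.frame: chrom, start, end, n_sites, n_diffs, n_comps, pi,
#'   partial.
#' @export
pi_windows <- function(m, group, window_bp = 10000) {
  dos <- group_dosages(m, group)
  t <- site_tallies(dos)
  diffs <- t$a * (t$n - t$a)
  comps <- t$n * (t$n - 1) / 2
  window_tally(m$sites, diffs, comps, window_bp, value_name = "pi")
}

#' Windowed between-group divergence (dxy)
#'
#' Same accounting as [pi_windows()] but over between-group haplotype pairs:
#' per site `a1*(n2-a2) + a2*(n1-a1)` mismatches out of `n1*n2` pairs.
#' Symmetric in group order.
#'
#' @inheritParams pi_windows
#' @param group1,group2 disjoint group labels.
#' @return data.frame: chrom, start, end, n_sites, n_diffs, n_comps, dxy,
#'   partial.
#' @export
dxy_windows <- function(m, group1, group2, window_bp = 10000) {
  s1 <- group_samples(m, group1); s2 <- group_samples(m, group2)
  if (length(intersect(s1, s2))) stop("groups overlap")
  t1 <- site_tallies(m$dosages[s1, , drop = FALSE])
  t2 <- site_tallies(m$dosages[s2, , drop = FALSE])
  diffs <- t1$a * (t2$n - t2$a) + t2$a * (t1$n - t1$a)
  comps <- t1$n * t2$n
  window_tally(m$sites, diffs, comps, window_bp, value_name = "dxy")
}

#' Windowed Weir-Cockerham (1984) Fst
#'
#' Per-site variance components for two populations: `a` (among populations),
#' `b` (among individuals within populations), `c` (within individuals),
#' computed from called sample sizes, alternate-allele frequencies and
#' observed heterozygote frequencies. Window Fst is `sum(a) / sum(a+b+c)`;
#' invariant sites contribute zeros. Sites with fewer than 2 called genotypes
#' in either group are skipped. A window with zero component total gets `NA`.
#'
#' @inheritParams dxy_windows
#' @return data.frame: chrom, start, end, n_sites, sum_a, sum_abc, fst,
#'   partial.
#' @export
fst_windows <- function(m, group1, group2, window_bp = 10000) {
  s1 <- group_samples(m, group1); s2 <- group_samples(m, group2)
  if (length(intersect(s1, s2))) stop("groups overlap")
  comp <- wc84_components(m$dosages[s1, , drop = FALSE],
                          m$dosages[s2, , drop = FALSE])
  out <- window_tally(m$sites, comp$a, comp$a + comp$b + comp$c, window_bp,
                      value_name = "fst", count_sites = comp$usable)
  names(out)[names(out) == "n_diffs"] <- "sum_a"
  names(out)[names(out) == "n_comps"] <- "sum_abc"
  out
}

# Weir & Cockerham (1984) per-site components for r = 2 populations.
# Returns vectors a, b, c (0 where unusable) and a usable flag.
wc84_components <- function(d1, d2) {
  r <- 2
  t1 <- site_tallies(d1); t2 <- site_tallies(d2)
  n1 <- t1$called; n2 <- t2$called
  usable <- n1 >= 2L & n2 >= 2L
  p1 <- ifelse(t1$n > 0, t1$a / t1$n, 0)
  p2 <- ifelse(t2$n > 0, t2$a / t2$n, 0)
  h1 <- colSums(d1 == 1L, na.rm = TRUE) / pmax(n1, 1L)
  h2 <- colSums(d2 == 1L, na.rm = TRUE) / pmax(n2, 1L)
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!usable] <- 0; b[!usable] <- 0; cc[!usable] <- 0
  list(a = a, b = b, c = cc, usable = usable)
}

# shared window aggregation: tile each chromosome from position 1 with
# half-open windows of window_bp; ratio-of-sums estimator with NA (not 0)
# for empty denominators.
window_tally <- function(sites, diffs, comps, window_bp,
                         value_name = "value", count_sites = comps > 0) {
  res <- list()
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    wi <- (sites$pos[i] - 1) %/% window_bp
    nwin <- max(wi) + 1L
    sum_d <- sum_c <- num <- numeric(nwin)
    f <- factor(wi, levels = 0:(nwin - 1L))
    sum_d <- as.numeric(tapply(diffs[i], f, sum, default = 0))
    sum_c <- as.numeric(tapply(comps[i], f, sum, default = 0))
    num <- as.numeric(tapply(count_sites[i], f, sum, default = 0))
    start <- (0:(nwin - 1L)) * window_bp + 1
    last_pos <- max(sites$pos[i])
    res[[ch]] <- data.frame(
      chrom = ch, start = start, end = start + window_bp - 1,
      n_sites = num, n_diffs = sum_d, n_comps = sum_c,
      value = ifelse(sum_c > 0, sum_d / sum_c, NA_real_),
      partial = start + window_bp - 1 > last_pos,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  names(out)[names(out) == "value"] <- value_name
  out
}

#' Per-individual heterozygosity and inbreeding coefficient
#'
#' For each site with `N >= 2` called alleles and cohort alternate frequency
#' `p`, the small-sample-corrected expected homozygosity is
#' `1 - 2 p (1 - p) N / (N - 1)`. Per individual, `exp_hom` sums that value
#' over the individual's called sites, `obs_hom` counts observed homozygous
#' calls, `he = (n_called - obs_hom) / n_called`, and
#' `fis = (obs_hom - exp_hom) / (n_called - exp_hom)` (the vcftools `--het`
#' convention). Allele frequencies are computed over the whole cohort present
#' in the matrix, not per group. `fis` is `NA` when its denominator is 0.
#'
#' @param m a [cohort_matrix()] (usually the filtered SNP set).
#' @return data.frame: sample, group, n_called, obs_hom, exp_hom, he, fis.
#' @export
het_fis <- function(m) {
  if (nrow(m$dosages) < 2L) stop("need >= 2 samples to estimate frequencies")
  t <- site_tallies(m$dosages)
  use <- t$n >= 2L
  p <- ifelse(use, t$a / pmax(t$n, 1L), NA_real_)
  site_exp <- ifelse(use, 1 - 2 * p * (1 - p) * t$n / (t$n - 1), 0)
  d <- m$dosages[, use, drop = FALSE]
  se <- site_exp[use]
  called <- !is.na(d)
  n_called <- rowSums(called)
  obs_hom <- rowSums(d != 1L, na.rm = TRUE)
  exp_hom <- as.numeric(called %*% se)
  he <- ifelse(n_called > 0, (n_called - obs_hom) / n_called, NA_real_)
  denom <- n_called - exp_hom
  fis <- ifelse(abs(denom) > 1e-12, (obs_hom - exp_hom) / denom, NA_real_)
  data.frame(
    sample = cohort_samples(m),
    group = if (is.null(m$groups)) NA_character_ else unname(m$groups),
    n_called = n_called, obs_hom = obs_hom, exp_hom = exp_hom,
    he = he, fis = fis,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pairwise genotype relatedness (Yang et al. Ajk)
#'
#' For samples `j != k`, the mean over usable sites (cohort alternate
#' frequency strictly between 0 and 1, both samples called) of
#' `(g_j - 2p)(g_k - 2p) / (2p(1-p))`.
#'
#' @param m a [cohort_matrix()].
#' @return data.frame: sample_j, sample_k (j < k in sample order), n_sites,
#'   ajk.
#' @export
relatedness_ajk <- function(m) {
  ns <- nrow(m$dosages)
  if (ns < 2L) stop("need >= 2 samples")
  t <- site_tallies(m$dosages)
  p <- ifelse(t$n > 0, t$a / pmax(t$n, 1L), NA_real_)
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("no polymorphic sites usable for relatedness")
  d <- m$dosages[, use, drop = FALSE]
  p <- p[use]
  x <- sweep(d, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  ok <- !is.na(x)
  x0 <- x; x0[!ok] <- 0
  num <- tcrossprod(x0)
  cnt <- tcrossprod(ok * 1)
  idx <- which(upper.tri(num), arr.ind = TRUE)
  data.frame(
    sample_j = cohort_samples(m)[idx[, 1]],
    sample_k = cohort_samples(m)[idx[, 2]],
    n_sites = cnt[idx],
    ajk = ifelse(cnt[idx] > 0, num[idx] / cnt[idx], NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Summarize diversity windows per chromosome and genome-wide
#'
#' Reports both the pooled ratio-of-sums (`sum(n_diffs)/sum(n_comps)`, the
#' estimator that is invariant to window size) and the plain mean of defined
#' window values, labeled separately. Works on the output of [pi_windows()],
#' [dxy_windows()] or [fst_windows()].
#'
#' @param w window data.frame.
#' @return data.frame: chrom ("genome" row included), n_windows, pooled,
#'   window_mean.
#' @export
summarize_windows <- function(w) {
  dcol <- intersect(c("n_diffs", "sum_a"), names(w))[1]
  ccol <- intersect(c("n_comps", "sum_abc"), names(w))[1]
  vcol <- setdiff(names(w), c("chrom", "start", "end", "n_sites", "partial",
                              dcol, ccol))[1]
  one <- function(x, label) {
    data.frame(chrom = label, n_windows = nrow(x),
               pooled = if (sum(x[[ccol]]) > 0)
                 sum(x[[dcol]]) / sum(x[[ccol]]) else NA_real_,
               window_mean = mean(x[[vcol]], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(split(w, w$chrom), function(x) one(x, x$chrom[1])))
  out <- rbind(out, one(w, "genome"))
  rownames(out) <- NULL
  out
}

#' Group means of the per-individual heterozygosity report
#'
#' The Table-2-style layout: per group, the mean and SD over member
#' individuals of `he` and `fis`, plus the per-site variant of expected
#' heterozygosity pooled over the group's called genotypes.
#'
#' @param het output of [het_fis()].
#' @return data.frame: group, n, he_mean, he_sd, fis_mean, fis_sd.
#' @export
group_het_summary <- function(het) {
  out <- do.call(rbind, lapply(split(het, het$group), function(x) {
    data.frame(group = x$group[1], n = nrow(x),
               he_mean = mean(x$he, na.rm = TRUE),
               he_sd = stats::sd(x$he),
               fis_mean = mean(x$fis, na.rm = TRUE),
               fis_sd = stats::sd(x$fis),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
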
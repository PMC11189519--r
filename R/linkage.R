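#' Pairwise genotype r2 within a distance cap
#'
#' Squared Pearson correlation of dosage vectors (composite LD on unphased
#' genotypes) over pairwise-complete samples, for every same-chromosome site
#' pair at distance <= `max_dist`. Pairs where either vector is monomorphic
#' among the pairwise-complete samples are skipped (counted in attribute
#' `"n_skipped"`), not reported as NaN.
#'
#' @param m a [cohort_matrix()] of filtered SNPs.
#' @param group group label, or `NULL` for all samples.
#' @param max_dist maximum pair distance in bp.
#' @return data.frame: chrom, site_i, site_j, dist_bp, r2.
#' @export
pairwise_r2 <- function(m, group = NULL, max_dist = 500000) {
  dos <- if (is.null(group)) m$dosages else group_dosages(m, group)
  if (nrow(dos) < 2L) stop("need >= 2 samples for r2")
  res <- vector("list", 0)
  skipped <- 0L
  for (ch in unique(m$sites$chrom)) {
    si <- which(m$sites$chrom == ch)
    pos <- m$sites$pos[si]
    o <- order(pos); si <- si[o]; pos <- pos[o]
    L <- length(si)
    if (L < 2L) next
    for (i in seq_len(L - 1L)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_dist)
      j <- j[j > i]
      if (!length(j)) next
      r2 <- suppressWarnings(as.numeric(
        stats::cor(dos[, si[i]], dos[, si[j], drop = FALSE],
                   use = "pairwise.complete.obs")))^2
      bad <- is.na(r2)
      skipped <- skipped + sum(bad)
      if (all(bad)) next
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch,
        site_i = m$sites$id[si[i]],
        site_j = m$sites$id[si[j[!bad]]],
        dist_bp = pos[j[!bad]] - pos[i],
        r2 = r2[!bad],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), site_i = character(0),
               site_j = character(0), dist_bp = numeric(0), r2 = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Bin an LD pair list into a decay curve
#'
#' Bins are `[0,b), [b,2b), ...`; each gets the mean r2 and the pair count.
#' Empty bins carry `NA` means.
#'
#' @param pairs output of [pairwise_r2()].
#' @param bin_width bin width in bp.
#' @return data.frame: bin_start, bin_end, mean_r2, n_pairs.
#' @export
decay_curve <- function(pairs, bin_width = 1000) {
  if (!nrow(pairs)) stop("no pairs to bin")
  b <- pairs$dist_bp %/% bin_width
  nbin <- max(b) + 1L
  f <- factor(b, levels = 0:(nbin - 1L))
  data.frame(
    bin_start = (0:(nbin - 1L)) * bin_width,
    bin_end = (1:nbin) * bin_width,
    mean_r2 = as.numeric(tapply(pairs$r2, f, mean)),
    n_pairs = as.numeric(tapply(pairs$r2, f, length, default = 0))
  )
}

#' LD decay with replicate down-sampling of a group
#'
#' Draws `reps` independent subsamples of `n_sub` individuals without
#' replacement (the scheme used to put a 25-individual group on the same
#' footing as 10-individual groups), computes one decay curve per replicate,
#' and their pointwise mean. The subsample sequence is reproducible from
#' `seed`.
#'
#' @inheritParams pairwise_r2
#' @param n_sub subsample size (individuals).
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param bin_width decay-curve bin width in bp.
#' @return list with `curves` (list of data.frames), `mean_curve`, and
#'   `subsamples`.
#' @export
downsampled_decay <- function(m, group, n_sub = 10, reps = 10, seed = 1,
                              max_dist = 500000, bin_width = 1000) {
  samp <- group_samples(m, group)
  if (length(samp) < n_sub) {
    stop("group '", group, "' has ", length(samp), " samples < n_sub = ", n_sub)
  }
  set.seed(seed)
  subs <- lapply(seq_len(reps), function(i) sort(sample(samp, n_sub)))
  curves <- lapply(subs, function(s) {
    ms <- subset_samples(m, s)
    decay_curve(pairwise_r2(ms, group = NULL, max_dist = max_dist), bin_width)
  })
  nbin <- max(vapply(curves, nrow, integer(1)))
  grid <- (0:(nbin - 1L)) * bin_width
  mat <- sapply(curves, function(cv) cv$mean_r2[match(grid, cv$bin_start)])
  mat <- matrix(mat, nrow = nbin)
  mean_curve <- data.frame(bin_start = grid, bin_end = grid + bin_width,
                           mean_r2 = rowMeans(mat, na.rm = TRUE))
  list(curves = curves, mean_curve = mean_curve, subsamples = subs)
}

#' Windowed r2 pruning of SNPs
#'
#' The `--indep-pairwise W S R` dialect: over successive windows of
#' `window_snps` SNPs advancing by `step_snps` (window extent counted on the
#' original site order per chromosome), while any retained pair within the
#' window has r2 > `r2_max`, one member is removed. Tie-break: the member
#' with the smaller minor allele frequency goes; on equal MAF the later
#' position goes. After completion no retained same-window pair exceeds
#' `r2_max`.
#'
#' @inheritParams pairwise_r2
#' @param window_snps window size in SNPs.
#' @param step_snps step in SNPs.
#' @param r2_max retention threshold.
#' @return pruned `cohort_matrix`; attributes `"kept"` and `"removed"` carry
#'   site IDs.
#' @export
ld_prune <- function(m, group = NULL, window_snps = 50, step_snps = 10,
                     r2_max = 0.1) {
  dos <- if (is.null(group)) m$dosages else group_dosages(m, group)
  t <- site_tallies(dos)
  maf <- ifelse(t$n > 0, pmin(t$a, t$n - t$a) / pmax(t$n, 1L), 0)
  keep <- rep(TRUE, n_sites(m))
  for (ch in unique(m$sites$chrom)) {
    si <- which(m$sites$chrom == ch)
    o <- order(m$sites$pos[si]); si <- si[o]
    L <- length(si)
    starts <- unique(c(seq(1L, max(L - 1L, 1L), by = step_snps)))
    for (s in starts) {
      win <- si[s:min(s + window_snps - 1L, L)]
      if (length(win) < 2L) next
      repeat {
        alive <- win[keep[win]]
        if (length(alive) < 2L) break
        cm <- suppressWarnings(
          stats::cor(dos[, alive, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        cm[lower.tri(cm, diag = TRUE)] <- NA
        worst <- suppressWarnings(max(cm, na.rm = TRUE))
        if (!is.finite(worst) || worst <= r2_max) break
        hit <- which(cm == worst, arr.ind = TRUE)[1, ]
        pair <- alive[hit]
        drop <- if (maf[pair[1]] < maf[pair[2]]) pair[1]
        else if (maf[pair[2]] < maf[pair[1]]) pair[2]
        else pair[which.max(m$sites$pos[pair])]
        keep[drop] <- FALSE
      }
    }
  }
  out <- subset_sites(m, keep)
  attr(out, "kept") <- m$sites$id[keep]
  attr(out, "removed") <- m$sites$id[!keep]
  out
}
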
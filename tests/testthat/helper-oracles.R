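# Independent brute-force oracles and random-fixture generators.
# Oracles enumerate haplotype/sample pairs explicitly; the package code uses
# allele-count algebra, so agreement is a real cross-check.

random_cohort <- function(n_samples = 8, n_sites = 100, missing_rate = 0,
                          groups = NULL, n_chrom = 2, invariant_frac = 0) {
  p <- stats::rbeta(n_sites, 0.8, 0.8)
  if (invariant_frac > 0) {
    p[stats::runif(n_sites) < invariant_frac] <- 0
  }
  dos <- vapply(p, function(pp) stats::rbinom(n_samples, 2, pp),
                integer(n_samples))
  dos <- matrix(as.integer(dos), nrow = n_samples)
  if (missing_rate > 0) dos[stats::runif(length(dos)) < missing_rate] <- NA
  rownames(dos) <- sprintf("s%02d", seq_len(n_samples))
  pos <- sort(sample.int(n_sites * 20, n_sites))
  chrom <- paste0("chr", 1 + (seq_len(n_sites) * n_chrom - 1) %/% n_sites)
  sites <- data.frame(chrom = chrom, pos = pos)
  g <- if (is.null(groups)) NULL else
    stats::setNames(rep(groups, length.out = n_samples)[order(seq_len(n_samples))],
                    rownames(dos))
  cohort_matrix(dos, sites, groups = g)
}

# dosages -> haplotype matrix (2 rows per sample); het split is arbitrary,
# which never affects mismatch counts
expand_haps <- function(dos) {
  h1 <- dos; h1[dos == 1L] <- 0L; h1[dos == 2L] <- 1L
  h2 <- dos; h2[dos >= 1L] <- 1L
  out <- matrix(NA_integer_, 2 * nrow(dos), ncol(dos))
  out[seq(1, 2 * nrow(dos), 2), ] <- h1
  out[seq(2, 2 * nrow(dos), 2), ] <- h2
  out
}

# per-site mismatch/comparison tallies over all within-set haplotype pairs
oracle_pair_tally <- function(dos) {
  H <- expand_haps(dos)
  nh <- nrow(H)
  diffs <- comps <- numeric(ncol(H))
  for (i in seq_len(nh - 1)) {
    for (j in (i + 1):nh) {
      ok <- !is.na(H[i, ]) & !is.na(H[j, ])
      comps <- comps + ok
      diffs <- diffs + (ok & H[i, ] != H[j, ])
    }
  }
  list(diffs = diffs, comps = comps)
}

# per-site tallies over between-set haplotype pairs
oracle_cross_tally <- function(dos1, dos2) {
  H1 <- expand_haps(dos1); H2 <- expand_haps(dos2)
  diffs <- comps <- numeric(ncol(H1))
  for (i in seq_len(nrow(H1))) {
    for (j in seq_len(nrow(H2))) {
      ok <- !is.na(H1[i, ]) & !is.na(H2[j, ])
      comps <- comps + ok
      diffs <- diffs + (ok & H1[i, ] != H2[j, ])
    }
  }
  list(diffs = diffs, comps = comps)
}

# Weir & Cockerham (1984), scalar transcription for r = 2, one site at a time
oracle_wc84 <- function(d1, d2) {
  S <- ncol(d1)
  a <- b <- cc <- numeric(S)
  usable <- logical(S)
  for (s in seq_len(S)) {
    x1 <- d1[, s]; x1 <- x1[!is.na(x1)]
    x2 <- d2[, s]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    usable[s] <- TRUE
    r <- 2
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    nbar <- mean(c(n1, n2))
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a[s] <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b[s] <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc[s] <- hbar / 2
  }
  list(a = a, b = b, c = cc, usable = usable)
}

oracle_het_fis <- function(dos) {
  ns <- nrow(dos); S <- ncol(dos)
  out <- data.frame(obs_hom = numeric(ns), exp_hom = numeric(ns),
                    n_called = numeric(ns))
  site_exp <- rep(NA_real_, S)
  for (s in seq_len(S)) {
    x <- dos[, s]; x <- x[!is.na(x)]
    N <- 2 * length(x)
    if (N < 2) next
    p <- sum(x) / N
    site_exp[s] <- 1 - 2 * p * (1 - p) * N / (N - 1)
  }
  for (i in seq_len(ns)) {
    for (s in seq_len(S)) {
      if (is.na(dos[i, s]) || is.na(site_exp[s])) next
      out$n_called[i] <- out$n_called[i] + 1
      out$exp_hom[i] <- out$exp_hom[i] + site_exp[s]
      if (dos[i, s] != 1) out$obs_hom[i] <- out$obs_hom[i] + 1
    }
  }
  out$he <- (out$n_called - out$obs_hom) / out$n_called
  out$fis <- (out$obs_hom - out$exp_hom) / (out$n_called - out$exp_hom)
  out
}

oracle_ajk <- function(dos) {
  ns <- nrow(dos)
  pv <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  use <- !is.na(pv) & pv > 0 & pv < 1
  out <- matrix(NA_real_, ns, ns)
  for (j in seq_len(ns - 1)) {
    for (k in (j + 1):ns) {
      num <- den <- 0
      for (s in which(use)) {
        gj <- dos[j, s]; gk <- dos[k, s]
        if (is.na(gj) || is.na(gk)) next
        p <- pv[s]
        num <- num + (gj - 2 * p) * (gk - 2 * p) / (2 * p * (1 - p))
        den <- den + 1
      }
      out[j, k] <- out[k, j] <- if (den > 0) num / den else NA_real_
    }
  }
  out
}

oracle_ibs <- function(dos) {
  ns <- nrow(dos)
  out <- matrix(0, ns, ns)
  for (j in seq_len(ns - 1)) {
    for (k in (j + 1):ns) {
      ok <- !is.na(dos[j, ]) & !is.na(dos[k, ])
      out[j, k] <- out[k, j] <- sum(abs(dos[j, ok] - dos[k, ok]) / 2) / sum(ok)
    }
  }
  out
}

oracle_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  (sum((x - mean(x)) * (y - mean(y)))^2) / (sx * sy)
}

oracle_folded_sfs <- function(dos) {
  n <- 2 * nrow(dos)
  bins <- stats::setNames(rep(0L, n %/% 2 + 1), 0:(n %/% 2))
  for (s in seq_len(ncol(dos))) {
    x <- dos[, s]
    if (anyNA(x)) next
    minor <- min(sum(x), n - sum(x))
    bins[minor + 1] <- bins[minor + 1] + 1L
  }
  bins
}

# Tajima (1989): literal transcription over one set of fully-called sites
oracle_tajima_d <- function(dos) {
  n <- 2 * nrow(dos)
  full <- colSums(is.na(dos)) == 0
  a <- colSums(dos[, full, drop = FALSE])
  S <- sum(a > 0 & a < n)
  theta_pi <- sum(a * (n - a)) / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  D <- if (S > 0) (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  else NA_real_
  list(S = S, theta_pi = theta_pi, theta_w = theta_w, D = D)
}

oracle_novel <- function(m, reference_groups, focal_groups) {
  refs <- names(m$groups)[m$groups %in% reference_groups]
  out <- list()
  for (s in seq_len(n_sites(m))) {
    if (any(m$dosages[refs, s] != 0L)) next
    fl <- vapply(focal_groups, function(g) {
      any(m$dosages[names(m$groups)[m$groups == g], s] > 0L)
    }, logical(1))
    out[[length(out) + 1]] <- c(site = m$sites$id[s], fl)
  }
  out
}

# expected folded-SFS shape under the standard neutral model
neutral_folded_shape <- function(n) {
  i <- seq_len(n %/% 2)
  w <- (1 / i + 1 / (n - i)) / (1 + (i == n - i))
  w / sum(w)
}
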
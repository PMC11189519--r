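# pi / dxy / Fst windows, He / F_IS, relatedness

two_diploid_cohort <- function() {
  # 10 fully-called sites, one with genotypes 0/0 and 1/1
  dos <- rbind(a = c(rep(0L, 9), 0L), b = c(rep(0L, 9), 2L))
  dos[, 10] <- c(0L, 2L)
  sites <- data.frame(chrom = "c1", pos = seq(100, 1000, by = 100))
  cohort_matrix(dos, sites, groups = c(a = "g1", b = "g1"))
}

test_that("pi on the 2-diploid/10-site worked example is 4/60", {
  w <- pi_windows(two_diploid_cohort(), "g1", window_bp = 1e6)
  expect_equal(w$n_diffs, 4)
  expect_equal(w$n_comps, 60)
  expect_equal(w$pi, 4 / 60)

  # all identical homozygotes -> pi = 0
  m0 <- cohort_matrix(rbind(a = rep(2L, 5), b = rep(2L, 5)),
                      data.frame(chrom = "c1", pos = 1:5),
                      groups = c(a = "g1", b = "g1"))
  expect_equal(pi_windows(m0, "g1", 100)$pi, 0)
})

test_that("dxy worked example and symmetry", {
  # one diploid 0/0 vs one diploid 1/1 at a single site; 10 called sites
  dos <- rbind(a = rep(0L, 10), b = c(rep(0L, 9), 2L))
  m <- cohort_matrix(dos, data.frame(chrom = "c1", pos = 1:10),
                     groups = c(a = "g1", b = "g2"))
  w <- dxy_windows(m, "g1", "g2", window_bp = 1e6)
  expect_equal(w$n_diffs, 4)
  expect_equal(w$n_comps, 40)
  expect_equal(w$dxy, 0.1)

  # monomorphic, identical panels -> 0
  m0 <- cohort_matrix(rbind(a = rep(0L, 6), b = rep(0L, 6)),
                      data.frame(chrom = "c1", pos = 1:6),
                      groups = c(a = "g1", b = "g2"))
  expect_equal(dxy_windows(m0, "g1", "g2", 100)$dxy, 0)

  set.seed(5)
  m <- random_cohort(8, 120, missing_rate = 0.2, groups = c("g1", "g2"))
  w12 <- dxy_windows(m, "g1", "g2", 500)
  w21 <- dxy_windows(m, "g2", "g1", 500)
  expect_equal(w12$dxy, w21$dxy)
})

test_that("pi/dxy match the brute-force haplotype-pair oracle", {
  set.seed(42)
  for (i in 1:25) {
    m <- random_cohort(n_samples = 6, n_sites = 200, missing_rate = 0.2,
                       groups = c("g1", "g2"), invariant_frac = 0.2)
    d1 <- m$dosages[group_samples(m, "g1"), ]
    d2 <- m$dosages[group_samples(m, "g2"), ]
    o <- oracle_pair_tally(d1)
    w <- pi_windows(m, "g1", window_bp = 1e7)
    for (ch in unique(m$sites$chrom)) {
      sel <- m$sites$chrom == ch
      expect_equal(w$n_diffs[w$chrom == ch], sum(o$diffs[sel]))
      expect_equal(w$n_comps[w$chrom == ch], sum(o$comps[sel]))
    }
    oc <- oracle_cross_tally(d1, d2)
    wd <- dxy_windows(m, "g1", "g2", window_bp = 1e7)
    expect_equal(sum(wd$n_diffs), sum(oc$diffs))
    expect_equal(sum(wd$n_comps), sum(oc$comps))
  }
})

test_that("pi is invariant to allele relabeling and grows with invariant sites", {
  set.seed(7)
  m <- random_cohort(6, 100, groups = "g1")
  w1 <- pi_windows(m, "g1", 1e7)
  flip <- m
  flip$dosages <- 2L - flip$dosages
  w2 <- pi_windows(flip, "g1", 1e7)
  expect_equal(w1$pi, w2$pi)

  # appending invariant sites lowers pooled pi monotonically
  inv <- cohort_matrix(
    matrix(0L, 6, 50, dimnames = list(cohort_samples(m), NULL)),
    data.frame(chrom = "chr1", pos = 5000 + 1:50),
    groups = m$groups)
  bigger <- concat_sites(m, inv)
  p1 <- summarize_windows(pi_windows(m, "g1", 1e7))
  p2 <- summarize_windows(pi_windows(bigger, "g1", 1e7))
  expect_lt(p2$pooled[p2$chrom == "genome"], p1$pooled[p1$chrom == "genome"])

  # all-missing site changes nothing
  gap <- cohort_matrix(
    matrix(NA_integer_, 6, 1, dimnames = list(cohort_samples(m), NULL)),
    data.frame(chrom = "chr1", pos = 9999L), groups = m$groups)
  w3 <- summarize_windows(pi_windows(concat_sites(m, gap), "g1", 1e7))
  expect_equal(w3$pooled[w3$chrom == "genome"],
               p1$pooled[p1$chrom == "genome"])
})

test_that("windows tile from position 1 and empty windows are NA, not 0", {
  dos <- rbind(a = c(0L, 2L), b = c(2L, 0L))
  m <- cohort_matrix(dos, data.frame(chrom = "c1", pos = c(150L, 25050L)),
                     groups = c(a = "g", b = "g"))
  w <- pi_windows(m, "g", window_bp = 10000)
  expect_equal(w$start, c(1, 10001, 20001))
  expect_true(is.na(w$pi[2]))
  expect_false(any(w$pi == 0, na.rm = TRUE) && all(!is.na(w$pi)))
  expect_true(w$partial[3])
})

test_that("Weir-Cockerham Fst: fixed difference gives 1, formula oracle agrees", {
  dos <- rbind(a = rep(0L, 5), b = rep(0L, 5), c = rep(2L, 5), d = rep(2L, 5))
  m <- cohort_matrix(dos, data.frame(chrom = "c1", pos = 1:5),
                     groups = c(a = "g1", b = "g1", c = "g2", d = "g2"))
  w <- fst_windows(m, "g1", "g2", 100)
  expect_equal(w$fst, 1)

  set.seed(9)
  for (i in 1:20) {
    m <- random_cohort(n_samples = 8, n_sites = 150, missing_rate = 0.15,
                       groups = c("g1", "g2"))
    d1 <- m$dosages[group_samples(m, "g1"), ]
    d2 <- m$dosages[group_samples(m, "g2"), ]
    o <- oracle_wc84(d1, d2)
    w <- fst_windows(m, "g1", "g2", 1e7)
    expect_equal(sum(w$sum_a), sum(o$a), tolerance = 1e-12)
    expect_equal(sum(w$sum_abc), sum(o$a + o$b + o$c), tolerance = 1e-12)
    got <- sum(w$sum_a) / sum(w$sum_abc)
    want <- sum(o$a) / sum(o$a + o$b + o$c)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("het_fis reproduces the two-heterozygote toy and the oracle", {
  m <- cohort_matrix(rbind(a = 1L, b = 1L),
                     data.frame(chrom = "c1", pos = 1L))
  h <- het_fis(m)
  expect_equal(h$exp_hom, c(1 / 3, 1 / 3))
  expect_equal(h$fis, c(-0.5, -0.5))
  expect_equal(h$he, c(1, 1))

  # fully homozygous cohort: he = 0, fis = 1 where defined
  m1 <- cohort_matrix(rbind(a = c(0L, 2L), b = c(2L, 0L)),
                      data.frame(chrom = "c1", pos = 1:2))
  h1 <- het_fis(m1)
  expect_equal(h1$he, c(0, 0))
  expect_equal(h1$fis, c(1, 1))

  set.seed(13)
  for (i in 1:15) {
    m <- random_cohort(n_samples = 9, n_sites = 120, missing_rate = 0.2)
    got <- het_fis(m)
    want <- oracle_het_fis(m$dosages)
    expect_equal(got$obs_hom, want$obs_hom)
    expect_equal(got$exp_hom, want$exp_hom, tolerance = 1e-12)
    expect_equal(got$he, want$he, tolerance = 1e-12)
    expect_equal(got$fis, want$fis, tolerance = 1e-12)
  }
})

test_that("relatedness ajk single-site terms and oracle equality", {
  # p = 0.5, both heterozygous -> 0; both hom-alt -> 2
  m <- cohort_matrix(rbind(a = c(1L, 2L), b = c(1L, 2L),
                           c = c(0L, 0L), d = c(2L, 0L)),
                     data.frame(chrom = "c1", pos = 1:2))
  r <- relatedness_ajk(subset_sites(m, 1))
  expect_equal(r$ajk[r$sample_j == "a" & r$sample_k == "b"], 0)
  r2 <- relatedness_ajk(subset_sites(m, 2))
  expect_equal(r2$ajk[r2$sample_j == "a" & r2$sample_k == "b"], 2)

  set.seed(17)
  for (i in 1:15) {
    m <- random_cohort(n_samples = 7, n_sites = 150, missing_rate = 0.2)
    got <- relatedness_ajk(m)
    want <- oracle_ajk(m$dosages)
    for (k in seq_len(nrow(got))) {
      j1 <- match(got$sample_j[k], cohort_samples(m))
      j2 <- match(got$sample_k[k], cohort_samples(m))
      expect_equal(got$ajk[k], want[j1, j2], tolerance = 1e-12)
    }
  }
})

test_that("summarize_windows reports pooled vs window-mean correctly", {
  w <- data.frame(chrom = "c1", start = c(1, 11), end = c(10, 20),
                  n_sites = c(1, 1), n_diffs = c(1, 3), n_comps = c(10, 10),
                  pi = c(0.1, 0.3), partial = FALSE)
  s <- summarize_windows(w)
  expect_equal(s$pooled[s$chrom == "genome"], 0.2)
  expect_equal(s$window_mean[s$chrom == "genome"], 0.2)

  w$n_comps <- c(10, 30); w$pi <- w$n_diffs / w$n_comps
  s <- summarize_windows(w)
  expect_equal(s$pooled[s$chrom == "genome"], 0.1)
  expect_equal(s$window_mean[s$chrom == "genome"], 0.1)

  # pooled value invariant under window size change
  set.seed(23)
  m <- random_cohort(6, 200, groups = "g1", invariant_frac = 0.3)
  s1 <- summarize_windows(pi_windows(m, "g1", 100))
  s2 <- summarize_windows(pi_windows(m, "g1", 1e7))
  expect_equal(s1$pooled[s1$chrom == "genome"],
               s2$pooled[s2$chrom == "genome"])
})
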
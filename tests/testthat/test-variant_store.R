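# data model, VCF I/O and the site-filtering / splitting / merging cascade

site_tallies_for_test <- function(m) colSums(m$dosages, na.rm = TRUE)

subset_samples_to_none <- function(m) {
  m$dosages <- m$dosages[0, , drop = FALSE]
  m$groups <- NULL
  m
}

toy_cohort <- function() {
  dos <- rbind(s1 = c(0L, 1L, 0L, 0L),
               s2 = c(0L, 2L, 1L, NA),
               s3 = c(0L, NA, 0L, 1L))
  sites <- data.frame(
    chrom = c("At_1", "At_1", "Dt_1", "Dt_1"),
    pos = c(5L, 10L, 3L, 20L),
    id = c("inv1", "snp1", "snp2", "snp3"),
    ref = c("A", "A", "C", "G"),
    alt = c("", "G", "T", "A"),
    mean_depth = c(12, 30.5, NA, 8)
  )
  cohort_matrix(dos, sites, groups = c(s1 = "wild", s2 = "wild", s3 = "MK"))
}

test_that("cohort construction assigns site classes and sorts sites", {
  m <- toy_cohort()
  expect_equal(m$sites$site_class, c("invariant", "snp", "snp", "snp"))
  expect_equal(m$sites$pos, c(5L, 10L, 3L, 20L))  # sorted within chrom
  expect_error(cohort_matrix(rbind(s1 = c(0L, 0L)),
                             data.frame(chrom = "c", pos = c(7L, 7L))),
               "duplicate")
  expect_error(cohort_matrix(rbind(s1 = 3L), data.frame(chrom = "c", pos = 1L)),
               "dosages")
})

test_that("VCF round trip is lossless for dosages, positions, IDs, classes", {
  m <- toy_cohort()
  # add an indel and a multiallelic site to exercise every class
  extra <- cohort_matrix(
    rbind(s1 = c(1L, 1L), s2 = c(0L, 2L), s3 = c(0L, 1L)),
    data.frame(chrom = "Dt_1", pos = c(40L, 50L), id = c("ind1", "multi1"),
               ref = c("CA", "C"), alt = c("C", "G,T"),
               n_allele_obs = c(2L, 3L), mean_depth = c(25, 25)))
  expect_equal(extra$sites$site_class, c("indel", "multiallelic"))
  m <- concat_sites(m, extra)
  path <- tempfile(fileext = ".vcf")
  write_vcf(m, path)
  m2 <- read_vcf(path)
  expect_equal(unname(m2$dosages), unname(m$dosages))
  expect_equal(m2$sites$pos, m$sites$pos)
  expect_equal(m2$sites$id, m$sites$id)
  expect_equal(m2$sites$site_class, m$sites$site_class)
  expect_equal(m2$sites$mean_depth, m$sites$mean_depth)
  expect_equal(cohort_samples(m2), cohort_samples(m))
})

test_that("read_vcf maps genotypes to dosages and handles an empty body", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=c1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", "b", "c", sep = "\t"),
    paste("c1", "10", "x1", "A", "G", ".", ".", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("c1", "11", "x2", "A", "G", ".", ".", ".", "GT",
          "0|1", "0/.", "0/0", sep = "\t")
  ), path)
  m <- read_vcf(path)
  expect_equal(unname(m$dosages[, 1]), c(1L, 2L, NA))
  expect_equal(unname(m$dosages[, 2]), c(1L, NA, 0L))  # half-call missing

  empty <- tempfile(fileext = ".vcf")
  writeLines(readLines(path)[1:4], empty)
  expect_equal(n_sites(read_vcf(empty)), 0L)
})

test_that("read_vcf rejects non-diploid GT and malformed files", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "a", sep = "\t"),
    paste("c1", "10", ".", "A", "G", ".", ".", ".", "GT", "0/1/1", sep = "\t")
  ), path)
  expect_error(read_vcf(path), "ploidy")
  bad <- tempfile(fileext = ".vcf")
  writeLines("not a vcf at all", bad)
  expect_error(read_vcf(bad), "parse error")
})

test_that("split/concat form a partition and concat checks its preconditions", {
  m <- toy_cohort()
  parts <- split_sites(m)
  expect_equal(n_sites(parts$invariant), 1L)
  expect_equal(n_sites(parts$variable), 3L)
  back <- concat_sites(parts$invariant, parts$variable)
  expect_equal(back$sites$id, m$sites$id)
  expect_equal(unname(back$dosages), unname(m$dosages))

  all_inv <- subset_sites(m, m$sites$site_class == "invariant")
  expect_equal(n_sites(split_sites(all_inv)$variable), 0L)

  expect_error(concat_sites(m, m), "duplicate")
  renamed <- m; rownames(renamed$dosages)[1] <- "zz"
  expect_error(concat_sites(m, renamed), "sample sets differ")

  # identity element
  empty <- subset_sites(m, logical(4))
  expect_equal(concat_sites(m, empty)$sites$id, m$sites$id)

  # property: partition holds on random cohorts
  set.seed(11)
  for (i in 1:20) {
    r <- random_cohort(n_samples = 6, n_sites = 60, missing_rate = 0.15,
                       invariant_frac = 0.3)
    p <- split_sites(r)
    expect_equal(n_sites(p$invariant) + n_sites(p$variable), 60L)
    rt <- concat_sites(p$invariant, p$variable)
    expect_equal(rt$sites$id, r$sites$id)
    expect_equal(unname(rt$dosages), unname(r$dosages))
    a <- site_tallies_for_test(p$invariant)
    expect_true(all(a == 0))
  }
})

test_that("the 8-record filter toy retains exactly the 2 passing SNPs", {
  n <- 30
  mk <- function(alt_count, miss = 0) {
    d <- c(rep(1L, alt_count), rep(0L, n - alt_count))
    if (miss > 0) d[seq_len(miss)] <- NA
    d
  }
  dos <- cbind(mk(20), mk(10), c(1L, 2L, rep(0L, n - 2)), mk(1), mk(5, miss = 1),
               mk(12), mk(12), mk(15))
  rownames(dos) <- sprintf("s%02d", 1:n)
  sites <- data.frame(
    chrom = "At_1", pos = 1:8 * 100L,
    id = c("pass1", "indel", "tri", "rare", "miss", "lowdp", "highdp", "pass2"),
    ref = c("A", "AT", "C", "G", "T", "A", "C", "G"),
    alt = c("G", "A", "G,T", "A", "C", "G", "T", "A"),
    n_allele_obs = c(2L, 2L, 3L, 2L, 2L, 2L, 2L, 2L),
    mean_depth = c(30, 30, 30, 30, 30, 5, 150, 50))
  m <- cohort_matrix(dos, sites)
  out <- filter_sites(m, filter_preset("cohort65_snp"))
  expect_equal(out$sites$id, c("pass1", "pass2"))

  # every clause individually verified on the survivors
  cl <- attr(out, "clauses")
  expect_true(all(cl[m$sites$id %in% c("pass1", "pass2"), ]))

  # disabled thresholds -> identity
  off <- filter_params(max_missing_count = n, max_alleles = 99L, min_mac = 0L,
                       min_maf = 0, min_mean_depth = 0, max_mean_depth = Inf,
                       drop_indels = FALSE)
  expect_equal(filter_sites(m, off)$sites$id, m$sites$id)

  # idempotence
  p <- filter_preset("cohort65_snp")
  expect_identical(filter_sites(filter_sites(m, p), p)$sites,
                   filter_sites(m, p)$sites)
})

test_that("filter clauses re-verify independently on random cohorts", {
  set.seed(21)
  p <- filter_params(max_missing_count = 1L, max_alleles = 2L, min_mac = 2L,
                     min_maf = 0.1, min_mean_depth = 0, max_mean_depth = Inf)
  for (i in 1:10) {
    m <- random_cohort(n_samples = 10, n_sites = 80, missing_rate = 0.1)
    out <- filter_sites(m, p)
    if (!n_sites(out)) next
    for (s in seq_len(n_sites(out))) {
      x <- out$dosages[, s]
      expect_lte(sum(is.na(x)), 1L)
      N <- 2 * sum(!is.na(x)); a <- sum(x, na.rm = TRUE)
      expect_gte(min(a, N - a), 2L)
      expect_gte(min(a, N - a) / N, 0.1)
    }
    expect_identical(filter_sites(out, p)$sites, out$sites)
  }
})

test_that("merge_cohorts unions samples and sites with missing fill", {
  m <- toy_cohort()
  og <- cohort_matrix(
    rbind(og1 = c(0L, 0L, 2L), og2 = c(0L, 1L, 2L)),
    data.frame(chrom = c("At_1", "At_1", "Dt_1"), pos = c(5L, 10L, 99L),
               id = c("inv1", "snp1", "ognew"), ref = c("A", "A", "T"),
               alt = c("", "G", "C")),
    groups = c(og1 = "outgroup", og2 = "outgroup"))
  mg <- merge_cohorts(m, og)
  expect_equal(nrow(mg$dosages), 5L)
  expect_equal(n_sites(mg), 5L)  # union of 4 + 3 with 2 shared
  # position only in m -> og samples missing there
  expect_true(all(is.na(mg$dosages[c("og1", "og2"), mg$sites$id == "snp2"])))
  # position only in og -> m samples missing
  expect_true(all(is.na(mg$dosages[c("s1", "s2", "s3"), mg$sites$id == "ognew"])))
  # shared positions keep both sides' dosages
  expect_equal(unname(mg$dosages[c("s2", "og2"), mg$sites$id == "snp1"]), c(2L, 1L))
  expect_equal(unname(mg$groups), c("wild", "wild", "MK", "outgroup", "outgroup"))

  empty <- subset_samples_to_none(og)
  expect_equal(merge_cohorts(m, empty)$sites$id, m$sites$id)

  conflict <- og
  conflict$sites$ref[2] <- "T"
  expect_error(merge_cohorts(m, conflict), "conflicting")
  expect_error(merge_cohorts(m, m), "overlap")
})

test_that("intersect_genic applies the 0-based half-open convention", {
  m <- cohort_matrix(rbind(s1 = rep(0L, 2)),
                     data.frame(chrom = "c1", pos = c(100L, 100L + 1L)))
  keep <- intersect_genic(m, genomic_intervals("c1", 99, 100))
  expect_equal(keep$sites$pos, 100L)
  drop <- intersect_genic(m, genomic_intervals("c1", 100, 101))
  expect_equal(drop$sites$pos, 101L)
  expect_equal(n_sites(intersect_genic(m, genomic_intervals("zz", 0, 10))), 0L)

  # brute-force membership oracle on random layouts
  set.seed(31)
  for (i in 1:10) {
    m <- random_cohort(n_samples = 3, n_sites = 60)
    st <- sample.int(800, 4)
    g <- genomic_intervals(
      chrom = rep(unique(m$sites$chrom), each = 2),
      start = st, end = st + sample(20:150, 4))
    got <- intersect_genic(m, g)$sites$id
    want <- m$sites$id[vapply(seq_len(60), function(s) {
      any(g$chrom == m$sites$chrom[s] & g$start <= m$sites$pos[s] - 1 &
            m$sites$pos[s] - 1 < g$end)
    }, logical(1))]
    expect_equal(got, want)
  }
})

test_that("BED and group tables round trip", {
  g <- genomic_intervals(c("c1", "c1", "c2"), c(10, 5, 0), c(20, 12, 7))
  expect_equal(nrow(g), 2L)  # overlapping intervals merged
  expect_equal(g$end[g$chrom == "c1"], 20)
  bed <- tempfile(fileext = ".bed")
  write.table(data.frame("c1", 5, 20), bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_equal(read_bed(bed)$start, 5)

  gr <- c(a = "wild", b = "MK")
  path <- tempfile(fileext = ".tsv")
  write_groups(gr, path)
  expect_equal(read_groups(path), gr)
})
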
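#' Site filter parameters
#'
#' The filter cascade applied to joint-called all-sites cohorts. Defaults are
#' the standard variant-toolkit preset used for the 65-sample SNP set:
#' no missing genotypes, at most 2 observed alleles, minor allele count >= 1,
#' minor allele frequency >= 0.05, mean depth in \[10, 100\], indels dropped.
#' MAF and MAC are computed on called genotypes only (missing calls excluded
#' from denominators). Sites without a depth annotation pass the depth clause.
#'
#' `filter_preset("cohort65_snp")` is this default; `"cohort67_novel"` is the
#' biallelic preset used upstream of novel-allele classification (no MAF and
#' no depth bounds -- the two presets intentionally differ and are not
#' harmonized).
#'
#' @param max_missing_count max number of missing genotypes per site.
#' @param max_alleles max number of distinct observed alleles.
#' @param min_mac minimum minor allele count.
#' @param min_maf minimum minor allele frequency (0..0.5).
#' @param min_mean_depth,max_mean_depth mean-depth bounds.
#' @param drop_indels drop sites classified as indels.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(max_missing_count = 0L, max_alleles = 2L,
                          min_mac = 1L, min_maf = 0.05,
                          min_mean_depth = 10, max_mean_depth = 100,
                          drop_indels = TRUE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, min_mean_depth <= max_mean_depth)
  structure(list(max_missing_count = as.integer(max_missing_count),
                 max_alleles = as.integer(max_alleles),
                 min_mac = as.integer(min_mac), min_maf = min_maf,
                 min_mean_depth = min_mean_depth,
                 max_mean_depth = max_mean_depth,
                 drop_indels = isTRUE(drop_indels)),
            class = "filter_params")
}

#' @rdname filter_params
#' @param name preset name.
#' @export
filter_preset <- function(name = c("cohort65_snp", "cohort67_novel")) {
  name <- match.arg(name)
  switch(name,
    cohort65_snp = filter_params(),
    cohort67_novel = filter_params(min_maf = 0, min_mean_depth = 0,
                                   max_mean_depth = Inf)
  )
}

#' Filter sites of a cohort matrix
#'
#' Retains sites satisfying every clause of `p`; sample set and site order are
#' unchanged. An empty result is returned, not an error. The operation is
#' idempotent.
#'
#' @param m a [cohort_matrix()].
#' @param p a [filter_params()].
#' @return filtered `cohort_matrix`; the per-clause pass matrix is attached as
#'   attribute `"clauses"` for accounting.
#' @export
filter_sites <- function(m, p) {
  stopifnot(inherits(p, "filter_params"))
  if (!n_sites(m)) return(m)
  t <- site_tallies(m$dosages)
  n_missing <- nrow(m$dosages) - t$called
  mac <- pmin(t$a, t$n - t$a)
  maf <- ifelse(t$n > 0, mac / t$n, NA_real_)
  dep <- m$sites$mean_depth
  clauses <- cbind(
    missing = n_missing <= p$max_missing_count,
    alleles = m$sites$n_allele_obs <= p$max_alleles,
    mac = mac >= p$min_mac & t$n > 0,
    maf = !is.na(maf) & maf >= p$min_maf,
    depth = is.na(dep) | (dep >= p$min_mean_depth & dep <= p$max_mean_depth),
    indel = !(p$drop_indels & m$sites$site_class == "indel")
  )
  # a mac/maf threshold of 0 is "disabled": sites with no called genotypes
  # still fail the missing clause when it is active
  if (p$min_mac == 0L) clauses[, "mac"] <- TRUE
  if (p$min_maf == 0) clauses[, "maf"] <- TRUE
  keep <- rowSums(clauses) == ncol(clauses)
  out <- subset_sites(m, keep)
  attr(out, "clauses") <- clauses
  out
}

#' Split a cohort into invariant and variable parts
#'
#' Invariant sites have alternate allele frequency 0 among called genotypes
#' (including sites with no called genotype at all); the split is a disjoint,
#' exhaustive partition, inverted by [concat_sites()].
#'
#' @param m a [cohort_matrix()].
#' @return list with elements `invariant` and `variable`.
#' @export
split_sites <- function(m) {
  a <- site_tallies(m$dosages)$a
  list(invariant = subset_sites(m, a == 0L),
       variable = subset_sites(m, a > 0L))
}

#' Concatenate two cohorts over the same samples
#'
#' @param a,b cohort matrices with identical sample sets and disjoint
#'   (chrom, pos) sets.
#' @return a `cohort_matrix` with the union of sites, sorted by (chrom, pos).
#' @export
concat_sites <- function(a, b) {
  if (!setequal(cohort_samples(a), cohort_samples(b))) {
    stop("concat_sites: sample sets differ")
  }
  b <- subset_samples(b, cohort_samples(a))
  ka <- paste(a$sites$chrom, a$sites$pos)
  kb <- paste(b$sites$chrom, b$sites$pos)
  if (length(intersect(ka, kb))) {
    stop("concat_sites: duplicate positions: ",
         paste(utils::head(intersect(ka, kb), 3), collapse = "; "))
  }
  cohort_matrix(cbind(a$dosages, b$dosages), rbind(a$sites, b$sites),
                groups = a$groups)
}

#' Merge two cohorts over disjoint sample sets
#'
#' Site set is the union of positions; a sample's dosage at a position absent
#' from its source cohort is missing. Where both cohorts define a site, REF
#' must agree and ALT must agree when both are non-empty (an invariant record
#' in one cohort adopts the other's ALT).
#'
#' @param a,b cohort matrices with disjoint sample sets.
#' @return merged `cohort_matrix`.
#' @export
merge_cohorts <- function(a, b) {
  if (length(intersect(cohort_samples(a), cohort_samples(b)))) {
    stop("merge_cohorts: sample sets overlap")
  }
  if (!nrow(b$dosages)) return(a)
  if (!nrow(a$dosages)) return(b)
  ka <- paste(a$sites$chrom, a$sites$pos)
  kb <- paste(b$sites$chrom, b$sites$pos)
  keys <- union(ka, kb)
  ia <- match(keys, ka)
  ib <- match(keys, kb)
  both <- !is.na(ia) & !is.na(ib)
  if (any(both)) {
    ra <- a$sites$ref[ia[both]]; rb <- b$sites$ref[ib[both]]
    aa <- a$sites$alt[ia[both]]; ab <- b$sites$alt[ib[both]]
    conflict <- ra != rb | (nzchar(aa) & nzchar(ab) & aa != ab)
    if (any(conflict)) {
      stop("merge_cohorts: conflicting ref/alt at ",
           paste(utils::head(keys[both][conflict], 3), collapse = "; "))
    }
  }
  take <- function(x, idx, default = NA) {
    out <- rep(default, length(idx)); ok <- !is.na(idx)
    out[ok] <- x[idx[ok]]; out
  }
  alt <- ifelse(!is.na(ia) & nzchar(take(a$sites$alt, ia, "")),
                take(a$sites$alt, ia, ""), take(b$sites$alt, ib, ""))
  md_a <- take(a$sites$mean_depth, ia)
  md_b <- take(b$sites$mean_depth, ib)
  sites <- data.frame(
    chrom = ifelse(is.na(ia), take(b$sites$chrom, ib, ""), take(a$sites$chrom, ia, "")),
    pos = ifelse(is.na(ia), take(b$sites$pos, ib), take(a$sites$pos, ia)),
    id = ifelse(is.na(ia), take(b$sites$id, ib, ""), take(a$sites$id, ia, "")),
    ref = ifelse(is.na(ia), take(b$sites$ref, ib, ""), take(a$sites$ref, ia, "")),
    alt = alt,
    mean_depth = ifelse(is.na(md_a), md_b,
                        ifelse(is.na(md_b), md_a, (md_a + md_b) / 2)),
    stringsAsFactors = FALSE
  )
  dos <- rbind(
    a$dosages[, ia, drop = FALSE],
    b$dosages[, ib, drop = FALSE]
  )
  # columns where a (or b) lacks the site -> NA for those samples
  dos[seq_len(nrow(a$dosages)), is.na(ia)] <- NA_integer_
  dos[nrow(a$dosages) + seq_len(nrow(b$dosages)), is.na(ib)] <- NA_integer_
  rownames(dos) <- c(cohort_samples(a), cohort_samples(b))
  groups <- NULL
  if (!is.null(a$groups) && !is.null(b$groups)) groups <- c(a$groups, b$groups)
  cohort_matrix(dos, sites, groups = groups)
}

#' Restrict a cohort to sites inside genomic intervals
#'
#' A site at 1-based `pos` is retained iff `pos - 1` lies inside some 0-based
#' half-open interval on the same chromosome.
#'
#' @param m a [cohort_matrix()].
#' @param g a [genomic_intervals()] object.
#' @return a `cohort_matrix` with the retained sites.
#' @export
intersect_genic <- function(m, g) {
  if (!nrow(g) || !n_sites(m)) return(subset_sites(m, logical(n_sites(m))))
  keep <- logical(n_sites(m))
  for (ch in unique(m$sites$chrom)) {
    gi <- g[g$chrom == ch, , drop = FALSE]
    si <- which(m$sites$chrom == ch)
    if (!nrow(gi) || !length(si)) next
    pos0 <- m$sites$pos[si] - 1
    idx <- findInterval(pos0, gi$start)
    keep[si] <- idx > 0 & pos0 < gi$end[pmax(idx, 1L)]
  }
  subset_sites(m, keep)
}
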
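#' Classify novel alleles against a reference panel
#'
#' A site is eligible when every reference-panel individual (by default the
#' wild group plus the outgroup) is homozygous reference (dosage 0). At an
#' eligible site, each focal group is flagged when at least one member
#' carries the alternate allele (dosage 1 or 2). The input must be the
#' fully-called biallelic SNP matrix (the `"cohort67_novel"` filter preset);
#' any missing genotype is an error.
#'
#' @param m a fully-called [cohort_matrix()] with groups.
#' @param reference_groups groups forming the reference panel.
#' @param focal_groups groups to flag.
#' @return data.frame of eligible sites (site_id + one logical column per
#'   focal group), with attributes `n_sites_total` and `n_eligible` (both
#'   denominators used when reporting percentages).
#' @export
classify_novel <- function(m, reference_groups = c("wild", "outgroup"),
                           focal_groups = c("MK", "LR1", "LR2", "cultivar")) {
  if (anyNA(m$dosages)) {
    stop("classify_novel requires fully-called genotypes (apply the ",
         "max-missing-count 0 filter first)")
  }
  ref <- m$dosages[group_samples(m, reference_groups), , drop = FALSE]
  eligible <- colSums(ref > 0L) == 0L
  out <- data.frame(site_id = m$sites$id[eligible], stringsAsFactors = FALSE)
  for (g in focal_groups) {
    gd <- m$dosages[group_samples(m, g), eligible, drop = FALSE]
    out[[g]] <- colSums(gd > 0L) > 0L
  }
  attr(out, "n_sites_total") <- n_sites(m)
  attr(out, "n_eligible") <- sum(eligible)
  attr(out, "focal_groups") <- focal_groups
  out
}

#' Exact-subset overlap decomposition of novel-allele flags
#'
#' For every nonempty subset Z of the focal groups, counts the sites whose
#' flagged-group set equals Z exactly (UpSet semantics: subsets are disjoint
#' and sum to the total of flagged sites). Per-group marginal totals are also
#' reported.
#'
#' @param f output of [classify_novel()].
#' @return list: `subsets` (data.frame subset, count; groups joined by "+"),
#'   `marginals` (named vector), `total` flagged sites.
#' @export
overlap_decomposition <- function(f) {
  groups <- attr(f, "focal_groups")
  if (is.null(groups)) groups <- setdiff(names(f), "site_id")
  flags <- as.matrix(f[, groups, drop = FALSE])
  any_flag <- rowSums(flags) > 0
  key <- apply(flags[any_flag, , drop = FALSE], 1, function(z) {
    paste(groups[z], collapse = "+")
  })
  counts <- sort(table(key), decreasing = TRUE)
  subsets <- data.frame(subset = as.character(names(counts)),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  if (!length(counts)) {
    subsets <- data.frame(subset = character(0), count = integer(0),
                          stringsAsFactors = FALSE)
  }
  list(subsets = subsets,
       marginals = colSums(flags),
       total = sum(any_flag))
}
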
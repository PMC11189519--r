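#' Cohort genotype matrix
#'
#' The central in-memory container: an all-sites diploid dosage matrix
#' (samples x sites) plus per-site metadata and an optional sample-to-group
#' assignment. Dosage is the count of non-reference alleles in a genotype
#' (0, 1, 2) with `NA` for missing calls (including half-calls such as `0/.`).
#'
#' Site metadata columns:
#' \describe{
#'   \item{chrom}{chromosome identifier (subgenome-tagged, e.g. `"At_01"`)}
#'   \item{pos}{1-based position}
#'   \item{id}{site identifier (VCF ID column)}
#'   \item{ref}{reference allele}
#'   \item{alt}{comma-separated alternate alleles, `""` if none}
#'   \item{mean_depth}{mean per-sample depth, `NA` if unknown}
#'   \item{n_allele_obs}{number of distinct alleles observed in genotypes}
#'   \item{site_class}{one of `"invariant"`, `"snp"`, `"indel"`,
#'     `"multiallelic"`}
#' }
#'
#' Sites are stored sorted by (chrom, pos); duplicate (chrom, pos) pairs are
#' an error.
#'
#' @param dosages integer matrix, samples in rows (rownames required), sites
#'   in columns; values in `{0, 1, 2, NA}`.
#' @param sites data.frame with at least `chrom` and `pos`; missing metadata
#'   columns are filled with defaults derived from `dosages`.
#' @param groups named character vector mapping every sample to a group label,
#'   or `NULL`.
#' @return An object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(dosages, sites, groups = NULL) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages))) {
    if (nrow(dosages)) stop("dosages must have sample rownames")
    rownames(dosages) <- character(0)
  }
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    stop("sites needs 'chrom' and 'pos' columns")
  }
  if (nrow(sites) != ncol(dosages)) {
    stop("sites rows (", nrow(sites), ") != dosage columns (", ncol(dosages), ")")
  }
  if (any(sites$pos < 1)) stop("positions must be >= 1")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"

  n <- nrow(sites)
  if (is.null(sites$id)) {
    sites$id <- if (n) paste0(sites$chrom, "_", sites$pos) else character(0)
  }
  if (is.null(sites$ref)) sites$ref <- rep("A", n)
  if (is.null(sites$alt)) sites$alt <- rep("T", n)
  if (is.null(sites$mean_depth)) sites$mean_depth <- rep(NA_real_, n)
  alt_obs <- colSums(dosages > 0L, na.rm = TRUE) > 0L
  ref_obs <- colSums(dosages < 2L, na.rm = TRUE) > 0L
  n_alts <- ifelse(is.na(sites$alt) | sites$alt == "" | sites$alt == ".",
                   0L, lengths(strsplit(sites$alt, ",", fixed = TRUE)))
  if (is.null(sites$n_allele_obs)) {
    sites$n_allele_obs <- as.integer(ref_obs) + ifelse(alt_obs, pmax(n_alts, 1L), 0L)
  }
  if (is.null(sites$site_class)) {
    sites$site_class <- classify_sites(sites, alt_obs)
  }
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) in sites")
  }
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- sites$id

  if (!is.null(groups)) {
    groups <- validate_groups(groups, rownames(dosages))
  }
  structure(list(dosages = dosages, sites = sites, groups = groups),
            class = "cohort_matrix")
}

# Assign a site class from allele strings and observed-alt flags.
# Precedence: invariant (no alt observed in genotypes) > indel (any allele
# length != 1) > multiallelic (>2 distinct observed alleles) > snp.
classify_sites <- function(sites, alt_obs) {
  n <- nrow(sites)
  if (!n) return(character(0))
  alt_list <- strsplit(ifelse(is.na(sites$alt) | sites$alt == ".", "", sites$alt),
                       ",", fixed = TRUE)
  any_len_ne1 <- mapply(function(r, a) {
    alleles <- c(r, a[nzchar(a) & a != "."])
    any(nchar(alleles) != 1L & !grepl("^<", alleles))
  }, sites$ref, alt_list, USE.NAMES = FALSE)
  cls <- rep("snp", n)
  cls[sites$n_allele_obs > 2L] <- "multiallelic"
  cls[any_len_ne1] <- "indel"
  cls[!alt_obs] <- "invariant"
  cls
}

validate_groups <- function(groups, samples) {
  groups <- groups[samples]
  if (any(is.na(groups)) || is.null(names(groups))) {
    missing <- samples[is.na(groups)]
    stop("samples without group assignment: ", paste(missing, collapse = ", "))
  }
  names(groups) <- samples
  groups
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages), "sites\n")
  if (ncol(x$dosages)) {
    tab <- table(x$sites$site_class)
    cat("  site classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Samples, sites and group helpers
#' @param m a [cohort_matrix()].
#' @return `cohort_samples`: character vector of sample names.
#' @export
cohort_samples <- function(m) rownames(m$dosages)

#' @rdname cohort_samples
#' @export
n_sites <- function(m) ncol(m$dosages)

#' @rdname cohort_samples
#' @param group group label (or vector of labels).
#' @return `group_samples`: sample names belonging to `group`.
#' @export
group_samples <- function(m, group) {
  if (is.null(m$groups)) stop("cohort has no group assignment")
  out <- names(m$groups)[m$groups %in% group]
  if (!length(out)) stop("no samples in group(s): ", paste(group, collapse = ","))
  out
}

#' Subset a cohort by site index or by sample name
#' @param m a [cohort_matrix()].
#' @param idx logical or integer index over sites (in stored order).
#' @return a `cohort_matrix` with the selected sites (order preserved).
#' @export
subset_sites <- function(m, idx) {
  m$dosages <- m$dosages[, idx, drop = FALSE]
  m$sites <- m$sites[idx, , drop = FALSE]
  rownames(m$sites) <- NULL
  m
}

#' @rdname subset_sites
#' @param samples character vector of sample names to keep.
#' @export
subset_samples <- function(m, samples) {
  stopifnot(all(samples %in% rownames(m$dosages)))
  m$dosages <- m$dosages[samples, , drop = FALSE]
  if (!is.null(m$groups)) m$groups <- m$groups[samples]
  m
}

# dosage submatrix for one group (samples x sites)
group_dosages <- function(m, group) {
  m$dosages[group_samples(m, group), , drop = FALSE]
}

# per-site allele tallies for a set of samples:
#   called (diploid genotypes), n (called alleles), a (alt allele count)
site_tallies <- function(dos) {
  called <- colSums(!is.na(dos))
  list(called = called,
       n = 2L * called,
       a = colSums(dos, na.rm = TRUE))
}
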
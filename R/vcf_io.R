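#' Read an all-sites VCF into a cohort matrix
#'
#' Parses a VCF 4.x file (plain or bgzip-compressed) containing both variant
#' and invariant records. Diploid GT is required; `./.` and half-calls
#' (`0/.`) become missing. Dosage is the number of non-reference alleles.
#' Mean per-site depth is taken from the mean of FORMAT/DP when present,
#' else INFO/MEANDP (written by [write_vcf()]), else INFO/DP divided by the
#' sample count; sites without any depth annotation get `NA` (treated as
#' passing depth filters, see [filter_sites()]).
#'
#' @param path VCF file path.
#' @param groups optional named character vector or 2-column TSV path with a
#'   sample-to-group assignment.
#' @return a [cohort_matrix()].
#' @export
read_vcf <- function(path, groups = NULL) {
  v <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("VCF parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  samples <- colnames(gt)
  nsite <- nrow(gt)

  # decode genotype strings once per distinct string
  uniq <- unique(as.vector(gt))
  dec <- vapply(uniq, decode_gt, numeric(1))
  dos <- matrix(dec[match(as.vector(gt), uniq)], nrow = nsite,
                ncol = length(samples))
  dos <- t(dos)  # samples x sites
  rownames(dos) <- samples
  storage.mode(dos) <- "integer"

  rr <- SummarizedExperiment::rowRanges(v)
  alt_list <- VariantAnnotation::alt(v)
  alt_chr <- vapply(as(alt_list, "CharacterList"), function(a) {
    a <- a[!is.na(a) & nzchar(a) & a != "."]
    paste(a, collapse = ",")
  }, character(1))

  # distinct observed alleles per site, from the raw GT allele indices
  n_obs <- n_alleles_observed(gt)

  mean_depth <- rep(NA_real_, nsite)
  dp <- VariantAnnotation::geno(v)$DP
  if (!is.null(dp)) {
    suppressWarnings(storage.mode(dp) <- "double")
    mean_depth <- rowMeans(dp, na.rm = TRUE)
    mean_depth[is.nan(mean_depth)] <- NA_real_
  } else {
    info <- VariantAnnotation::info(v)
    if (!is.null(info$MEANDP)) {
      mean_depth <- as.numeric(info$MEANDP)
    } else if (!is.null(info$DP)) {
      mean_depth <- as.numeric(info$DP) / length(samples)
    }
  }

  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = if (is.null(names(rr))) paste0("site", seq_len(nsite)) else names(rr),
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt_chr,
    mean_depth = mean_depth,
    n_allele_obs = n_obs,
    stringsAsFactors = FALSE
  )
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- read_groups(groups)
  }
  cohort_matrix(dos, sites, groups = groups)
}

# GT string -> dosage; NA for missing/half calls; error on ploidy != 2
decode_gt <- function(g) {
  if (is.na(g) || g == "." || g == "./." || g == ".|.") return(NA_real_)
  a <- strsplit(g, "[/|]")[[1]]
  if (length(a) != 2L) {
    stop("unsupported ploidy in genotype '", g, "' (diploid GT required)",
         call. = FALSE)
  }
  if (any(a == ".")) return(NA_real_)
  sum(as.integer(a) > 0L)
}

n_alleles_observed <- function(gt) {
  nsite <- nrow(gt)
  out <- integer(nsite)
  for (i in seq_len(nsite)) {
    al <- unlist(strsplit(gt[i, ], "[/|]"), use.names = FALSE)
    al <- al[al != "." & !is.na(al)]
    out[i] <- length(unique(al))
  }
  out
}

#' Write a cohort matrix as a VCF 4.2 file
#'
#' Emits one record per site with GT per sample; invariant sites carry `.` in
#' ALT. Mean depth, when known, is stored as the Float INFO field `MEANDP`
#' so that [read_vcf()] round-trips it. Missing dosages are written `./.`.
#' At multiallelic sites a dosage of 2 is serialized `1/2` so that the
#' observed-allele count survives the round trip.
#'
#' @param m a [cohort_matrix()].
#' @param path output path (`.vcf`; plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- cohort_samples(m)
  chroms <- unique(m$sites$chrom)
  lens <- vapply(chroms, function(ch) {
    lay <- attr(m, "layout")
    if (!is.null(lay) && ch %in% names(lay)) lay[[ch]]
    else max(m$sites$pos[m$sites$chrom == ch], 1L)
  }, numeric(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(lens)),
    "##INFO=<ID=MEANDP,Number=1,Type=Float,Description=\"Mean per-sample depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  if (n_sites(m)) {
    multi <- m$sites$n_allele_obs > 2L
    gt <- apply_gt_strings(m$dosages, multi)
    info <- ifelse(is.na(m$sites$mean_depth), ".",
                   paste0("MEANDP=", format(m$sites$mean_depth, digits = 15,
                                            scientific = FALSE, trim = TRUE)))
    alt <- ifelse(m$sites$alt == "" | is.na(m$sites$alt), ".", m$sites$alt)
    lines <- paste(m$sites$chrom, m$sites$pos, m$sites$id, m$sites$ref, alt,
                   ".", "PASS", info, "GT", gt, sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

apply_gt_strings <- function(dos, multi) {
  n <- ncol(dos)
  out <- character(n)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(n)) {
    d <- dos[, j]
    g <- code[as.character(d)]
    g[is.na(d)] <- "./."
    if (multi[j]) g[!is.na(d) & d == 2L] <- "1/2"
    out[j] <- paste(g, collapse = "\t")
  }
  out
}

#' Read / write a sample-to-group assignment table
#'
#' Two-column tab-separated file: sample, group. No header.
#' @param path TSV path.
#' @return named character vector (names = samples).
#' @export
read_groups <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("sample", "group"))
  stats::setNames(d$group, d$sample)
}

#' @rdname read_groups
#' @param groups named character vector.
#' @export
write_groups <- function(groups, path) {
  utils::write.table(data.frame(names(groups), unname(groups)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Genomic intervals (BED convention)
#'
#' 0-based half-open intervals; normalization sorts and merges overlapping or
#' bookended intervals per chromosome. VCF positions are 1-based: a site at
#' `pos` falls in an interval iff `start <= pos - 1 < end`.
#'
#' @param chrom,start,end equal-length vectors.
#' @return data.frame of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start >= end)) stop("intervals need start < end")
  d <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
  out <- do.call(rbind, lapply(split(d, d$chrom), function(x) {
    if (nrow(x) <= 1L) return(x)
    keep <- x[1, ]
    for (i in 2:nrow(x)) {
      last <- nrow(keep)
      if (x$start[i] <= keep$end[last]) {
        keep$end[last] <- max(keep$end[last], x$end[i])
      } else {
        keep <- rbind(keep, x[i, ])
      }
    }
    keep
  }))
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' @rdname genomic_intervals
#' @param path 3-column BED file.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[, 1:3]
  genomic_intervals(d[[1]], d[[2]], d[[3]])
}
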
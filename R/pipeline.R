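#' Pipeline run configuration
#'
#' A flat key-value configuration for the end-to-end workflow. Two canonical
#' shapes exist: the ingroup analysis chain over the combined (variant +
#' invariant) cohort VCF -- filter, genic extraction, LD pruning, PCA/NJ
#' structure, windowed diversity, LD decay, SFS/Tajima -- and the
#' outgroup-merged novel-allele run. Stage parameters default to the standard
#' preset values (see [filter_params()] and each stage function).
#'
#' @param vcf input all-sites VCF path.
#' @param groups sample-to-group TSV path or named vector.
#' @param out_dir output directory (created if needed).
#' @param bed optional BED path of genic intervals.
#' @param stages character vector of stages to run, a subset of
#'   `c("filter", "genic", "prune", "structure", "diversity", "ld",
#'   "neutrality", "novel")`.
#' @param params named list overriding stage parameters: `window_bp`,
#'   `tajima_window_bp`, `tajima_step_bp`, `max_dist`, `bin_width`,
#'   `window_snps`, `step_snps`, `r2_max`, `n_components`, `outgroup`,
#'   `reference_groups`, `focal_groups`, `pi_groups`, `pair_groups`,
#'   `neutrality_group`, `ld_group`, `filter` (a [filter_params()]).
#' @param seed integer seed for stages with randomness.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, groups, out_dir, bed = NULL,
                       stages = c("filter", "diversity", "neutrality"),
                       params = list(), seed = 1) {
  if (!file.exists(vcf)) stop("input VCF not found: ", vcf)
  if (is.character(groups) && length(groups) == 1L) {
    if (!file.exists(groups)) stop("groups file not found: ", groups)
  }
  if (!is.null(bed) && !file.exists(bed)) stop("BED file not found: ", bed)
  defaults <- list(
    window_bp = 10000, tajima_window_bp = 50000, tajima_step_bp = 10000,
    max_dist = 500000, bin_width = 1000, window_snps = 50, step_snps = 10,
    r2_max = 0.1, n_components = 20, outgroup = "outgroup",
    reference_groups = c("wild", "outgroup"),
    focal_groups = c("MK", "LR1", "LR2", "cultivar"),
    pi_groups = NULL, pair_groups = NULL, neutrality_group = "MK",
    ld_group = NULL, filter = filter_params()
  )
  defaults[names(params)] <- params
  structure(list(vcf = vcf, groups = groups, out_dir = out_dir, bed = bed,
                 stages = stages, params = defaults, seed = seed),
            class = "run_config")
}

#' Run the pipeline
#'
#' Stages run in dependency order; each stage writes parameter-stamped TSV
#' outputs into `out_dir` and one structured log line with site/sample counts
#' at entry and exit. A stage whose outputs already exist is skipped, so
#' deleting an intermediate recomputes only that stage onward. Re-running an
#' unchanged config reproduces identical outputs.
#'
#' @param cfg a [run_config()].
#' @return data.frame manifest: stage, outputs, md5, n_sites_in, n_sites_out,
#'   seconds.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  manifest <- list()
  log_stage <- function(stage, files, n_in, n_out, secs) {
    message(sprintf("[%s] sites %d -> %d (%.2fs): %s", stage, n_in, n_out,
                    secs, paste(basename(files), collapse = ", ")))
    manifest[[stage]] <<- data.frame(
      stage = stage, outputs = paste(basename(files), collapse = ";"),
      md5 = paste(tools::md5sum(files), collapse = ";"),
      n_sites_in = n_in, n_sites_out = n_out, seconds = round(secs, 3),
      stringsAsFactors = FALSE)
  }
  outfile <- function(name) file.path(cfg$out_dir, name)
  write_tsv <- function(d, path, header_params = NULL) {
    con <- file(path, "w")
    if (!is.null(header_params)) {
      writeLines(paste0("# ", paste(names(header_params), header_params,
                                    sep = "=", collapse = " ")), con)
    }
    suppressWarnings(utils::write.table(d, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    path
  }

  m <- read_vcf(cfg$vcf, groups = cfg$groups)
  groups <- unique(m$groups)

  combined <- m
  snps <- NULL
  stage_files <- list(
    filter = "filtered_snps.vcf", genic = "genic_snps.vcf",
    prune = "pruned.vcf")

  if ("filter" %in% cfg$stages) {
    f <- outfile(stage_files$filter)
    t0 <- proc.time()[3]
    if (file.exists(f)) {
      snps <- read_vcf(f, groups = cfg$groups)
      message("[filter] outputs exist, skipped")
    } else {
      parts <- split_sites(m)
      snps <- filter_sites(parts$variable, p$filter)
      inv <- filter_sites(parts$invariant,
                          filter_params(max_missing_count = nrow(m$dosages),
                                        max_alleles = 99, min_mac = 0,
                                        min_maf = 0,
                                        min_mean_depth = p$filter$min_mean_depth,
                                        max_mean_depth = p$filter$max_mean_depth))
      combined <- concat_sites(inv, snps)
      write_vcf(snps, f)
      log_stage("filter", f, n_sites(m), n_sites(snps), proc.time()[3] - t0)
    }
  } else snps <- split_sites(m)$variable

  genic <- snps
  if ("genic" %in% cfg$stages && !is.null(cfg$bed)) {
    f <- outfile(stage_files$genic)
    t0 <- proc.time()[3]
    genic <- intersect_genic(snps, read_bed(cfg$bed))
    write_vcf(genic, f)
    log_stage("genic", f, n_sites(snps), n_sites(genic), proc.time()[3] - t0)
  }

  pruned <- genic
  if ("prune" %in% cfg$stages) {
    f <- outfile(stage_files$prune)
    kf <- outfile("prune_kept.txt"); rf <- outfile("prune_removed.txt")
    t0 <- proc.time()[3]
    full <- subset_sites(genic, colSums(is.na(genic$dosages)) == 0L)
    pruned <- ld_prune(full, window_snps = p$window_snps,
                       step_snps = p$step_snps, r2_max = p$r2_max)
    write_vcf(pruned, f)
    writeLines(attr(pruned, "kept"), kf)
    writeLines(attr(pruned, "removed"), rf)
    log_stage("prune", c(f, kf, rf), n_sites(full), n_sites(pruned),
              proc.time()[3] - t0)
  }

  if ("structure" %in% cfg$stages) {
    fp <- outfile("pca.tsv"); ft <- outfile("nj.nwk")
    t0 <- proc.time()[3]
    pca <- pca_genotypes(pruned, n_components = p$n_components)
    d <- data.frame(sample = rownames(pca$coords), pca$coords,
                    check.names = FALSE)
    write_tsv(d, fp, header_params = list(
      pct_variance = paste(round(pca$pct_variance, 3), collapse = ",")))
    tr <- nj_tree(ibs_distance(pruned))
    og <- intersect(p$outgroup, unique(m$groups))
    if (length(og)) {
      tr <- tryCatch(root_with_outgroup(tr, group_samples(m, og)),
                     error = function(e) tr)
    }
    write_newick(tr, ft)
    log_stage("structure", c(fp, ft), n_sites(pruned), n_sites(pruned),
              proc.time()[3] - t0)
  }

  if ("diversity" %in% cfg$stages) {
    t0 <- proc.time()[3]
    pig <- if (is.null(p$pi_groups)) groups else p$pi_groups
    files <- character(0)
    for (g in pig) {
      w <- pi_windows(combined, g, window_bp = p$window_bp)
      files <- c(files, write_tsv(w, outfile(paste0("pi_", g, ".tsv")),
                                  list(stat = "pi", group = g,
                                       window_bp = p$window_bp)))
    }
    pairs <- p$pair_groups
    if (is.null(pairs) && length(pig) > 1) {
      pairs <- utils::combn(pig, 2, simplify = FALSE)
    }
    for (pr in pairs) {
      wd <- dxy_windows(combined, pr[1], pr[2], window_bp = p$window_bp)
      wf <- fst_windows(combined, pr[1], pr[2], window_bp = p$window_bp)
      tag <- paste(pr, collapse = "_")
      files <- c(files,
                 write_tsv(wd, outfile(paste0("dxy_", tag, ".tsv")),
                           list(stat = "dxy", window_bp = p$window_bp)),
                 write_tsv(wf, outfile(paste0("fst_", tag, ".tsv")),
                           list(stat = "fst", window_bp = p$window_bp)))
    }
    het <- het_fis(snps)
    files <- c(files, write_tsv(het, outfile("het_fis.tsv")),
               write_tsv(group_het_summary(het), outfile("het_groups.tsv")))
    log_stage("diversity", files, n_sites(combined), n_sites(combined),
              proc.time()[3] - t0)
  }

  if ("ld" %in% cfg$stages) {
    t0 <- proc.time()[3]
    g <- if (is.null(p$ld_group)) groups[1] else p$ld_group
    pr <- pairwise_r2(snps, group = g, max_dist = p$max_dist)
    cv <- decay_curve(pr, bin_width = p$bin_width)
    f <- write_tsv(cv, outfile(paste0("ld_decay_", g, ".tsv")),
                   list(group = g, max_dist = p$max_dist,
                        bin_width = p$bin_width))
    log_stage("ld", f, n_sites(snps), nrow(pr), proc.time()[3] - t0)
  }

  if ("neutrality" %in% cfg$stages) {
    t0 <- proc.time()[3]
    g <- p$neutrality_group
    if (g %in% groups) {
      sfs <- folded_sfs(snps, g)
      fs <- write_tsv(data.frame(minor_count = names(sfs$bins),
                                 n_sites = as.integer(sfs$bins)),
                      outfile(paste0("sfs_", g, ".tsv")),
                      list(group = g, n_alleles = sfs$n_alleles))
      tw <- tajima_windows(combined, g, window_bp = p$tajima_window_bp,
                           step_bp = p$tajima_step_bp)
      ft <- write_tsv(tw, outfile(paste0("tajima_", g, ".tsv")),
                      list(group = g, window_bp = p$tajima_window_bp,
                           step_bp = p$tajima_step_bp))
      log_stage("neutrality", c(fs, ft), n_sites(combined), nrow(tw),
                proc.time()[3] - t0)
    }
  }

  if ("novel" %in% cfg$stages) {
    t0 <- proc.time()[3]
    full <- subset_sites(snps, colSums(is.na(snps$dosages)) == 0L)
    flags <- classify_novel(full, reference_groups = p$reference_groups,
                            focal_groups = intersect(p$focal_groups, groups))
    dec <- overlap_decomposition(flags)
    f1 <- write_tsv(flags, outfile("novel_flags.tsv"),
                    list(n_sites_total = attr(flags, "n_sites_total"),
                         n_eligible = attr(flags, "n_eligible")))
    f2 <- write_tsv(dec$subsets, outfile("novel_overlaps.tsv"),
                    list(total = dec$total))
    log_stage("novel", c(f1, f2), n_sites(full), dec$total,
              proc.time()[3] - t0)
  }

  out <- do.call(rbind, manifest)
  if (!is.null(out)) rownames(out) <- NULL
  utils::write.table(out, outfile("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a flat key=value config file into a run_config
#'
#' Lines of the form `key = value`; `#` comments allowed. Recognized keys:
#' vcf, groups, out_dir, bed, stages (comma-separated), seed, plus any stage
#' parameter from [run_config()] (comma-separated vectors allowed).
#'
#' @param path config file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="),
                        character(1)))
  conf <- stats::setNames(as.list(vals), keys)
  split_val <- function(x) {
    v <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    n <- suppressWarnings(as.numeric(v))
    if (!anyNA(n)) n else v
  }
  main <- c("vcf", "groups", "out_dir", "bed", "stages", "seed")
  params <- lapply(conf[setdiff(names(conf), main)], split_val)
  run_config(
    vcf = conf$vcf, groups = conf$groups, out_dir = conf$out_dir,
    bed = conf$bed,
    stages = if (is.null(conf$stages)) c("filter", "diversity", "neutrality")
    else split_val(conf$stages),
    params = params,
    seed = if (is.null(conf$seed)) 1L else as.integer(conf$seed)
  )
}
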
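#' Population specification for the demography model
#'
#' Ne trajectories are piecewise constant in generations before present
#' (tbp). `epochs` is a data.frame with strictly decreasing `time` and
#' diploid `ne`; `Ne(tbp)` is the `ne` of the last epoch whose `time >= tbp`.
#' Root populations use `time = Inf` for their first epoch; a daughter
#' population's first epoch time is its split time.
#'
#' @param name population label (used as the group label of emitted samples).
#' @param epochs data.frame(time, ne).
#' @param selfing per-generation selfing probability in \[0, 1\].
#' @param parent name of the parent population (`NA` for a root).
#' @param split_time generations before present at which the population
#'   splits off (`NA` for a root).
#' @return list of class `pop_spec`.
#' @export
pop_spec <- function(name, epochs, selfing = 0, parent = NA, split_time = NA) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(diff(epochs$time) < 0), all(epochs$ne >= 2),
            selfing >= 0, selfing <= 1)
  if (is.na(split_time) && !is.infinite(epochs$time[1])) {
    stop("root population needs epochs$time[1] = Inf")
  }
  structure(list(name = name, epochs = epochs, selfing = selfing,
                 parent = parent, split_time = split_time),
            class = "pop_spec")
}

#' Demography model for the forward simulator
#'
#' @param pops list of [pop_spec()] objects.
#' @param mu per-site per-generation mutation rate. Desk-scale presets use
#'   values around 1e-4 (the study-scale rate, 4.56e-9/site/year with 1-year
#'   generations, is preserved through 4*Ne*mu by shrinking Ne and times by
#'   the same factor).
#' @param recomb_rate per-site per-generation crossover probability.
#' @param migration optional P x P row-stochastic matrix of source-deme
#'   probabilities (dimnames = population names); `NULL` means no migration.
#' @param generation_time generation time in years (bookkeeping only).
#' @param burn_factor burn-in length as a multiple of the largest root Ne
#'   (>= 10 per the simulator contract).
#' @return list of class `demography_model`.
#' @export
demography_model <- function(pops, mu, recomb_rate, migration = NULL,
                             generation_time = 1, burn_factor = 10) {
  stopifnot(burn_factor >= 10, mu >= 0, mu <= 1, recomb_rate >= 0,
            recomb_rate <= 1)
  names(pops) <- vapply(pops, function(p) p$name, character(1))
  for (p in pops) {
    if (!is.na(p$parent) && !p$parent %in% names(pops)) {
      stop("unknown parent population: ", p$parent)
    }
  }
  if (!is.null(migration)) {
    stopifnot(nrow(migration) == length(pops),
              all(abs(rowSums(migration) - 1) < 1e-9))
  }
  structure(list(pops = pops, mu = mu, recomb_rate = recomb_rate,
                 migration = migration, generation_time = generation_time,
                 burn_factor = burn_factor),
            class = "demography_model")
}

ne_at <- function(spec, tbp) {
  idx <- vapply(tbp, function(t) {
    ok <- which(spec$epochs$time >= t)
    if (!length(ok)) NA_integer_ else max(ok)
  }, integer(1))
  out <- spec$epochs$ne[idx]
  out[is.na(idx)] <- 0L
  as.integer(out)
}

#' Forward Wright-Fisher simulation
#'
#' Discrete generations from a burn-in of `burn_factor * Ne` generations
#' before the oldest demographic event; random mating with per-population
#' selfing probability; Poisson(mu * L) infinite-sites mutations on a
#' continuous position line; Poisson(recomb_rate * L) crossovers per meiosis;
#' individuals sampled without replacement at present with their two
#' haplotypes kept paired (so selfing-induced homozygosity survives into
#' [draw_diploids()]). Fixed seeds give identical output.
#'
#' @param d a [demography_model()].
#' @param L sequence length (bp).
#' @param n_sample named vector of haplotype counts per population (even;
#'   2 x the number of individuals). Populations absent from `n_sample`
#'   contribute no samples.
#' @param seed integer seed.
#' @return list of class `sim_result`: `positions` (continuous, sorted,
#'   unique), `geno` (haplotypes x sites 0/1), `hap_pop` (population label
#'   per haplotype), `truth` (theta and expected F_IS per population, seed,
#'   rates), `L`, `model`.
#' @export
simulate_wf <- function(d, L, n_sample, seed = 1) {
  stopifnot(inherits(d, "demography_model"), L > 0)
  pops <- d$pops
  P <- length(pops)
  max_ne <- max(vapply(pops, function(p) max(p$epochs$ne), numeric(1)))
  if (4 * max_ne * d$mu > 0.25) {
    stop("4*Ne*mu = ", 4 * max_ne * d$mu,
         " too large for infinite-sites bookkeeping (<= 0.25 required)")
  }
  root_ne <- max(vapply(pops, function(p)
    if (is.na(p$parent)) p$epochs$ne[1] else 0, numeric(1)))
  finite_times <- unlist(lapply(pops, function(p)
    c(p$split_time, p$epochs$time[is.finite(p$epochs$time)])))
  t_oldest <- if (length(finite_times) && any(!is.na(finite_times)))
    max(finite_times, na.rm = TRUE) else 0
  G <- as.integer(d$burn_factor * root_ne + t_oldest + 1)

  tbp <- (G - 1):0
  ne <- sapply(pops, function(p) {
    v <- ne_at(p, tbp)
    if (!is.na(p$split_time)) v[tbp >= p$split_time] <- 0L
    v
  })
  ne <- matrix(as.integer(ne), nrow = G, ncol = P)
  parent <- vapply(pops, function(p) {
    if (is.na(p$parent)) -1L else match(p$parent, names(pops)) - 1L
  }, integer(1))
  selfing <- vapply(pops, function(p) p$selfing, numeric(1))
  mig <- if (is.null(d$migration)) diag(P) else
    as.matrix(d$migration[names(pops), names(pops)])

  ns <- stats::setNames(integer(P), names(pops))
  ns[names(n_sample)] <- as.integer(n_sample)
  if (any(ns %% 2L != 0L)) stop("n_sample must be even haplotype counts")
  present <- ne[G, ]
  if (any(ns / 2 > present)) {
    stop("n_sample exceeds 2*Ne at present for: ",
         paste(names(pops)[ns / 2 > present], collapse = ", "))
  }

  set.seed(seed)
  raw <- wf_sim_cpp(ne, parent, selfing, mig, d$mu * L, d$recomb_rate * L, L,
                    as.integer(ns / 2L), purge_every = 20L)
  hap_pop <- names(pops)[raw$hap_pop + 1L]
  truth <- list(
    seed = seed, mu = d$mu, recomb_rate = d$recomb_rate, L = L,
    generations = G,
    theta = stats::setNames(4 * present * d$mu, names(pops)),
    selfing = selfing,
    fis_expected = stats::setNames(selfing / (2 - selfing), names(pops)),
    n_mutation_sites = length(raw$positions)
  )
  structure(list(positions = raw$positions, geno = raw$geno,
                 hap_pop = hap_pop, truth = truth, L = L, model = d),
            class = "sim_result")
}

#' Two-subgenome genome layout
#'
#' Splits a total length `L` into one "At" and one "Dt" chromosome with
#' length ratio approximately 1.6 (the allopolyploid cotton subgenome ratio).
#'
#' @param L total length in bp.
#' @return named numeric vector of chromosome lengths.
#' @export
at_dt_layout <- function(L) {
  la <- round(L * 1.6 / 2.6)
  c(At_1 = la, Dt_1 = L - la)
}

#' Pair sampled haplotypes into a diploid cohort matrix
#'
#' Consecutive haplotypes belong to the same simulated individual and are
#' kept together, preserving selfing-induced homozygosity. Continuous
#' positions are mapped onto the two-subgenome layout and discretized to
#' unique integer positions (collisions pushed to the next free base).
#' Ancestral allele = REF. Optionally materializes invariant records across
#' the full layout, injects missing genotypes, and simulates a Poisson
#' per-site mean depth so depth filters have teeth.
#'
#' @param s a [simulate_wf()] result.
#' @param pairing_seed seed for missingness/depth injection.
#' @param include_invariant materialize invariant sites over the layout
#'   (required for pi/dxy denominators).
#' @param missing_rate per-genotype missing probability.
#' @param depth_mean target mean depth (`NA` = no depth field).
#' @param layout named chromosome lengths, default [at_dt_layout()].
#' @return a [cohort_matrix()] with groups = population labels and attribute
#'   `"truth"` carried over.
#' @export
draw_diploids <- function(s, pairing_seed = 1, include_invariant = TRUE,
                          missing_rate = 0, depth_mean = NA,
                          layout = at_dt_layout(s$L)) {
  stopifnot(inherits(s, "sim_result"))
  H <- nrow(s$geno)
  if (H %% 2L) stop("odd haplotype count")
  n_ind <- H / 2L
  dos <- s$geno[seq(1, H, by = 2), , drop = FALSE] +
    s$geno[seq(2, H, by = 2), , drop = FALSE]
  pop <- s$hap_pop[seq(1, H, by = 2)]
  counts <- stats::setNames(rep(0L, 0), character(0))
  nm <- character(n_ind)
  for (i in seq_len(n_ind)) {
    counts[pop[i]] <- if (is.na(counts[pop[i]])) 1L else counts[pop[i]] + 1L
    nm[i] <- sprintf("%s_%02d", pop[i], counts[pop[i]])
  }
  rownames(dos) <- nm

  map <- map_positions(s$positions, layout)
  sites <- data.frame(chrom = map$chrom, pos = map$pos,
                      id = paste0(map$chrom, "_", map$pos),
                      ref = "A", alt = "T", stringsAsFactors = FALSE)

  if (include_invariant) {
    inv <- do.call(rbind, lapply(names(layout), function(ch) {
      allpos <- seq_len(layout[[ch]])
      used <- map$pos[map$chrom == ch]
      keep <- setdiff(allpos, used)
      data.frame(chrom = ch, pos = keep, id = paste0(ch, "_", keep),
                 ref = "A", alt = "", stringsAsFactors = FALSE)
    }))
    sites <- rbind(sites, inv)
    dos <- cbind(dos, matrix(0L, n_ind, nrow(inv)))
  }

  set.seed(pairing_seed)
  if (!is.na(depth_mean)) {
    sites$mean_depth <- stats::rpois(nrow(sites), depth_mean)
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(dos)) < missing_rate
    dos[drop] <- NA_integer_
  }
  m <- cohort_matrix(dos, sites, groups = stats::setNames(pop, nm))
  attr(m, "truth") <- s$truth
  attr(m, "layout") <- layout
  m
}

# map continuous [0, L) positions to per-chromosome unique integer positions
map_positions <- function(positions, layout) {
  bounds <- cumsum(c(0, layout))
  chrom_idx <- findInterval(positions, bounds, rightmost.closed = TRUE)
  chrom_idx <- pmin(pmax(chrom_idx, 1L), length(layout))
  chrom <- names(layout)[chrom_idx]
  pos <- integer(length(positions))
  for (k in seq_along(layout)) {
    i <- which(chrom_idx == k)
    if (!length(i)) next
    if (length(i) > layout[[k]]) {
      stop("too many mutations for chromosome ", names(layout)[k])
    }
    raw <- floor(positions[i] - bounds[k]) + 1
    for (j in seq_along(raw)) {       # positions sorted; push collisions right
      if (j > 1 && raw[j] <= raw[j - 1]) raw[j] <- raw[j - 1] + 1
    }
    if (raw[length(raw)] > layout[[k]]) {  # pull the overflowing tail back
      raw[length(raw)] <- layout[[k]]
      for (j in rev(seq_along(raw))[-1]) {
        if (raw[j] >= raw[j + 1]) raw[j] <- raw[j + 1] - 1
      }
    }
    pos[i] <- raw
  }
  list(chrom = chrom, pos = as.integer(pos))
}

#' Emit a simulated cohort as an all-sites VCF plus group table
#'
#' @param m a [cohort_matrix()] from [draw_diploids()].
#' @param path VCF output path.
#' @param groups_path optional TSV path for the sample-to-group table.
#' @return `path`, invisibly.
#' @export
emit_cohort_vcf <- function(m, path, groups_path = NULL) {
  write_vcf(m, path)
  if (!is.null(groups_path)) write_groups(m$groups, groups_path)
  invisible(path)
}

#' Built-in demography presets
#'
#' Desk-scaled scenarios (Ne <= 500; mutation and recombination inflated to
#' preserve 4\*Ne\*mu and 4\*Ne\*r) with the statistical structure the
#' analyses assume:
#' \describe{
#'   \item{neutral_equilibrium}{one panmictic deme, N = 100, mu = r =
#'     2.5e-4: theta = 0.1/site, E\[Tajima's D\] = 0.}
#'   \item{two_deme_island}{two demes of N = 100 exchanging migrants;
#'     `Nm` is the island-model effective migrant number: pairwise migration
#'     is set to `Nm/(2N)` so that E\[WC Fst\] = 1/(1 + 4Nm) (two demes double
#'     the pairwise rate relative to the infinite-island pool; see the
#'     methods vignette for the coalescent argument).}
#'   \item{domestication_series}{the full six-group cohort: wild (root),
#'     a deep outgroup, an isolated MK deme, two landrace bottlenecks and a
#'     second cultivar bottleneck, with partial selfing throughout -- diversity
#'     ordering wild > landraces > cultivar.}
#'   \item{island_relict}{one isolated deme with a crash 100 generations
#'     back, re-expansion 30 back and a recent decline (the study-scale
#'     crash ~10,000 and expansion ~3,000 generations ago shrunk 100x):
#'     negative Tajima's D and a singleton-enriched folded SFS.}
#' }
#'
#' @param name preset name.
#' @param Nm effective migrant number (two_deme_island only).
#' @return a [demography_model()].
#' @export
preset_scenario <- function(name = c("neutral_equilibrium", "two_deme_island",
                                     "domestication_series", "island_relict"),
                            Nm = 1) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown preset '", name[1], "'; available: neutral_equilibrium, ",
         "two_deme_island, domestication_series, island_relict", call. = FALSE))
  ep <- function(...) data.frame(rbind(...))
  switch(name,
    neutral_equilibrium = demography_model(
      pops = list(pop_spec("wild", data.frame(time = Inf, ne = 100))),
      mu = 2.5e-4, recomb_rate = 2.5e-4
    ),
    two_deme_island = {
      N <- 100
      m <- Nm / (2 * N)
      mig <- matrix(c(1 - m, m, m, 1 - m), 2, 2, byrow = TRUE,
                    dimnames = list(c("deme1", "deme2"), c("deme1", "deme2")))
      demography_model(
        pops = list(
          pop_spec("deme1", data.frame(time = Inf, ne = N)),
          pop_spec("deme2", data.frame(time = Inf, ne = N))
        ),
        mu = 2.5e-4, recomb_rate = 2.5e-4, migration = mig
      )
    },
    domestication_series = demography_model(
      pops = list(
        pop_spec("wild", data.frame(time = Inf, ne = 120), selfing = 0.5),
        pop_spec("outgroup", data.frame(time = 800, ne = 100), selfing = 0.5,
                 parent = "wild", split_time = 800),
        pop_spec("MK", data.frame(time = 500, ne = 40), selfing = 0.7,
                 parent = "wild", split_time = 500),
        pop_spec("LR1", data.frame(time = c(300, 250), ne = c(15, 40)),
                 selfing = 0.75, parent = "wild", split_time = 300),
        pop_spec("LR2", data.frame(time = c(300, 250), ne = c(15, 40)),
                 selfing = 0.75, parent = "wild", split_time = 300),
        pop_spec("cultivar", data.frame(time = c(100, 70), ne = c(6, 12)),
                 selfing = 0.9, parent = "LR2", split_time = 100)
      ),
      mu = 5e-5, recomb_rate = 5e-5
    ),
    island_relict = demography_model(
      pops = list(
        pop_spec("MK", data.frame(time = c(Inf, 100, 30, 4),
                                  ne = c(150, 20, 200, 80)),
                 selfing = 0.7)
      ),
      mu = 2e-4, recomb_rate = 2e-4
    )
  )
}
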
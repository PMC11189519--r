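#' PCA on standardized genotype dosages
#'
#' Each site is centered by `2p` and scaled by `sqrt(2p(1-p))` (`p` the
#' alternate-allele frequency in the analyzed cohort); sample coordinates are
#' the principal-component scores of the standardized matrix and
#' `pct_variance` the eigenvalue shares. Monomorphic sites are dropped with a
#' warning; missing dosages are an error (run on fully-called SNP sets).
#' Component signs are fixed by making the first sample's coordinate
#' nonnegative.
#'
#' @param m a [cohort_matrix()] with no missing dosages.
#' @param n_components number of components to report (truncated to
#'   `n_samples - 1`).
#' @return list of class `pca_result`: `coords` (samples x components),
#'   `pct_variance`, `n_sites_used`.
#' @export
pca_genotypes <- function(m, n_components = 20) {
  d <- m$dosages
  if (anyNA(d)) stop("pca requires fully-called dosages")
  if (nrow(d) < 2L) stop("need >= 2 samples")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic site(s) dropped from PCA")
  }
  x <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(x, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(x)
  k <- min(n_components, nrow(d) - 1L)
  ev <- sv$d^2
  ev <- ev[ev > max(ev) * 1e-12]
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i0 <- which(abs(coords[, j]) > 1e-12)[1]
    if (!is.na(i0) && coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- cohort_samples(m)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords,
                 pct_variance = 100 * (sv$d[seq_len(k)]^2) / sum(ev),
                 n_sites_used = sum(poly)),
            class = "pca_result")
}

#' Identity-by-state distance matrix
#'
#' Entry (j, k) is the mean over mutually-called sites of `|d_j - d_k| / 2`
#' (the `1-ibs` allele-sharing distance). A pair with no mutually-called
#' sites is an error.
#'
#' @param m a [cohort_matrix()].
#' @return symmetric numeric matrix with zero diagonal, sample labels on both
#'   dimensions.
#' @export
ibs_distance <- function(m) {
  d <- m$dosages
  ns <- nrow(d)
  if (ns < 2L) stop("need >= 2 samples")
  out <- matrix(0, ns, ns, dimnames = list(rownames(d), rownames(d)))
  for (j in seq_len(ns - 1L)) {
    for (k in (j + 1L):ns) {
      ok <- !is.na(d[j, ]) & !is.na(d[k, ])
      if (!any(ok)) {
        stop("no mutually-called sites for pair ",
             rownames(d)[j], " / ", rownames(d)[k])
      }
      out[j, k] <- out[k, j] <- mean(abs(d[j, ok] - d[k, ok])) / 2
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion; ties broken by the
#' lowest index pair (row-major over the upper triangle), so output is
#' deterministic. Branch lengths come from the two-point formulas; a negative
#' estimate is clamped to 0 with the excess transferred to its sibling branch
#' (their sum is preserved). Consistent: an additive input matrix is
#' recovered exactly.
#'
#' @param d symmetric distance matrix with >= 3 labeled taxa.
#' @return an unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  labs <- rownames(d)
  if (is.null(labs)) stop("distance matrix needs row/column labels")
  r <- nrow(d)
  if (r < 3L) stop("neighbor joining needs >= 3 taxa")
  frag <- vapply(labs, quote_newick_label, character(1))
  while (r > 3L) {
    R <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in 1:(r - 1L)) {
      qi <- (r - 2) * d[i, (i + 1L):r] - R[i] - R[(i + 1L):r]
      w <- which.min(qi)  # first minimum: lowest-index tie-break
      if (qi[w] < bq - 1e-12) {
        bq <- qi[w]
        best <- c(i, i + w)
      }
    }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newf <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newf)
    r <- r - 1L
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- clamp_three(c(l1, l2, l3))
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], ls[1], frag[2], ls[2], frag[3], ls[3])
  unquote_newick_labels(ape::read.tree(text = nwk))
}

# clamp negative lengths at the final 3-way join, spreading the deficit over
# the positive siblings
clamp_three <- function(l) {
  neg <- l < 0
  if (any(neg)) {
    deficit <- sum(l[neg])
    l[neg] <- 0
    pos <- which(!neg)
    l[pos] <- pmax(l[pos] + deficit / length(pos), 0)
  }
  l
}

quote_newick_label <- function(x) {
  if (grepl("[][ \t(),:;']", x)) {
    paste0("'", gsub("'", "''", x), "'")
  } else x
}

unquote_newick_labels <- function(t) {
  fix <- function(lab) {
    q <- grepl("^'.*'$", lab)
    lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]))
    lab
  }
  t$tip.label <- fix(t$tip.label)
  if (!is.null(t$node.label)) t$node.label <- fix(t$node.label)
  t
}

#' Read a Newick tree, unquoting quoted labels
#'
#' `ape::read.tree` keeps the surrounding single quotes on quoted labels;
#' this wrapper strips them and un-doubles embedded quotes so that
#' `read_newick(write_newick(t))` is an identity on labels.
#'
#' @param path file path, or `NULL` when `text` is given.
#' @param text Newick string.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  t <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  unquote_newick_labels(t)
}

#' Root a tree on the branch separating an outgroup
#'
#' The outgroup labels must form a clade-compatible set on the unrooted
#' topology (otherwise an error names the conflicting leaves); the root is
#' placed at the midpoint of the separating branch.
#'
#' @param t an `ape::phylo` tree.
#' @param outgroup_labels character vector of leaf labels.
#' @return a rooted `ape::phylo` tree.
#' @export
root_with_outgroup <- function(t, outgroup_labels) {
  stopifnot(inherits(t, "phylo"))
  missing <- setdiff(outgroup_labels, t$tip.label)
  if (length(missing)) {
    stop("outgroup labels not in tree: ", paste(missing, collapse = ", "))
  }
  rt <- tryCatch(
    ape::root(t, outgroup = outgroup_labels, resolve.root = TRUE),
    error = function(e) stop("outgroup {", paste(outgroup_labels, collapse = ", "),
                             "} is not monophyletic on the unrooted topology",
                             call. = FALSE)
  )
  root <- ape::Ntip(rt) + 1L
  ce <- which(rt$edge[, 1] == root)
  if (length(ce) == 2L) {
    tot <- sum(rt$edge.length[ce])
    rt$edge.length[ce] <- tot / 2
  }
  rt
}

#' Write a tree in Newick format
#'
#' Labels containing Newick metacharacters (spaces, parentheses, colons,
#' commas, quotes, ...) are single-quoted; branch lengths are written with 15
#' significant digits so that `ape::read.tree(write_newick(t))` round-trips.
#'
#' @param t an `ape::phylo` tree.
#' @param path output file path, or `NULL` to return the string.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(t, path = NULL) {
  stopifnot(inherits(t, "phylo"))
  ntip <- ape::Ntip(t)
  kids <- split(seq_len(nrow(t$edge)), t$edge[, 1])
  rec <- function(node, elen) {
    sub <- if (node <= ntip) {
      quote_newick_label(t$tip.label[node])
    } else {
      e <- kids[[as.character(node)]]
      paste0("(", paste(vapply(e, function(ei) {
        rec(t$edge[ei, 2], t$edge.length[ei])
      }, character(1)), collapse = ","), ")")
    }
    if (is.na(elen)) sub else sprintf("%s:%.15g", sub, elen)
  }
  nwk <- paste0(rec(ntip + 1L, NA), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
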
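#' Nei (1972) standard genetic distance
#'
#' `D = -ln( J_xy / sqrt(J_x J_y) )` with the gene identities
#' `J_xy = sum_l sum_i x_i y_i`, `J_x = sum_l sum_i x_i^2` summed over loci
#' *before* the ratio. Loci unscored in either unit are excluded pairwise
#' (the J sums for that pair skip them). At the individual level the
#' "frequencies" are 0/0.5/1 from the genotype, which is the classical way
#' to apply the distance between single diploids. A pair with zero shared
#' identity (`J_xy = 0`) gets the documented ceiling `cap` (default 10)
#' instead of infinity so that UPGMA stays finite; a pair sharing no scored
#' locus gets `NA` with a warning.
#'
#' @param freqs a `freq_table` from [allele_frequencies()], at population
#'   or individual level.
#' @param cap ceiling replacing infinite distances.
#' @return an object of class `dist_matrix`: symmetric numeric matrix with
#'   zero diagonal and a `"distance"` attribute.
#' @export
nei_distance <- function(freqs, cap = 10) {
  stopifnot(inherits(freqs, "freq_table"))
  u <- length(freqs$units)
  if (u < 2L) stop("need at least two units for a distance matrix")
  Jxy <- matrix(0, u, u)
  Jx <- matrix(0, u, u)   # Jx[i, j]: identity of i over loci shared with j
  for (l in seq_along(freqs$loci)) {
    fm <- freqs$f[[l]]
    scored <- freqs$n[, l] > 0L & !apply(fm, 1L, anyNA)
    if (!any(scored)) next
    fm0 <- fm
    fm0[!scored, ] <- 0
    m <- as.numeric(scored)
    Jxy <- Jxy + (fm0 %*% t(fm0)) * outer(m, m)
    Jx <- Jx + outer(rowSums(fm0^2) * m, m)
  }
  shared <- Jx > 0 & t(Jx) > 0
  D <- matrix(NA_real_, u, u, dimnames = list(freqs$units, freqs$units))
  I <- Jxy / sqrt(Jx * t(Jx))
  D[shared] <- ifelse(Jxy[shared] > 0, -log(I[shared]), cap)
  D[!shared] <- NA_real_
  D <- pmin(D, cap)
  diag(D) <- 0
  if (anyNA(D))
    warning("unit pair(s) sharing no scored locus: distance undefined (NA)")
  structure(D, distance = "Nei 1972 standard", class = "dist_matrix")
}

#' Shared-allele distance between individuals
#'
#' `1 - (proportion of shared alleles)`, the common alternative individual
#' distance: per locus the two genotypes share 0, 1 or 2 alleles (counting
#' multiplicity) and the proportion is averaged over pairwise-complete
#' loci.
#'
#' @param x a [genotype_matrix()].
#' @return a `dist_matrix` over individuals.
#' @export
shared_allele_distance <- function(x) {
  validate_genotype_matrix(x)
  n <- n_ind(x)
  shared <- matrix(0, n, n)
  loci_n <- matrix(0, n, n)
  for (l in seq_len(n_loci(x))) {
    a1 <- x$a1[, l]; a2 <- x$a2[, l]
    sc <- !is.na(a1)
    idx <- which(sc)
    # multiset intersection of {u1,u2} and {v1,v2} = best of the two
    # slot pairings (calls are stored with allele1 <= allele2)
    s11 <- outer(a1[idx], a1[idx], "==")
    s12 <- outer(a1[idx], a2[idx], "==")
    s21 <- outer(a2[idx], a1[idx], "==")
    s22 <- outer(a2[idx], a2[idx], "==")
    cnt <- pmax(s11 + s22, s12 + s21)
    shared[idx, idx] <- shared[idx, idx] + cnt
    loci_n[idx, idx] <- loci_n[idx, idx] + 2
  }
  D <- 1 - shared / ifelse(loci_n > 0, loci_n, NA_real_)
  diag(D) <- 0
  dimnames(D) <- list(x$ids, x$ids)
  structure(D, distance = "shared allele", class = "dist_matrix")
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration with the merge height set to half the
#' cluster distance, so cophenetic distances reproduce the average-linkage
#' distances. After each merge the new cluster's distance to the others is
#' the size-weighted arithmetic mean of its members' distances. Ties at the
#' minimum distance are broken deterministically by the lexicographically
#' smallest pair of cluster representative labels (a cluster is represented
#' by its smallest leaf label).
#'
#' @param d a `dist_matrix` (no `NA` entries; cap or impute first).
#' @return an object of classes `upgma_tree` and `hclust` (fields `merge`,
#'   `height`, `order`, `labels`), usable with [stats::cutree()],
#'   [stats::cophenetic()] and convertible via [ape::as.phylo()].
#' @examples
#' d <- structure(matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'                       dimnames = list(c("A", "B", "C"), c("A", "B", "C"))),
#'                class = "dist_matrix")
#' tr <- upgma(d)
#' to_newick(tr)
#' @export
upgma <- function(d) {
  if (anyNA(d))
    stop("distance matrix contains undefined entries; ",
         "cap or impute them before clustering")
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two labels to cluster")
  D <- unclass(d)
  size <- rep(1L, n)
  node <- -seq_len(n)           # hclust convention: negatives are leaves
  rep_lab <- labels             # representative (smallest) leaf label
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    cand <- which(sub == mn, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break on sorted representative label pairs
    keys <- apply(cand, 1L, function(rc) {
      pair <- sort(c(rep_lab[idx[rc[1L]]], rep_lab[idx[rc[2L]]]))
      paste(pair, collapse = "\r")
    })
    pick <- cand[order(keys)[1L], ]
    i <- idx[pick[1L]]; j <- idx[pick[2L]]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- mn / 2
    # weighted average linkage update, stored in slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      D[i, others] <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[others, i] <- D[i, others]
    }
    size[i] <- size[i] + size[j]
    node[i] <- step
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    active[j] <- FALSE
  }
  tr <- structure(list(merge = merge, height = height,
                       order = tree_leaf_order(merge, n),
                       labels = labels, method = "average",
                       call = match.call(), dist.method = attr(d, "distance")),
                  class = c("upgma_tree", "hclust"))
  tr
}

tree_leaf_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(n - 1L)
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are height differences between a node and its parent
#' (the ultrametric d/2 convention of [upgma()]).
#'
#' @param tree an `upgma_tree` (or any `hclust`).
#' @param path optional file; when given, the string is also written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(tree, path = NULL) {
  ph <- as_phylo_tree(tree)
  s <- ape::write.tree(ph)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Convert a dendrogram to an ape phylo object
#'
#' Branch lengths are differences of the [upgma()] node heights, so leaf
#' depths equal the root height and path lengths between leaves reproduce
#' the average-linkage distances. (This compensates for the extra halving
#' `ape::as.phylo.hclust` applies to `hclust` heights.)
#'
#' @param tree an `upgma_tree` (or any `hclust`).
#' @return an object of class `phylo`.
#' @export
as_phylo_tree <- function(tree) {
  h2 <- stats::as.hclust(tree)
  h2$height <- h2$height * 2   # undo ape's height/2 convention
  ape::as.phylo(h2)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k-1 highest merges; cluster ids are assigned in leaf (label)
#' order of first appearance.
#'
#' @param tree an `upgma_tree`.
#' @param k number of clusters, between 1 and the leaf count.
#' @return named integer vector of cluster ids with a `"sizes"` attribute.
#' @export
cut_clusters <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must lie between 1 and ", n)
  cl <- stats::cutree(stats::as.hclust(tree), k = k)
  structure(cl, sizes = as.integer(table(cl)))
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Gower double-centering of `-d^2/2`, eigendecomposition, and coordinates
#' scaled by the square roots of the non-negative eigenvalues. Negative
#' eigenvalues (from non-Euclidean distances) are reported but excluded
#' from the coordinates and from the percent-variance denominator. Axis
#' signs are fixed by making the largest-magnitude coordinate of each axis
#' positive.
#'
#' @param d a `dist_matrix`.
#' @param axes number of axes to return.
#' @return an object of class `pcoa_result`: list with `coordinates`
#'   (labels x axes), `eigenvalues` (all, non-increasing), and `percent`
#'   (percent variance per returned axis over positive eigenvalues).
#' @export
pcoa <- function(d, axes = 2L) {
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  n <- nrow(d)
  if (n < 2L) stop("need at least two labels")
  A <- -0.5 * unclass(d)^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  ev <- eig$values
  pos <- ev > max(ev[1L], 0) * 1e-9
  npos <- sum(pos)
  if (axes > npos) {
    warning("only ", npos, " positive eigenvalue(s); axes truncated")
    axes <- npos
  }
  coords <- matrix(0, n, axes)
  dimnames(coords) <- list(rownames(d),
                           if (axes > 0L) paste0("Axis", seq_len(axes)))
  for (a in seq_len(axes)) {
    v <- eig$vectors[, a] * sqrt(ev[a])
    if (v[which.max(abs(v))] < 0) v <- -v
    coords[, a] <- v
  }
  pct <- if (npos > 0) 100 * ev[seq_len(axes)] / sum(ev[pos]) else numeric(0)
  structure(list(coordinates = coords, eigenvalues = ev, percent = pct),
            class = "pcoa_result")
}
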
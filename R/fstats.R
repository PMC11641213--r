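#' Wright's F-statistics and gene flow
#'
#' Nei-style F-statistics from unweighted population means. Per locus:
#' `Hi` is the unweighted mean of per-population observed heterozygosity,
#' `Hs` the unweighted mean of per-population gene diversity
#' (1 - sum p^2), and `Ht` the gene diversity of the unweighted mean of the
#' per-population frequency vectors. Then `Fis = (Hs - Hi)/Hs`,
#' `Fit = (Ht - Hi)/Ht`, `Fst = (Ht - Hs)/Ht`, and the island-model gene
#' flow `Nm = 0.25 (1 - Fst)/Fst`. The over-loci mean row is arithmetic in
#' every column -- in particular mean Nm is the mean of per-locus Nm, not
#' Nm of mean Fst. Populations with no scored individual at a locus are
#' dropped from that locus's means. With population sizes as unbalanced as
#' 374/16/26 the unweighted convention is consequential; `weighted = TRUE`
#' switches to size-weighted means.
#'
#' Degenerate loci are marked, not zeroed: `Fis` is `NA` where `Hs = 0`,
#' and `Nm` is `Inf` where `Fst = 0`.
#'
#' @param x a [genotype_matrix()] with at least two populations.
#' @param weighted weight population means by scored sample size?
#' @return data frame, one row per locus plus a `"Mean"` row, columns
#'   `locus`, `Hi`, `Hs`, `Ht`, `Fis`, `Fit`, `Fst`, `Nm`. Infinite
#'   per-locus `Nm` is excluded from the mean (with a warning).
#' @export
f_statistics <- function(x, weighted = FALSE) {
  validate_genotype_matrix(x)
  if (nlevels(x$pop) < 2L)
    stop("F-statistics need at least two populations")
  fp <- allele_frequencies(x, by = "population")
  L <- n_loci(x)
  out <- data.frame(locus = x$loci, Hi = NA_real_, Hs = NA_real_,
                    Ht = NA_real_, Fis = NA_real_, Fit = NA_real_,
                    Fst = NA_real_, Nm = NA_real_, stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    fm <- fp$f[[l]]
    nvec <- fp$n[, l]
    ok <- nvec > 0L & !apply(fm, 1L, anyNA)
    if (sum(ok) < 2L) next
    fm <- fm[ok, , drop = FALSE]
    w <- if (weighted) nvec[ok] / sum(nvec[ok]) else rep(1 / sum(ok), sum(ok))
    ho_pop <- vapply(which(ok), function(u) {
      in_pop <- as.integer(x$pop) == u
      a1 <- x$a1[in_pop, l]; a2 <- x$a2[in_pop, l]
      scored <- !is.na(a1)
      sum(a1[scored] != a2[scored]) / sum(scored)
    }, numeric(1))
    hs_pop <- 1 - rowSums(fm^2)
    pbar <- colSums(fm * w)
    Hi <- sum(w * ho_pop)
    Hs <- sum(w * hs_pop)
    Ht <- 1 - sum(pbar^2)
    out$Hi[l] <- Hi
    out$Hs[l] <- Hs
    out$Ht[l] <- Ht
    out$Fis[l] <- if (Hs > 0) (Hs - Hi) / Hs else NA_real_
    if (Ht > 0) {
      out$Fit[l] <- (Ht - Hi) / Ht
      fst <- (Ht - Hs) / Ht
      if (abs(fst) < 1e-12) fst <- 0  # snap float noise at Hs == Ht
      out$Fst[l] <- fst
      out$Nm[l] <- if (fst > 0) 0.25 * (1 - fst) / fst else Inf
    }
  }
  nm <- out$Nm
  if (any(is.infinite(nm), na.rm = TRUE)) {
    warning("Nm infinite at Fst = 0 locus/loci; excluded from the mean")
    nm[is.infinite(nm)] <- NA_real_
  }
  mean_row <- data.frame(locus = "Mean",
                         t(colMeans(out[, c("Hi", "Hs", "Ht", "Fis",
                                            "Fit", "Fst")], na.rm = TRUE)),
                         Nm = mean(nm, na.rm = TRUE))
  names(mean_row) <- names(out)
  rbind(out, mean_row)
}

#' Pairwise Fst between populations
#'
#' For each pair of populations, the mean-over-loci Fst of
#' [f_statistics()] computed on the pair alone.
#'
#' @param x a [genotype_matrix()] with at least two populations.
#' @param weighted passed to [f_statistics()].
#' @return symmetric matrix over populations with zero diagonal.
#' @export
pairwise_fst <- function(x, weighted = FALSE) {
  validate_genotype_matrix(x)
  pops <- levels(x$pop)
  k <- length(pops)
  if (k < 2L) stop("pairwise Fst needs at least two populations")
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      sub <- subset_accessions(x, x$ids[x$pop %in% pops[c(i, j)]])
      fs <- f_statistics(sub, weighted = weighted)
      m[i, j] <- m[j, i] <- fs$Fst[fs$locus == "Mean"]
    }
  }
  m
}
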
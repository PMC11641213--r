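#' Allele relative frequencies
#'
#' Computes per-locus allele relative frequencies over the whole sample,
#' within each population, or per individual (where the "frequency" of an
#' allele in one diploid is 0, 0.5 or 1). Missing calls contribute nothing:
#' `p_i` is the number of copies of allele `i` among non-missing calls of
#' the unit, divided by twice the unit's non-missing sample size. A unit
#' with zero scored calls at a locus gets an all-`NA` row there and is
#' flagged; downstream statistics propagate the undefined marker rather
#' than reporting zero.
#'
#' @param x a [genotype_matrix()].
#' @param by aggregation level: `"total"`, `"population"`, or
#'   `"individual"`.
#' @return an object of class `freq_table`: list with `units` (labels),
#'   `loci`, `f` (per locus, a unit x allele matrix of relative
#'   frequencies), and `n` (unit x locus matrix of scored individuals).
#' @export
allele_frequencies <- function(x, by = c("total", "population", "individual")) {
  validate_genotype_matrix(x)
  by <- match.arg(by)
  groups <- switch(by,
    total = factor(rep("TOTAL", n_ind(x))),
    population = x$pop,
    individual = factor(x$ids, levels = x$ids))
  units <- levels(groups)
  L <- n_loci(x)
  f <- vector("list", L)
  names(f) <- x$loci
  nmat <- matrix(0L, length(units), L, dimnames = list(units, x$loci))
  gi <- as.integer(groups)
  for (l in seq_len(L)) {
    al <- c(x$a1[, l], x$a2[, l])
    gg <- c(gi, gi)
    keep <- !is.na(al)
    alleles <- sort(unique(al[keep]))
    A <- length(alleles)
    cnt <- matrix(0, length(units), max(A, 1L))
    if (A > 0L) {
      ai <- match(al[keep], alleles)
      cnt <- matrix(tabulate(gg[keep] + length(units) * (ai - 1L),
                             nbins = length(units) * A),
                    length(units), A)
    }
    copies <- rowSums(cnt)
    nmat[, l] <- as.integer(copies / 2)
    fm <- cnt / ifelse(copies > 0, copies, NA_real_)
    dimnames(fm) <- list(units, if (A > 0L) alleles else NULL)
    f[[l]] <- fm
  }
  structure(list(units = units, loci = x$loci, by = by, f = f, n = nmat),
            class = "freq_table")
}

# per-unit locus statistics from one frequency matrix row; NA-safe
locus_stats_from_freq <- function(p) {
  if (anyNA(p) || length(p) == 0L) {
    return(c(MAF = NA_real_, Na = NA_real_, Ne = NA_real_, I = NA_real_,
             He = NA_real_, PIC = NA_real_))
  }
  p <- p[p > 0]
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  c(MAF = max(p),
    Na = length(p),
    Ne = 1 / s2,
    I = -sum(p * log(p)),
    He = 1 - s2,
    PIC = 1 - s2 - (s2^2 - s4))
}

#' Per-locus diversity summaries
#'
#' For each locus computes, from total-sample allele frequencies: the major
#' allele frequency (MAF), the number of scored individuals N, the observed
#' allele count Na, the effective allele count Ne = 1/sum(p^2), Shannon's
#' information index I = -sum(p log p), observed heterozygosity Ho, Nei's
#' gene diversity He = 1 - sum(p^2) (the uncorrected estimator; the
#' small-sample corrected value `He_unbiased` = 2N/(2N-1) He is an extra
#' column), and Botstein's polymorphism information content
#' PIC = 1 - sum(p^2) - sum_{i<j} 2 p_i^2 p_j^2.
#'
#' @param x a [genotype_matrix()].
#' @param include_mean append an over-loci arithmetic mean row (locus name
#'   `"Mean"`, N left `NA`)?
#' @return a data frame, one row per locus, columns `locus`, `N`, `MAF`,
#'   `Na`, `Ne`, `I`, `Ho`, `He`, `He_unbiased`, `PIC`.
#' @examples
#' gm <- simulate_sophora_panel(seed = 1)
#' head(locus_summaries(gm))
#' @export
locus_summaries <- function(x, include_mean = FALSE) {
  ft <- allele_frequencies(x, by = "total")
  L <- n_loci(x)
  out <- data.frame(locus = x$loci, N = as.integer(ft$n[1L, ]),
                    MAF = NA_real_, Na = NA_real_, Ne = NA_real_,
                    I = NA_real_, Ho = NA_real_, He = NA_real_,
                    He_unbiased = NA_real_, PIC = NA_real_,
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    st <- locus_stats_from_freq(ft$f[[l]][1L, ])
    out$MAF[l] <- st[["MAF"]]
    out$Na[l] <- st[["Na"]]
    out$Ne[l] <- st[["Ne"]]
    out$I[l] <- st[["I"]]
    out$He[l] <- st[["He"]]
    out$PIC[l] <- st[["PIC"]]
    nl <- out$N[l]
    if (!is.na(st[["He"]]) && nl > 0L)
      out$He_unbiased[l] <- st[["He"]] * 2 * nl / (2 * nl - 1)
    het <- !is.na(x$a1[, l]) & x$a1[, l] != x$a2[, l]
    out$Ho[l] <- if (nl > 0L) sum(het) / nl else NA_real_
  }
  if (include_mean) {
    mean_row <- data.frame(locus = "Mean", N = NA_integer_,
                           t(colMeans(out[, -(1:2)], na.rm = TRUE)))
    names(mean_row) <- names(out)
    out <- rbind(out, mean_row)
  }
  rownames(out) <- NULL
  out
}

#' Per-population diversity summaries
#'
#' Recomputes the locus statistics on each population's individuals alone,
#' then averages over loci (loci unscored within a population are dropped
#' from that population's means). A final `"Total"` row is the unweighted
#' mean of the population rows.
#'
#' @param x a [genotype_matrix()].
#' @return data frame with columns `pop`, `N`, `mean_Na`, `mean_Ne`,
#'   `mean_I`, `mean_Ho`, `mean_He`, plus the `Total` row (its `N` is the
#'   full sample size).
#' @export
population_summaries <- function(x) {
  validate_genotype_matrix(x)
  pops <- levels(x$pop)
  present <- tabulate(x$pop) > 0L
  if (any(!present)) {
    warning("population(s) with zero individuals excluded: ",
            paste(pops[!present], collapse = ", "))
    pops <- pops[present]
  }
  rows <- lapply(pops, function(pp) {
    sub <- subset_accessions(x, x$ids[x$pop == pp])
    ls <- locus_summaries(sub)
    data.frame(pop = pp, N = sum(x$pop == pp),
               mean_Na = mean(ls$Na, na.rm = TRUE),
               mean_Ne = mean(ls$Ne, na.rm = TRUE),
               mean_I = mean(ls$I, na.rm = TRUE),
               mean_Ho = mean(ls$Ho, na.rm = TRUE),
               mean_He = mean(ls$He, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(pop = "Total", N = n_ind(x),
                      t(colMeans(out[, -(1:2)])))
  names(total) <- names(out)
  rbind(out, total)
}
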
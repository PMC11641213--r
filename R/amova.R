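#' Three-level AMOVA for codominant diploid data
#'
#' Partitions molecular variance among populations, among individuals
#' within populations, and within individuals, on allele copies. Sums of
#' squares come from the nested ANOVA of allele-indicator vectors summed
#' over alleles and loci (equivalently: squared Euclidean distances between
#' allele indicator vectors, so two copies of different alleles are at
#' squared distance 2 and each heterozygous call contributes 1 to the
#' within-individual SS). Individuals unscored at a locus are dropped for
#' that locus only, while the degrees of freedom follow the global
#' bookkeeping: with `N` individuals carrying any data and `k` populations,
#' df = (k - 1, N - k, N) and total 2N - 1.
#'
#' Variance components use the standard nested-ANOVA estimators:
#' `sigma2_within = MS_within`,
#' `sigma2_among_ind = (MS_among_ind - MS_within)/2`, and
#' `sigma2_among_pop = (MS_among_pop - MS_among_ind)/(2 n_c)` with
#' `n_c = (N - sum(N_k^2)/N)/(k - 1)`. Negative estimates are truncated to
#' zero (raw values kept in the `raw_var` column) before percentages.
#'
#' @param x a [genotype_matrix()] with at least two populations.
#' @return an object of class `amova_table`: data frame with rows
#'   `Among Pops`, `Among Indiv`, `Within Indiv`, `Total` and columns
#'   `source`, `df`, `SS`, `MS`, `var`, `raw_var`, `percent`.
#' @examples
#' gm <- simulate_sophora_panel(seed = 1)
#' amova(gm)
#' @export
amova <- function(x) {
  validate_genotype_matrix(x)
  k <- nlevels(x$pop)
  if (k < 2L)
    stop("hierarchical AMOVA needs at least two populations ",
         "(use locus summaries for a single population)")
  has_data <- rowSums(!is.na(x$a1)) > 0L
  if (!all(has_data))
    warning(sum(!has_data), " individual(s) with no scored locus dropped")
  ids <- x$ids[has_data]
  N <- length(ids)
  pop <- x$pop[has_data]
  if (N <= k)
    stop("AMOVA needs at least one population with two or more ",
         "individuals (no within-population degrees of freedom)")
  Nk <- tabulate(pop, nbins = k)
  ss_pop <- ss_ind <- ss_within <- 0
  for (l in seq_len(n_loci(x))) {
    a1 <- x$a1[has_data, l]
    a2 <- x$a2[has_data, l]
    scored <- !is.na(a1)
    if (!any(scored)) {
      warning("locus ", x$loci[l], " has no scored calls; skipped")
      next
    }
    al <- c(a1[scored], a2[scored])
    alleles <- sort(unique(al))
    A <- length(alleles)
    gpop <- as.integer(pop[scored])
    nl <- sum(scored)
    # allele-count matrices: individuals x alleles (0/1/2 copies)
    ci <- matrix(0L, nl, A)
    ci[cbind(seq_len(nl), match(a1[scored], alleles))] <-
      ci[cbind(seq_len(nl), match(a1[scored], alleles))] + 1L
    ci[cbind(seq_len(nl), match(a2[scored], alleles))] <-
      ci[cbind(seq_len(nl), match(a2[scored], alleles))] + 1L
    ybar_ind <- ci / 2
    cp <- rowsum(ci, gpop)                # pops-with-data x alleles
    npop <- tabulate(gpop)[sort(unique(gpop))]
    ybar_pop <- cp / (2 * npop)
    ybar <- colSums(cp) / (2 * nl)
    # within individuals: each heterozygous call contributes 1
    ss_within <- ss_within + sum(a1[scored] != a2[scored])
    dev_ind <- ybar_ind - ybar_pop[match(gpop, sort(unique(gpop))), ,
                                   drop = FALSE]
    ss_ind <- ss_ind + 2 * sum(dev_ind^2)
    dev_pop <- sweep(ybar_pop, 2L, ybar, "-")
    ss_pop <- ss_pop + sum(2 * npop * rowSums(dev_pop^2))
  }
  df <- c(k - 1L, N - k, N)
  ss <- c(ss_pop, ss_ind, ss_within)
  ms <- ss / df
  n_c <- (N - sum(Nk^2) / N) / (k - 1)
  raw <- c((ms[1L] - ms[2L]) / (2 * n_c), (ms[2L] - ms[3L]) / 2, ms[3L])
  sigma <- pmax(raw, 0)
  tot <- sum(sigma)
  if (tot == 0) {
    warning("no molecular variation; percentages undefined, reported as 0")
    pct <- c(0, 0, 0)
  } else {
    pct <- 100 * sigma / tot
  }
  out <- data.frame(
    source = c("Among Pops", "Among Indiv", "Within Indiv", "Total"),
    df = c(df, 2L * N - 1L),
    SS = c(ss, sum(ss)),
    MS = c(ms, NA_real_),
    var = c(sigma, sum(sigma)),
    raw_var = c(raw, NA_real_),
    percent = c(pct, if (tot == 0) 0 else 100),
    stringsAsFactors = FALSE)
  class(out) <- c("amova_table", "data.frame")
  out
}
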
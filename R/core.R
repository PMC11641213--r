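# Internal: per-locus squared-frequency bookkeeping for fast leave-one-out
# He. For the current accession set we keep, per locus, the allele copy
# counts, their sum T and the sum of squared counts S, so that removing one
# accession updates mean He in O(1) per locus.
he_state <- function(x) {
  L <- n_loci(x)
  counts <- vector("list", L)
  ai1 <- matrix(NA_integer_, n_ind(x), L)
  ai2 <- matrix(NA_integer_, n_ind(x), L)
  for (l in seq_len(L)) {
    al <- c(x$a1[, l], x$a2[, l])
    codes <- sort(unique(al[!is.na(al)]))
    counts[[l]] <- tabulate(match(al[!is.na(al)], codes), nbins = length(codes))
    ai1[, l] <- match(x$a1[, l], codes)
    ai2[, l] <- match(x$a2[, l], codes)
  }
  list(counts = counts, S = vapply(counts, function(cn) sum(cn^2), numeric(1)),
       T = vapply(counts, sum, numeric(1)), ai1 = ai1, ai2 = ai2)
}

#' Rank accessions by their contribution to expected heterozygosity
#'
#' The stepwise construction: at every step, for each remaining accession
#' the mean-over-loci He of the set *without* it is computed
#' (full leave-one-out recomputation of allele frequencies, not an
#' individual-heterozygosity shortcut), and the accession whose removal
#' leaves the highest mean He -- the lowest contributor -- is removed. Ties
#' are broken by ascending accession id. Repeating down to a single
#' survivor yields a total order; the high-contribution tail of the order
#' is the core candidate at any size.
#'
#' @param x a [genotype_matrix()] with >= 2 accessions.
#' @return character vector of accession ids in removal order (first =
#'   least contribution, last = sole survivor).
#' @export
rank_by_het <- function(x) {
  validate_genotype_matrix(x)
  n <- n_ind(x)
  if (n < 2L) stop("ranking needs at least two accessions")
  st <- he_state(x)
  L <- n_loci(x)
  remaining <- seq_len(n)
  order_out <- character(n)
  S <- st$S; T <- st$T
  counts <- st$counts
  any_tie_run <- FALSE
  for (step in seq_len(n - 1L)) {
    m <- length(remaining)
    he_sum <- numeric(m)   # sum over defined loci of He after removal
    he_cnt <- numeric(m)
    for (l in seq_len(L)) {
      i1 <- st$ai1[remaining, l]
      i2 <- st$ai2[remaining, l]
      scored <- !is.na(i1)
      c1 <- ifelse(scored, counts[[l]][i1], 0L)
      c2 <- ifelse(scored, counts[[l]][i2], 0L)
      hom <- scored & i1 == i2
      dS <- ifelse(hom, -4 * c1 + 4, -2 * c1 + 1 - 2 * c2 + 1)
      Sp <- S[l] + ifelse(scored, dS, 0)
      Tp <- T[l] - ifelse(scored, 2, 0)
      ok <- Tp > 0
      he_sum <- he_sum + ifelse(ok, 1 - Sp / Tp^2, 0)
      he_cnt <- he_cnt + ok
    }
    he_after <- ifelse(he_cnt > 0, he_sum / he_cnt, -Inf)
    best <- max(he_after)
    cand <- remaining[he_after >= best - 1e-12]
    if (length(cand) > 1L) any_tie_run <- TRUE
    drop_i <- cand[order(x$ids[cand])][1L]
    order_out[step] <- x$ids[drop_i]
    for (l in seq_len(L)) {
      i1 <- st$ai1[drop_i, l]
      if (is.na(i1)) next
      i2 <- st$ai2[drop_i, l]
      cn <- counts[[l]]
      S[l] <- S[l] - cn[i1]^2 - (if (i1 == i2) 0 else cn[i2]^2)
      cn[i1] <- cn[i1] - 1L
      cn[i2] <- cn[i2] - 1L
      S[l] <- S[l] + cn[i1]^2 + (if (i1 == i2) 0 else cn[i2]^2)
      T[l] <- T[l] - 2
      counts[[l]] <- cn
    }
    remaining <- setdiff(remaining, drop_i)
  }
  order_out[n] <- x$ids[remaining]
  if (all(vapply(seq_len(L), function(l)
        length(unique(stats::na.omit(c(x$a1[, l], x$a2[, l])))) <= 1L,
        logical(1))))
    warning("all accessions are effectively identical; ",
            "removal order is pure tie-break order")
  order_out
}

#' Build and evaluate nested core-collection candidates
#'
#' Takes the high-contribution tail of the [rank_by_het()] order at each
#' requested proportion (subset size = `round(p * N)`, so the subsets are
#' nested), recomputes the diversity statistics on every subset, and
#' reports each parameter's retention as percent of the full-collection
#' value. `Fst` is the mean multi-locus value of [f_statistics()] and is
#' `NA` for subsets that no longer span two populations.
#'
#' @param x a [genotype_matrix()].
#' @param proportions proportions in (0, 1]; default is the ten-step scan
#'   50%, 45%, ..., 5%.
#' @param order optional precomputed removal order (from [rank_by_het()]).
#' @return an object of class `core_selection`: list with `removal_order`,
#'   `subsets` (proportion -> ids), `evaluation` (data frame: proportion,
#'   size, mean Na/Ne/I/Ho/He/PIC, Fst), and `retention` (same shape, as
#'   percent of the full collection; the `Na` column counts alleles
#'   observed in the subset, so its retention cannot exceed 100%).
#' @examples
#' gm <- simulate_sophora_panel(seed = 1)
#' sel <- select_candidates(gm, proportions = c(0.5, 0.25))
#' sel$evaluation
#' @export
select_candidates <- function(x, proportions = seq(0.50, 0.05, by = -0.05),
                              order = NULL) {
  validate_genotype_matrix(x)
  if (any(proportions <= 0 | proportions > 1))
    stop("proportions must lie in (0, 1]")
  if (is.null(order)) order <- rank_by_het(x)
  stopifnot(setequal(order, x$ids))
  n <- n_ind(x)
  proportions <- sort(proportions, decreasing = TRUE)
  sizes <- as.integer(round(proportions * n))
  if (any(sizes < 1L))
    stop("proportion ", proportions[which(sizes < 1L)[1L]],
         " yields an empty subset")
  subsets <- lapply(sizes, function(s) order[seq(n - s + 1L, n)])
  names(subsets) <- format(proportions)
  eval_one <- function(ids) {
    sub <- subset_accessions(x, ids)
    ls <- locus_summaries(sub)
    fst <- if (nlevels(droplevels(sub$pop)) >= 2L) {
      fs <- f_statistics(sub)
      fs$Fst[fs$locus == "Mean"]
    } else NA_real_
    c(Na = mean(ls$Na, na.rm = TRUE), Ne = mean(ls$Ne, na.rm = TRUE),
      I = mean(ls$I, na.rm = TRUE), Ho = mean(ls$Ho, na.rm = TRUE),
      He = mean(ls$He, na.rm = TRUE), PIC = mean(ls$PIC, na.rm = TRUE),
      Fst = fst)
  }
  full <- eval_one(x$ids)
  ev <- t(vapply(subsets, eval_one, full))
  evaluation <- data.frame(proportion = proportions, size = sizes, ev)
  retention <- evaluation
  for (p in names(full))
    retention[[p]] <- ifelse(rep(full[[p]] != 0 & !is.na(full[[p]]),
                                 nrow(retention)),
                             100 * evaluation[[p]] / full[[p]], NA_real_)
  rownames(evaluation) <- rownames(retention) <- NULL
  structure(list(removal_order = order, subsets = subsets,
                 evaluation = evaluation, retention = retention,
                 full = full, n = n),
            class = "core_selection")
}

#' Retention report for one core against the original collection
#'
#' Percent retention `100 * core / original` per diversity parameter, for
#' the core subset and for its complement (the reserved set).
#'
#' @param x a [genotype_matrix()].
#' @param core_ids accession ids of the core collection.
#' @return data frame with rows `original`, `core`, `core_retention_pct`,
#'   `reserved`, `reserved_retention_pct` and the parameter columns of
#'   [select_candidates()]'s evaluation. A zero original value yields `NA`
#'   retention.
#' @export
retention_report <- function(x, core_ids) {
  validate_genotype_matrix(x)
  stopifnot(all(core_ids %in% x$ids))
  reserved_ids <- setdiff(x$ids, core_ids)
  stat_row <- function(ids) {
    sub <- subset_accessions(x, ids)
    ls <- locus_summaries(sub)
    fst <- if (nlevels(droplevels(sub$pop)) >= 2L) {
      fs <- f_statistics(sub)
      fs$Fst[fs$locus == "Mean"]
    } else NA_real_
    c(N = length(ids), Na = mean(ls$Na, na.rm = TRUE),
      Ne = mean(ls$Ne, na.rm = TRUE), I = mean(ls$I, na.rm = TRUE),
      Ho = mean(ls$Ho, na.rm = TRUE), He = mean(ls$He, na.rm = TRUE),
      PIC = mean(ls$PIC, na.rm = TRUE), Fst = fst)
  }
  orig <- stat_row(x$ids)
  core <- stat_row(core_ids)
  resv <- if (length(reserved_ids)) stat_row(reserved_ids) else orig * NA
  pct <- function(v) ifelse(!is.na(orig) & orig != 0, 100 * v / orig,
                            NA_real_)
  out <- rbind(original = orig, core = core, core_retention_pct = pct(core),
               reserved = resv, reserved_retention_pct = pct(resv))
  out["core_retention_pct", "N"] <- 100 * length(core_ids) / n_ind(x)
  out["reserved_retention_pct", "N"] <- 100 * length(reserved_ids) / n_ind(x)
  as.data.frame(out)
}

#' Paired t-test of diversity parameters, core vs original
#'
#' For each parameter (Na, Ne, I, Ho, He, PIC) the per-locus values are
#' computed on the core subset and on the full collection, and the paired
#' two-sided t-test across loci is reported. If every per-locus difference
#' is zero the test is degenerate and `p = 1` by convention; zero variance
#' around a non-zero mean difference is reported as `NA` with a warning.
#'
#' @param x a [genotype_matrix()] with >= 2 loci.
#' @param core_ids accession ids of the core collection.
#' @param paired set `FALSE` for the unpaired (Welch) variant.
#' @return data frame with columns `parameter`, `t`, `p`.
#' @export
core_vs_original_test <- function(x, core_ids, paired = TRUE) {
  validate_genotype_matrix(x)
  if (n_loci(x) < 2L) stop("need at least two loci for the t-test")
  core <- locus_summaries(subset_accessions(x, core_ids))
  orig <- locus_summaries(x)
  pars <- c("Na", "Ne", "I", "Ho", "He", "PIC")
  res <- lapply(pars, function(p) {
    a <- core[[p]]; b <- orig[[p]]
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (paired && all(a == b))
      return(data.frame(parameter = p, t = 0, p = 1))
    tt <- tryCatch(stats::t.test(a, b, paired = paired),
                   error = function(e) NULL)
    if (is.null(tt)) {
      warning("degenerate t-test for ", p, " (zero variance)")
      return(data.frame(parameter = p, t = NA_real_, p = NA_real_))
    }
    data.frame(parameter = p, t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, res)
}
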
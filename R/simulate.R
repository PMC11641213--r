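#' Simulation parameters for structured SSR data
#'
#' Bundles the design of a Balding-Nichols simulation: population count and
#' sizes, locus count and nominal allele counts, the target differentiation
#' F (the Fst-like parameter of the Balding-Nichols model), a
#' missing-at-random call dropout rate, and an optional Dirichlet
#' concentration for admixed ancestry.
#'
#' @param pop_sizes integer vector of accessions per population.
#' @param alleles_per_locus integer vector (>= 2 each), one entry per locus.
#' @param fst_target differentiation parameter F in `[0, 1)`.
#' @param missing_rate probability in `[0, 1)` that a call is dropped.
#' @param pop_labels optional population labels (default `P1`, `P2`, ...).
#' @param locus_names optional locus names (default `L1`, `L2`, ...).
#' @param admixture_alpha optional positive Dirichlet concentration; when
#'   set, each individual receives ancestry proportions drawn from a
#'   Dirichlet with weight `1 + alpha` on its home population and `alpha`
#'   elsewhere, so `alpha -> 0` recovers the unadmixed model.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(pop_sizes, alleles_per_locus, fst_target = 0.04,
                       missing_rate = 0, pop_labels = NULL,
                       locus_names = NULL, admixture_alpha = NULL) {
  pop_sizes <- as.integer(pop_sizes)
  alleles_per_locus <- as.integer(alleles_per_locus)
  if (any(pop_sizes < 1L)) stop("all population sizes must be >= 1")
  if (any(alleles_per_locus < 2L))
    stop("each locus needs at least 2 alleles")
  if (!is.numeric(fst_target) || fst_target < 0 || fst_target >= 1)
    stop("fst_target must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (is.null(pop_labels)) pop_labels <- paste0("P", seq_along(pop_sizes))
  if (is.null(locus_names)) locus_names <- paste0("L", seq_along(alleles_per_locus))
  stopifnot(length(pop_labels) == length(pop_sizes),
            length(locus_names) == length(alleles_per_locus))
  if (!is.null(admixture_alpha) && admixture_alpha <= 0)
    stop("admixture_alpha must be positive (or NULL for no admixture)")
  structure(list(pop_sizes = pop_sizes, pop_labels = pop_labels,
                 alleles_per_locus = alleles_per_locus,
                 locus_names = locus_names, fst_target = fst_target,
                 missing_rate = missing_rate,
                 admixture_alpha = admixture_alpha),
            class = "sim_params")
}

# Dirichlet draws via normalized gammas; guards the all-zero corner that
# tiny concentrations can produce in floating point
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  s <- rowSums(g)
  zero <- s == 0
  if (any(zero)) {
    pick <- sample.int(k, sum(zero), replace = TRUE)
    g[zero, ] <- 0
    g[cbind(which(zero), pick)] <- 1
    s[zero] <- 1
  }
  g / s
}

#' Draw population allele frequencies under the Balding-Nichols model
#'
#' Each locus gets an ancestral frequency vector (symmetric Dirichlet(1)
#' unless supplied), and each population's vector is drawn
#' `Dirichlet(ancestral * (1 - F) / F)` for `F > 0`; at `F = 0` every
#' population's vector equals the ancestral vector exactly. The model gives
#' the closed-form variance `Var(p_pop) = F p (1 - p)` per allele, which
#' the test suite exploits.
#'
#' @param params a [sim_params()].
#' @param ancestral optional list of ancestral frequency vectors, one per
#'   locus.
#' @return an object of class `pop_frequencies`: a list with `loci`,
#'   `pop_labels`, and per-locus elements `alleles` (integer codes),
#'   `ancestral` (vector) and `pops` (population x allele matrix).
#' @export
simulate_frequencies <- function(params, ancestral = NULL) {
  stopifnot(inherits(params, "sim_params"))
  k <- length(params$pop_sizes)
  F <- params$fst_target
  per_locus <- vector("list", length(params$alleles_per_locus))
  for (l in seq_along(per_locus)) {
    A <- params$alleles_per_locus[l]
    codes <- as.integer(seq(100L, by = 2L, length.out = A))
    anc <- if (is.null(ancestral)) as.vector(rdirichlet(1, rep(1, A)))
           else ancestral[[l]]
    stopifnot(length(anc) == A, abs(sum(anc) - 1) < 1e-9)
    if (F == 0) {
      pops <- matrix(anc, k, A, byrow = TRUE)
    } else {
      pops <- rdirichlet(k, anc * (1 - F) / F)
    }
    dimnames(pops) <- list(params$pop_labels, codes)
    per_locus[[l]] <- list(alleles = codes, ancestral = anc, pops = pops)
  }
  names(per_locus) <- params$locus_names
  structure(list(loci = params$locus_names, pop_labels = params$pop_labels,
                 freq = per_locus),
            class = "pop_frequencies")
}

#' Simulate diploid genotypes from population frequencies
#'
#' Each individual's two alleles per locus are drawn independently from its
#' population's frequency vector (Hardy-Weinberg within population); with
#' `admixture_alpha` set, each allele copy is drawn from the
#' individual-specific mixture of population frequencies instead. Calls are
#' then dropped (both alleles set missing) independently with probability
#' `missing_rate`.
#'
#' @param freqs a `pop_frequencies` from [simulate_frequencies()].
#' @param params the same [sim_params()] used to build `freqs`.
#' @param id_prefix prefix for generated accession ids.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(freqs, params, id_prefix = "acc") {
  stopifnot(inherits(freqs, "pop_frequencies"), inherits(params, "sim_params"))
  k <- length(params$pop_sizes)
  stopifnot(nrow(freqs$freq[[1L]]$pops) == k)
  n <- sum(params$pop_sizes)
  L <- length(freqs$loci)
  pop_idx <- rep(seq_len(k), times = params$pop_sizes)
  alpha <- params$admixture_alpha
  Q <- NULL
  if (!is.null(alpha)) {
    Q <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
    Q[cbind(seq_len(n), pop_idx)] <-
      stats::rgamma(n, shape = 1 + alpha)
    Q <- Q / rowSums(Q)
  }
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (l in seq_len(L)) {
    fl <- freqs$freq[[l]]
    if (is.null(Q)) {
      pmat <- fl$pops[pop_idx, , drop = FALSE]
    } else {
      pmat <- Q %*% fl$pops
    }
    cum <- t(apply(pmat, 1L, cumsum))
    draw <- function() {
      u <- stats::runif(n) * cum[, ncol(cum)]
      idx <- rowSums(u > cum) + 1L
      fl$alleles[pmin(idx, length(fl$alleles))]
    }
    a1[, l] <- draw()
    a2[, l] <- draw()
    if (params$missing_rate > 0) {
      drop <- stats::runif(n) < params$missing_rate
      a1[drop, l] <- NA_integer_
      a2[drop, l] <- NA_integer_
    }
  }
  genotype_matrix(a1, a2,
                  ids = sprintf("%s%04d", id_prefix, seq_len(n)),
                  pop = params$pop_labels[pop_idx],
                  loci = freqs$loci)
}

#' Design constants of the ancient Sophora japonica SSR panel
#'
#' The published study design this package's simulations emulate: 416
#' accessions from three provinces (Shandong 374, Hebei 16, Shanxi 26),
#' 16 SSR loci with observed allele counts between 4 and 19 (160 alleles in
#' total), overall differentiation near Fst = 0.04, and sporadic missing
#' calls leaving 410-416 scored individuals per locus.
#'
#' @return a [sim_params()] with those constants.
#' @export
sophora_design <- function() {
  sim_params(
    pop_sizes = c(374L, 16L, 26L),
    pop_labels = c("SD", "HB", "SX"),
    alleles_per_locus = c(4L, 10L, 7L, 10L, 19L, 13L, 8L, 10L, 15L, 7L,
                          7L, 8L, 11L, 6L, 12L, 13L),
    locus_names = c("2541", "2128", "2114", "1970", "2844", "3049", "1609",
                    "1302", "1060", "2434", "1820", "1663", "953", "1527",
                    "2270", "756"),
    fst_target = 0.04,
    missing_rate = 0.005)
}

#' Simulate a Sophora-like SSR genotype panel
#'
#' Draws one realization of the [sophora_design()] study: Balding-Nichols
#' population frequencies at F = 0.04 followed by Hardy-Weinberg genotype
#' draws and 0.5% call dropout (expected per-locus sample size about 414 of
#' 416).
#'
#' @param seed integer seed; the draw is fully reproducible given it.
#' @return a [genotype_matrix()] of 416 accessions x 16 loci.
#' @examples
#' gm <- simulate_sophora_panel(seed = 1)
#' gm
#' @export
simulate_sophora_panel <- function(seed = 1L) {
  params <- sophora_design()
  set.seed(seed)
  freqs <- simulate_frequencies(params)
  simulate_genotypes(freqs, params, id_prefix = "SJ")
}
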
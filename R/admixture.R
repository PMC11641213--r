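#' Fit the admixture model by Gibbs sampling
#'
#' A minimal model-based structure inference for unlinked codominant loci:
#' each individual `i` has ancestry proportions `Q[i, ]` over `K` clusters,
#' each cluster `k` has allele frequencies `P[k, l, ]` per locus, and every
#' allele copy is drawn by first picking an origin cluster from `Q[i, ]`
#' and then an allele from that cluster's frequencies. The Gibbs sweep
#' samples the latent origins `Z` of every copy proportional to
#' `q_ik p_kl(a)`, then `P` from Dirichlet(lambda + origin-weighted allele
#' counts) and `Q` from Dirichlet(alpha + per-cluster origin counts).
#' Missing calls contribute nothing. `Q` and `P` are posterior means over
#' post-burn-in thinned samples. The model-choice statistic is
#' `lnPD = mean(logLik) - var(logLik)/2` over the recorded trace, the
#' harmonic-style estimator conventional for this model.
#'
#' Default chain lengths are desk-scale (2,000 burn-in + 8,000 sampling
#' iterations, thinning 10); production-scale settings such as 10,000 +
#' 100,000 are plain arguments.
#'
#' @param x a [genotype_matrix()].
#' @param K number of ancestry clusters (>= 1).
#' @param burn_in discarded initial iterations.
#' @param iterations post-burn-in iterations.
#' @param thin record every `thin`-th post-burn-in iteration.
#' @param alpha Dirichlet concentration of the ancestry prior (fixed, not
#'   sampled).
#' @param lambda Dirichlet concentration of the allele-frequency prior.
#' @param seed integer seed; the chain is reproducible given it.
#' @return an object of class `admixture_fit`: list with `K`, `Q`
#'   (accessions x K posterior means), `P` (per locus, K x alleles
#'   posterior means), `lnPD`, `loglik_trace`, and the chain settings.
#' @examples
#' \donttest{
#' p <- sim_params(c(30, 30), rep(2, 10), fst_target = 0.3)
#' set.seed(7)
#' gm <- simulate_genotypes(simulate_frequencies(p), p)
#' fit <- fit_admixture(gm, K = 2, burn_in = 200, iterations = 800, seed = 1)
#' head(fit$Q)
#' }
#' @export
fit_admixture <- function(x, K, burn_in = 2000L, iterations = 8000L,
                          thin = 10L, alpha = 1.0, lambda = 1.0, seed = 1L) {
  validate_genotype_matrix(x)
  if (K < 1L) stop("K must be at least 1")
  if (iterations < thin)
    stop("iterations must cover at least one recording interval")
  set.seed(seed)
  n <- n_ind(x)
  L <- n_loci(x)
  # per-locus allele index coding; copies stacked as 2n rows per locus
  allele_codes <- vector("list", L)
  copy_idx <- vector("list", L)   # which of the 2n copies are scored
  copy_ind <- vector("list", L)   # individual of each scored copy
  copy_allele <- vector("list", L)
  for (l in seq_len(L)) {
    al <- c(x$a1[, l], x$a2[, l])
    codes <- sort(unique(al[!is.na(al)]))
    if (length(codes) == 0L) {
      warning("locus ", x$loci[l], " has no data; skipped")
      allele_codes[[l]] <- integer(0)
      next
    }
    allele_codes[[l]] <- codes
    sc <- which(!is.na(al))
    copy_idx[[l]] <- sc
    copy_ind[[l]] <- ((sc - 1L) %% n) + 1L
    copy_allele[[l]] <- match(al[sc], codes)
  }
  used <- which(lengths(allele_codes) > 0L)
  P <- lapply(seq_len(L), function(l) {
    A <- length(allele_codes[[l]])
    if (A == 0L) return(NULL)
    m <- rdirichlet(K, rep(lambda, A))
    dimnames(m) <- list(NULL, allele_codes[[l]])
    m
  })
  Q <- matrix(1 / K, n, K)
  Qsum <- matrix(0, n, K)
  Psum <- lapply(P, function(m) if (is.null(m)) NULL else m * 0)
  trace <- numeric(0)
  nrec <- 0L
  total <- burn_in + iterations
  for (it in seq_len(total)) {
    qcounts <- matrix(0, n, K)
    record <- it > burn_in && (it - burn_in) %% thin == 0L
    ll <- 0
    for (l in used) {
      A <- length(allele_codes[[l]])
      ii <- copy_ind[[l]]
      aa <- copy_allele[[l]]
      W <- Q[ii, , drop = FALSE] * t(P[[l]])[aa, , drop = FALSE]
      if (record) ll <- ll + sum(log(rowSums(W)))
      z <- sample_categorical_rows(W)
      # allele x cluster counts for P update
      cnt <- matrix(tabulate(aa + A * (z - 1L), nbins = A * K), A, K)
      P[[l]] <- rdirichlet_byrow(t(cnt) + lambda)
      dimnames(P[[l]]) <- list(NULL, allele_codes[[l]])
      qcounts <- qcounts +
        matrix(tabulate(ii + n * (z - 1L), nbins = n * K), n, K)
    }
    if (K == 1L) {
      Q[] <- 1
    } else {
      Q <- rdirichlet_byrow(qcounts + alpha)
    }
    if (record) {
      nrec <- nrec + 1L
      trace[nrec] <- ll
      Qsum <- Qsum + Q
      for (l in used) Psum[[l]] <- Psum[[l]] + P[[l]]
    }
  }
  Qm <- Qsum / nrec
  rownames(Qm) <- x$ids
  colnames(Qm) <- paste0("K", seq_len(K))
  Pm <- lapply(Psum, function(m) if (is.null(m)) NULL else m / nrec)
  names(Pm) <- x$loci
  lnPD <- mean(trace) - stats::var(trace) / 2
  if (length(trace) < 2L) lnPD <- mean(trace)
  structure(list(K = K, Q = Qm, P = Pm, lnPD = lnPD, loglik_trace = trace,
                 seed = seed, burn_in = burn_in, iterations = iterations,
                 thin = thin, alpha = alpha, lambda = lambda),
            class = "admixture_fit")
}

# one categorical draw per row of a non-negative weight matrix
sample_categorical_rows <- function(W) {
  m <- nrow(W)
  K <- ncol(W)
  u <- stats::runif(m) * rowSums(W)
  z <- rep(1L, m)
  if (K > 1L) {
    cs <- W[, 1L]
    for (k in seq_len(K - 1L)) {
      z <- z + (u > cs)
      if (k < K - 1L) cs <- cs + W[, k + 1L]
    }
  }
  z
}

# independent Dirichlet draw per row of a positive shape matrix
rdirichlet_byrow <- function(shape) {
  g <- matrix(stats::rgamma(length(shape), shape = shape), nrow(shape))
  s <- rowSums(g)
  bad <- s == 0
  if (any(bad)) {
    g[bad, ] <- 1
    s[bad] <- ncol(shape)
  }
  g / s
}

#' Evanno delta-K table
#'
#' Chooses the number of clusters from replicate model log-probabilities:
#' `L'(K) = mean L(K) - mean L(K-1)`, `|L''(K)| = |L'(K+1) - L'(K)|`, and
#' `deltaK = |L''(K)| / sd(L(K))`, defined only for interior K. The chosen
#' K maximizes deltaK; if every second difference is zero the choice is
#' flagged ambiguous (`chosen_K = NA`).
#'
#' @param lnPD_by_K named list: K value (coercible to integer, consecutive)
#'   -> numeric vector of replicate lnPD values (>= 2 replicates each).
#' @return an object of class `evanno_table`: data frame with columns `K`,
#'   `reps`, `mean_lnPD`, `sd_lnPD`, `Lprime`, `Lsecond`, `deltaK`, plus
#'   attribute `chosen_K`.
#' @examples
#' ev <- evanno(list(`1` = c(-101, -99), `2` = c(-51, -49),
#'                   `3` = c(-46, -44), `4` = c(-45, -43)))
#' attr(ev, "chosen_K")
#' @export
evanno <- function(lnPD_by_K) {
  Ks <- as.integer(names(lnPD_by_K))
  if (anyNA(Ks)) stop("names of lnPD_by_K must be the K values")
  o <- order(Ks)
  Ks <- Ks[o]
  vals <- lnPD_by_K[o]
  if (length(Ks) < 3L)
    stop("need at least 3 consecutive K values to compute deltaK")
  if (any(diff(Ks) != 1L)) stop("K values must be consecutive")
  if (any(lengths(vals) < 2L))
    stop("need >= 2 replicates per K for the sd")
  mu <- vapply(vals, mean, numeric(1))
  sdv <- vapply(vals, stats::sd, numeric(1))
  m <- length(Ks)
  Lp <- c(NA, diff(mu))                       # L'(K), defined from 2nd K
  Ls <- rep(NA_real_, m)
  Ls[2:(m - 1L)] <- abs(Lp[3:m] - Lp[2:(m - 1L)])
  dK <- rep(NA_real_, m)
  interior <- 2:(m - 1L)
  zero_sd <- sdv[interior] == 0 & !is.na(Ls[interior])
  if (any(zero_sd))
    warning("zero sd of lnPD at K = ",
            paste(Ks[interior][zero_sd], collapse = ", "),
            "; deltaK reported as Inf")
  dK[interior] <- ifelse(sdv[interior] > 0, Ls[interior] / sdv[interior],
                         ifelse(Ls[interior] > 0, Inf, 0))
  out <- data.frame(K = Ks, reps = lengths(vals), mean_lnPD = mu,
                    sd_lnPD = sdv, Lprime = Lp, Lsecond = Ls, deltaK = dK)
  chosen <- if (all(dK[interior] == 0, na.rm = TRUE)) {
    warning("all second differences are zero; chosen K is ambiguous")
    NA_integer_
  } else Ks[interior][which.max(dK[interior])]
  structure(out, chosen_K = chosen, class = c("evanno_table", "data.frame"))
}

#' Align replicate admixture fits and average Q
#'
#' Handles label switching across replicate chains: each replicate's Q
#' columns are greedily permuted to best match the first replicate
#' (maximizing column correlation, falling back to negative squared
#' distance for constant columns), then the aligned Q matrices are
#' averaged.
#'
#' @param results list of `admixture_fit` objects with identical K and
#'   accessions.
#' @return list with `Q` (mean aligned matrix) and `permutations` (one
#'   integer vector per replicate).
#' @export
align_replicates <- function(results) {
  stopifnot(length(results) >= 1L)
  K <- results[[1L]]$K
  ids <- rownames(results[[1L]]$Q)
  for (r in results) {
    if (r$K != K) stop("mixed K across replicates")
    if (!identical(rownames(r$Q), ids))
      stop("replicates cover different accessions")
  }
  ref <- results[[1L]]$Q
  perms <- vector("list", length(results))
  perms[[1L]] <- seq_len(K)
  acc <- ref
  if (length(results) > 1L) {
    for (r in seq(2L, length(results))) {
      Q <- results[[r]]$Q
      score <- matrix(NA_real_, K, K)
      for (a in seq_len(K)) for (b in seq_len(K)) {
        if (stats::sd(ref[, a]) > 0 && stats::sd(Q[, b]) > 0) {
          score[a, b] <- stats::cor(ref[, a], Q[, b])
        } else {
          score[a, b] <- -mean((ref[, a] - Q[, b])^2)
        }
      }
      perm <- integer(K)
      free <- rep(TRUE, K)
      for (a in seq_len(K)) {
        b <- which.max(ifelse(free, score[a, ], -Inf))
        perm[a] <- b
        free[b] <- FALSE
      }
      perms[[r]] <- perm
      acc <- acc + Q[, perm, drop = FALSE]
    }
  }
  list(Q = acc / length(results), permutations = perms)
}

#' Scan K values with replicate admixture runs
#'
#' Convenience driver: fits `reps` chains at every K in `k_range` (seeds
#' derived from `seed`), collects the lnPD values, and applies [evanno()].
#'
#' @param x a [genotype_matrix()].
#' @param k_range integer vector of consecutive K values (>= 3 of them for
#'   deltaK).
#' @param reps replicate chains per K.
#' @param seed base seed; chain r at the i-th K uses
#'   `seed + 1000 * i + r`.
#' @param ... passed to [fit_admixture()].
#' @return list with `fits` (list of lists of `admixture_fit`), `lnPD`
#'   (named list), and `evanno` (when >= 3 K values).
#' @export
structure_scan <- function(x, k_range = 2:6, reps = 10L, seed = 1L, ...) {
  fits <- vector("list", length(k_range))
  names(fits) <- k_range
  lnPD <- vector("list", length(k_range))
  names(lnPD) <- k_range
  for (i in seq_along(k_range)) {
    fits[[i]] <- lapply(seq_len(reps), function(r)
      fit_admixture(x, K = k_range[i], seed = seed + 1000L * i + r, ...))
    lnPD[[i]] <- vapply(fits[[i]], function(f) f$lnPD, numeric(1))
  }
  ev <- if (length(k_range) >= 3L) evanno(lnPD) else NULL
  list(fits = fits, lnPD = lnPD, evanno = ev)
}
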
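# Fixture builders and independent brute-force oracles shared across tests.

# random genotype matrix: k populations of size n_per, L loci, A alleles per
# locus, optional MCAR missingness
rand_gm <- function(n_per = 5, L = 3, k = 2, A = 3, missing = 0) {
  n <- n_per * k
  codes <- 100L + 2L * seq_len(A)
  a1 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
  a2 <- matrix(sample(codes, n * L, replace = TRUE), n, L)
  if (missing > 0) {
    drop <- matrix(runif(n * L) < missing, n, L)
    a1[drop] <- NA_integer_
    a2[drop] <- NA_integer_
    # never leave an accession with no data at all
    empty <- rowSums(!is.na(a1)) == 0
    a1[empty, 1L] <- codes[1L]
    a2[empty, 1L] <- codes[1L]
  }
  genotype_matrix(a1, a2, ids = sprintf("A%03d", seq_len(n)),
                  pop = rep(paste0("P", seq_len(k)), each = n_per),
                  loci = paste0("L", seq_len(L)))
}

# build a genotype matrix from per-locus genotype strings "a/b" ("." missing)
gm_from_calls <- function(calls, pop = NULL, ids = NULL) {
  m <- as.matrix(calls)
  n <- nrow(m); L <- ncol(m)
  a1 <- a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) for (l in seq_len(L)) {
    if (m[i, l] != ".") {
      ab <- as.integer(strsplit(m[i, l], "/", fixed = TRUE)[[1L]])
      a1[i, l] <- ab[1L]; a2[i, l] <- ab[2L]
    }
  }
  if (is.null(ids)) ids <- if (!is.null(rownames(m))) rownames(m)
                           else paste0("A", seq_len(n))
  if (is.null(pop)) pop <- rep("P1", n)
  loci <- if (!is.null(colnames(m))) colnames(m) else paste0("L", seq_len(L))
  genotype_matrix(a1, a2, ids = ids, pop = pop, loci = loci)
}

# explicit double-loop He / PIC from an allele frequency vector
bf_he_pic <- function(p) {
  p <- unname(p)
  he <- 1
  for (i in seq_along(p)) he <- he - p[i]^2
  pic <- he
  for (i in seq_along(p)) for (j in seq_along(p))
    if (i < j) pic <- pic - 2 * p[i]^2 * p[j]^2
  list(He = he, PIC = pic)
}

# brute-force AMOVA sums of squares from pairwise squared distances between
# allele copies (d^2 = 2 for different alleles); SS of a group of m copies
# is the pair sum divided by m
bf_ss_group <- function(al) {
  m <- length(al)
  if (m < 2L) return(0)
  s <- 0
  for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m))
    s <- s + 2 * (al[i] != al[j])
  s / m
}

bf_amova_ss <- function(gm) {
  ss_pop <- ss_ind <- ss_within <- 0
  for (l in seq_len(n_loci(gm))) {
    sc <- which(!is.na(gm$a1[, l]))
    al <- c(gm$a1[sc, l], gm$a2[sc, l])
    pp <- rep(as.character(gm$pop)[sc], 2L)
    tot_l <- bf_ss_group(al)
    w_l <- sum(vapply(sc, function(i)
      bf_ss_group(c(gm$a1[i, l], gm$a2[i, l])), numeric(1)))
    p_l <- sum(vapply(unique(pp), function(P)
      bf_ss_group(al[pp == P]), numeric(1)))
    ss_within <- ss_within + w_l
    ss_ind <- ss_ind + (p_l - w_l)
    ss_pop <- ss_pop + (tot_l - p_l)
  }
  c(among_pop = ss_pop, among_ind = ss_ind, within_ind = ss_within)
}

rdirichlet_rows_for_test <- function(n, k) {
  g <- matrix(rgamma(n * k, 1), n, k)
  g / rowSums(g)
}

# mean over loci of He for an accession subset (plain recomputation)
mean_he_of <- function(gm, ids) {
  mean(locus_summaries(subset_accessions(gm, ids))$He, na.rm = TRUE)
}
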
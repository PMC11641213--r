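#' Diploid SSR genotype matrix
#'
#' The central data container of the package: codominant diploid genotype
#' calls for a set of accessions at a set of microsatellite loci, together
#' with a population label per accession. Allele codes are opaque positive
#' integers (typically fragment sizes in base pairs); no binning or size
#' calling is performed. A missing genotype is recorded as `NA` in *both*
#' allele slots -- missingness is pair-level, matching how per-locus sample
#' sizes are counted downstream.
#'
#' @param allele1,allele2 integer matrices (accessions x loci) holding the
#'   two allele codes of each call; `NA` in both marks a missing call.
#'   Within a call the pair is unordered; it is stored with
#'   `allele1 <= allele2`.
#' @param ids character vector of unique accession identifiers.
#' @param pop factor (or character) of population labels, one per accession.
#' @param loci character vector of unique locus names.
#' @return An object of class `genotype_matrix` with fields `ids`, `pop`,
#'   `loci`, `a1`, `a2`.
#' @examples
#' gm <- genotype_matrix(matrix(c(120L, 120L), 2, 1),
#'                       matrix(c(122L, 120L), 2, 1),
#'                       ids = c("A1", "A2"), pop = c("P1", "P1"),
#'                       loci = "L1")
#' n_ind(gm)
#' @export
genotype_matrix <- function(allele1, allele2, ids, pop, loci) {
  a1 <- as.matrix(allele1)
  a2 <- as.matrix(allele2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  ids <- as.character(ids)
  loci <- as.character(loci)
  pop <- factor(pop, levels = unique(as.character(pop)))
  # store each unordered pair in sorted slot order for determinism
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]
    a1[swap] <- a2[swap]
    a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  obj <- structure(list(ids = ids, pop = pop, loci = loci, a1 = a1, a2 = a2),
                   class = "genotype_matrix")
  validate_genotype_matrix(obj)
  obj
}

#' Validate a genotype matrix
#'
#' Checks every structural invariant of the container and stops with a
#' message naming the offending accession or locus on the first violation.
#'
#' @param x a `genotype_matrix`.
#' @return `x`, invisibly, if valid.
#' @export
validate_genotype_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  n <- length(x$ids)
  L <- length(x$loci)
  if (n < 1L) stop("genotype matrix must contain at least one accession")
  if (L < 1L) stop("genotype matrix must contain at least one locus")
  if (anyDuplicated(x$ids))
    stop("duplicate accession id: ", x$ids[anyDuplicated(x$ids)])
  if (anyDuplicated(x$loci))
    stop("duplicate locus name: ", x$loci[anyDuplicated(x$loci)])
  if (length(x$pop) != n)
    stop("population vector length ", length(x$pop),
         " does not match accession count ", n)
  if (nlevels(x$pop) < 1L) stop("at least one population is required")
  if (!identical(dim(x$a1), c(n, L)) || !identical(dim(x$a2), c(n, L)))
    stop("allele matrices must be accessions x loci")
  half <- xor(is.na(x$a1), is.na(x$a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)[1L, ]
    stop("half-missing call at accession ", x$ids[w[1L]],
         ", locus ", x$loci[w[2L]],
         " (one allele slot NA); promote to fully missing first")
  }
  bad <- (!is.na(x$a1) & x$a1 <= 0L) | (!is.na(x$a2) & x$a2 <= 0L)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-positive allele code at accession ", x$ids[w[1L]],
         ", locus ", x$loci[w[2L]])
  }
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "accessions x",
      length(x$loci), "loci,", nlevels(x$pop), "population(s)\n")
  miss <- sum(is.na(x$a1))
  cat("  populations:",
      paste(sprintf("%s (%d)", levels(x$pop), tabulate(x$pop)),
            collapse = ", "), "\n")
  cat(sprintf("  missing calls: %d (%.2f%%)\n", miss,
              100 * miss / length(x$a1)))
  invisible(x)
}

#' Number of accessions / loci
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_ind <- function(x) length(x$ids)

#' @rdname n_ind
#' @export
n_loci <- function(x) length(x$loci)

#' Subset a genotype matrix by accession
#'
#' @param x a `genotype_matrix`.
#' @param ids accession identifiers to keep (order preserved as given).
#' @return a `genotype_matrix` restricted to `ids`.
#' @export
subset_accessions <- function(x, ids) {
  idx <- match(ids, x$ids)
  if (anyNA(idx)) stop("unknown accession id: ", ids[which(is.na(idx))[1L]])
  genotype_matrix(x$a1[idx, , drop = FALSE], x$a2[idx, , drop = FALSE],
                  ids = x$ids[idx], pop = as.character(x$pop)[idx],
                  loci = x$loci)
}

#' Per-locus non-missing sample sizes
#' @param x a `genotype_matrix`.
#' @return named integer vector, individuals with a scored call per locus.
#' @export
locus_n <- function(x) {
  n <- colSums(!is.na(x$a1))
  names(n) <- x$loci
  n
}
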
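#' Read a GenAlEx-dialect codominant genotype CSV
#'
#' The dialect has three comma-separated header lines: (1) counts -- number
#' of loci, number of samples, number of populations, then one size per
#' population; (2) a title row whose columns 4 onward carry the population
#' labels aligned with the sizes; (3) column headers -- `id`, `pop`, then
#' each locus name heading its first allele column (second column blank).
#' Each data row is one individual: id, population label, then two integer
#' allele columns per locus. `0` is the missing sentinel; a half-missing
#' pair (one allele 0) is promoted to a fully missing call with a warning.
#' Population membership follows the header's population blocks (the first
#' `size1` rows belong to population 1, and so on).
#'
#' @param path path to the CSV file.
#' @return a [genotype_matrix()].
#' @seealso [write_genalex()], [read_structure()]
#' @export
read_genalex <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 4L) stop("GenAlEx file too short: ", path)
  counts <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  counts <- suppressWarnings(as.integer(counts))
  if (length(counts) < 3L || anyNA(counts[1:3]))
    stop("malformed GenAlEx count header (line 1)")
  L <- counts[1L]; n <- counts[2L]; k <- counts[3L]
  sizes <- counts[seq_len(k) + 3L]
  if (anyNA(sizes) || sum(sizes) != n)
    stop("GenAlEx header: population sizes ",
         paste(sizes, collapse = "+"), " do not sum to sample count ", n)
  title_row <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  pop_labels <- title_row[seq_len(k) + 3L]
  pop_labels[is.na(pop_labels) | !nzchar(pop_labels)] <-
    paste0("pop", seq_len(k))[is.na(pop_labels) | !nzchar(pop_labels)]
  hdr <- strsplit(lines[3L], ",", fixed = TRUE)[[1L]]
  loci <- hdr[seq(3L, by = 2L, length.out = L)]
  loci <- trimws(loci)
  if (any(!nzchar(loci))) stop("GenAlEx header: empty locus name (line 3)")

  data_lines <- lines[-(1:3)]
  if (length(data_lines) != n)
    stop("GenAlEx header declares ", n, " samples but file has ",
         length(data_lines), " data rows (first data row is line 4)")
  cells <- strsplit(data_lines, ",", fixed = TRUE)
  ids <- character(n)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (i in seq_len(n)) {
    row <- trimws(cells[[i]])
    if (length(row) < 2L + 2L * L)
      stop("GenAlEx data row ", i, " has ", length(row),
           " columns; expected ", 2L + 2L * L)
    ids[i] <- row[1L]
    vals <- suppressWarnings(as.integer(row[2L + seq_len(2L * L)]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop("non-integer allele cell at data row ", i,
           ", column ", 2L + j, " (locus ", loci[ceiling(j / 2)], ")")
    }
    a1[i, ] <- vals[seq(1L, 2L * L, by = 2L)]
    a2[i, ] <- vals[seq(2L, 2L * L, by = 2L)]
  }
  if (anyDuplicated(ids))
    stop("duplicate accession id: ", ids[anyDuplicated(ids)])
  pop <- rep(pop_labels, times = sizes)
  gm <- build_from_raw(a1, a2, ids, pop, loci)
  gm
}

# shared assembly: 0 -> NA sentinel, half-missing promotion with warning
build_from_raw <- function(a1, a2, ids, pop, loci, sentinel = 0L) {
  a1[a1 == sentinel] <- NA_integer_
  a2[a2 == sentinel] <- NA_integer_
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    w <- which(half, arr.ind = TRUE)
    warning(sum(half), " half-missing call(s) promoted to fully missing ",
            "(first: accession ", ids[w[1L, 1L]], ", locus ",
            loci[w[1L, 2L]], ")")
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  genotype_matrix(a1, a2, ids = ids, pop = pop, loci = loci)
}

#' Write a genotype matrix in the GenAlEx dialect
#'
#' Output is byte-stable for a fixed matrix: fixed column order, LF line
#' endings, missing calls written as `0,0`.
#'
#' @param x a `genotype_matrix`.
#' @param path output file path.
#' @param title dataset title placed in the second header row.
#' @return `path`, invisibly.
#' @export
write_genalex <- function(x, path, title = "ssrpop export") {
  validate_genotype_matrix(x)
  ord <- order(as.integer(x$pop))  # contiguous population blocks
  a1 <- x$a1[ord, , drop = FALSE]
  a2 <- x$a2[ord, , drop = FALSE]
  ids <- x$ids[ord]
  sizes <- tabulate(x$pop)
  k <- nlevels(x$pop)
  L <- n_loci(x)
  line1 <- paste(c(L, n_ind(x), k, sizes), collapse = ",")
  line2 <- paste(c(title, "", "", levels(x$pop)), collapse = ",")
  locus_cols <- as.vector(rbind(x$loci, ""))
  line3 <- paste(c("id", "pop", locus_cols), collapse = ",")
  a1c <- a1; a2c <- a2
  a1c[is.na(a1c)] <- 0L
  a2c[is.na(a2c)] <- 0L
  body <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], as.character(x$pop[ord][i]),
            as.vector(rbind(a1c[i, ], a2c[i, ]))), collapse = ",")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(line1, line2, line3, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a STRUCTURE-format genotype file
#'
#' Two consecutive whitespace-separated rows per individual, one allele per
#' locus per row; column 1 is the individual id, column 2 an integer
#' population code; `-9` is the missing sentinel. Population codes are
#' mapped to labels in ascending order of first appearance (code 1 -> first
#' label, ...).
#'
#' @param path path to the file.
#' @param markers ordered locus names; must match the allele column count.
#' @param pop_labels optional character vector naming the population codes
#'   (in ascending code order); defaults to the codes as characters.
#' @return a [genotype_matrix()].
#' @export
read_structure <- function(path, markers, pop_labels = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) %% 2L != 0L)
    stop("STRUCTURE file has an odd number of data rows (",
         nrow(tab), "); two rows per individual required")
  L <- length(markers)
  if (ncol(tab) != 2L + L)
    stop("STRUCTURE file has ", ncol(tab) - 2L,
         " allele columns; expected ", L, " markers")
  odd <- seq(1L, nrow(tab), by = 2L)
  even <- odd + 1L
  if (!all(tab[odd, 1L] == tab[even, 1L])) {
    bad <- which(tab[odd, 1L] != tab[even, 1L])[1L]
    stop("mismatched ids between the two rows of individual ", bad,
         ": '", tab[odd[bad], 1L], "' vs '", tab[even[bad], 1L], "'")
  }
  ids <- as.character(tab[odd, 1L])
  codes <- as.integer(tab[odd, 2L])
  ucodes <- sort(unique(codes))
  if (is.null(pop_labels)) pop_labels <- as.character(ucodes)
  if (length(pop_labels) != length(ucodes))
    stop("pop_labels length ", length(pop_labels),
         " does not match the ", length(ucodes), " population codes")
  pop <- pop_labels[match(codes, ucodes)]
  a1 <- as.matrix(tab[odd, 2L + seq_len(L)])
  a2 <- as.matrix(tab[even, 2L + seq_len(L)])
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  build_from_raw(a1, a2, ids, pop, markers, sentinel = -9L)
}

#' Write a genotype matrix in STRUCTURE two-row format
#'
#' @param x a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  validate_genotype_matrix(x)
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- -9L
  a2[is.na(a2)] <- -9L
  code <- as.integer(x$pop)
  rows <- character(2L * n_ind(x))
  for (i in seq_len(n_ind(x))) {
    rows[2L * i - 1L] <- paste(c(x$ids[i], code[i], a1[i, ]), collapse = " ")
    rows[2L * i] <- paste(c(x$ids[i], code[i], a2[i, ]), collapse = " ")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Export a genotype matrix
#'
#' Single entry point over the supported output dialects. `csv_long` writes
#' one row per accession/locus/allele-slot with columns
#' `id,pop,locus,slot,allele` (empty allele for missing).
#'
#' @param x a `genotype_matrix`.
#' @param format one of `"genalex"`, `"structure"`, `"csv_long"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_genotypes <- function(x, format = c("genalex", "structure", "csv_long"),
                             path) {
  validate_genotype_matrix(x)
  format <- match.arg(format)
  switch(format,
    genalex = write_genalex(x, path),
    structure = write_structure(x, path),
    csv_long = {
      n <- n_ind(x); L <- n_loci(x)
      df <- data.frame(
        id = rep(x$ids, each = 2L * L),
        pop = rep(as.character(x$pop), each = 2L * L),
        locus = rep(rep(x$loci, each = 2L), times = n),
        slot = rep(1:2, times = n * L),
        allele = as.vector(vapply(seq_len(n), function(i)
          as.vector(rbind(x$a1[i, ], x$a2[i, ])), integer(2L * L))),
        stringsAsFactors = FALSE)
      con <- file(path, open = "wb")
      on.exit(close(con))
      writeLines(c("id,pop,locus,slot,allele",
                   sprintf("%s,%s,%s,%d,%s", df$id, df$pop, df$locus,
                           df$slot,
                           ifelse(is.na(df$allele), "", df$allele))),
                 con, sep = "\n", useBytes = TRUE)
      invisible(path)
    })
}
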
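#' Microsatellite genotype table
#'
#' Diploid multilocus genotypes for a set of individuals, with optional
#' sampling locality and projected coordinates. Alleles are positive integer
#' labels; missing genotypes are `NA` (both gene copies of a locus).
#'
#' @param ids character vector of unique individual ids.
#' @param alleles integer array `n x L x 2` of allele labels (`NA` missing),
#'   with locus names on the second dimension.
#' @param locality optional character vector of locality ids (recycled `NA`).
#' @param coords optional two-column matrix of easting/northing (meters).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ids, alleles, locality = NULL, coords = NULL) {
  ids <- as.character(ids)
  n <- length(ids)
  if (anyDuplicated(ids))
    stop("duplicate individual_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(dim(alleles)) != 3L || dim(alleles)[3] != 2L)
    stop("alleles must be an n x L x 2 array")
  if (dim(alleles)[1] != n) stop("alleles rows do not match ids")
  storage.mode(alleles) <- "integer"
  if (is.null(dimnames(alleles)[[2]]))
    dimnames(alleles)[[2]] <- paste0("L", seq_len(dim(alleles)[2]))
  obs <- alleles[!is.na(alleles)]
  if (length(obs) && any(obs <= 0L))
    stop("allele labels must be positive integers")
  # a genotype is missing as a whole: if one copy is NA, drop both
  half <- xor(is.na(alleles[, , 1, drop = FALSE]),
              is.na(alleles[, , 2, drop = FALSE]))
  if (any(half)) {
    alleles[, , 1][half[, , 1]] <- NA_integer_
    alleles[, , 2][half[, , 1]] <- NA_integer_
  }
  typed <- matrix(!is.na(alleles[, , 1]), nrow = n)
  if (any(rowSums(typed) == 0L))
    stop("individuals with no typed locus: ",
         paste(ids[rowSums(typed) == 0L], collapse = ", "))
  if (any(colSums(typed) == 0L))
    stop("loci with no observed allele: ",
         paste(dimnames(alleles)[[2]][colSums(typed) == 0L], collapse = ", "))
  if (is.null(locality)) locality <- rep(NA_character_, n)
  locality <- as.character(locality)
  if (length(locality) != n) stop("locality length does not match ids")
  if (!is.null(coords)) {
    coords <- as.matrix(coords)[, 1:2, drop = FALSE]
    if (nrow(coords) != n) stop("coords rows do not match ids")
    if (any(!is.finite(coords))) stop("coordinates must be finite")
    colnames(coords) <- c("x", "y")
    rownames(coords) <- ids
  }
  structure(list(ids = ids, alleles = alleles, locality = locality,
                 coords = coords),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d individuals x %d loci\n",
              n_individuals(x), n_loci(x)))
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  localities: %d; missing genotypes: %.1f%%; coords: %s\n",
              length(unique(stats::na.omit(x$locality))), 100 * miss,
              if (is.null(x$coords)) "absent" else "present"))
  invisible(x)
}

#' @rdname genotype_table
#' @param g a `genotype_table`.
#' @export
n_individuals <- function(g) length(g$ids)

#' @rdname genotype_table
#' @export
n_loci <- function(g) dim(g$alleles)[2]

#' @rdname genotype_table
#' @export
locus_names <- function(g) dimnames(g$alleles)[[2]]

# n x L logical: genotype observed at locus
typed_matrix <- function(g) {
  matrix(!is.na(g$alleles[, , 1]), nrow = n_individuals(g))
}

#' Subset a genotype table by individual id
#'
#' @param g a [genotype_table()].
#' @param keep character vector of ids to retain.
#' @export
subset_individuals <- function(g, keep) {
  keep <- as.character(keep)
  miss <- setdiff(keep, g$ids)
  if (length(miss)) stop("unknown ids: ", paste(miss, collapse = ", "))
  sel <- match(keep, g$ids)
  genotype_table(g$ids[sel], g$alleles[sel, , , drop = FALSE],
                 locality = g$locality[sel],
                 coords = if (is.null(g$coords)) NULL else
                   g$coords[sel, , drop = FALSE])
}

#' Read genotypes from CSV
#'
#' Wide layout: an `id` column, an optional `locality` column, then either
#' two columns per locus (`locus.1`, `locus.2`) or, when `allele_sep` is
#' given, one delimited column per locus (e.g. `"123/127"`).
#'
#' @param path CSV file with a header row.
#' @param missing_code token coding a missing gene copy (default `"0"`;
#'   `"0/0"` and `NA` cells are treated as missing too).
#' @param allele_sep delimiter for one-column-per-locus dialect, or `NULL`
#'   (default) for the two-columns-per-locus dialect.
#' @param coords optional data frame / path of `id, x, y` sampling
#'   coordinates to attach (see [read_coordinates()]).
#' @param quiet suppress the parsing summary message.
#' @return A validated [genotype_table()].
#' @export
read_genotypes <- function(path, missing_code = "0", allele_sep = NULL,
                           coords = NULL, quiet = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2L) stop("genotype CSV needs an id column plus loci")
  ids <- df[[1]]
  has_loc <- tolower(names(df)[2]) %in% c("locality", "locality_id", "site")
  locality <- if (has_loc) df[[2]] else NULL
  gcols <- df[, (2L + has_loc):ncol(df), drop = FALSE]

  parse_token <- function(tok, row, colname) {
    tok <- trimws(tok)
    if (is.na(tok) || tok == "" || tok == missing_code ||
        toupper(tok) == "NA")
      return(NA_integer_)
    val <- suppressWarnings(as.integer(tok))
    if (is.na(val) || val < 0L)
      stop(sprintf("malformed allele token '%s' at row %d, column '%s'",
                   tok, row, colname), call. = FALSE)
    if (val == 0L) NA_integer_ else val
  }

  if (is.null(allele_sep)) {
    if (ncol(gcols) %% 2L != 0L)
      stop("two-columns-per-locus dialect needs an even number of ",
           "genotype columns; got ", ncol(gcols))
    L <- ncol(gcols) %/% 2L
    loci <- sub("[._ ]?[12aAbB]$", "", names(gcols)[seq(1L, by = 2L,
                                                        length.out = L)])
    arr <- array(NA_integer_, dim = c(nrow(df), L, 2L),
                 dimnames = list(NULL, loci, NULL))
    for (l in seq_len(L)) {
      for (a in 1:2) {
        cn <- names(gcols)[2L * (l - 1L) + a]
        arr[, l, a] <- vapply(seq_len(nrow(df)), function(r)
          parse_token(gcols[r, 2L * (l - 1L) + a], r, cn), integer(1))
      }
    }
  } else {
    L <- ncol(gcols)
    loci <- names(gcols)
    arr <- array(NA_integer_, dim = c(nrow(df), L, 2L),
                 dimnames = list(NULL, loci, NULL))
    for (l in seq_len(L)) {
      for (r in seq_len(nrow(df))) {
        tok <- trimws(gcols[r, l])
        if (is.na(tok) || tok == "" || toupper(tok) == "NA" ||
            tok == missing_code) next
        parts <- strsplit(tok, allele_sep, fixed = TRUE)[[1]]
        if (length(parts) != 2L)
          stop(sprintf("malformed genotype '%s' at row %d, column '%s'",
                       tok, r, loci[l]), call. = FALSE)
        a1 <- parse_token(parts[1], r, loci[l])
        a2 <- parse_token(parts[2], r, loci[l])
        if (!is.na(a1) && !is.na(a2)) {
          arr[r, l, 1] <- a1
          arr[r, l, 2] <- a2
        }
      }
    }
  }

  if (!is.null(coords) && !is.matrix(coords) && !is.data.frame(coords))
    coords <- read_coordinates(coords)
  cmat <- NULL
  if (!is.null(coords)) {
    cdf <- as.data.frame(coords)
    if (!"id" %in% names(cdf)) names(cdf)[1:3] <- c("id", "x", "y")
    sel <- match(ids, cdf$id)
    if (anyNA(sel))
      stop("coordinates missing for: ",
           paste(ids[is.na(sel)], collapse = ", "))
    cmat <- as.matrix(cdf[sel, c("x", "y")])
  }
  g <- genotype_table(ids, arr, locality = locality, coords = cmat)
  if (!quiet) {
    na_frac <- mean(is.na(g$alleles[, , 1]))
    message(sprintf(
      "read %d individuals x %d loci (%s); %.1f%% missing genotypes; %s",
      n_individuals(g), n_loci(g),
      paste(utils::head(locus_names(g), 5L), collapse = ", "),
      100 * na_frac,
      paste0("alleles/locus: ",
             paste(vapply(seq_len(n_loci(g)), function(l)
               length(unique(stats::na.omit(c(g$alleles[, l, ])))),
               integer(1)), collapse = "/"))))
  }
  g
}

#' Write genotypes to CSV (delimited one-column-per-locus dialect)
#'
#' @param g a [genotype_table()].
#' @param path output file.
#' @param missing_code token written for missing genotypes.
#' @param allele_sep delimiter between the two alleles.
#' @export
write_genotypes <- function(g, path, missing_code = "0", allele_sep = "/") {
  L <- n_loci(g)
  out <- data.frame(id = g$ids, stringsAsFactors = FALSE)
  if (any(!is.na(g$locality))) out$locality <- g$locality
  for (l in seq_len(L)) {
    a1 <- g$alleles[, l, 1]
    a2 <- g$alleles[, l, 2]
    tok <- ifelse(is.na(a1), missing_code,
                  paste0(a1, allele_sep, a2))
    out[[locus_names(g)[l]]] <- tok
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a sampling-coordinates CSV (`id, easting, northing`)
#'
#' @param path CSV file.
#' @return A data frame with columns `id`, `x`, `y`.
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path)
  names(df)[1:3] <- c("id", "x", "y")
  df$id <- as.character(df$id)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("non-finite coordinates in ", path)
  df[, c("id", "x", "y")]
}

#' Sample allele frequencies per locus
#'
#' @param g a [genotype_table()].
#' @return A list with one named frequency vector per locus (sums to 1).
#' @export
allele_freqs <- function(g) {
  lapply(seq_len(n_loci(g)), function(l) {
    obs <- c(g$alleles[, l, 1], g$alleles[, l, 2])
    obs <- obs[!is.na(obs)]
    tab <- table(obs)
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    p
  }) |> stats::setNames(locus_names(g))
}

#' @export
summary.genotype_table <- function(object, ...) {
  fr <- allele_freqs(object)
  typed <- typed_matrix(object)
  data.frame(
    locus = locus_names(object),
    n_alleles = vapply(fr, length, integer(1)),
    n_typed = colSums(typed),
    missing_frac = 1 - colMeans(typed),
    row.names = NULL
  )
}
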
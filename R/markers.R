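#' Marker genotypes of a multi-family DH population
#'
#' Couples a line x marker allele-count matrix with its genetic map and
#' family structure. DH lines are fully homozygous, so every non-missing
#' entry is 0 or 2 copies of the family's reference-parent allele.
#'
#' @param geno numeric matrix, lines in rows (rownames = line ids), markers
#'   in columns (colnames = marker ids in map order); entries 0, 2 or NA.
#' @param map a \code{genmap}.
#' @param fam a \code{dh_families} covering every row.
#' @return object of class \code{"dh_geno"}: list(geno, map, fam).
#' @export
dh_geno <- function(geno, map, fam) {
  stopifnot(is.matrix(geno), inherits(map, "genmap"),
            inherits(fam, "dh_families"))
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix needs line ids as rownames and marker ids as colnames")
  if (ncol(geno) != nrow(map) || !identical(colnames(geno), map$marker)) {
    i <- match(map$marker, colnames(geno))
    if (anyNA(i)) stop("genotype columns do not cover the map's markers")
    geno <- geno[, i, drop = FALSE]
  }
  bad <- !(geno %in% c(0, 2) | is.na(geno))
  if (any(bad))
    stop("DH genotype entries must be 0, 2 or NA; found: ",
         paste(utils::head(unique(geno[bad]), 5), collapse = ", "))
  family_of(fam, rownames(geno))  # errors if a line is absent from fam
  structure(list(geno = geno, map = map, fam = fam), class = "dh_geno")
}

#' @export
print.dh_geno <- function(x, ...) {
  cat("DH genotypes:", nrow(x$geno), "lines x", ncol(x$geno), "markers,",
      nrow(x$fam$families), "families;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Subset a DH genotype object by line ids
#'
#' @param geno a \code{dh_geno}.
#' @param line_ids character vector of line ids to keep.
#' @export
subset_lines <- function(geno, line_ids) {
  stopifnot(inherits(geno, "dh_geno"))
  i <- match(line_ids, rownames(geno$geno))
  if (anyNA(i)) stop("unknown line id(s)")
  keep <- geno$fam$lines$line %in% line_ids
  fam <- dh_families(geno$fam$lines[keep, , drop = FALSE], geno$fam$families)
  dh_geno(geno$geno[i, , drop = FALSE], geno$map, fam)
}

#' Read / write DH line x marker genotypes
#'
#' CSV with a \code{line_id} column followed by one column per marker;
#' entries 0, 2 or NA (copies of the family's reference-parent allele).
#' Columns are aligned to the map's marker order, rows to the family table.
#'
#' @param path file path.
#' @param map a \code{genmap}.
#' @param fam a \code{dh_families}.
#' @return \code{read_genotypes}: a \code{dh_geno}.
#' @export
read_genotypes <- function(path, map, fam) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "line_id") stop("first column must be line_id")
  g <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(d$line_id)
  dh_geno(g, map, fam)
}

#' @rdname read_genotypes
#' @param geno a \code{dh_geno}.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "dh_geno"))
  utils::write.csv(
    data.frame(line_id = rownames(geno$geno), geno$geno,
               check.names = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
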
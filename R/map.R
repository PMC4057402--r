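#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' assuming crossovers occur as a Poisson process with no interference:
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d numeric vector of distances in cM, all >= 0.
#' @return recombination fractions in [0, 0.5).
#' @examples
#' haldane_r(c(0, 10, 50))
#' @export
haldane_r <- function(d) {
  if (!is.numeric(d)) stop("'d' must be numeric")
  if (any(!is.na(d) & d < 0)) stop("map distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker, columns
#' \code{marker}, \code{chrom}, \code{genome}, \code{pos} (cM), sorted by
#' chromosome then position. The (sub)genome label is the trailing letter of
#' the chromosome name, one of A, B or R -- the durum-wheat and rye
#' subgenomes of hexaploid triticale.
#'
#' @param markers data frame with columns \code{marker}, \code{chrom},
#'   \code{pos}; a \code{genome} column is derived if absent.
#' @return object of class \code{c("genmap", "data.frame")}.
#' @export
genetic_map <- function(markers) {
  stopifnot(is.data.frame(markers))
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(markers)))
    stop("map needs columns: ", paste(need, collapse = ", "))
  m <- data.frame(
    marker = as.character(markers$marker),
    chrom  = as.character(markers$chrom),
    pos    = as.numeric(markers$pos),
    stringsAsFactors = FALSE
  )
  m$genome <- parse_genome(m$chrom)
  if (anyDuplicated(m$marker))
    stop("duplicate marker ids: ",
         paste(unique(m$marker[duplicated(m$marker)]), collapse = ", "))
  if (any(!is.finite(m$pos)) || any(m$pos < 0))
    stop("marker positions must be finite and >= 0")
  # preserve chromosome order of first appearance, sort within chromosome
  chr_order <- unique(m$chrom)
  m <- m[order(match(m$chrom, chr_order), m$pos), , drop = FALSE]
  rownames(m) <- NULL
  tab <- table(m$chrom)
  if (any(tab < 2))
    stop("every chromosome needs at least 2 markers; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  class(m) <- c("genmap", "data.frame")
  m
}

parse_genome <- function(chrom) {
  g <- toupper(substring(chrom, nchar(chrom)))
  bad <- !(g %in% c("A", "B", "R"))
  if (any(bad))
    stop("cannot parse genome letter (A/B/R) from chromosome name(s): ",
         paste(unique(chrom[bad]), collapse = ", "))
  g
}

#' Per-chromosome summary of a genetic map
#'
#' @param map a \code{genmap}.
#' @return data frame with columns chrom, genome, n_markers, length (cM).
#' @export
chromosomes <- function(map) {
  stopifnot(inherits(map, "genmap"))
  chr <- unique(map$chrom)
  data.frame(
    chrom = chr,
    genome = map$genome[match(chr, map$chrom)],
    n_markers = as.integer(table(factor(map$chrom, levels = chr))),
    length = vapply(chr, function(cc) max(map$pos[map$chrom == cc]), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
`[.genmap` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.genmap <- function(x, ...) {
  ch <- chromosomes(x)
  cat("Genetic map:", nrow(x), "markers on", nrow(ch), "chromosomes (",
      paste(sprintf("%s:%d", c("A", "B", "R"),
                    vapply(c("A", "B", "R"),
                           function(g) sum(ch$genome == g), 0L)),
            collapse = " "), ")\n")
  cat("Total length:", round(sum(ch$length), 1), "cM\n")
  invisible(x)
}

#' Read a genetic map from CSV
#'
#' Expects a header with columns \code{marker_id}, \code{chromosome},
#' \code{position_cM} (comma separated, UTF-8, missing = NA). Genome labels
#' are parsed from the trailing letter of chromosome names (5A, 1B, 5R ...).
#'
#' @param path file path.
#' @return a \code{genmap}.
#' @export
read_genetic_map <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marker_id", "chromosome", "position_cM")
  if (!all(need %in% names(d)))
    stop("map file needs columns: ", paste(need, collapse = ", "))
  genetic_map(data.frame(marker = d$marker_id, chrom = d$chromosome,
                         pos = d$position_cM))
}

#' Write a genetic map to CSV
#' @param map a \code{genmap}.
#' @param path file path.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(inherits(map, "genmap"))
  utils::write.csv(
    data.frame(marker_id = map$marker, chromosome = map$chrom,
               position_cM = map$pos),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
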
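#' Family structure of a multi-family DH population
#'
#' Records which biparental family each DH line belongs to, and the two
#' parents of each family. The family membership defines the J matrix of the
#' multiple-line cross model (one indicator column per family) and the
#' "reference parent" (parent1) whose allele count the genotype coding uses.
#'
#' @param lines data frame with columns \code{line}, \code{family}.
#' @param parents data frame with columns \code{family}, \code{parent1},
#'   \code{parent2}; derived with NA parents if omitted.
#' @return object of class \code{"dh_families"}: list with elements
#'   \code{lines} (line, family) and \code{families}
#'   (family, parent1, parent2, n_lines).
#' @export
dh_families <- function(lines, parents = NULL) {
  stopifnot(is.data.frame(lines), all(c("line", "family") %in% names(lines)))
  ln <- data.frame(line = as.character(lines$line),
                   family = as.character(lines$family),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ln$line))
    stop("each line must map to exactly one family")
  fam_ids <- unique(ln$family)
  if (is.null(parents)) {
    parents <- data.frame(family = fam_ids, parent1 = NA_character_,
                          parent2 = NA_character_, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("family", "parent1", "parent2") %in% names(parents)))
  parents <- parents[match(fam_ids, parents$family), , drop = FALSE]
  if (any(is.na(parents$family)))
    stop("every family in 'lines' must appear in 'parents'")
  fams <- data.frame(
    family = fam_ids,
    parent1 = as.character(parents$parent1),
    parent2 = as.character(parents$parent2),
    n_lines = as.integer(table(factor(ln$family, levels = fam_ids))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(lines = ln, families = fams), class = "dh_families")
}

#' @export
print.dh_families <- function(x, ...) {
  cat("DH population:", nrow(x$lines), "lines in", nrow(x$families),
      "families\n")
  print(x$families, row.names = FALSE)
  invisible(x)
}

#' Family of each line, as a factor in family order
#'
#' @param fam a \code{dh_families}.
#' @param line_ids character vector of line ids (default: all lines).
#' @export
family_of <- function(fam, line_ids = fam$lines$line) {
  stopifnot(inherits(fam, "dh_families"))
  i <- match(line_ids, fam$lines$line)
  if (anyNA(i))
    stop("line(s) absent from family table: ",
         paste(utils::head(line_ids[is.na(i)], 5), collapse = ", "))
  factor(fam$lines$family[i], levels = fam$families$family)
}

#' Read / write the family assignment table
#'
#' CSV with columns \code{line_id}, \code{family_id}, \code{parent1},
#' \code{parent2} (parents repeated on every line of a family).
#'
#' @param path file path.
#' @return \code{read_families}: a \code{dh_families}.
#' @export
read_families <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "family_id")
  if (!all(need %in% names(d)))
    stop("family file needs columns: ", paste(need, collapse = ", "))
  if (!"parent1" %in% names(d)) d$parent1 <- NA_character_
  if (!"parent2" %in% names(d)) d$parent2 <- NA_character_
  par <- unique(d[, c("family_id", "parent1", "parent2")])
  names(par) <- c("family", "parent1", "parent2")
  if (anyDuplicated(par$family))
    stop("inconsistent parents within a family")
  dh_families(data.frame(line = d$line_id, family = d$family_id), par)
}

#' @rdname read_families
#' @param fam a \code{dh_families}.
#' @export
write_families <- function(fam, path) {
  stopifnot(inherits(fam, "dh_families"))
  i <- match(fam$lines$family, fam$families$family)
  utils::write.csv(
    data.frame(line_id = fam$lines$line, family_id = fam$lines$family,
               parent1 = fam$families$parent1[i],
               parent2 = fam$families$parent2[i]),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
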
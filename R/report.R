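#' Major QTL by proportion of genotypic variance
#'
#' A QTL is called major when its overall pG strictly exceeds the cutoff
#' (default 10 percent of the genotypic variance).
#'
#' @param qtls a \code{qtl_table} with a \code{pg} column.
#' @param cutoff percent.
#' @return the qualifying subset, same class.
#' @export
classify_major <- function(qtls, cutoff = 10) {
  stopifnot("pg" %in% names(qtls))
  out <- qtls[qtls$pg > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# gap between two closed intervals (0 when they touch or overlap)
interval_gap <- function(lo1, hi1, lo2, hi2) {
  pmax(0, lo2 - hi1, lo1 - hi2)
}

#' Overlapping QTL between two traits
#'
#' Two QTL overlap when they map to the same chromosome and are within the
#' window: under the default \code{"interval"} rule the gap between their
#' support intervals is at most \code{window} cM; under the \code{"point"}
#' rule the distance between peak positions is. Pairs are matched greedily
#' by smallest gap and each QTL is used at most once, so the pairing is
#' symmetric in the two lists.
#'
#' @param qtls_a,qtls_b \code{qtl_table}s for the two traits.
#' @param window cM.
#' @param rule \code{"interval"} (support-interval gap, default) or
#'   \code{"point"} (peak distance).
#' @return object of class \code{"trait_comparison"}: data frame
#'   \code{pairs} (chrom, pos_a, pos_b, gap), count \code{n_overlap}, and
#'   the rule/window used (also in the output metadata, since the interval
#'   reading of the published window is an inference).
#' @export
find_overlaps <- function(qtls_a, qtls_b, window = 10,
                          rule = c("interval", "point")) {
  rule <- match.arg(rule)
  cand <- list()
  for (i in seq_len(nrow(qtls_a))) {
    for (j in seq_len(nrow(qtls_b))) {
      if (qtls_a$chrom[i] != qtls_b$chrom[j]) next
      gap <- if (rule == "interval")
        interval_gap(qtls_a$si_lo[i], qtls_a$si_hi[i],
                     qtls_b$si_lo[j], qtls_b$si_hi[j])
      else abs(qtls_a$pos[i] - qtls_b$pos[j])
      if (gap <= window)
        cand[[length(cand) + 1]] <- data.frame(
          i = i, j = j, chrom = qtls_a$chrom[i],
          pos_a = qtls_a$pos[i], pos_b = qtls_b$pos[j], gap = gap,
          stringsAsFactors = FALSE)
    }
  }
  pairs <- data.frame(chrom = character(), pos_a = numeric(),
                      pos_b = numeric(), gap = numeric())
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$gap, cand$pos_a), , drop = FALSE]
    used_a <- used_b <- integer()
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      if (cand$i[r] %in% used_a || cand$j[r] %in% used_b) next
      keep[r] <- TRUE
      used_a <- c(used_a, cand$i[r])
      used_b <- c(used_b, cand$j[r])
    }
    pairs <- cand[keep, c("chrom", "pos_a", "pos_b", "gap"), drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, n_overlap = nrow(pairs), rule = rule,
                 window = window), class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat(x$n_overlap, "overlapping QTL (rule:", x$rule, ", window",
      x$window, "cM)\n")
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Per-genome pG totals
#'
#' Sums the overall and per-family proportions of genotypic variance over
#' the QTL on each (sub)genome's chromosomes -- the additivity of this
#' summary is that of the table, not of the joint genetic model.
#'
#' @param qtls a \code{qtl_table} (needs \code{pg}; \code{pg_<family>}
#'   columns are summed too when present).
#' @return data frame: genome, n_qtl, pg_total, plus summed per-family
#'   columns. All three genomes A, B, R are always reported.
#' @export
genome_summary <- function(qtls) {
  gen <- if ("genome" %in% names(qtls)) qtls$genome
         else parse_genome(qtls$chrom)
  pgf <- grep("^pg_", names(qtls), value = TRUE)
  out <- data.frame(genome = c("A", "B", "R"), stringsAsFactors = FALSE)
  out$n_qtl <- vapply(out$genome, function(g) sum(gen == g), 0L)
  out$pg_total <- vapply(out$genome, function(g)
    sum(qtls$pg[gen == g]), 0)
  for (cl in pgf)
    out[[cl]] <- vapply(out$genome, function(g)
      sum(qtls[[cl]][gen == g]), 0)
  out
}

#' Write / read a QTL result table
#'
#' One row per QTL (chromosome, peak position, support interval, LOD,
#' overall and per-family pG, per-family effects) followed by the
#' per-genome summary rows; a \code{type} column distinguishes the two.
#' Reading returns the QTL records only, so write-then-read is the
#' identity on the records.
#'
#' @param qtls a \code{qtl_table}.
#' @param path file path.
#' @export
write_qtl_table <- function(qtls, path) {
  d <- as.data.frame(qtls)
  d <- cbind(type = rep("qtl", nrow(d)), d, stringsAsFactors = FALSE)
  if ("pg" %in% names(qtls) && nrow(d)) {
    gs <- genome_summary(qtls)
    sm <- d[0, , drop = FALSE]
    for (r in seq_len(nrow(gs))) {
      row <- as.list(rep(NA, ncol(d)))
      names(row) <- names(d)
      row$type <- "genome_summary"
      row$chrom <- paste(gs$genome[r], "genome")
      row$genome <- gs$genome[r]
      row$pg <- gs$pg_total[r]
      for (cl in grep("^pg_", names(gs), value = TRUE))
        if (cl %in% names(d)) row[[cl]] <- gs[[cl]][r]
      sm <- rbind(sm, as.data.frame(row, stringsAsFactors = FALSE))
    }
    d <- rbind(d, sm)
  }
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_qtl_table
#' @export
read_qtl_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("type" %in% names(d)) {
    d <- d[d$type == "qtl", setdiff(names(d), "type"), drop = FALSE]
  }
  rownames(d) <- NULL
  class(d) <- c("qtl_table", "data.frame")
  d
}

#' Write a scan profile (chromosome, position, LOD) to CSV
#' @param scan an \code{mcqtl_scan}.
#' @param path file path.
#' @export
write_scan <- function(scan, path) {
  utils::write.csv(as.data.frame(scan)[, c("chrom", "pos", "lod")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
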
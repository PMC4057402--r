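#' Per-test alpha for the two-locus epistasis scan
#'
#' Bonferroni correction by the number of possible independent pairwise
#' interactions between chromosome regions, assuming
#' \code{regions_per_chrom} separate regions per chromosome:
#' per-test alpha = alpha / choose(n_chrom x regions_per_chrom, 2).
#'
#' @param alpha nominal experiment-wise alpha.
#' @param n_chrom number of chromosomes (>= 1).
#' @param regions_per_chrom assumed independent regions per chromosome.
#' @export
epistasis_threshold <- function(alpha, n_chrom, regions_per_chrom = 2) {
  stopifnot(n_chrom >= 1, alpha > 0, alpha < 1)
  alpha / choose(n_chrom * regions_per_chrom, 2)
}

#' Two-dimensional scan for pairwise epistatic interactions
#'
#' Over all marker pairs on different chromosomes or at least
#' \code{min_pair_distance} cM apart, the additive two-locus model (family
#' means + the two family-specific count blocks) is extended by an
#' interaction block whose family column is the product of the two
#' within-family mean-centred counts, and the interaction term is tested by
#' the likelihood-ratio test (evaluated with its exact finite-sample F
#' reference distribution). Pairs with p below the region-corrected
#' threshold (\code{\link{epistasis_threshold}}) are kept, and overlapping
#' significant pairs are collapsed to the best pair per region pair, a
#' region being one of \code{regions_per_chromosome} equal spans of a
#' chromosome. The interaction's share of genotypic variance is
#' 100 x (adjusted-R2 increment) / h2.
#'
#' @inheritParams genome_scan
#' @param h2 entry-mean heritability scaling pG (1 reports plain adjusted
#'   R2 percent).
#' @return data frame of class \code{c("epi_table", "data.frame")}:
#'   chrom1, pos1, chrom2, pos2, p_value, pg; attributes
#'   \code{"per_test_alpha"}, \code{"n_tests"}, \code{"n_skipped"} and the
#'   uncollapsed significant pairs as \code{"all_significant"}.
#' @export
pair_scan <- function(y, geno, cfg = mcqtl_config(), h2 = 1) {
  yv <- align_y(y, geno)
  fl <- family_of(geno$fam, rownames(geno$geno))
  map <- geno$map
  n <- length(yv)
  J <- stats::model.matrix(~ 0 + fl)
  qrJ <- qr(J)
  rssJ <- sum(qr.resid(qrJ, yv)^2)
  chr_len <- stats::setNames(chromosomes(map)$length, chromosomes(map)$chrom)
  alpha_t <- epistasis_threshold(cfg$epistasis_alpha,
                                 length(chr_len),
                                 cfg$regions_per_chromosome)
  blocks <- lapply(seq_len(nrow(map)), function(i)
    position_block(geno, fl, map$chrom[i], map$pos[i]))
  poly <- which(vapply(blocks, function(b) length(b$fams) > 0, TRUE))
  adj_r2_from <- function(rss, rank) {
    r2 <- 1 - rss / rssJ
    1 - (1 - r2) * (n - qrJ$rank) / (n - rank)
  }
  rows <- list()
  n_tests <- 0L
  n_skipped <- 0L
  for (ii in seq_along(poly)) {
    i <- poly[ii]
    for (jj in seq_len(length(poly) - ii)) {
      j <- poly[ii + jj]
      same <- map$chrom[i] == map$chrom[j]
      if (same && abs(map$pos[j] - map$pos[i]) < cfg$min_pair_distance)
        next
      b1 <- blocks[[i]]; b2 <- blocks[[j]]
      common <- intersect(b1$fams, b2$fams)
      if (!length(common)) next
      XI <- matrix(0, n, length(common))
      for (kf in seq_along(common)) {
        f <- common[kf]
        rowsf <- fl == f
        x1 <- b1$ec[rowsf]; x2 <- b2$ec[rowsf]
        XI[rowsf, kf] <- (x1 - mean(x1)) * (x2 - mean(x2))
      }
      keep <- apply(XI, 2, stats::var) > 1e-12
      if (!any(keep)) next
      XI <- XI[, keep, drop = FALSE]
      n_tests <- n_tests + 1L
      Xn <- cbind(J, b1$X, b2$X)
      qr0 <- qr(Xn)
      qr1 <- qr(cbind(Xn, XI))
      dfI <- qr1$rank - qr0$rank
      if (dfI == 0) { n_skipped <- n_skipped + 1L; next }
      rss0 <- sum(qr.resid(qr0, yv)^2)
      rss1 <- sum(qr.resid(qr1, yv)^2)
      if (rss1 <= 1e-12 || n - qr1$rank < 1) {
        n_skipped <- n_skipped + 1L; next
      }
      Fst <- ((rss0 - rss1) / dfI) / (rss1 / (n - qr1$rank))
      p <- stats::pf(Fst, dfI, n - qr1$rank, lower.tail = FALSE)
      if (p < alpha_t) {
        pg <- 100 * max(0, adj_r2_from(rss1, qr1$rank) -
                          adj_r2_from(rss0, qr0$rank)) / h2
        rows[[length(rows) + 1]] <- data.frame(
          chrom1 = map$chrom[i], pos1 = map$pos[i],
          chrom2 = map$chrom[j], pos2 = map$pos[j],
          p_value = p, pg = pg, stringsAsFactors = FALSE)
      }
    }
  }
  sig <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom1 = character(), pos1 = numeric(),
               chrom2 = character(), pos2 = numeric(),
               p_value = numeric(), pg = numeric())
  out <- sig
  if (nrow(sig)) {
    region <- function(chrom, pos) {
      nr <- cfg$regions_per_chromosome
      band <- pmin(nr, 1 + floor(nr * pos / pmax(chr_len[chrom], 1e-9)))
      paste0(chrom, ":", band)
    }
    key <- paste(region(sig$chrom1, sig$pos1),
                 region(sig$chrom2, sig$pos2), sep = "~")
    out <- do.call(rbind, lapply(split(sig, key), function(d)
      d[which.min(d$p_value), , drop = FALSE]))
    out <- out[order(match(out$chrom1, names(chr_len)), out$pos1,
                     match(out$chrom2, names(chr_len)), out$pos2), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, per_test_alpha = alpha_t, n_tests = n_tests,
            n_skipped = n_skipped, all_significant = sig,
            class = c("epi_table", "data.frame"))
}

#' Read / write epistasis scan results
#' @param x an \code{epi_table}.
#' @param path file path.
#' @export
write_epistasis <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_epistasis
#' @export
read_epistasis <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(d) <- c("epi_table", "data.frame")
  d
}
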
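#' Fit the multiple-line cross QTL mapping model
#'
#' The main entry point: runs the whole 1-D mapping pipeline on per-line
#' adjusted means. Steps: forward-BIC cofactor selection (unless cofactors
#' are supplied), a joint genome scan of the observed response and
#' \code{n_perm} within-family permutations of it in one pass, the
#' permutation-based genome-wide LOD threshold at the configured alpha, QTL
#' identification with LOD fall-off support intervals, backward trimming of
#' the QTL list by conditional LOD (\code{\link{trim_qtl}}), and (when
#' \code{h2} is given) estimation of the proportion of genotypic variance
#' explained.
#'
#' @param pheno a \code{line_values} with one adjusted mean per line.
#' @param geno a \code{dh_geno}.
#' @param config an \code{mcqtl_config}.
#' @param h2 entry-mean heritability used for pG estimation; \code{NULL}
#'   skips the pG step.
#' @param cofactors optional character vector of cofactor marker ids;
#'   selected automatically when \code{NULL}.
#' @param n_perm number of permutations (default from config); 0 requires
#'   an explicit \code{threshold}.
#' @param threshold explicit LOD threshold overriding the permutation one.
#' @param seed integer seed for the permutations.
#' @return object of class \code{"mcqtl"}: list with elements \code{scan}
#'   (an \code{mcqtl_scan}), \code{threshold}, \code{max_lods} (permutation
#'   distribution), \code{qtl} (a \code{qtl_table}), \code{cofactors},
#'   \code{h2}, \code{config}, \code{n}.
#' @seealso \code{\link{genome_scan}}, \code{\link{identify_qtl}},
#'   \code{\link{estimate_pg}}, \code{\link{run_cv}}, \code{\link{pair_scan}}
#' @examples
#' \donttest{
#' study <- simulate_triticale(seed = 1, n_markers = 5, chrom_per_genome = 1)
#' y <- simulate_blues(study$geno, study$qtl_wh, var_g = 3, h2 = 0.87)
#' fit <- mcqtl(y, study$geno, mcqtl_config(n_permutations = 100),
#'              h2 = 0.87, seed = 1)
#' summary(fit)
#' }
#' @export
mcqtl <- function(pheno, geno, config = mcqtl_config(), h2 = NULL,
                  cofactors = NULL, n_perm = config$n_permutations,
                  threshold = NULL, seed = 1) {
  yv <- align_y(pheno, geno)
  fl <- family_of(geno$fam, rownames(geno$geno))
  if (is.null(cofactors))
    cofactors <- select_cofactors(pheno, geno, config)
  max_lods <- NULL
  if (is.null(threshold)) {
    if (n_perm < 100) stop("need at least 100 permutations (or a threshold)")
    set.seed(seed)
    idx <- perm_within_family(fl, n_perm)
    Y <- cbind(yv, matrix(yv[idx], nrow = length(yv)))
    res <- scan_core(Y, geno, cofactors, config)
    max_lods <- apply(res$lod[, -1, drop = FALSE], 2, max)
    threshold <- unname(stats::quantile(max_lods, 1 - config$alpha, type = 1))
  } else {
    res <- scan_core(matrix(yv, ncol = 1), geno, cofactors, config)
  }
  scan <- new_scan(res, cofactors, config)
  qtl <- identify_qtl(scan, threshold, config)
  qtl <- trim_qtl(qtl, pheno, geno, threshold)
  if (!is.null(h2)) qtl <- estimate_pg(qtl, pheno, geno, h2)
  structure(list(scan = scan, threshold = threshold, max_lods = max_lods,
                 qtl = qtl, cofactors = cofactors, h2 = h2,
                 config = config, n = length(yv), call = match.call()),
            class = "mcqtl")
}

#' @export
print.mcqtl <- function(x, ...) {
  cat("Multiple-line cross QTL mapping fit\n")
  cat(sprintf("  %d lines, %d scan positions, %d cofactors\n", x$n,
              nrow(x$scan), length(x$cofactors)))
  cat(sprintf("  LOD threshold %.2f (alpha %.2f)\n", x$threshold,
              x$config$alpha))
  cat(sprintf("  %d QTL detected", nrow(x$qtl)))
  if (!is.null(x$h2) && nrow(x$qtl))
    cat(sprintf(", explaining %.1f%% of genotypic variance (h2 = %.2f)",
                attr(x$qtl, "pg_total"), x$h2))
  cat("\n")
  invisible(x)
}

#' @export
summary.mcqtl <- function(object, ...) {
  structure(list(fit = object,
                 genome = if (nrow(object$qtl))
                   genome_summary(object$qtl) else NULL),
            class = "summary.mcqtl")
}

#' @export
print.summary.mcqtl <- function(x, ...) {
  print(x$fit)
  if (nrow(x$fit$qtl)) {
    cat("\nDetected QTL:\n")
    q <- as.data.frame(x$fit$qtl)
    num <- vapply(q, is.numeric, TRUE)
    q[num] <- lapply(q[num], round, 2)
    print(q, row.names = FALSE)
    if (!is.null(x$genome)) {
      cat("\nPer-genome pG totals:\n")
      print(round(x$genome$pg_total, 2))
    }
  }
  invisible(x)
}

#' @export
coef.mcqtl <- function(object, ...) {
  q <- object$qtl
  eff <- as.matrix(q[, grep("^eff_", names(q)), drop = FALSE])
  rownames(eff) <- sprintf("%s@%.1f", q$chrom, q$pos)
  colnames(eff) <- sub("^eff_", "", colnames(eff))
  eff
}

#' Plot the LOD profile of a fit or scan
#'
#' Base-graphics LOD profile along the genome, chromosomes laid out
#' side-by-side, with the significance threshold as a dashed line and
#' detected QTL marked.
#'
#' @param x an \code{mcqtl} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.mcqtl <- function(x, ...) {
  sc <- x$scan
  chrs <- unique(sc$chrom)
  offs <- c(0, cumsum(vapply(chrs, function(cc)
    max(sc$pos[sc$chrom == cc]) + 10, 0)))
  names(offs) <- c(chrs, "end")
  gx <- sc$pos + offs[sc$chrom]
  graphics::plot(gx, sc$lod, type = "n", xlab = "chromosome",
                 ylab = "LOD", xaxt = "n", ...)
  for (cc in chrs) {
    i <- sc$chrom == cc
    graphics::lines(gx[i], sc$lod[i])
  }
  graphics::axis(1, at = offs[chrs] +
                   vapply(chrs, function(cc)
                     max(sc$pos[sc$chrom == cc]) / 2, 0),
                 labels = chrs, las = 2, cex.axis = 0.7)
  graphics::abline(h = x$threshold, lty = 2)
  if (nrow(x$qtl))
    graphics::points(x$qtl$pos + offs[x$qtl$chrom],
                     x$qtl$lod, pch = 25, bg = "black")
  invisible(x)
}
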
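#' Expected reference-allele count at a position between flanking markers
#'
#' For a DH line the genotype at an unobserved position is 0 or 2 copies of
#' the reference-parent allele; its conditional expectation given the
#' flanking marker genotypes follows from Haldane recombination fractions
#' with no interference. With r1 = haldane_r(d_left), r2 = haldane_r(d_right)
#' and rT = r1 + r2 - 2 r1 r2, the probability of carrying the reference
#' allele is, e.g., (1-r1)(1-r2)/(1-rT) when both flanks carry it. A single
#' non-missing flank uses the one-marker conditional (1-r or r); with both
#' flanks missing the population expectation 1 is returned.
#'
#' All arguments are vectorized over lines.
#'
#' @param left_geno,right_geno flanking genotypes, 0/2/NA.
#' @param d_left,d_right distances to the flanks in cM (>= 0).
#' @return expected counts in [0, 2].
#' @export
expected_count <- function(left_geno, right_geno, d_left, d_right) {
  n <- max(length(left_geno), length(right_geno))
  gl <- rep_len(left_geno, n); gr <- rep_len(right_geno, n)
  r1 <- rep_len(haldane_r(d_left), n)
  r2 <- rep_len(haldane_r(d_right), n)
  rT <- r1 + r2 - 2 * r1 * r2
  p <- rep(0.5, n)
  lo <- !is.na(gl) & is.na(gr)
  ro <- is.na(gl) & !is.na(gr)
  p[lo] <- ifelse(gl[lo] == 2, 1 - r1[lo], r1[lo])
  p[ro] <- ifelse(gr[ro] == 2, 1 - r2[ro], r2[ro])
  bo <- !is.na(gl) & !is.na(gr)
  if (any(bo)) {
    g1 <- gl[bo] == 2; g2 <- gr[bo] == 2
    a1 <- ifelse(g1, 1 - r1[bo], r1[bo])
    a2 <- ifelse(g2, 1 - r2[bo], r2[bo])
    joint <- ifelse(g1 == g2, 1 - rT[bo], rT[bo])
    pb <- ifelse(joint > 0, a1 * a2 / joint, (gl[bo] + gr[bo]) / 4)
    p[bo] <- pb
  }
  2 * p
}

#' LOD score from nested residual sums of squares
#'
#' LOD = (n/2) log10(rss0/rss1) for the Gaussian likelihood-ratio test of
#' the full against the null least-squares model; negative values (possible
#' only through rounding) are clipped to 0.
#'
#' @param rss0,rss1 residual sums of squares of null and full model (> 0).
#' @param n number of observations.
#' @export
lod_score <- function(rss0, rss1, n) {
  if (any(rss0 <= 0) || any(rss1 <= 0))
    stop("residual sums of squares must be positive")
  pmax(0, n / 2 * log10(rss0 / rss1))
}

# grid of evaluated positions: every scan_step cM plus every marker
scan_positions <- function(map, step) {
  out <- lapply(unique(map$chrom), function(cc) {
    mpos <- map$pos[map$chrom == cc]
    data.frame(chrom = cc,
               pos = sort(unique(c(seq(0, max(mpos), by = step), mpos))))
  })
  do.call(rbind, out)
}

# family-specific design block at a map position.
# Returns X (N x kept families), expected counts, the flanking-marker
# interval used for cofactor exclusion, and the kept family set. Lines with
# missing flanks fall back to the nearest non-missing marker on that side.
position_block <- function(geno, fl, chrom, pos, keep_fams = NULL) {
  map <- geno$map
  idx <- which(map$chrom == chrom)
  mpos <- map$pos[idx]
  M <- geno$geno[, idx, drop = FALSE]
  n <- nrow(M)
  li0 <- findInterval(pos, mpos)
  exact <- li0 >= 1 && abs(mpos[li0] - pos) < 1e-9
  ri0 <- if (exact) li0 else li0 + 1L
  li <- rep(li0, n)
  repeat {                                  # walk left past missing calls
    bad <- li >= 1 & is.na(M[cbind(seq_len(n), pmax(li, 1))])
    if (!any(bad)) break
    li[bad] <- li[bad] - 1L
  }
  ri <- rep(ri0, n)
  m <- length(mpos)
  repeat {                                  # walk right past missing calls
    bad <- ri <= m & is.na(M[cbind(seq_len(n), pmin(ri, m))])
    if (!any(bad)) break
    ri[bad] <- ri[bad] + 1L
  }
  gl <- ifelse(li >= 1, M[cbind(seq_len(n), pmax(li, 1))], NA)
  gr <- ifelse(ri <= m, M[cbind(seq_len(n), pmin(ri, m))], NA)
  dl <- ifelse(li >= 1, pos - mpos[pmax(li, 1)], 0)
  dr <- ifelse(ri <= m, mpos[pmin(ri, m)] - pos, 0)
  ec <- expected_count(gl, gr, dl, dr)
  fams <- levels(fl)
  if (is.null(keep_fams)) {
    keep_fams <- fams[vapply(fams, function(f) {
      v <- ec[fl == f]
      # a truly segregating family has count variance near 1; families with
      # essentially constant expected counts at this position get no column
      length(v) > 0 && stats::var(v) > 1e-2
    }, TRUE)]
  }
  X <- matrix(0, n, length(keep_fams))
  colnames(X) <- if (length(keep_fams)) paste0(".q_", keep_fams)
                 else character(0)
  for (j in seq_along(keep_fams))
    X[fl == keep_fams[j], j] <- ec[fl == keep_fams[j]]
  interval <- c(if (li0 >= 1) mpos[li0] else pos,
                if (ri0 <= m) mpos[ri0] else pos)
  list(X = X, ec = ec, fams = keep_fams, interval = interval)
}

# distance from a point to an interval [a, b]
dist_to_interval <- function(p, a, b) pmax(0, a - p, p - b)

# align a line_values object to the genotype object's line order
align_y <- function(y, geno) {
  stopifnot(inherits(y, "line_values"), inherits(geno, "dh_geno"))
  i <- match(rownames(geno$geno), y$line)
  if (anyNA(i))
    stop("phenotype missing for line(s): ",
         paste(utils::head(rownames(geno$geno)[is.na(i)], 5), collapse = ", "))
  y$value[i]
}

# residual sums of squares of Y's columns under a QR-decomposed model
rss_qr <- function(qrobj, Y) {
  qty <- qr.qty(qrobj, Y)
  colSums(Y^2) - colSums(qty[seq_len(qrobj$rank), , drop = FALSE]^2)
}

# core scan over all grid positions for an n x B response matrix.
# Returns LOD per position and column, plus family effects for column 1.
scan_core <- function(Y, geno, cofactors, cfg) {
  fl <- family_of(geno$fam, rownames(geno$geno))
  n <- nrow(Y)
  J <- stats::model.matrix(~ 0 + fl)
  cof_blocks <- lapply(cofactors, function(mk) {
    i <- match(mk, geno$map$marker)
    if (is.na(i)) stop("unknown cofactor marker: ", mk)
    b <- position_block(geno, fl, geno$map$chrom[i], geno$map$pos[i])
    b$chrom <- geno$map$chrom[i]; b$pos <- geno$map$pos[i]
    b
  })
  grid <- scan_positions(geno$map, cfg$scan_step)
  npos <- nrow(grid)
  lod <- matrix(0, npos, ncol(Y))
  eff <- matrix(NA_real_, npos, nlevels(fl),
                dimnames = list(NULL, levels(fl)))
  tssY <- colSums(Y^2)
  null_cache <- new.env(parent = emptyenv())
  for (i in seq_len(npos)) {
    blk <- position_block(geno, fl, grid$chrom[i], grid$pos[i])
    keep <- vapply(cof_blocks, function(cb) {
      !(cb$chrom == grid$chrom[i] &&
          dist_to_interval(cb$pos, blk$interval[1], blk$interval[2]) <
            cfg$cofactor_window)
    }, TRUE)
    key <- paste0("k", paste(which(keep), collapse = ","))
    nul <- get0(key, envir = null_cache)
    if (is.null(nul)) {
      Xn <- do.call(cbind, c(list(J), lapply(cof_blocks[keep], `[[`, "X")))
      qr0 <- qr(Xn)
      nul <- list(Xn = Xn, qr0 = qr0, rss0 = rss_qr(qr0, Y))
      assign(key, nul, envir = null_cache)
    }
    if (ncol(blk$X) == 0) next            # every family monomorphic here
    colnames(blk$X) <- paste0(".qtl_", blk$fams)  # distinct from cofactors
    qr1 <- qr(cbind(nul$Xn, blk$X))
    rss1 <- rss_qr(qr1, Y)
    ok <- nul$rss0 > 1e-12   # zero-variance response: LOD stays 0
    r1 <- pmax(rss1, nul$rss0 * 1e-15)   # perfect fit: large finite LOD
    lod[i, ok] <- pmax(0, n / 2 * log10(nul$rss0[ok] / r1[ok]))
    cf <- qr.coef(qr1, Y[, 1])
    eff[i, blk$fams] <- unname(cf[paste0(".qtl_", blk$fams)])
  }
  list(grid = grid, lod = lod, effects = eff, families = levels(fl))
}

#' Multiple-line cross genome scan
#'
#' At every grid position (each \code{scan_step} cM plus every marker
#' position) the null model -- family means plus family-specific cofactor
#' blocks -- and the full model -- plus the family-specific expected-count
#' block of the tested position -- are fitted by least squares, and the LOD
#' score of the likelihood-ratio test is recorded. Cofactors whose marker
#' lies closer than \code{cofactor_window} cM to the tested marker interval
#' are excluded from both models at that position. Families in which the
#' tested position is monomorphic contribute no effect column there.
#'
#' @param y a \code{line_values} covering every genotyped line.
#' @param geno a \code{dh_geno}.
#' @param cofactors character vector of cofactor marker ids (possibly
#'   empty), e.g. from \code{\link{select_cofactors}}.
#' @param cfg an \code{mcqtl_config}.
#' @return object of class \code{"mcqtl_scan"}: data frame of positions with
#'   \code{chrom}, \code{pos}, \code{lod}; family effect estimates in
#'   attribute \code{"effects"}; cofactors and config attached.
#' @export
genome_scan <- function(y, geno, cofactors = character(), cfg = mcqtl_config()) {
  yv <- align_y(y, geno)
  res <- scan_core(matrix(yv, ncol = 1), geno, cofactors, cfg)
  new_scan(res, cofactors, cfg)
}

new_scan <- function(res, cofactors, cfg) {
  sc <- data.frame(chrom = res$grid$chrom, pos = res$grid$pos,
                   lod = res$lod[, 1])
  structure(sc, effects = res$effects, cofactors = cofactors, cfg = cfg,
            families = res$families,
            class = c("mcqtl_scan", "data.frame"))
}

#' @export
print.mcqtl_scan <- function(x, ...) {
  cat("Genome scan:", nrow(x), "positions on", length(unique(x$chrom)),
      "chromosomes;", length(attr(x, "cofactors")), "cofactors\n")
  i <- which.max(x$lod)
  cat(sprintf("Max LOD %.2f at %s %.1f cM\n", x$lod[i], x$chrom[i], x$pos[i]))
  invisible(x)
}

#' Forward cofactor selection by BIC
#'
#' Starting from the family-means model, markers are added greedily as
#' family-specific expected-count blocks; at each step the marker giving the
#' largest improvement of the Schwarz criterion (BIC) enters, ties broken in
#' favour of the earlier map position, until no marker improves the
#' criterion or \code{max_cofactors} is reached. The procedure is
#' deterministic given its input.
#'
#' @inheritParams genome_scan
#' @return character vector of selected marker ids (map order of entry
#'   preserved in selection order).
#' @export
select_cofactors <- function(y, geno, cfg = mcqtl_config()) {
  yv <- align_y(y, geno)
  fl <- family_of(geno$fam, rownames(geno$geno))
  n <- length(yv)
  J <- stats::model.matrix(~ 0 + fl)
  blocks <- lapply(seq_len(nrow(geno$map)), function(i)
    position_block(geno, fl, geno$map$chrom[i], geno$map$pos[i])$X)
  cand <- which(vapply(blocks, ncol, 0L) > 0)
  qrJ <- qr(J)
  Q <- qr.Q(qrJ)[, seq_len(qrJ$rank), drop = FALSE]
  yres <- yv - Q %*% crossprod(Q, yv)
  rss <- sum(yres^2)
  p <- qrJ$rank
  bic <- n * log(max(rss, 1e-12) / n) + p * log(n)
  selected <- integer()
  while (length(selected) < cfg$max_cofactors && length(cand)) {
    best <- NULL
    for (j in cand) {
      B <- blocks[[j]] - Q %*% crossprod(Q, blocks[[j]])
      qb <- qr(B)
      rk <- qb$rank
      if (rk == 0 || sum(abs(diag(qb$qr))[seq_len(rk)] > 1e-8) == 0) next
      Qb <- qr.Q(qb)[, seq_len(rk), drop = FALSE]
      dec <- sum(crossprod(Qb, yres)^2)
      rss_new <- max(rss - dec, 1e-12)
      bic_new <- n * log(rss_new / n) + (p + rk) * log(n)
      if (is.null(best) || bic_new < best$bic - 1e-12)
        best <- list(j = j, bic = bic_new, Qb = Qb, rss = rss_new, rk = rk)
    }
    if (is.null(best) || best$bic >= bic - 1e-8) break
    selected <- c(selected, best$j)
    cand <- setdiff(cand, best$j)
    Q <- cbind(Q, best$Qb)
    yres <- yres - best$Qb %*% crossprod(best$Qb, yres)
    rss <- best$rss
    p <- p + best$rk
    bic <- best$bic
  }
  geno$map$marker[selected]
}

# within-family permutation index matrix (n x B)
perm_within_family <- function(fl, B) {
  n <- length(fl)
  idx <- matrix(0L, n, B)
  rows <- split(seq_len(n), fl)
  for (b in seq_len(B)) {
    i <- seq_len(n)
    for (rr in rows) if (length(rr) > 1) i[rr] <- rr[sample.int(length(rr))]
    idx[, b] <- i
  }
  idx
}

#' Permutation-based genome-wide LOD threshold
#'
#' Phenotype values are permuted within family (respecting the family-mean
#' term of the model), the genome scan's maximum LOD is recorded for each
#' permutation, and the threshold is the empirical (1 - alpha) quantile of
#' that max-LOD distribution (inverse-ECDF quantile, so alpha = 1 returns
#' the minimum).
#'
#' @inheritParams genome_scan
#' @param seed integer seed; the threshold is deterministic given the seed.
#' @return threshold (numeric scalar) with the max-LOD distribution attached
#'   as attribute \code{"max_lods"}.
#' @export
permutation_threshold <- function(y, geno, cofactors = character(),
                                  cfg = mcqtl_config(), seed = 1) {
  if (cfg$n_permutations < 100)
    stop("need at least 100 permutations")
  yv <- align_y(y, geno)
  fl <- family_of(geno$fam, rownames(geno$geno))
  set.seed(seed)
  idx <- perm_within_family(fl, cfg$n_permutations)
  Y <- matrix(yv[idx], nrow = length(yv))
  res <- scan_core(Y, geno, cofactors, cfg)
  maxl <- apply(res$lod, 2, max)
  thr <- unname(stats::quantile(maxl, 1 - cfg$alpha, type = 1))
  attr(thr, "max_lods") <- maxl
  thr
}

#' Identify QTL from a scan profile
#'
#' Per chromosome, local LOD maxima above the threshold become candidate
#' QTL; the support interval of each extends from the peak outwards to the
#' first grid positions whose LOD has dropped by at least
#' \code{lod_falloff} (truncated at chromosome ends). Peaks whose support
#' intervals overlap, or whose peaks lie within \code{cofactor_window} cM
#' of each other (the package's resolution for calling QTL distinct; the
#' exclusion boundary of a cofactor can notch an otherwise single peak in
#' two), are merged keeping the higher peak (ties: the lower position).
#'
#' @param scan an \code{mcqtl_scan}.
#' @param threshold genome-wide LOD threshold.
#' @param cfg an \code{mcqtl_config} (for \code{lod_falloff}).
#' @return data frame of class \code{c("qtl_table", "data.frame")}: chrom,
#'   genome, pos, si_lo, si_hi, lod, and one effect column per family.
#' @export
identify_qtl <- function(scan, threshold, cfg = attr(scan, "cfg")) {
  stopifnot(inherits(scan, "mcqtl_scan"))
  eff <- attr(scan, "effects")
  fams <- attr(scan, "families")
  recs <- list()
  for (cc in unique(scan$chrom)) {
    si <- which(scan$chrom == cc)
    l <- scan$lod[si]
    k <- length(l)
    is_peak <- l > threshold &
      l >= c(-Inf, l[-k]) & l >= c(l[-1], -Inf)
    cand <- which(is_peak)
    if (!length(cand)) next
    cand <- cand[order(-l[cand], scan$pos[si][cand])]
    acc <- list()
    for (pk in cand) {
      drop_at <- l[pk] - cfg$lod_falloff
      left <- which(l[seq_len(pk)] <= drop_at)
      lo <- if (length(left)) scan$pos[si][max(left)] else scan$pos[si][1]
      right <- which(l[pk:k] <= drop_at)
      hi <- if (length(right)) scan$pos[si][pk + min(right) - 1]
            else scan$pos[si][k]
      p_pos <- scan$pos[si][pk]
      overlaps <- any(vapply(acc, function(a)
        (lo <= a$hi && a$lo <= hi) ||
          abs(p_pos - scan$pos[si][a$pk]) < cfg$cofactor_window, TRUE))
      if (overlaps) next
      acc[[length(acc) + 1]] <- list(pk = pk, lo = lo, hi = hi)
    }
    for (a in acc) {
      i <- si[a$pk]
      recs[[length(recs) + 1]] <- data.frame(
        chrom = cc, genome = parse_genome(cc), pos = scan$pos[i],
        si_lo = a$lo, si_hi = a$hi, lod = scan$lod[i],
        stringsAsFactors = FALSE)
      for (f in fams)
        recs[[length(recs)]][[paste0("eff_", f)]] <- eff[i, f]
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else {
    out0 <- data.frame(chrom = character(), genome = character(),
                       pos = numeric(), si_lo = numeric(),
                       si_hi = numeric(), lod = numeric())
    for (f in fams) out0[[paste0("eff_", f)]] <- numeric()
    out0
  }
  out <- out[order(match(out$chrom, unique(scan$chrom)), out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("qtl_table", "data.frame")
  out
}

#' Trim a QTL list by conditional support in the joint model
#'
#' Backward elimination: in the simultaneous multi-QTL fit (family means
#' plus all QTL blocks), each QTL's conditional LOD is its drop-one
#' likelihood-ratio LOD. While any QTL falls below the threshold, the
#' weakest is removed and the model refitted. Genuinely distinct QTL keep
#' conditional support close to their marginal LOD; collinear duplicates of
#' one signal (e.g. twin peaks straddling a cofactor-exclusion boundary) do
#' not, and are pruned. This keeps the reported QTL count and the drop-one
#' pG decomposition interpretable.
#'
#' @inheritParams estimate_pg
#' @param threshold conditional-LOD threshold, normally the scan's
#'   genome-wide permutation threshold.
#' @return the trimmed \code{qtl_table}.
#' @export
trim_qtl <- function(qtls, y, geno, threshold) {
  yv <- align_y(y, geno)
  fl <- family_of(geno$fam, rownames(geno$geno))
  J <- stats::model.matrix(~ 0 + fl)
  n <- length(yv)
  repeat {
    nq <- nrow(qtls)
    if (nq <= 1) break
    blocks <- lapply(seq_len(nq), function(q)
      position_block(geno, fl, qtls$chrom[q], qtls$pos[q])$X)
    rss_full <- sum(qr.resid(qr(do.call(cbind, c(list(J), blocks))), yv)^2)
    cond <- vapply(seq_len(nq), function(q) {
      rss_q <- sum(qr.resid(qr(do.call(cbind, c(list(J), blocks[-q]))),
                            yv)^2)
      n / 2 * log10(rss_q / max(rss_full, rss_q * 1e-15))
    }, 0)
    if (min(cond) >= threshold) break
    qtls <- qtls[-which.min(cond), , drop = FALSE]
  }
  rownames(qtls) <- NULL
  qtls
}

#' Proportion of genotypic variance explained by detected QTL
#'
#' Fits the simultaneous multi-QTL model (family means plus the
#' expected-count blocks of all QTL) and estimates the proportion of
#' genotypic variance as 100 R2adj / h2, where R2adj is the adjusted
#' coefficient of determination of the QTL terms beyond family means.
#' Per-QTL values come from the drop-one decrement of R2adj in the joint
#' fit; per-family values repeat the computation within each family's
#' subsample (using the population h2 as proxy for the family h2, recorded
#' in attribute \code{"pg_h2_note"}). All values are floored at 0.
#'
#' @param qtls a \code{qtl_table} from \code{\link{identify_qtl}}.
#' @param y,geno response and genotypes as in \code{\link{genome_scan}}.
#' @param h2 entry-mean heritability in (0, 1].
#' @return the \code{qtl_table} with columns \code{pg} and one
#'   \code{pg_<family>} per family added; the overall and per-family totals
#'   are in attributes \code{"pg_total"} and \code{"pg_total_family"}.
#' @export
estimate_pg <- function(qtls, y, geno, h2) {
  stopifnot(h2 > 0, h2 <= 1)
  yv <- align_y(y, geno)
  fl <- family_of(geno$fam, rownames(geno$geno))
  fams <- levels(fl)
  nq <- nrow(qtls)
  qtls$pg <- numeric(nq)
  for (f in fams) qtls[[paste0("pg_", f)]] <- numeric(nq)
  if (nq == 0) {
    attr(qtls, "pg_total") <- 0
    attr(qtls, "pg_total_family") <- stats::setNames(numeric(length(fams)),
                                                     fams)
    return(qtls)
  }
  blocks <- lapply(seq_len(nq), function(q)
    position_block(geno, fl, qtls$chrom[q], qtls$pos[q]))
  J <- stats::model.matrix(~ 0 + fl)
  adj_r2 <- function(yy, Xbase, block_list) {
    n <- length(yy)
    qb <- qr(Xbase)
    rss_b <- sum(qr.resid(qb, yy)^2)
    Xf <- do.call(cbind, c(list(Xbase), block_list))
    qf <- qr(Xf)
    if (n - qf$rank < 1) stop("more model columns than lines")
    rss_f <- sum(qr.resid(qf, yy)^2)
    m <- qf$rank - qb$rank
    if (rss_b < 1e-12) return(0)
    r2 <- 1 - rss_f / rss_b
    1 - (1 - r2) * (n - qb$rank) / (n - qb$rank - m)
  }
  Xall <- lapply(blocks, `[[`, "X")
  r2_full <- adj_r2(yv, J, Xall)
  attr(qtls, "pg_total") <- 100 * max(0, r2_full) / h2
  for (q in seq_len(nq)) {
    r2_minus <- adj_r2(yv, J, Xall[-q])
    qtls$pg[q] <- 100 * max(0, r2_full - r2_minus) / h2
  }
  tot_f <- stats::setNames(numeric(length(fams)), fams)
  for (f in fams) {
    rows <- fl == f
    yy <- yv[rows]
    Xb <- matrix(1, sum(rows), 1)
    Xf_list <- lapply(blocks, function(b) {
      if (!f %in% b$fams) return(NULL)
      b$X[rows, paste0(".q_", f), drop = FALSE]
    })
    present <- !vapply(Xf_list, is.null, TRUE)
    if (!any(present)) next
    r2f <- adj_r2(yy, Xb, Xf_list[present])
    tot_f[f] <- 100 * max(0, r2f) / h2
    for (q in seq_len(nq)) {
      if (!present[q]) next
      keep <- present & seq_len(nq) != q
      r2m <- if (any(keep)) adj_r2(yy, Xb, Xf_list[keep]) else 0
      qtls[[paste0("pg_", f)]][q] <- 100 * max(0, r2f - r2m) / h2
    }
  }
  attr(qtls, "pg_total_family") <- tot_f
  attr(qtls, "pg_h2_note") <-
    "per-family pG uses the population h2 as proxy for family h2"
  qtls
}
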
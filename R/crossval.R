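#' Relative bias of cross-validated pG
#'
#' 100 (pg_es - pg_ts) / pg_es: the percent drop from the estimation-set to
#' the test-set estimate of the proportion of genotypic variance, the usual
#' summary of overfitting in QTL cross-validation.
#'
#' @param pg_es,pg_ts percents from estimation and test sets.
#' @return percent; NA with a warning when pg_es <= 0 (undefined).
#' @export
relative_bias <- function(pg_es, pg_ts) {
  if (any(pg_es <= 0)) {
    warning("relative bias undefined for pg_es <= 0")
    return(ifelse(pg_es <= 0, NA_real_, 100 * (pg_es - pg_ts) / pg_es))
  }
  100 * (pg_es - pg_ts) / pg_es
}

# stratified fold assignment: within each family, a shuffled repetition of
# 1..k, so per-fold family counts differ by at most one line
cv_folds <- function(fl, k) {
  fold <- integer(length(fl))
  for (f in levels(fl)) {
    rows <- which(fl == f)
    if (length(rows) < k) stop("every family needs at least k lines")
    fold[rows[sample.int(length(rows))]] <-
      rep_len(seq_len(k), length(rows))
  }
  fold
}

# joint multi-QTL least-squares fit; returns per-block coefficients
qtl_joint_coef <- function(qtls, yv, geno, fl) {
  blocks <- lapply(seq_len(nrow(qtls)), function(q) {
    b <- position_block(geno, fl, qtls$chrom[q], qtls$pos[q])
    colnames(b$X) <- paste0("q", q, "_", b$fams)
    b
  })
  J <- stats::model.matrix(~ 0 + fl)
  X <- do.call(cbind, c(list(J), lapply(blocks, `[[`, "X")))
  cf <- qr.coef(qr(X), yv)
  cf[is.na(cf)] <- 0
  list(blocks = blocks, coef = cf)
}

#' Fivefold cross-validation of the mapping pipeline
#'
#' Per run, the lines are split into \code{k} folds stratified by family.
#' Each fold in turn is the test set; on the remaining estimation set the
#' full pipeline runs from scratch (cofactor selection, permutation
#' threshold with \code{n_perm} permutations, QTL detection, joint effect
#' estimation, pG). Test-set pG is the shrinkage-adjusted squared
#' correlation between the QTL-predicted and observed values (centred
#' within family), divided by h2; folds whose estimation set yields no QTL
#' contribute 0. Results are averaged over all k x runs fold instances.
#'
#' @inheritParams mcqtl
#' @param y a \code{line_values}.
#' @param h2 entry-mean heritability.
#' @param k number of folds (>= 2).
#' @param runs number of independent k-fold replications.
#' @param n_perm permutations per estimation-set threshold (reduced from
#'   the full-data default for tractability).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return object of class \code{"mcqtl_cv"}: n_runs, k, qtl_ds, pg_ds,
#'   qtl_es, pg_es, pg_ts, relative_bias, per-fold table \code{folds},
#'   detection-frequency table \code{frequency} (chrom, pos, count).
#' @export
run_cv <- function(y, geno, h2, config = mcqtl_config(), k = 5, runs = 20,
                   n_perm = 200, seed = 1) {
  stopifnot(k >= 2)
  fl <- family_of(geno$fam, rownames(geno$geno))
  fit_ds <- mcqtl(y, geno, config, h2 = h2, n_perm = n_perm, seed = seed)
  freq <- list()
  fold_rows <- list()
  for (r in seq_len(runs)) {
    set.seed(seed + 7919L * r)
    fold <- cv_folds(fl, k)
    for (kk in seq_len(k)) {
      es_lines <- rownames(geno$geno)[fold != kk]
      ts_lines <- rownames(geno$geno)[fold == kk]
      geno_es <- subset_lines(geno, es_lines)
      y_es <- line_values(y[y$line %in% es_lines, ])
      fit_es <- mcqtl(y_es, geno_es, config, h2 = h2, n_perm = n_perm,
                      seed = seed + 104729L * r + kk)
      nq <- nrow(fit_es$qtl)
      pg_es <- if (nq) attr(fit_es$qtl, "pg_total") else 0
      pg_ts <- 0
      if (nq) {
        for (q in seq_len(nq))
          freq[[length(freq) + 1]] <- data.frame(
            chrom = fit_es$qtl$chrom[q], pos = fit_es$qtl$pos[q])
        jc <- qtl_joint_coef(fit_es$qtl, align_y(y_es, geno_es), geno_es,
                             family_of(geno_es$fam, es_lines))
        geno_ts <- subset_lines(geno, ts_lines)
        fl_ts <- family_of(geno_ts$fam, ts_lines)
        pred <- numeric(length(ts_lines))
        for (q in seq_len(nq)) {
          b <- jc$blocks[[q]]
          bt <- position_block(geno_ts, fl_ts, fit_es$qtl$chrom[q],
                               fit_es$qtl$pos[q], keep_fams = b$fams)
          colnames(bt$X) <- colnames(b$X)
          pred <- pred + drop(bt$X %*% jc$coef[colnames(b$X)])
        }
        obs <- align_y(line_values(y[y$line %in% ts_lines, ]), geno_ts)
        obs_c <- obs - stats::ave(obs, fl_ts)
        pred_c <- pred - stats::ave(pred, fl_ts)
        if (stats::sd(pred_c) > 0 && stats::sd(obs_c) > 0) {
          rr <- stats::cor(obs_c, pred_c)
          n_ts <- length(obs)
          r2adj <- 1 - (1 - rr^2) * (n_ts - 1) / (n_ts - 2)
          pg_ts <- if (rr > 0) 100 * max(0, r2adj) / h2 else 0
        }
      }
      fold_rows[[length(fold_rows) + 1]] <- data.frame(
        run = r, fold = kk, n_qtl = nq, pg_es = pg_es, pg_ts = pg_ts)
    }
  }
  folds <- do.call(rbind, fold_rows)
  freq_df <- if (length(freq)) {
    f <- do.call(rbind, freq)
    stats::aggregate(list(count = rep(1L, nrow(f))),
                     by = list(chrom = f$chrom, pos = f$pos), FUN = sum)
  } else data.frame(chrom = character(), pos = numeric(), count = integer())
  pg_es <- mean(folds$pg_es)
  pg_ts <- mean(folds$pg_ts)
  structure(list(
    n_runs = runs, k = k,
    qtl_ds = nrow(fit_ds$qtl),
    pg_ds = if (nrow(fit_ds$qtl)) attr(fit_ds$qtl, "pg_total") else 0,
    qtl_es = mean(folds$n_qtl), pg_es = pg_es, pg_ts = pg_ts,
    relative_bias = if (pg_es > 0) relative_bias(pg_es, pg_ts) else NA_real_,
    folds = folds, frequency = freq_df, fit_ds = fit_ds),
    class = "mcqtl_cv")
}

#' @export
print.mcqtl_cv <- function(x, ...) {
  cat("Fivefold cross-validation (", x$n_runs, " runs x ", x$k,
      " folds)\n", sep = "")
  cat(sprintf("  QTL_DS %d   pG_DS %.1f\n", x$qtl_ds, x$pg_ds))
  cat(sprintf("  QTL_ES %.1f  pG_ES %.1f  pG_TS %.1f\n",
              x$qtl_es, x$pg_es, x$pg_ts))
  cat(sprintf("  relative bias %.1f%%\n", x$relative_bias))
  invisible(x)
}
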
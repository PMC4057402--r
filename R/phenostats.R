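#' Per-line adjusted phenotype means
#'
#' Container for one trait's adjusted entry means (BLUE-style), the
#' response vector of the genome scan.
#'
#' @param x data frame with columns \code{line}, \code{value}.
#' @param trait trait name.
#' @param n_locations locations the means are based on.
#' @return data frame of class \code{c("line_values", "data.frame")}.
#' @export
line_values <- function(x, trait = "trait", n_locations = NA_integer_) {
  stopifnot(is.data.frame(x), all(c("line", "value") %in% names(x)))
  lv <- data.frame(line = as.character(x$line), value = as.numeric(x$value),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(lv$line)) stop("one value per line required")
  if (any(!is.finite(lv$value))) stop("line values must be finite")
  structure(lv, trait = trait, n_locations = n_locations,
            class = c("line_values", "data.frame"))
}

# fit value ~ 0 + line + replicate within one location by least squares;
# returns adjusted line means (replicate effects averaged over levels),
# residual SS and df
fit_location <- function(d) {
  line <- factor(d$line_id)
  if (nrow(d) < 2) stop("singular design: a location needs >= 2 plots")
  rep_f <- if ("replicate" %in% names(d)) factor(d$replicate) else factor(1)
  X <- stats::model.matrix(~ 0 + line)
  rep_lev <- levels(rep_f)
  if (length(rep_lev) > 1)
    X <- cbind(X, stats::model.matrix(~rep_f)[, -1, drop = FALSE])
  if (nrow(X) < nlevels(line) + (length(rep_lev) > 1))
    stop("singular design: more parameters than plots")
  fit <- stats::lm.fit(X, d$value)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  nl <- nlevels(line)
  rep_eff <- if (length(rep_lev) > 1) c(0, cf[-seq_len(nl)]) else 0
  adj <- cf[seq_len(nl)] + mean(rep_eff)
  names(adj) <- levels(line)
  list(means = adj, rss = sum(fit$residuals^2),
       df = nrow(X) - fit$rank,
       reps = table(line))
}

#' Adjusted entry means from a plot-level trial
#'
#' Two-stage fixed-effects adjustment: within each location, line and
#' replicate effects are fitted jointly by least squares and each line's
#' adjusted mean is taken at the average replicate effect; the
#' location-wise estimates are then averaged across locations. Adding a
#' constant to all plots of one location therefore shifts all means
#' equally and leaves line contrasts unchanged. Lines present in the trial
#' but absent from \code{fam} (check varieties) contribute to the
#' adjustment but are dropped from the output.
#'
#' @param trial data frame with columns \code{line_id}, \code{location},
#'   \code{replicate}, \code{value}, or pre-adjusted \code{line_id},
#'   \code{value} (returned as-is); a \code{sim_trial} is also accepted.
#' @param fam optional \code{dh_families}; every family line must be
#'   observed at least once.
#' @param trait trait name carried in the result.
#' @return a \code{line_values}.
#' @export
compute_line_means <- function(trial, fam = NULL, trait = "trait") {
  if (inherits(trial, "sim_trial")) trial <- trial$plots
  stopifnot(is.data.frame(trial), "line_id" %in% names(trial),
            "value" %in% names(trial))
  if (!"location" %in% names(trial)) {
    lv <- line_values(data.frame(line = trial$line_id, value = trial$value),
                      trait = trait, n_locations = 1L)
  } else {
    locs <- unique(trial$location)
    per_loc <- lapply(locs, function(l)
      fit_location(trial[trial$location == l, , drop = FALSE])$means)
    all_lines <- unique(trial$line_id)
    M <- vapply(per_loc, function(m) m[all_lines], numeric(length(all_lines)))
    M <- matrix(M, nrow = length(all_lines),
                dimnames = list(all_lines, locs))
    lv <- line_values(
      data.frame(line = all_lines, value = rowMeans(M, na.rm = TRUE)),
      trait = trait, n_locations = length(locs))
  }
  if (!is.null(fam)) {
    missing_lines <- setdiff(fam$lines$line, lv$line)
    if (length(missing_lines))
      stop("line(s) with no observation: ",
           paste(utils::head(missing_lines, 5), collapse = ", "))
    lv <- lv[lv$line %in% fam$lines$line, , drop = FALSE]
    lv <- line_values(lv, trait = trait,
                      n_locations = attr(lv, "n_locations"))
  }
  lv
}

#' Entry-mean heritability from variance components
#'
#' h2 = var_g / (var_g + var_gxl/L + var_e/(L rbar)). With a single
#' location (var_gxl unavailable) the same expression gives the
#' repeatability.
#'
#' @param var_g,var_gxl,var_e variance components (var_gxl may be NA).
#' @param n_locations number of locations L.
#' @param rbar effective (harmonic-mean) replicate number.
#' @export
heritability <- function(var_g, var_gxl, var_e, n_locations, rbar = 1) {
  gxl <- if (is.na(var_gxl)) 0 else var_gxl / n_locations
  denom <- var_g + gxl + var_e / (n_locations * rbar)
  if (denom <= 0) return(NA_real_)
  min(1, max(0, var_g / denom))
}

#' Variance components and heritability from a plot-level trial
#'
#' Method-of-moments (expected mean squares) estimation on the line x
#' location table of adjusted cell means: the plot error variance comes
#' from the pooled within-location residual mean square, the
#' genotype-by-location component from the interaction mean square minus
#' the error contribution, and the genotypic component from the line mean
#' square. Negative solutions are truncated at zero. With a single
#' location var_gxl is unavailable (NA) and h2 is the repeatability.
#'
#' @inheritParams compute_line_means
#' @return list of class \code{"variance_components"} with var_g, var_gxl,
#'   var_e, h2, n_locations, effective_reps.
#' @export
estimate_vc <- function(trial, fam = NULL) {
  if (inherits(trial, "sim_trial")) trial <- trial$plots
  stopifnot(is.data.frame(trial),
            all(c("line_id", "location", "value") %in% names(trial)))
  if (!is.null(fam))
    trial <- trial[trial$line_id %in% fam$lines$line, , drop = FALSE]
  if (length(unique(trial$line_id)) < 2) stop("need at least 2 lines")
  locs <- unique(trial$location)
  L <- length(locs)
  fits <- lapply(locs, function(l)
    fit_location(trial[trial$location == l, , drop = FALSE]))
  rss <- sum(vapply(fits, `[[`, 0, "rss"))
  dfe <- sum(vapply(fits, `[[`, 0, "df"))
  var_e <- if (dfe > 0) rss / dfe else 0
  reps <- unlist(lapply(fits, `[[`, "reps"))
  rbar <- length(reps) / sum(1 / reps)
  lines <- Reduce(intersect, lapply(fits, function(f) names(f$means)))
  X <- vapply(fits, function(f) f$means[lines], numeric(length(lines)))
  X <- matrix(X, nrow = length(lines), dimnames = list(lines, locs))
  n <- nrow(X)
  if (L >= 2) {
    ms_g <- L * stats::var(rowMeans(X))
    resid <- X - outer(rowMeans(X), rep(1, L)) -
      outer(rep(1, n), colMeans(X)) + mean(X)
    ms_gl <- sum(resid^2) / ((n - 1) * (L - 1))
    var_gxl <- max(0, ms_gl - var_e / rbar)
    var_g <- max(0, (ms_g - ms_gl) / L)
  } else {
    var_gxl <- NA_real_
    var_g <- max(0, stats::var(X[, 1]) - var_e / rbar)
  }
  structure(list(var_g = var_g, var_gxl = var_gxl, var_e = var_e,
                 h2 = heritability(var_g, var_gxl, var_e, L, rbar),
                 n_locations = L, effective_reps = rbar),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("var_g = %.3f  var_gxl = %s  var_e = %.3f\n", x$var_g,
              ifelse(is.na(x$var_gxl), "n.a.", sprintf("%.3f", x$var_gxl)),
              x$var_e))
  cat(sprintf("%s = %.2f  (%d location%s, effective reps %.2f)\n",
              if (x$n_locations > 1) "h2" else "repeatability", x$h2,
              x$n_locations, if (x$n_locations > 1) "s" else "",
              x$effective_reps))
  invisible(x)
}

#' Phenotypic correlation between two traits' line values
#'
#' Product-moment correlation over the lines common to both traits, with a
#' two-sided t test.
#'
#' @param a,b \code{line_values} objects.
#' @return list of class \code{"pheno_cor"}: r, p_value, n.
#' @export
pheno_correlation <- function(a, b) {
  stopifnot(inherits(a, "line_values"), inherits(b, "line_values"))
  common <- intersect(a$line, b$line)
  if (length(common) < 3) stop("need >= 3 common lines")
  x <- a$value[match(common, a$line)]
  y <- b$value[match(common, b$line)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: a trait has zero variance")
  ct <- stats::cor.test(x, y)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(common)), class = "pheno_cor")
}

#' @export
print.pheno_cor <- function(x, ...) {
  cat(sprintf("r = %.3f (n = %d, P = %.3g)\n", x$r, x$n, x$p_value))
  invisible(x)
}

#' Read / write phenotype tables
#'
#' Plot-level tables have columns \code{line_id}, \code{location},
#' \code{replicate}, \code{value}; pre-adjusted means have \code{line_id},
#' \code{value} and are returned as \code{line_values}.
#'
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("line_id", "location", "replicate", "value") %in% names(d)))
    return(d)
  if (all(c("line_id", "value") %in% names(d)))
    return(line_values(data.frame(line = d$line_id, value = d$value)))
  stop("unrecognized phenotype file layout")
}

#' @rdname read_phenotypes
#' @param x a plot-level data frame or a \code{line_values}.
#' @export
write_phenotypes <- function(x, path) {
  if (inherits(x, "line_values")) {
    utils::write.csv(data.frame(line_id = x$line, value = x$value),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
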
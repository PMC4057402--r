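#' Simulate a random genetic map
#'
#' Chromosomes are named \code{1A..7A, 1B.., 1R..} by genome; markers are
#' placed uniformly at random along each chromosome and sorted. Optional
#' anchor positions (e.g. the true location of a simulated QTL) are added as
#' extra markers so that simulated loci always coincide with map positions.
#'
#' @param genomes data frame with columns \code{genome}, \code{n_chrom},
#'   \code{length} (cM), \code{n_markers} (>= 2 per chromosome).
#' @param seed integer seed; the map is deterministic given the seed.
#' @param anchors optional data frame with columns \code{chrom}, \code{pos}
#'   of positions that must carry a marker.
#' @return a \code{genmap}.
#' @export
make_map <- function(genomes, seed = 1, anchors = NULL) {
  stopifnot(all(c("genome", "n_chrom", "length", "n_markers") %in%
                  names(genomes)))
  if (any(genomes$n_markers < 2)) stop("need >= 2 markers per chromosome")
  set.seed(seed)
  out <- list()
  counter <- integer()
  for (i in seq_len(nrow(genomes))) {
    g <- genomes$genome[i]
    if (is.na(counter[g])) counter[g] <- 0L
    for (cc in seq_len(genomes$n_chrom[i])) {
      counter[g] <- counter[g] + 1L
      chrom <- paste0(counter[g], g)
      pos <- sort(stats::runif(genomes$n_markers[i], 0, genomes$length[i]))
      if (!is.null(anchors)) {
        a <- anchors$pos[anchors$chrom == chrom]
        pos <- sort(unique(c(pos, a)))
      }
      out[[chrom]] <- data.frame(
        marker = sprintf("%s_m%02d", chrom, seq_along(pos)),
        chrom = chrom, pos = pos, stringsAsFactors = FALSE)
    }
  }
  genetic_map(do.call(rbind, out))
}

#' Draw random homozygous parent genotypes
#'
#' Each parent carries allele 0 or 1 at every marker, independently with
#' probability one half, so roughly half the markers segregate in any given
#' biparental cross.
#'
#' @param map a \code{genmap}.
#' @param parent_ids character vector of parent names.
#' @param seed integer seed.
#' @return matrix parents x markers of alleles in \{0,1\}.
#' @export
simulate_parents <- function(map, parent_ids, seed = 1) {
  set.seed(seed)
  al <- matrix(stats::rbinom(length(parent_ids) * nrow(map), 1, 0.5),
               nrow = length(parent_ids),
               dimnames = list(parent_ids, map$marker))
  al
}

#' Simulate one doubled-haploid family
#'
#' A DH line is the chromosome-doubled copy of a single F1 gamete, so one
#' meiosis separates it from the cross. Gametes are generated per
#' chromosome as a Markov chain over the marker loci: the parental origin of
#' the first marker is fair, and it switches between adjacent markers with
#' probability \code{haldane_r(d)} (no crossover interference). Genotypes
#' are coded as copies (0 or 2) of parent1's allele, parent1 being the
#' family's reference parent; markers where the parents carry the same
#' allele are monomorphic and score 2 in every line.
#'
#' @param p1_alleles,p2_alleles named numeric vectors of parental alleles,
#'   in map marker order.
#' @param n_lines number of DH lines (> 0).
#' @param map a \code{genmap}.
#' @param seed integer seed.
#' @param prefix line-id prefix.
#' @return genotype matrix n_lines x markers with entries in \{0,2\}.
#' @export
simulate_dh_family <- function(p1_alleles, p2_alleles, n_lines, map,
                               seed = 1, prefix = "L") {
  if (n_lines <= 0) stop("n_lines must be positive")
  stopifnot(length(p1_alleles) == nrow(map),
            length(p2_alleles) == nrow(map))
  set.seed(seed)
  m <- nrow(map)
  G <- matrix(0, n_lines, m, dimnames = list(
    sprintf("%s%04d", prefix, seq_len(n_lines)), map$marker))
  mono <- p1_alleles == p2_alleles
  for (cc in unique(map$chrom)) {
    idx <- which(map$chrom == cc)
    k <- length(idx)
    origin <- matrix(0L, n_lines, k)
    origin[, 1] <- stats::rbinom(n_lines, 1, 0.5)
    if (k > 1) {
      r <- haldane_r(diff(map$pos[idx]))
      sw <- matrix(stats::runif(n_lines * (k - 1)) <
                     rep(r, each = n_lines), n_lines, k - 1)
      cum <- sw
      if (k > 2) cum <- t(apply(sw, 1, cumsum))
      origin[, -1] <- (origin[, 1] + cum) %% 2
    }
    G[, idx] <- 2 * ((origin == 0) |
                       matrix(mono[idx], n_lines, k, byrow = TRUE))
  }
  G
}

#' Simulate a full multi-family DH population
#'
#' Runs \code{\link{simulate_dh_family}} for every family in \code{fam}
#' using the parents recorded there, and assembles a \code{\link{dh_geno}}.
#'
#' @param fam a \code{dh_families} whose parent columns name rows of
#'   \code{parent_alleles}.
#' @param parent_alleles matrix from \code{\link{simulate_parents}}.
#' @param map a \code{genmap}.
#' @param seed integer seed.
#' @return a \code{dh_geno}.
#' @export
simulate_cross <- function(fam, parent_alleles, map, seed = 1) {
  stopifnot(inherits(fam, "dh_families"))
  fl <- family_of(fam)
  G <- matrix(NA_real_, nrow(fam$lines), nrow(map),
              dimnames = list(fam$lines$line, map$marker))
  for (i in seq_len(nrow(fam$families))) {
    fr <- fam$families[i, ]
    rows <- which(fl == fr$family)
    Gi <- simulate_dh_family(parent_alleles[fr$parent1, ],
                             parent_alleles[fr$parent2, ],
                             length(rows), map, seed = seed + i)
    G[rows, ] <- Gi
  }
  dh_geno(G, map, fam)
}

#' QTL truth model for simulation
#'
#' Holds the simulated loci (which must coincide with map markers), their
#' family-specific additive effects per copy of the reference-parent allele,
#' and the standard deviation of the normal polygenic background. A family
#' whose parents carry the same allele at a locus does not segregate there
#' regardless of the nominal effect.
#'
#' @param loci data frame with columns \code{chrom}, \code{pos}.
#' @param effects numeric matrix, one row per locus, one column per family
#'   (colnames = family ids); trait units per allele copy.
#' @param polygenic_sd trait units; \code{NA} requests auto-calibration to a
#'   target genotypic variance at simulation time.
#' @return object of class \code{"qtl_model"}.
#' @export
qtl_model <- function(loci, effects, polygenic_sd = NA_real_) {
  stopifnot(is.data.frame(loci), all(c("chrom", "pos") %in% names(loci)))
  effects <- as.matrix(effects)
  if (nrow(effects) != nrow(loci))
    stop("one effect row per locus required")
  structure(list(loci = loci, effects = effects,
                 polygenic_sd = polygenic_sd), class = "qtl_model")
}

# genotype counts at the model's loci; errors if a locus is off the map
qtl_counts <- function(geno, qtl) {
  map <- geno$map
  idx <- integer(nrow(qtl$loci))
  for (q in seq_len(nrow(qtl$loci))) {
    hit <- which(map$chrom == qtl$loci$chrom[q] &
                   abs(map$pos - qtl$loci$pos[q]) < 1e-9)
    if (length(hit) != 1)
      stop("QTL locus ", qtl$loci$chrom[q], "@", qtl$loci$pos[q],
           " does not coincide with a map marker")
    idx[q] <- hit
  }
  geno$geno[, idx, drop = FALSE]
}

#' True genetic values of simulated lines
#'
#' Genetic value = sum over loci of (allele count x family effect) plus a
#' normal polygenic deviate. When the model's \code{polygenic_sd} is NA it
#' is calibrated from this population so that the realized variance of the
#' genetic values matches \code{var_g}: the polygenic variance is set to
#' \code{var_g} minus the realized QTL variance (floored at 0).
#'
#' @param geno a \code{dh_geno}.
#' @param qtl a \code{qtl_model}.
#' @param var_g target genotypic variance (used only for calibration).
#' @param seed integer seed for the polygenic draw.
#' @param polygenic optional pre-drawn standard-normal vector (length N),
#'   e.g. to correlate the backgrounds of two traits.
#' @return list: \code{g} named vector of genetic values, \code{qtl_part},
#'   \code{polygenic_sd} actually used.
#' @export
genetic_values <- function(geno, qtl, var_g = NULL, seed = 1,
                           polygenic = NULL) {
  fl <- family_of(geno$fam, rownames(geno$geno))
  n <- nrow(geno$geno)
  if (nrow(qtl$loci) == 0) {
    qp <- stats::setNames(numeric(n), rownames(geno$geno))
  } else {
    cnt <- qtl_counts(geno, qtl)
    eff <- qtl$effects[, levels(fl), drop = FALSE]
    # per-line effect = sum_q count_iq * effect_q,f(i)
    qp <- rowSums(cnt * t(eff[, as.integer(fl), drop = FALSE]))
    names(qp) <- rownames(geno$geno)
  }
  if (is.null(polygenic)) {
    set.seed(seed)
    polygenic <- stats::rnorm(n)
  }
  sdp <- qtl$polygenic_sd
  if (is.na(sdp)) {
    if (is.null(var_g)) stop("var_g needed to calibrate polygenic_sd")
    sdp <- sqrt(max(0, var_g - stats::var(qp)))
    # pilot-draw calibration: make this draw orthogonal to the QTL part
    # and of unit variance, so the realized var(g) equals var_g exactly
    z <- polygenic - mean(polygenic)
    if (stats::var(qp) > 1e-12)
      z <- z - (qp - mean(qp)) * stats::cov(z, qp) / stats::var(qp)
    if (stats::sd(z) > 0) z <- z / stats::sd(z)
    polygenic <- z
  }
  g <- qp + sdp * polygenic
  list(g = g, qtl_part = qp, polygenic_sd = sdp)
}

#' Trait simulation settings for a multi-location trial
#'
#' @param var_g genotypic variance on the trait scale.
#' @param var_gxl genotype-by-location interaction variance.
#' @param var_e plot error variance.
#' @param n_locations number of locations (>= 1).
#' @param mean trait-scale intercept.
#' @param prep_fraction fraction of lines grown in two replicates per
#'   location (partially replicated design); the rest get one plot.
#' @return list of class \code{"trait_sim_spec"}.
#' @export
trait_sim_spec <- function(var_g, var_gxl = 0, var_e = 0, n_locations = 1,
                           mean = 0, prep_fraction = 0.484) {
  stopifnot(var_g >= 0, var_gxl >= 0, var_e >= 0, n_locations >= 1)
  structure(list(var_g = var_g, var_gxl = var_gxl, var_e = var_e,
                 n_locations = n_locations, mean = mean,
                 prep_fraction = prep_fraction), class = "trait_sim_spec")
}

#' Simulate a multi-location partially replicated trial
#'
#' Plot value = mean + location effect + genetic value + genotype-by-location
#' deviate + plot error. Location effects are N(0,1) draws; genetic values
#' come from \code{\link{genetic_values}} (QTL + calibrated polygenic
#' background). A fraction of lines (\code{spec$prep_fraction}, resampled
#' per location) is duplicated within each location. Scores are not clamped
#' to any scale.
#'
#' @param geno a \code{dh_geno}.
#' @param qtl a \code{qtl_model}.
#' @param spec a \code{trait_sim_spec}.
#' @param seed integer seed.
#' @param genetic optional precomputed result of \code{genetic_values};
#'   drawn internally if NULL.
#' @return list of class \code{"sim_trial"}: \code{plots} data frame
#'   (line_id, location, replicate, value), \code{genetic} named true
#'   genetic values, \code{polygenic_sd}, \code{loc_effects}.
#' @export
simulate_trial <- function(geno, qtl, spec, seed = 1, genetic = NULL) {
  stopifnot(inherits(spec, "trait_sim_spec"))
  if (is.null(genetic))
    genetic <- genetic_values(geno, qtl, var_g = spec$var_g, seed = seed)
  g <- genetic$g
  n <- length(g)
  set.seed(seed + 1000003L)
  loc_eff <- stats::rnorm(spec$n_locations)
  out <- vector("list", spec$n_locations)
  for (l in seq_len(spec$n_locations)) {
    ndup <- round(spec$prep_fraction * n)
    dup <- sample(names(g), ndup)
    ids <- c(names(g), dup)
    rep_no <- c(rep(1L, n), rep(2L, ndup))
    gxl <- stats::rnorm(n, 0, sqrt(spec$var_gxl))
    names(gxl) <- names(g)
    err <- stats::rnorm(length(ids), 0, sqrt(spec$var_e))
    out[[l]] <- data.frame(
      line_id = ids, location = paste0("loc", l), replicate = rep_no,
      value = spec$mean + loc_eff[l] + g[ids] + gxl[ids] + err,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(plots = do.call(rbind, out), genetic = g,
                 polygenic_sd = genetic$polygenic_sd,
                 loc_effects = loc_eff), class = "sim_trial")
}

#' Simulate per-line adjusted means directly
#'
#' Shortcut past the field-trial stage: line value = genetic value + normal
#' noise whose variance is set from the entry-mean heritability,
#' \code{var_err = var_g (1 - h2) / h2}.
#'
#' @inheritParams genetic_values
#' @param h2 entry-mean heritability in (0, 1].
#' @param mean trait intercept.
#' @return a \code{line_values} data frame; the true genetic values are
#'   attached as attribute \code{"genetic"}.
#' @export
simulate_blues <- function(geno, qtl, var_g, h2, mean = 0, seed = 1,
                           polygenic = NULL) {
  stopifnot(h2 > 0, h2 <= 1)
  gv <- genetic_values(geno, qtl, var_g = var_g, seed = seed,
                       polygenic = polygenic)
  set.seed(seed + 2000003L)
  v_err <- var_g * (1 - h2) / h2
  y <- mean + gv$g + stats::rnorm(length(gv$g), 0, sqrt(v_err))
  lv <- line_values(data.frame(line = names(gv$g), value = y),
                    trait = "simulated", n_locations = 1L)
  attr(lv, "genetic") <- gv$g
  lv
}
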
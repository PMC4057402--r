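#' Simulate the default four-family triticale study
#'
#' Generates a synthetic study with the structure the mapping pipeline
#' assumes: 647 DH lines in four families (DH06 131, DH07 120, EAW74 200,
#' EAW78 196) from six parents (the first two families share one parent,
#' the last two another; the two parent pools are disjoint), a 21-chromosome
#' map with seven chromosomes per subgenome A/B/R, and two correlated traits
#' ("winter hardiness" with genotypic variance 3.00, genotype-by-location
#' variance 0.33 and plot error 0.81 over two locations; "frost tolerance"
#' with 2.36 and 0.34 at one location). Each trait is controlled by three
#' major QTL (on the 5A, 1B and 5R analogues, with pG targets 14.1, 12.5
#' and 24.1 percent) and six minor QTL (2.5 percent each) plus a calibrated
#' polygenic background. The 5A locus segregates only in the third family
#' and the 5R locus in all but the third. The two traits share all QTL
#' (effects scaled to the variance ratio) and their polygenic backgrounds
#' are correlated 0.99, so the line-value correlation targets 0.88.
#'
#' When fewer chromosomes or shorter maps are requested (for quick
#' experiments), QTL chromosome numbers are wrapped into the available
#' range and positions rescaled proportionally; every QTL position is
#' anchored by a marker.
#'
#' @param seed integer seed; everything downstream is deterministic.
#' @param n_lines named family sizes.
#' @param chrom_per_genome chromosomes per subgenome (7 for the full map).
#' @param chrom_length chromosome length in cM.
#' @param n_markers markers per chromosome.
#' @param with_trials also simulate the two plot-level field trials.
#' @param rg_polygenic correlation of the two traits' polygenic deviates.
#' @return list of class \code{"triticale_sim"}: map, fam, parents, geno,
#'   qtl_wh, qtl_ft, spec_wh, spec_ft, truth (data frame of loci with
#'   per-family segregation and effects), genetic_wh, genetic_ft, and
#'   (optionally) trial_wh, trial_ft.
#' @export
simulate_triticale <- function(seed = 1,
                               n_lines = c(DH06 = 131, DH07 = 120,
                                           EAW74 = 200, EAW78 = 196),
                               chrom_per_genome = 7, chrom_length = 120,
                               n_markers = 40, with_trials = FALSE,
                               rg_polygenic = 0.99) {
  var_g_wh <- 3.00; var_g_ft <- 2.36
  loci0 <- data.frame(
    chrom_no = c(5, 1, 5, 2, 7, 2, 5, 6, 4),
    genome   = c("A", "B", "R", "A", "A", "B", "B", "B", "R"),
    pos      = c(52.7, 54.1, 58.9, 62.1, 63.6, 107.4, 39.9, 56.8, 35.7),
    target   = c(0.141, 0.125, 0.241, rep(0.025, 6)),
    stringsAsFactors = FALSE)
  loci0$chrom_no <- (loci0$chrom_no - 1) %% chrom_per_genome + 1
  loci0$pos <- round(loci0$pos * chrom_length / 120, 1)
  loci0$chrom <- paste0(loci0$chrom_no, loci0$genome)
  # two loci wrapped onto the same spot would collide; jitter deterministically
  dup <- duplicated(loci0[, c("chrom", "pos")])
  loci0$pos[dup] <- loci0$pos[dup] + 1
  map <- make_map(
    data.frame(genome = c("A", "B", "R"), n_chrom = chrom_per_genome,
               length = chrom_length, n_markers = n_markers),
    seed = seed,
    anchors = loci0[, c("chrom", "pos")])
  fam <- dh_families(
    data.frame(line = unlist(lapply(names(n_lines), function(f)
      sprintf("%s_%03d", f, seq_len(n_lines[[f]])))),
      family = rep(names(n_lines), n_lines)),
    data.frame(family = names(n_lines),
               parent1 = c("P1", "P1", "P4", "P4"),
               parent2 = c("P2", "P3", "P5", "P6")))
  parents <- simulate_parents(map, paste0("P", 1:6), seed = seed + 17L)
  qmk <- vapply(seq_len(nrow(loci0)), function(q)
    map$marker[map$chrom == loci0$chrom[q] &
                 abs(map$pos - loci0$pos[q]) < 1e-9][1], "")
  # deliberate segregation patterns at the three major loci
  parents[, qmk[1]] <- c(1, 1, 1, 1, 0, 1)  # 5A: only family 3 segregates
  parents[, qmk[2]] <- c(1, 0, 0, 1, 0, 0)  # 1B: all four segregate
  parents[, qmk[3]] <- c(1, 0, 0, 1, 1, 0)  # 5R: family 3 monomorphic
  geno <- simulate_cross(fam, parents, map, seed = seed + 101L)
  # family weights and realized segregation decide the effect sizes
  seg <- t(vapply(qmk, function(mk) {
    p <- parents[, mk]
    c(DH06 = p["P1"] != p["P2"], DH07 = p["P1"] != p["P3"],
      EAW74 = p["P4"] != p["P5"], EAW78 = p["P4"] != p["P6"])
  }, logical(4)))
  w <- n_lines / sum(n_lines)
  a_wh <- vapply(seq_len(nrow(loci0)), function(q) {
    ws <- sum(w[seg[q, ]])
    if (ws == 0) 0 else sqrt(loci0$target[q] * var_g_wh / ws)
  }, 0)
  eff_wh <- matrix(a_wh, nrow(loci0), length(n_lines),
                   dimnames = list(NULL, names(n_lines)))
  eff_ft <- eff_wh * sqrt(var_g_ft / var_g_wh)
  qtl_wh <- qtl_model(loci0[, c("chrom", "pos")], eff_wh)
  qtl_ft <- qtl_model(loci0[, c("chrom", "pos")], eff_ft)
  set.seed(seed + 1009L)
  z1 <- stats::rnorm(nrow(geno$geno))
  z2 <- rg_polygenic * z1 +
    sqrt(1 - rg_polygenic^2) * stats::rnorm(nrow(geno$geno))
  genetic_wh <- genetic_values(geno, qtl_wh, var_g = var_g_wh,
                               polygenic = z1)
  genetic_ft <- genetic_values(geno, qtl_ft, var_g = var_g_ft,
                               polygenic = z2)
  spec_wh <- trait_sim_spec(var_g_wh, 0.33, 0.81, n_locations = 2,
                            mean = 3.9)
  spec_ft <- trait_sim_spec(var_g_ft, 0, 0.34, n_locations = 1,
                            mean = 4.8)
  truth <- cbind(loci0[, c("chrom", "pos", "target")],
                 seg = seg, eff_wh = a_wh)
  out <- list(map = map, fam = fam, parents = parents, geno = geno,
              qtl_wh = qtl_wh, qtl_ft = qtl_ft,
              spec_wh = spec_wh, spec_ft = spec_ft,
              genetic_wh = genetic_wh, genetic_ft = genetic_ft,
              truth = truth, seed = seed)
  if (with_trials) {
    out$trial_wh <- simulate_trial(geno, qtl_wh, spec_wh,
                                   seed = seed + 23L, genetic = genetic_wh)
    out$trial_ft <- simulate_trial(geno, qtl_ft, spec_ft,
                                   seed = seed + 29L, genetic = genetic_ft)
  }
  class(out) <- "triticale_sim"
  out
}

#' @export
print.triticale_sim <- function(x, ...) {
  cat("Simulated multi-family DH study (seed", x$seed, ")\n")
  print(x$fam)
  print(x$map)
  cat(nrow(x$truth), "QTL per trait; majors on",
      paste(x$truth$chrom[x$truth$target > 0.10], collapse = ", "), "\n")
  invisible(x)
}
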
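# shared simulation fixtures, all built in code at test time

four_families <- function(n_per_fam = 50) {
  dh_families(
    data.frame(line = sprintf("L%04d", seq_len(4 * n_per_fam)),
               family = rep(c("F1", "F2", "F3", "F4"), each = n_per_fam)),
    data.frame(family = c("F1", "F2", "F3", "F4"),
               parent1 = c("P1", "P1", "P4", "P4"),
               parent2 = c("P2", "P3", "P5", "P6")))
}

# null multi-family study: 4 families x n lines, 5 chromosomes, no QTL
null_study <- function(seed, n_per_fam = 50, n_markers = 10, length = 100) {
  map <- make_map(data.frame(genome = c("A", "B", "R"),
                             n_chrom = c(2, 2, 1),
                             length = length, n_markers = n_markers),
                  seed = seed)
  fam <- four_families(n_per_fam)
  parents <- simulate_parents(map, paste0("P", 1:6), seed = seed + 1)
  geno <- simulate_cross(fam, parents, map, seed = seed + 2)
  set.seed(seed + 3)
  y <- line_values(data.frame(line = rownames(geno$geno),
                              value = stats::rnorm(nrow(geno$geno))))
  list(map = map, fam = fam, geno = geno, y = y)
}

# one QTL at 52.7 cM on 5A-analogue segregating in all four families,
# explaining pg of the genotypic variance, entry-mean heritability h2
single_qtl_study <- function(seed, pg = 0.25, h2 = 0.87, var_g = 3,
                             n_per_fam = 50, n_markers = 10,
                             length = 100, qtl_pos = 52.7) {
  map <- make_map(data.frame(genome = c("A", "B", "R"),
                             n_chrom = c(2, 2, 1),
                             length = length, n_markers = n_markers),
                  seed = seed,
                  anchors = data.frame(chrom = "1A", pos = qtl_pos))
  fam <- four_families(n_per_fam)
  parents <- simulate_parents(map, paste0("P", 1:6), seed = seed + 1)
  qmk <- map$marker[map$chrom == "1A" & abs(map$pos - qtl_pos) < 1e-9]
  parents[, qmk] <- c(1, 0, 0, 1, 0, 0)   # segregates in every family
  geno <- simulate_cross(fam, parents, map, seed = seed + 2)
  a <- sqrt(pg * var_g)                   # within-family count variance is 1
  qtl <- qtl_model(data.frame(chrom = "1A", pos = qtl_pos),
                   matrix(a, 1, 4, dimnames = list(NULL,
                                                   c("F1", "F2", "F3", "F4"))))
  y <- simulate_blues(geno, qtl, var_g = var_g, h2 = h2, seed = seed + 3)
  list(map = map, fam = fam, geno = geno, qtl = qtl, y = y,
       qtl_pos = qtl_pos, effect = a)
}

fast_cfg <- function(scan_step = 2, ...) {
  mcqtl_config(n_permutations = 100, scan_step = scan_step, ...)
}

# sparse two-locus design whose pair grid matches the region count of the
# Bonferroni assumption: 5 chromosomes x 2 markers 60 cM apart
sparse_study <- function(seed, n_per_fam = 50, seg_families = "all") {
  mk <- expand.grid(i = 1:2, chrom = c("1A", "2A", "1B", "2B", "1R"),
                    stringsAsFactors = FALSE)
  map <- genetic_map(data.frame(
    marker = sprintf("%s_m%d", mk$chrom, mk$i),
    chrom = mk$chrom, pos = ifelse(mk$i == 1, 0, 60)))
  fam <- four_families(n_per_fam)
  parents <- simulate_parents(map, paste0("P", 1:6), seed = seed + 1)
  # interacting loci: first marker of 1A and of 1B
  seg <- if (identical(seg_families, "all")) c(1, 0, 0, 1, 0, 0)
         else c(1, 0, 1, 1, 1, 1)          # only F1 (P1 x P2) segregates
  parents[, "1A_m1"] <- seg
  parents[, "1B_m1"] <- seg
  geno <- simulate_cross(fam, parents, map, seed = seed + 2)
  list(map = map, fam = fam, geno = geno,
       m1 = match("1A_m1", map$marker), m2 = match("1B_m1", map$marker))
}

# interaction-only trait: effect a when both loci carry the reference allele
interaction_trait <- function(st, seed, a = 1, h2 = 0.9) {
  g <- a * (st$geno$geno[, st$m1] == 2) * (st$geno$geno[, st$m2] == 2)
  set.seed(seed)
  vg <- stats::var(g)
  line_values(data.frame(
    line = rownames(st$geno$geno),
    value = g + stats::rnorm(length(g), 0, sqrt(vg * (1 - h2) / h2))))
}
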
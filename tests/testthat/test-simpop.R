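test_that("DH meiosis honours the degenerate cases", {
  map <- genetic_map(data.frame(marker = c("m1", "m2"), chrom = "1A",
                                pos = c(0, 30)))
  p <- c(m1 = 1, m2 = 0)
  # identical parents: no segregation, every line equals the parents
  G <- simulate_dh_family(p, p, 20, map, seed = 1)
  expect_true(all(G == 2))
  # markers 0 cM apart: alleles always co-inherited
  map0 <- genetic_map(data.frame(marker = c("m1", "m2"), chrom = "1A",
                                 pos = c(10, 10)))
  G0 <- simulate_dh_family(c(m1 = 1, m2 = 1), c(m1 = 0, m2 = 0), 500,
                           map0, seed = 2)
  expect_true(all(G0[, 1] == G0[, 2]))
  expect_error(simulate_dh_family(p, p, 0, map), "positive")
  # determinism
  Ga <- simulate_dh_family(c(m1 = 1, m2 = 0), c(m1 = 0, m2 = 1), 50,
                           map, seed = 9)
  Gb <- simulate_dh_family(c(m1 = 1, m2 = 0), c(m1 = 0, m2 = 1), 50,
                           map, seed = 9)
  expect_identical(Ga, Gb)
})

test_that("recombination converges to one half at large distance", {
  map <- genetic_map(data.frame(marker = c("m1", "m2"), chrom = "1A",
                                pos = c(0, 1000)))
  G <- simulate_dh_family(c(m1 = 1, m2 = 1), c(m1 = 0, m2 = 0), 10000,
                          map, seed = 4)
  rec <- mean(G[, 1] != G[, 2])
  expect_lt(abs(rec - 0.5), 0.015)
})

test_that("map expansion matches Haldane within 3 SE on a large family", {
  map <- make_map(data.frame(genome = "A", n_chrom = 1, length = 120,
                             n_markers = 10), seed = 5)
  alleles1 <- stats::setNames(rep(1, 10), map$marker)
  alleles2 <- stats::setNames(rep(0, 10), map$marker)
  n <- 10000
  G <- simulate_dh_family(alleles1, alleles2, n, map, seed = 6)
  for (j in seq_len(9)) {
    r_exp <- haldane_r(map$pos[j + 1] - map$pos[j])
    r_obs <- mean(G[, j] != G[, j + 1])
    se <- sqrt(r_exp * (1 - r_exp) / n)
    expect_lt(abs(r_obs - r_exp), 3 * se + 1e-9)
  }
  # allele frequency at segregating markers is one half
  freq <- colMeans(G == 2)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / n)))
})

test_that("simulated populations satisfy the DH genotype invariants", {
  st <- null_study(7, n_per_fam = 30)
  expect_true(all(st$geno$geno %in% c(0, 2)))
  expect_equal(dim(st$geno$geno), c(120, nrow(st$map)))
  # monomorphic parental markers stay monomorphic within each family
  fl <- family_of(st$fam)
  for (f in levels(fl)) {
    fr <- st$fam$families[st$fam$families$family == f, ]
    pe <- simulate_parents(st$map, paste0("P", 1:6), seed = 7 + 1)
    mono <- pe[fr$parent1, ] == pe[fr$parent2, ]
    gm <- st$geno$geno[fl == f, mono, drop = FALSE]
    expect_true(all(gm == 2))
  }
})

test_that("polygenic calibration hits the target genotypic variance", {
  st <- single_qtl_study(11, pg = 0.25, var_g = 3)
  for (s in 1:5) {
    gv <- genetic_values(st$geno, st$qtl, var_g = 3, seed = s)
    expect_lt(abs(stats::var(gv$g) - 3) / 3, 0.05)
  }
})

test_that("a trial with no genetic or residual variation is deterministic", {
  st <- null_study(13, n_per_fam = 10, n_markers = 4)
  qtl <- qtl_model(data.frame(chrom = character(), pos = numeric()),
                   matrix(0, 0, 4), polygenic_sd = 0)
  spec <- trait_sim_spec(var_g = 0, var_gxl = 0, var_e = 0,
                         n_locations = 2, mean = 5)
  tr <- simulate_trial(st$geno, qtl, spec, seed = 1)
  for (l in unique(tr$plots$location)) {
    v <- tr$plots$value[tr$plots$location == l]
    le <- tr$loc_effects[match(l, unique(tr$plots$location))]
    expect_equal(v, rep(5 + le, length(v)))
  }
})

test_that("the default study reproduces the assumed variance structure", {
  # ANOVA on simulated trials recovers var_g : var_gxl near 9:1 (median),
  # and the two traits' line values correlate near 0.88, over seeds
  ratios <- numeric(10)
  cors <- numeric(10)
  for (s in 1:10) {
    st <- simulate_triticale(seed = s, n_markers = 10, with_trials = TRUE)
    vc <- estimate_vc(st$trial_wh)
    ratios[s] <- vc$var_g / vc$var_gxl
    lw <- compute_line_means(st$trial_wh, st$fam, trait = "wh")
    lf <- compute_line_means(st$trial_ft, st$fam, trait = "ft")
    cors[s] <- pheno_correlation(lw, lf)$r
  }
  expect_lt(abs(stats::median(ratios) - 9), 1)
  expect_true(all(cors >= 0.85 & cors <= 0.92))
})

test_that("perfectly shared genetics gives unit line-value correlation", {
  st <- simulate_triticale(seed = 21, chrom_per_genome = 1, n_markers = 6,
                           n_lines = c(DH06 = 40, DH07 = 40, EAW74 = 40,
                                       EAW78 = 40),
                           rg_polygenic = 1)
  # identical loci, proportional effects, rg = 1: genetic values collinear
  expect_gt(stats::cor(st$genetic_wh$g, st$genetic_ft$g), 0.9999)
})
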
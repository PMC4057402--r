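test_that("expected counts match the enumeration oracle to 1e-12", {
  genos <- list(c(2, 2), c(2, 0), c(0, 2), c(0, 0), c(2, NA), c(0, NA),
                c(NA, 2), c(NA, 0), c(NA, NA))
  dists <- list(c(5, 5), c(10, 10), c(1, 30), c(25, 3), c(80, 40))
  for (g in genos) for (d in dists) {
    expect_equal(expected_count(g[1], g[2], d[1], d[2]),
                 enum_expected_count(g[1], g[2], d[1], d[2]),
                 tolerance = 1e-12,
                 label = sprintf("g=(%s,%s) d=(%g,%g)", g[1], g[2],
                                 d[1], d[2]))
  }
  # at a typed marker the count is the marker's genotype
  expect_equal(expected_count(2, 0, 0, 7), 2)
  expect_equal(expected_count(0, 2, 0, 7), 0)
  # both flanks missing: population expectation
  expect_equal(expected_count(NA, NA, 10, 10), 1)
  expect_true(all(expected_count(c(2, 0, NA), c(0, 2, NA),
                                 c(3, 8, 1), c(4, 2, 9)) >= 0))
  expect_error(expected_count(2, 2, -1, 5), "distance")
})

test_that("LOD scores agree with explicit Gaussian likelihoods", {
  expect_equal(lod_score(1.7, 1.7, 50), 0)
  expect_equal(lod_score(10^0.1, 1, 100), 5)
  set.seed(1)
  for (i in 1:10) {
    rss0 <- stats::runif(1, 1, 10)
    rss1 <- stats::runif(1, 0.1, 1) * rss0
    n <- sample(20:500, 1)
    expect_equal(lod_score(rss0, rss1, n), gaussian_lod(rss0, rss1, n),
                 tolerance = 1e-12)
  }
  expect_error(lod_score(0, 1, 10), "positive")
  expect_error(lod_score(1, -1, 10), "positive")
})

test_that("genome scan handles degenerate inputs", {
  st <- null_study(41, n_per_fam = 20, n_markers = 6)
  cfg <- fast_cfg()
  # zero-variance phenotype: LOD identically 0
  y0 <- line_values(data.frame(line = st$y$line, value = 1))
  sc <- genome_scan(y0, st$geno, character(), cfg)
  expect_true(all(sc$lod == 0))
  # grid covers every chromosome at scan_step resolution plus markers
  for (cc in unique(st$map$chrom)) {
    mpos <- st$map$pos[st$map$chrom == cc]
    gpos <- sc$pos[sc$chrom == cc]
    expect_true(all(mpos %in% gpos))
    expect_true(all(seq(0, max(mpos), by = cfg$scan_step) %in% gpos))
  }
  # monomorphic-everywhere genotypes: empty cofactor set, flat scan
  gmono <- st$geno
  gmono$geno[] <- 2
  expect_length(select_cofactors(st$y, gmono, cfg), 0)
  sc2 <- genome_scan(st$y, gmono, character(), cfg)
  expect_true(all(sc2$lod == 0))
})

test_that("a noiseless single QTL is found exactly and LOD is nonnegative", {
  st <- single_qtl_study(43, pg = 0.25, h2 = 1)
  y <- line_values(data.frame(line = st$y$line,
                              value = attr(st$y, "genetic")[st$y$line]))
  # strip the polygenic part: response = QTL effect alone
  cnt <- st$geno$geno[, st$map$marker[st$map$chrom == "1A" &
                                        abs(st$map$pos - st$qtl_pos) < 1e-9]]
  y$value <- cnt * st$effect
  sc <- genome_scan(y, st$geno, character(), fast_cfg(scan_step = 1))
  expect_true(all(sc$lod >= 0))
  expect_equal(sc$chrom[which.max(sc$lod)], "1A")
  expect_equal(sc$pos[which.max(sc$lod)], st$qtl_pos)
})

test_that("forward BIC selection is specific and powerful", {
  # pure noise: few false entries (median 0-2 cofactors over 20 seeds)
  nfalse <- vapply(1:20, function(s) {
    st <- null_study(200 + s, n_per_fam = 50, n_markers = 5)
    length(select_cofactors(st$y, st$geno, fast_cfg()))
  }, 0L)
  expect_lte(stats::median(nfalse), 2)
  # single strong QTL: a cofactor lands within 10 cM in >= 18/20 seeds
  hits <- vapply(1:20, function(s) {
    st <- single_qtl_study(300 + s, pg = 0.25)
    cof <- select_cofactors(st$y, st$geno, fast_cfg())
    if (!length(cof)) return(FALSE)
    i <- match(cof, st$map$marker)
    any(st$map$chrom[i] == "1A" & abs(st$map$pos[i] - st$qtl_pos) <= 10)
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("an orthogonal remote cofactor leaves the LOD profile unchanged", {
  # families built by duplicating each line with cofactor 0 and 2, so the
  # centred cofactor is exactly orthogonal to every chrom-1 design column
  set.seed(7)
  map <- genetic_map(data.frame(
    marker = c("a1", "a2", "a3", "c1", "c2"),
    chrom = c("1A", "1A", "1A", "2A", "2A"),
    pos = c(0, 25, 50, 0, 60)))
  k <- 20
  fam <- dh_families(data.frame(line = sprintf("L%03d", 1:(4 * k)),
                                family = rep(c("F1", "F2"), each = 2 * k)))
  G1 <- matrix(sample(c(0, 2), 2 * k * 3, replace = TRUE), 2 * k, 3)
  G <- cbind(G1[rep(seq_len(2 * k), each = 2), ],
             rep(c(0, 2), 2 * k), rep(c(0, 2), 2 * k))
  dimnames(G) <- list(fam$lines$line, map$marker)
  geno <- dh_geno(G, map, fam)
  yv <- G1[rep(seq_len(2 * k), each = 2), 2] * 0.5 +
    rep(stats::rnorm(2 * k), each = 2)
  y <- line_values(data.frame(line = fam$lines$line, value = yv))
  cfg <- fast_cfg(scan_step = 5)
  s0 <- genome_scan(y, geno, character(), cfg)
  s1 <- genome_scan(y, geno, "c1", cfg)
  on1A <- s0$chrom == "1A"
  expect_lt(max(abs(s0$lod[on1A] - s1$lod[on1A])), 1e-6)
})

test_that("permutation thresholds have the stated quantile behaviour", {
  st <- null_study(47, n_per_fam = 20, n_markers = 5)
  cfg1 <- mcqtl_config(n_permutations = 100, alpha = 0.999999,
                       scan_step = 5)
  thr_min <- permutation_threshold(st$y, st$geno, character(), cfg1,
                                   seed = 3)
  expect_equal(as.numeric(thr_min), min(attr(thr_min, "max_lods")))
  # doubling the phenotype leaves the threshold unchanged (LOD is
  # scale-equivariant and the permutations share the seed)
  cfg2 <- mcqtl_config(n_permutations = 100, alpha = 0.1, scan_step = 5)
  t1 <- permutation_threshold(st$y, st$geno, character(), cfg2, seed = 5)
  y2 <- line_values(data.frame(line = st$y$line, value = 2 * st$y$value))
  t2 <- permutation_threshold(y2, st$geno, character(), cfg2, seed = 5)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-10)
  expect_error(permutation_threshold(st$y, st$geno, character(),
                                     mcqtl_config(n_permutations = 50),
                                     seed = 1),
               "100 permutations")
})

test_that("permuted phenotypes behave like exchangeable null draws", {
  st <- null_study(53, n_per_fam = 25, n_markers = 6)
  cfg <- fast_cfg(scan_step = 5)
  fl <- family_of(st$fam)
  n <- nrow(st$geno$geno)
  set.seed(11)
  Yfresh <- matrix(stats::rnorm(n * 100), n)
  y0 <- stats::rnorm(n)
  idx <- mcqtl:::perm_within_family(fl, 100)
  Yperm <- matrix(y0[idx], n)
  mfresh <- apply(mcqtl:::scan_core(Yfresh, st$geno, character(),
                                    cfg)$lod, 2, max)
  mperm <- apply(mcqtl:::scan_core(Yperm, st$geno, character(),
                                   cfg)$lod, 2, max)
  expect_gt(suppressWarnings(stats::ks.test(mfresh, mperm)$p.value), 0.01)
})

test_that("peak LOD grows with the simulated effect size", {
  med <- vapply(c(0.1, 0.2, 0.35), function(pg) {
    stats::median(vapply(1:10, function(s) {
      st <- single_qtl_study(400 + s, pg = pg, n_per_fam = 30,
                             n_markers = 5)
      max(genome_scan(st$y, st$geno, character(),
                      fast_cfg(scan_step = 5))$lod)
    }, 0))
  }, 0)
  expect_true(all(diff(med) > 0))
})

test_that("support intervals follow the LOD fall-off geometry", {
  mk_scan <- function(lod, pos = seq_along(lod) - 1, chrom = "1A") {
    structure(data.frame(chrom = chrom, pos = pos, lod = lod),
              effects = matrix(NA_real_, length(lod), 1,
                               dimnames = list(NULL, "F1")),
              families = "F1", cofactors = character(),
              cfg = mcqtl_config(),
              class = c("mcqtl_scan", "data.frame"))
  }
  # triangular peak: LOD 6 at 50 cM, slope 0.5/cM -> interval [48, 52]
  tri <- mk_scan(pmax(0, 6 - 0.5 * abs(0:100 - 50)))
  q <- identify_qtl(tri, threshold = 4, cfg = mcqtl_config())
  expect_equal(nrow(q), 1)
  expect_equal(q$pos, 50)
  expect_equal(c(q$si_lo, q$si_hi), c(48, 52))
  # flat profile below threshold: nothing
  expect_equal(nrow(identify_qtl(mk_scan(rep(1, 101)), 4,
                                 mcqtl_config())), 0)
  # two separated peaks with disjoint intervals: two QTL
  two <- mk_scan(pmax(0, 6 - 0.5 * abs(0:100 - 30)) +
                   pmax(0, 7 - 0.5 * abs(0:100 - 70)))
  q2 <- identify_qtl(two, threshold = 4, cfg = mcqtl_config())
  expect_equal(q2$pos, c(30, 70))
  # overlapping support intervals merge, keeping the higher peak
  close2 <- mk_scan(pmax(0, 6 - 0.2 * abs(0:100 - 45)) +
                      pmax(0, 6.5 - 0.2 * abs(0:100 - 55)))
  q3 <- identify_qtl(close2, threshold = 4, cfg = mcqtl_config())
  expect_equal(nrow(q3), 1)
})

test_that("pG estimation saturates and vanishes at the extremes", {
  st <- single_qtl_study(61, pg = 0.25)
  cnt <- st$geno$geno[, st$map$marker[st$map$chrom == "1A" &
                                        abs(st$map$pos - st$qtl_pos) < 1e-9]]
  y <- line_values(data.frame(line = rownames(st$geno$geno),
                              value = cnt * st$effect))
  q <- structure(data.frame(chrom = "1A", genome = "A", pos = st$qtl_pos,
                            si_lo = 50, si_hi = 55, lod = 50),
                 class = c("qtl_table", "data.frame"))
  q <- estimate_pg(q, y, st$geno, h2 = 1)
  expect_equal(attr(q, "pg_total"), 100, tolerance = 1e-6)
  expect_equal(q$pg, 100, tolerance = 1e-6)
  # empty QTL list: zero
  q0 <- q[0, 1:6]
  class(q0) <- c("qtl_table", "data.frame")
  q0 <- estimate_pg(q0, y, st$geno, h2 = 1)
  expect_equal(attr(q0, "pg_total"), 0)
})
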
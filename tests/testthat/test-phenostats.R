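test_that("adjusted means reduce to raw values in a balanced 1-rep trial", {
  d <- data.frame(line_id = c("l1", "l2", "l3"), location = "loc1",
                  replicate = 1, value = c(4, 5, 7))
  lv <- compute_line_means(d)
  expect_equal(stats::setNames(lv$value, lv$line),
               c(l1 = 4, l2 = 5, l3 = 7))
})

test_that("adjusted means are invariant to location-wise constants", {
  st <- simulate_triticale(seed = 31, chrom_per_genome = 1, n_markers = 5,
                           n_lines = c(DH06 = 20, DH07 = 20, EAW74 = 20,
                                       EAW78 = 20),
                           with_trials = TRUE)
  plots <- st$trial_wh$plots
  lv1 <- compute_line_means(plots, st$fam)
  plots$value[plots$location == "loc1"] <-
    plots$value[plots$location == "loc1"] + 100
  lv2 <- compute_line_means(plots, st$fam)
  d1 <- lv1$value - mean(lv1$value)
  d2 <- lv2$value - mean(lv2$value)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("noiseless trials return the true genetic values exactly", {
  st <- simulate_triticale(seed = 32, chrom_per_genome = 1, n_markers = 5,
                           n_lines = c(DH06 = 15, DH07 = 15, EAW74 = 15,
                                       EAW78 = 15))
  spec0 <- trait_sim_spec(var_g = 3, var_gxl = 0, var_e = 0,
                          n_locations = 2, mean = 3.9)
  tr <- simulate_trial(st$geno, st$qtl_wh, spec0, seed = 1,
                       genetic = st$genetic_wh)
  lv <- compute_line_means(tr, st$fam)
  g <- st$genetic_wh$g[lv$line]
  expect_equal(lv$value - mean(lv$value), unname(g - mean(g)),
               tolerance = 1e-8)
})

test_that("checks are used for adjustment but excluded from line values", {
  d <- data.frame(line_id = c("l1", "l2", "CHK", "CHK"),
                  location = "loc1", replicate = c(1, 1, 1, 2),
                  value = c(4, 5, 6, 8))
  fam <- dh_families(data.frame(line = c("l1", "l2"), family = "F1"))
  lv <- compute_line_means(d, fam)
  expect_setequal(lv$line, c("l1", "l2"))
  expect_error(compute_line_means(
    d[d$line_id != "l2", , drop = FALSE], fam), "no observation")
})

test_that("variance components recover simulation truth at study scale", {
  est <- sapply(1:10, function(s) {
    st <- simulate_triticale(seed = 100 + s, n_markers = 10,
                             with_trials = TRUE)
    vc <- estimate_vc(st$trial_wh)
    c(vc$var_g, vc$var_gxl, vc$var_e)
  })
  med <- apply(est, 1, stats::median)
  truth <- c(3.00, 0.33, 0.81)
  expect_true(all(abs(med - truth) / truth < 0.15))
})

test_that("degenerate variance components behave", {
  d <- data.frame(line_id = rep(c("l1", "l2", "l3"), each = 2),
                  location = rep(c("loc1", "loc2"), 3),
                  replicate = 1, value = 2)
  vc <- estimate_vc(d)
  expect_equal(vc$var_g, 0)                 # identical lines, truncated
  expect_error(estimate_vc(d[d$line_id == "l1", , drop = FALSE]),
               "2 lines")
  expect_equal(heritability(1, 0, 0, n_locations = 2), 1)
  expect_true(is.na(estimate_vc(
    data.frame(line_id = c("l1", "l2"), location = "loc1",
               replicate = 1, value = c(1, 2)))$var_gxl))
})

test_that("moment estimators are unbiased on balanced designs", {
  # 200 small balanced trials: 30 lines x 2 locations x 2 reps
  truth <- c(var_g = 2, var_gxl = 0.5, var_e = 1)
  n <- 30; L <- 2; r <- 2
  est <- matrix(0, 200, 3)
  set.seed(99)
  for (b in 1:200) {
    g <- stats::rnorm(n, 0, sqrt(truth["var_g"]))
    gl <- matrix(stats::rnorm(n * L, 0, sqrt(truth["var_gxl"])), n, L)
    d <- expand.grid(line_id = sprintf("l%02d", 1:n),
                     location = c("loc1", "loc2"), replicate = 1:r,
                     stringsAsFactors = FALSE)
    i <- match(d$line_id, sprintf("l%02d", 1:n))
    l <- match(d$location, c("loc1", "loc2"))
    d$value <- g[i] + gl[cbind(i, l)] +
      stats::rnorm(nrow(d), 0, sqrt(truth["var_e"]))
    vc <- estimate_vc(d)
    est[b, ] <- c(vc$var_g, vc$var_gxl, vc$var_e)
  }
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth) < 3 * se))
})

test_that("heritability is monotone in the variance components", {
  h <- function(vg, ve) heritability(vg, 0.3, ve, 2, 1.3)
  expect_true(all(diff(sapply(c(1, 2, 4, 8), h, ve = 1)) > 0))
  expect_true(all(diff(sapply(c(0.5, 1, 2, 4), function(ve)
    h(2, ve))) < 0))
})

test_that("phenotypic correlation handles identities and degeneracies", {
  a <- line_values(data.frame(line = sprintf("l%d", 1:10),
                              value = stats::rnorm(10)))
  b <- line_values(data.frame(line = a$line, value = -a$value))
  expect_equal(pheno_correlation(a, a)$r, 1)
  expect_equal(pheno_correlation(a, b)$r, -1)
  const <- line_values(data.frame(line = a$line, value = 1))
  expect_error(pheno_correlation(a, const), "zero variance")
  expect_error(pheno_correlation(a[1:2, ], a[1:2, ]), "3 common lines")
})
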
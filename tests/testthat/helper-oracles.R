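# independent oracles, kept deliberately brute-force

# enumeration over the 8 possible DH haplotypes (left, q, right), each
# locus carrying the reference allele (1) or not (0); transitions follow
# Haldane recombination fractions
enum_expected_count <- function(left_geno, right_geno, d_left, d_right) {
  r1 <- (1 - exp(-2 * d_left / 100)) / 2
  r2 <- (1 - exp(-2 * d_right / 100)) / 2
  trans <- function(a, b, r) ifelse(a == b, 1 - r, r)
  num <- 0; den <- 0
  for (x in 0:1) for (q in 0:1) for (z in 0:1) {
    pr <- 0.5 * trans(x, q, r1) * trans(q, z, r2)
    ok <- (is.na(left_geno) || x == left_geno / 2) &&
      (is.na(right_geno) || z == right_geno / 2)
    if (!ok) next
    den <- den + pr
    if (q == 1) num <- num + pr
  }
  2 * num / den
}

# LOD from explicit Gaussian profile log-likelihoods
gaussian_lod <- function(rss0, rss1, n) {
  ll <- function(rss) -n / 2 * (log(2 * pi * rss / n) + 1)
  2 * (ll(rss1) - ll(rss0)) / (2 * log(10))
}
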
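#' Run configuration for the mapping pipeline
#'
#' Bundles the tunable parameters of the genome scan and downstream steps.
#' Defaults follow the study design this package targets: 2000 permutations
#' at an experiment-wise alpha of 0.10, a support-interval LOD fall-off of
#' 1.0, 10 cM cofactor-exclusion and QTL-overlap windows, a 10% cutoff for
#' "major" QTL, epistasis alpha 0.05 Bonferroni-corrected assuming two
#' independent regions per chromosome.
#'
#' @param scan_step grid step of the 1-D scan, cM.
#' @param n_permutations permutations for the genome-wide threshold.
#' @param alpha experiment-wise type I error of the threshold.
#' @param lod_falloff LOD drop defining the support interval.
#' @param cofactor_window cM; cofactors closer than this to the tested
#'   marker interval are excluded from both models at that position.
#' @param overlap_window cM; gap tolerance when declaring QTL of two traits
#'   overlapping.
#' @param major_pg_cutoff percent of genotypic variance above which a QTL is
#'   called major (strict inequality).
#' @param epistasis_alpha nominal alpha of the two-locus scan before
#'   region-pair Bonferroni correction.
#' @param regions_per_chromosome assumed independent regions per chromosome
#'   for that correction.
#' @param min_pair_distance cM; minimum intra-chromosome separation of the
#'   locus pairs tested for epistasis.
#' @param max_cofactors cap on forward-selected cofactors.
#' @param seed integer seed recorded with the run (optional).
#' @return list of class \code{"mcqtl_config"}.
#' @export
mcqtl_config <- function(scan_step = 1, n_permutations = 2000, alpha = 0.10,
                         lod_falloff = 1.0, cofactor_window = 10,
                         overlap_window = 10, major_pg_cutoff = 10,
                         epistasis_alpha = 0.05, regions_per_chromosome = 2,
                         min_pair_distance = 20, max_cofactors = 20,
                         seed = NULL) {
  cfg <- list(scan_step = scan_step, n_permutations = n_permutations,
              alpha = alpha, lod_falloff = lod_falloff,
              cofactor_window = cofactor_window,
              overlap_window = overlap_window,
              major_pg_cutoff = major_pg_cutoff,
              epistasis_alpha = epistasis_alpha,
              regions_per_chromosome = regions_per_chromosome,
              min_pair_distance = min_pair_distance,
              max_cofactors = max_cofactors, seed = seed)
  num <- setdiff(names(cfg), "seed")
  for (k in num) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config field '", k, "' must be a positive number")
  }
  if (cfg$alpha >= 1 || cfg$epistasis_alpha >= 1)
    stop("alpha and epistasis_alpha must lie in (0,1)")
  class(cfg) <- "mcqtl_config"
  cfg
}

#' @export
print.mcqtl_config <- function(x, ...) {
  cat("mcqtl run configuration:\n")
  for (k in names(x)) if (!is.null(x[[k]]))
    cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read / write a run configuration as a flat key=value text file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path file path.
#' @export
read_config <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("config lines must be key=value")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  known <- names(formals(mcqtl_config))
  if (any(!keys %in% known))
    stop("unknown config key(s): ", paste(setdiff(keys, known), collapse = ", "))
  args <- lapply(vals, function(v) as.numeric(v))
  names(args) <- keys
  do.call(mcqtl_config, args)
}

#' @rdname read_config
#' @param cfg an \code{mcqtl_config}.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mcqtl_config"))
  keep <- !vapply(cfg, is.null, TRUE)
  writeLines(sprintf("%s=%s", names(cfg)[keep],
                     vapply(cfg[keep], format, "")), path)
  invisible(path)
}
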
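#' Example QTL tables for two winter-stress traits
#'
#' Two ready-made QTL result tables for a four-family triticale DH
#' population scored for winter hardiness and frost tolerance: per QTL the
#' chromosome, peak position with its LOD fall-off support interval (cM),
#' and the proportion of genotypic variance explained overall and within
#' each family (percent). They exercise the reporting rules
#' (\code{\link{classify_major}}, \code{\link{find_overlaps}},
#' \code{\link{genome_summary}}) on realistic numbers: each trait has nine
#' QTL, three of them major, with six QTL shared between the traits.
#'
#' @param trait \code{"winter_hardiness"} or \code{"frost_tolerance"}.
#' @return a \code{qtl_table}.
#' @examples
#' wh <- example_qtl_table("winter_hardiness")
#' ft <- example_qtl_table("frost_tolerance")
#' classify_major(wh)
#' find_overlaps(wh, ft)
#' genome_summary(wh)
#' @export
example_qtl_table <- function(trait = c("winter_hardiness",
                                        "frost_tolerance")) {
  trait <- match.arg(trait)
  path <- system.file("extdata", paste0("qtl_", trait, ".csv"),
                      package = "mcqtl", mustWork = TRUE)
  d <- read_qtl_table(path)
  d$genome <- parse_genome(d$chrom)
  d[, c("chrom", "genome", setdiff(names(d), c("chrom", "genome")))]
}
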
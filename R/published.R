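#' Published SCDC surveillance counts
#'
#' The confirmed/probable case counts by data source published by the Sickle
#' Cell Data Collection programs of California and Georgia (cumulative
#' 2004-2018 and annual 2018), together with the totals and
#' percentage-of-deduplicated-total cells as printed. The component counts
#' serve as inputs for checking that [prevalence_arithmetic()] reproduces the
#' printed derived cells under the package's rounding rules.
#'
#' @return Tibble with columns `state`, `period`, `source`, `confirmed`,
#'   `probable`, `published_total`, `published_pct`.
#' @examples
#' counts <- published_prevalence_counts()
#' ca <- subset(counts, state == "California" & period == "2004-2018")
#' prevalence_arithmetic(ca)
#' @export
published_prevalence_counts <- function() {
  path <- system.file("extdata", "published_counts.tsv",
                      package = "scdlink", mustWork = TRUE)
  readr::read_tsv(path, col_types = "cccnnnn", progress = FALSE)
}
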
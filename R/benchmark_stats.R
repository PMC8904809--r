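#' Benchmark dataset statistics
#'
#' Entity and positive-association counts of the curated public DTI
#' benchmark (707 drugs, 1489 proteins, 4192 side effects, 5603
#' diseases) that fixes the feature-vector dimensions at full scale.
#' Shipped with the package so summary quantities can be derived without
#' downloading the dataset itself.
#'
#' @return A named numeric vector of counts.
#' @export
benchmark_counts <- function() {
  path <- system.file("extdata", "benchmark_counts.tsv", package = "hetdti")
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$value), df$stat)
}

#' Summary statistics derived from the benchmark counts
#'
#' Currently: the mean number of positive interactions per drug (the
#' quantity that motivates giving zero-positive drugs three sampled
#' negatives) and the per-matrix densities.
#'
#' @param counts named vector from [benchmark_counts()].
#' @return A list with `mean_positives_per_drug` and `density` (named
#'   vector over the six association matrices).
#' @export
benchmark_summary <- function(counts = benchmark_counts()) {
  nd <- counts[["n_drugs"]]; np <- counts[["n_proteins"]]
  density <- c(
    DTI = counts[["dti_positives"]] / (nd * np),
    DDI = counts[["ddi_positives"]] / (nd * nd),
    DSIE = counts[["dsie_positives"]] / (nd * counts[["n_side_effects"]]),
    DDIS = counts[["ddis_positives"]] / (nd * counts[["n_diseases"]]),
    PPI = counts[["ppi_positives"]] / (np * np),
    PDIS = counts[["pdis_positives"]] / (np * counts[["n_diseases"]])
  )
  list(mean_positives_per_drug = counts[["dti_positives"]] / nd,
       density = density)
}
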
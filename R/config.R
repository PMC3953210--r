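#' Pipeline configuration
#'
#' Validated bundle of the knobs the caller exposes. Unknown keys are
#' rejected.
#'
#' @param orientation concordant mate-pair orientation convention, `"RF"`
#'   (default) or `"FR"`; must match the library preparation.
#' @param min_support minimum read pairs per retained cluster (default 6).
#' @param cutoff linking/distance cutoff in bp, or `NULL` (`"auto"`) to use
#'   2 x the estimated median insert.
#' @param mapq_threshold minimum per-read mapping quality (default 20).
#' @param read_length read length in bp (default 36).
#' @param nominal_insert kit-nominal insert size in bp; only used to bound
#'   the spans admitted into insert-size estimation (default 5000).
#' @param median_insert optional fixed median insert, bypassing estimation.
#' @param min_reciprocal_overlap reciprocal-overlap threshold used when
#'   matching two call sets (default 0.5).
#' @param seed integer seed for any stochastic step.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(orientation = c("RF", "FR"), min_support = 6L,
                            cutoff = NULL, mapq_threshold = 20,
                            read_length = 36L, nominal_insert = 5000,
                            median_insert = NULL,
                            min_reciprocal_overlap = 0.5, seed = 1L) {
  orientation <- match.arg(orientation)
  if (!is.null(cutoff) && identical(cutoff, "auto")) cutoff <- NULL
  num_pos <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || x <= 0)
      stopf("%s must be a positive number", what)
    x
  }
  num_pos(min_support, "min_support")
  num_pos(mapq_threshold, "mapq_threshold")
  num_pos(read_length, "read_length")
  num_pos(nominal_insert, "nominal_insert")
  if (!is.null(cutoff)) num_pos(cutoff, "cutoff")
  if (!is.null(median_insert)) num_pos(median_insert, "median_insert")
  if (min_reciprocal_overlap <= 0 || min_reciprocal_overlap > 1)
    stopf("min_reciprocal_overlap must lie in (0, 1]")
  structure(list(orientation = orientation,
                 min_support = as.integer(min_support),
                 cutoff = cutoff, mapq_threshold = mapq_threshold,
                 read_length = as.integer(read_length),
                 nominal_insert = nominal_insert,
                 median_insert = median_insert,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected with an error naming them.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
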
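#' Relative expression from qPCR threshold cycles (delta-delta CT)
#'
#' Converts threshold cycles to dimensionless fold change relative to a
#' calibrator: `2^-ddCT` with `ddCT = (marker_ct - normalizer_ct) -
#' reference_dct`, where `reference_dct` is the calibrator's delta-CT.
#' Constant offsets (e.g. fixed preamplification cycles) cancel in the
#' double difference and, downstream, in MoM normalization. Missing cycles
#' give `NA` (treated as below detection), not an error.
#'
#' @param marker_ct,normalizer_ct Threshold cycles of the marker and the
#'   normalization gene run in the same reaction.
#' @param reference_dct Calibrator delta-CT (marker minus normalizer in the
#'   reference sample), in cycles.
#' @return Strictly positive fold change, or `NA` where any cycle is missing.
#' @export
#' @examples
#' delta_delta_ct(24, 20, 5)  # ddCT = -1 -> fold change 2
delta_delta_ct <- function(marker_ct, normalizer_ct, reference_dct) {
  ddct <- (marker_ct - normalizer_ct) - reference_dct
  2^(-ddct)
}

#' Flag qPCR measurements below the detection limit
#'
#' A measurement is below detection when its threshold cycle is missing or
#' reaches `max_ct`. The cutoff is a convention of the qPCR instrument (the
#' default 40 is the usual cycle ceiling), configurable per assay.
#'
#' @param marker_ct Threshold cycles (may contain `NA`).
#' @param max_ct Detection cutoff in cycles (default 40).
#' @return Logical vector, `TRUE` where below detection.
#' @export
#' @examples
#' flag_below_detection(c(30, 46, NA))
flag_below_detection <- function(marker_ct, max_ct = 40) {
  is.na(marker_ct) | marker_ct >= max_ct
}

#' Fill expression columns of a cohort table from CT-mode columns
#'
#' For each marker with companion columns `<marker>_ct`, `normalizer_ct` and
#' `reference_dct` present in `data`, computes relative expression by
#' [delta_delta_ct()], writes it into the marker column, and sets
#' `<marker>_below_detection` by [flag_below_detection()]. Markers without
#' CT columns are left untouched, so expression-mode and CT-mode inputs share
#' one schema.
#'
#' @param data Cohort tibble, possibly with CT-mode columns.
#' @param markers Markers to consider (default the RNA panel).
#' @inheritParams flag_below_detection
#' @return The tibble with expression and detection-flag columns filled.
#' @export
preprocess_ct <- function(data, markers = rna_markers(), max_ct = 40) {
  for (m in markers) {
    ct_col <- paste0(m, "_ct")
    if (!ct_col %in% names(data)) next
    if (!all(c("normalizer_ct", "reference_dct") %in% names(data))) {
      abort("CT-mode input needs `normalizer_ct` and `reference_dct` columns.")
    }
    below <- flag_below_detection(data[[ct_col]], max_ct)
    expr <- delta_delta_ct(data[[ct_col]], data$normalizer_ct,
                           data$reference_dct)
    expr[below] <- NA_real_
    data[[m]] <- expr
    data[[paste0(m, "_below_detection")]] <- below
  }
  data
}
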
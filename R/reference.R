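# Published treatment-mean summaries of the reference saline-irrigation
# trial (means over 2 years per tillage/irrigation/mulch level, with SE_m
# rows), shipped as package data so the headline treatment contrasts can be
# recomputed without the unpublished plot-level data.

#' Reference trial treatment means
#'
#' Loads the shipped per-level treatment means of the reference trial
#' (pH_s, EC_e, WBOC, KMnO4-N, Olsen's P, NH4OAc-K; means over 2 years per
#' tillage, irrigation and mulch level, plus `SE_m` rows). These summary
#' means anchor the synthetic generator's defaults and feed the headline
#' treatment contrasts via [mean_difference()] and [percent_change()].
#'
#' @param season Optional filter, `"sorghum"` or `"wheat"`.
#' @param drop_se Drop the `SE_m` rows (default `TRUE`).
#' @return Data frame with `season`, `factor`, `level` and the six
#'   attribute columns.
#' @export
reference_treatment_means <- function(season = NULL, drop_se = TRUE) {
  path <- system.file("extdata", "reference_treatment_means.csv",
                      package = "soilhealth", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(season)) {
    season <- match.arg(season, design_levels()$season)
    df <- df[df$season == season, , drop = FALSE]
  }
  if (drop_se) df <- df[df$level != "SE_m", , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Look up one reference mean
#'
#' @param season,factor_name,level Row selector.
#' @param response Attribute column.
#' @return Single numeric mean.
#' @export
reference_mean <- function(season, factor_name, level, response) {
  df <- reference_treatment_means(season)
  row <- df[df$factor == factor_name & df$level == level, , drop = FALSE]
  if (nrow(row) != 1L || !response %in% names(row)) {
    stop("no reference mean for ", season, "/", factor_name, "/", level,
         "/", response, call. = FALSE)
  }
  row[[response]]
}
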
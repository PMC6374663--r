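#' Interpolate soil nutrient values at tree locations
#'
#' Nutrient availability at each location is the inverse-distance-weighted
#' (power 1) average of the `k` nearest soil sample points in the same plot.
#' A location coincident with a sample point returns that sample's values
#' exactly. If a plot holds fewer than `k` samples, all available samples
#' are used with a warning.
#'
#' @param soil data frame following the soil schema.
#' @param locations data frame with columns `plot_id`, `x_m`, `y_m`.
#' @param k number of nearest samples averaged (default 5).
#' @param power inverse-distance power (default 1).
#' @return data frame, one row per location, with interpolated nutrient
#'   columns (`no3_i`, `nh4_i`, `no3_f`, `nh4_f`, `p`, `k`, `ca`, `mg`).
#' @export
interpolate_soil <- function(soil, locations, k = 5, power = 1) {
  nutr <- c("no3_i", "nh4_i", "no3_f", "nh4_f", "p", "k", "ca", "mg")
  out <- matrix(NA_real_, nrow(locations), length(nutr),
                dimnames = list(NULL, nutr))
  warned <- FALSE
  for (pl in unique(locations$plot_id)) {
    li <- which(locations$plot_id == pl)
    si <- which(soil$plot_id == pl)
    if (!length(si)) stopf("no soil samples in plot %s", pl)
    kk <- min(k, length(si))
    if (kk < k && !warned) {
      warnf("plot %s has only %d soil samples; using all of them", pl, length(si))
      warned <- TRUE
    }
    sv <- as.matrix(soil[si, nutr])
    sx <- soil$x_m[si]; sy <- soil$y_m[si]
    for (i in li) {
      d2 <- (sx - locations$x_m[i])^2 + (sy - locations$y_m[i])^2
      nn <- order(d2)[seq_len(kk)]
      d <- sqrt(d2[nn])
      if (d[1] == 0) {
        out[i, ] <- sv[nn[1], ]
      } else {
        w <- 1 / d^power
        out[i, ] <- colSums(sv[nn, , drop = FALSE] * w) / sum(w)
      }
    }
  }
  cbind(locations[c("plot_id", "x_m", "y_m")], as.data.frame(out))
}

#' Derive the model soil covariates: NMin, P, SBC
#'
#' Potential nitrogen mineralization (NMin) is the 30-day incubation change
#' in extractable nitrate plus ammonium; it represents nitrogen availability
#' over time better than either single measurement. Potassium, calcium and
#' magnesium strongly covary and are combined into the sum of base cation
#' availability (SBC). Phosphorus passes through unchanged. Rows with
#' missing constituents are flagged via the `"incomplete"` attribute and
#' carry `NA` covariates.
#'
#' @param values data frame holding the nutrient columns (raw samples or
#'   [interpolate_soil()] output).
#' @return data frame with columns `nmin`, `p`, `sbc` (other columns of
#'   `values` preserved).
#' @examples
#' derive_soil_covariates(data.frame(no3_i = 2, nh4_i = 3, no3_f = 5,
#'                                   nh4_f = 6, p = 1, k = 1, ca = 2, mg = 3))
#' @export
derive_soil_covariates <- function(values) {
  need <- c("no3_i", "nh4_i", "no3_f", "nh4_f", "p", "k", "ca", "mg")
  missing <- setdiff(need, names(values))
  if (length(missing)) stopf("missing nutrient column(s): %s",
                             paste(missing, collapse = ", "))
  nmin <- (values$no3_f + values$nh4_f) - (values$no3_i + values$nh4_i)
  sbc <- values$k + values$ca + values$mg
  out <- values
  out$nmin <- nmin
  out$sbc <- sbc
  incomplete <- !complete.cases(values[need])
  attr(out, "incomplete") <- which(incomplete)
  out
}
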
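# Subpopulation-ratio estimation for dual-fluorophore cocultures: per-strain
# calibration curves (fluorescence vs OD), linear unmixing of the two
# channel intensities into per-strain OD estimates, proportion trajectories,
# and stability comparison across serial passages.

#' Fit a fluorescence-vs-OD calibration curve
#'
#' Ordinary least squares line `intensity = slope * OD + background` fit to
#' a monoculture dilution series (the screen used ODs 0.95, 0.90, 0.80,
#' 0.66, 0.5, 0.33, 0.20, 0.10, 0.05).
#'
#' @param dilution_ods Numeric ODs (at least 2 distinct values).
#' @param intensities Matching fluorescence intensities.
#' @param strain_id Strain label.
#' @param channel `"blue"` or `"red"`.
#' @return list of class `calibration_curve`: `strain_id`, `channel`,
#'   `slope`, `background`, `fit_r2`, `n_points`.
#' @export
fit_calibration <- function(dilution_ods, intensities, strain_id, channel) {
  if (length(dilution_ods) < 2L || length(unique(dilution_ods)) < 2L) {
    stop("calibration needs at least 2 distinct OD points")
  }
  if (length(dilution_ods) != length(intensities)) {
    stop("dilution_ods and intensities must have equal length")
  }
  if (!channel %in% c("blue", "red")) stop("channel must be blue or red")
  fit <- stats::lm(intensities ~ dilution_ods)
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((intensities - mean(intensities))^2)
  structure(list(
    strain_id = strain_id, channel = channel,
    slope = unname(stats::coef(fit)[2]),
    background = unname(stats::coef(fit)[1]),
    fit_r2 = if (tss > 0) 1 - rss / tss else NA_real_,
    n_points = length(dilution_ods)
  ), class = "calibration_curve")
}

# Build the 2x2 slope matrix A (rows: channels blue/red; cols: strains
# blue-tagged/red-tagged) and per-channel backgrounds from a list of
# calibration curves. Cross-channel slopes absent from the list are 0
# (the screen's two channels, ex400/em465 and ex560/em620, are well
# separated).
.calibration_system <- function(curves, strain_blue, strain_red) {
  A <- matrix(0, 2, 2, dimnames = list(c("blue", "red"),
                                       c(strain_blue, strain_red)))
  bg <- c(blue = 0, red = 0)
  for (cv in curves) {
    s <- match(cv$strain_id, c(strain_blue, strain_red))
    ch <- match(cv$channel, c("blue", "red"))
    if (is.na(s) || is.na(ch)) next
    A[ch, s] <- cv$slope
    if (s == ch) bg[ch] <- cv$background  # own-channel fit carries background
  }
  list(A = A, bg = bg)
}

#' Unmix two-channel fluorescence into per-strain OD estimates
#'
#' Solves the linear system `A od = F - background` where `A` holds the
#' calibration slopes (own-channel, plus any measured cross-channel
#' slopes). Negative components are clipped to 0 with a flag; the blue
#' proportion is `od_blue / (od_blue + od_red)` where the sum is positive,
#' missing otherwise.
#'
#' @param F_blue,F_red Numeric vectors of channel intensities.
#' @param curves List of [fit_calibration()] objects (the two own-channel
#'   curves at minimum; cross-channel curves optional).
#' @param strain_blue,strain_red Strain ids carrying the blue/red tag;
#'   default to the strains of the own-channel curves.
#' @return data.frame: `od_blue`, `od_red`, `proportion_blue`, `clipped`.
#' @export
unmix <- function(F_blue, F_red, curves,
                  strain_blue = NULL, strain_red = NULL) {
  if (is.null(strain_blue)) {
    strain_blue <- Find(function(cv) cv$channel == "blue", curves)$strain_id
  }
  if (is.null(strain_red)) {
    strain_red <- Find(function(cv) cv$channel == "red", curves)$strain_id
  }
  sys <- .calibration_system(curves, strain_blue, strain_red)
  d <- svd(sys$A)$d
  kap <- if (d[2] > 0) d[1] / d[2] else Inf
  if (!is.finite(kap) || kap > 1e12) {
    stop("singular calibration matrix (condition number ", format(kap), ")")
  }
  rhs <- rbind(F_blue - sys$bg["blue"], F_red - sys$bg["red"])
  od <- solve(sys$A, rhs)
  clipped <- od[1, ] < 0 | od[2, ] < 0
  od <- pmax(od, 0)
  total <- od[1, ] + od[2, ]
  data.frame(
    od_blue = od[1, ], od_red = od[2, ],
    proportion_blue = ifelse(total > 0, od[1, ] / total, NA_real_),
    clipped = clipped
  )
}

#' Proportion trajectory of a two-strain coculture
#'
#' Per-timepoint unmixing of a dual-channel fluorescence time series.
#' Inoculation-ratio metadata (the characterization series used 1:20, 1:10,
#' 1:5, 1:2, 1:1, 2:1, 5:1, 10:1, 20:1 at total inoculum OD 0.10) is
#' carried as an attribute for reporting.
#'
#' @param times Hours; shared grid of both channels.
#' @param F_blue,F_red Channel intensity series, same length as `times`.
#' @param curves Calibration curves, as for [unmix()].
#' @param inoculation_ratio Optional numeric pair, e.g. `c(1, 20)`.
#' @return data.frame: `time`, `F_blue`, `F_red`, `od_blue`, `od_red`,
#'   `proportion_blue`, `clipped`; attribute `inoculation_ratio`.
#' @export
proportion_trajectory <- function(times, F_blue, F_red, curves,
                                  inoculation_ratio = NULL) {
  if (length(times) != length(F_blue) || length(times) != length(F_red)) {
    stop("channel series must share one time grid")
  }
  u <- unmix(F_blue, F_red, curves)
  out <- data.frame(time = times, F_blue = F_blue, F_red = F_red,
                    od_blue = u$od_blue, od_red = u$od_red,
                    proportion_blue = u$proportion_blue, clipped = u$clipped)
  attr(out, "inoculation_ratio") <- inoculation_ratio
  out
}

#' Compare subpopulation trajectories across serial passages
#'
#' Quantifies whether a community re-establishes its composition after
#' dilution into fresh medium: `final_delta` is the absolute difference in
#' final blue proportion between the two passages; `trend_corr` is the
#' Pearson correlation of the two trajectories on their common
#' relative-time grid (pass 2 linearly interpolated onto pass 1 times).
#' The community is classified re-established when
#' `final_delta <= stability_tolerance`.
#'
#' @param pass1,pass2 Trajectories from [proportion_trajectory()] (columns
#'   `time` and `proportion_blue`), time measured since each inoculation.
#' @param stability_tolerance Re-establishment tolerance on the final
#'   proportion. Default 0.15.
#' @return list: `final_delta`, `trend_corr` (NA with fewer than 3 common
#'   timepoints), `re_established`.
#' @export
stability_compare <- function(pass1, pass2, stability_tolerance = 0.15) {
  p1 <- pass1[!is.na(pass1$proportion_blue), ]
  p2 <- pass2[!is.na(pass2$proportion_blue), ]
  if (!nrow(p1) || !nrow(p2)) stop("both passes need proportion values")
  final_delta <- abs(p1$proportion_blue[nrow(p1)] - p2$proportion_blue[nrow(p2)])
  lo <- max(min(p1$time), min(p2$time))
  hi <- min(max(p1$time), max(p2$time))
  grid <- p1$time[p1$time >= lo & p1$time <= hi]
  trend_corr <- NA_real_
  if (length(grid) >= 3L && nrow(p2) >= 2L) {
    y1 <- p1$proportion_blue[p1$time %in% grid]
    y2 <- stats::approx(p2$time, p2$proportion_blue, xout = grid)$y
    if (stats::sd(y1) > 0 && stats::sd(y2) > 0) {
      trend_corr <- stats::cor(y1, y2)
    }
  }
  list(final_delta = final_delta, trend_corr = trend_corr,
       re_established = final_delta <= stability_tolerance)
}
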
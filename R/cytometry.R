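# Peak extraction from binned fluorescence histograms, sample/standard
# ratios, reference-based DNA ploidy calling, and the peak index.

#' Extract Gaussian peaks from a binned fluorescence histogram
#'
#' Peaks are located on a moving-average-smoothed copy of the histogram as
#' local maxima, then each is refined by a least-squares Gaussian fit to the
#' bins within two initial widths of the candidate mode. Peaks supported by
#' fewer than `min_events` events or broader than `max_cv` are discarded.
#'
#' @param hist A data frame with columns `channel` (strictly increasing
#'   positive bin centres, fluorescence units) and `count` (non-negative
#'   events per bin).
#' @param min_events Minimum number of events under a peak for it to be kept.
#' @param max_cv Maximum coefficient of variation (percent) for a peak.
#' @param window Moving-average smoothing window in bins (odd; default 5).
#' @param min_prominence Minimum smoothed height of a candidate maximum,
#'   as a fraction of the tallest smoothed bin (default 0.05); guards
#'   against ripples on the flanks of real peaks.
#'
#' @return A tibble with one row per retained peak, sorted by `mean`
#'   ascending: columns `mean` (fluorescence units), `cv` (percent) and
#'   `n_events`. Zero rows when no peak survives the filters.
#' @export
extract_peaks <- function(hist, min_events = 100, max_cv = 10,
                          window = 5L, min_prominence = 0.05) {
  stopifnot(is.data.frame(hist), all(c("channel", "count") %in% names(hist)))
  ch <- as.numeric(hist$channel)
  ct <- as.numeric(hist$count)
  if (length(ch) == 0) abort("histogram is empty")
  if (any(diff(ch) <= 0)) abort("histogram channels must be strictly increasing")
  if (any(ct < 0)) abort("histogram counts must be non-negative")

  empty <- tibble::tibble(mean = double(), cv = double(), n_events = double())
  if (sum(ct) == 0) return(empty)

  sm <- moving_average(ct, window)
  n <- length(sm)
  floor_h <- min_prominence * max(sm)
  is_max <- sm >= floor_h &
    sm >= c(-Inf, sm[-n]) &
    sm > c(sm[-1], -Inf)
  cand <- which(is_max)
  if (length(cand) == 0) return(empty)

  peaks <- purrr::map(cand, function(i) refine_peak(ch, ct, i))
  peaks <- purrr::compact(peaks)
  if (length(peaks) == 0) return(empty)
  out <- dplyr::bind_rows(peaks)
  # merge near-duplicate fits (two candidates converging on the same peak)
  out <- dplyr::distinct(out, round(.data$mean, 6), .keep_all = TRUE)[, 1:3]
  out <- dplyr::filter(out, .data$n_events >= min_events, .data$cv <= max_cv)
  dplyr::arrange(out, .data$mean)
}

moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  k <- rep(1 / window, window)
  as.numeric(stats::filter(c(rep(x[1], window), x, rep(x[length(x)], window)),
                           k, sides = 2))[(window + 1):(window + length(x))]
}

# Gaussian refinement around the candidate bin `i0`: initial width from the
# second moment of a local neighbourhood, then nls fit of
# count ~ A * exp(-(channel - mu)^2 / (2 sigma^2)) over +-2 initial widths;
# falls back to the moment estimates when nls fails to converge.
refine_peak <- function(ch, ct, i0) {
  binw <- stats::median(diff(ch))
  # local neighbourhood: walk out until counts drop below 10% of the mode
  thr <- 0.1 * ct[i0]
  lo <- i0; while (lo > 1 && ct[lo - 1] >= thr) lo <- lo - 1
  hi <- i0; while (hi < length(ch) && ct[hi + 1] >= thr) hi <- hi + 1
  idx <- lo:hi
  w <- ct[idx]
  if (sum(w) <= 0) return(NULL)
  mu0 <- sum(ch[idx] * w) / sum(w)
  s0 <- sqrt(sum(w * (ch[idx] - mu0)^2) / sum(w))
  s0 <- max(s0, binw / 2)

  fit_idx <- which(ch >= mu0 - 2 * s0 & ch <= mu0 + 2 * s0)
  fit <- tryCatch(
    suppressWarnings(
      nls(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
          data = list(x = ch[fit_idx], y = ct[fit_idx]),
          start = list(A = max(ct[fit_idx]), mu = mu0, s = s0),
          control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    if (is.finite(cf[["mu"]]) && cf[["mu"]] > 0 && cf[["s"]] > 0) {
      mu0 <- cf[["mu"]]
      s0 <- abs(cf[["s"]])
    }
  }
  ev_idx <- which(ch >= mu0 - 3 * s0 & ch <= mu0 + 3 * s0)
  tibble::tibble(mean = mu0, cv = 100 * s0 / mu0, n_events = sum(ct[ev_idx]))
}

#' Sample/standard fluorescence ratio
#'
#' The dimensionless ratio of a sample peak mean to the internal-standard
#' peak mean; the quantity on which DNA ploidy calling operates.
#'
#' @param sample_mean,standard_mean Peak means in fluorescence units, or
#'   single-row peak tibbles as returned by [extract_peaks()].
#' @return The ratio `sample / standard`.
#' @export
sample_standard_ratio <- function(sample_mean, standard_mean) {
  sample_mean <- peak_mean_of(sample_mean)
  standard_mean <- peak_mean_of(standard_mean)
  if (any(!is.finite(standard_mean)) || any(standard_mean <= 0))
    abort("standard peak mean must be strictly positive")
  if (any(!is.finite(sample_mean)) || any(sample_mean <= 0))
    abort("sample peak mean must be strictly positive")
  sample_mean / standard_mean
}

peak_mean_of <- function(x) {
  if (is.data.frame(x)) as.numeric(x$mean) else as.numeric(x)
}

#' Build a fluorescence calibration from reference individuals
#'
#' Reference plants of known chromosome number anchor the mapping from
#' sample/standard fluorescence ratios to DNA ploidy. The per-`x` unit ratio
#' is the least-squares slope of reference ratios on reference ploidies
#' through the origin (fluorescence assumed proportional to genome copy
#' number; fluorochrome base bias is not modelled).
#'
#' @param ploidy_x Integer chromosome-set counts of the references.
#' @param ratio Their sample/standard fluorescence ratios.
#' @param standard_label Name of the internal standard (bookkeeping only).
#' @return An object of class `fcss_calibration`.
#' @export
calibration <- function(ploidy_x, ratio, standard_label = "standard") {
  stopifnot(length(ploidy_x) == length(ratio), length(ploidy_x) >= 1)
  ord <- order(ploidy_x)
  ploidy_x <- as.numeric(ploidy_x[ord]); ratio <- as.numeric(ratio[ord])
  if (any(ratio <= 0) || any(ploidy_x <= 0))
    abort("calibration ploidies and ratios must be positive")
  if (length(ratio) > 1 && any(diff(ratio) <= 0))
    abort("calibration ratios must increase strictly with ploidy")
  structure(
    list(ploidy_x = ploidy_x, ratio = ratio,
         unit_ratio = sum(ploidy_x * ratio) / sum(ploidy_x^2),
         standard_label = standard_label),
    class = "fcss_calibration")
}

#' @export
print.fcss_calibration <- function(x, ...) {
  cat("FCSS calibration (", x$standard_label, "): unit ratio ",
      format(x$unit_ratio, digits = 6), " per x\n", sep = "")
  print(tibble::tibble(ploidy_x = x$ploidy_x, ratio = x$ratio))
  invisible(x)
}

#' Default calibration used by the simulator and examples
#'
#' Proportional calibration anchored at reference tetraploid, pentaploid and
#' heptaploid individuals (ratio 0.25 per chromosome set).
#' @return An `fcss_calibration`.
#' @export
default_calibration <- function() {
  calibration(c(4, 5, 7), c(1.0, 1.25, 1.75), standard_label = "internal")
}

#' Call DNA ploidy from a sample/standard ratio
#'
#' The continuous ploidy estimate is `ratio / unit_ratio` with the unit
#' ratio taken from the calibration; the called ploidy is the nearest point
#' of the half-integer grid `{2, 2.5, ..., 12}` provided it lies within
#' `tolerance` (relative) of the continuous estimate, otherwise `NA`.
#' Half-integer grid points accommodate odd gametic contributions and high
#' ploidies beyond the reference range.
#'
#' @param ratio Sample/standard fluorescence ratio(s).
#' @param cal An [calibration()] object.
#' @param tolerance Maximum relative deviation for a grid call (default 0.05).
#' @param grid Candidate ploidy grid.
#' @return A tibble with columns `continuous_x`, `called_x` (NA when no grid
#'   point is within tolerance) and `within_tolerance`.
#' @export
call_ploidy <- function(ratio, cal, tolerance = 0.05,
                        grid = seq(2, 12, by = 0.5)) {
  stopifnot(inherits(cal, "fcss_calibration"), tolerance > 0)
  ratio <- as.numeric(ratio)
  continuous <- ratio / cal$unit_ratio
  nearest <- grid[pmax(1L, purrr::map_int(continuous, function(cx) {
    if (!is.finite(cx)) return(1L)
    which.min(abs(grid - cx))
  }))]
  ok <- is.finite(continuous) & continuous > 0 &
    abs(continuous - nearest) <= tolerance * continuous
  tibble::tibble(
    continuous_x = continuous,
    called_x = ifelse(ok, nearest, NA_real_),
    within_tolerance = ok)
}

#' Endosperm/embryo peak index
#'
#' The ratio of the endosperm peak mean to the embryo peak mean — the key
#' FCSS observable. For a seed from double fertilization of a reduced egg by
#' a balanced sperm the index is 1.5; parthenogenetic seeds with pseudogamous
#' endosperm have indices of at least 2.
#'
#' @param endosperm_mean,embryo_mean Peak means (or single-row peak tibbles).
#'   `endosperm_mean` may be `NA` (no distinct endosperm signal), giving
#'   `NA` — downstream the seed is classified `UNKNOWN`.
#' @return Dimensionless index, `NA` where the endosperm peak is absent.
#' @export
peak_index <- function(endosperm_mean, embryo_mean) {
  endo <- peak_mean_of(endosperm_mean)
  emb <- peak_mean_of(embryo_mean)
  if (any(!is.na(emb) & emb <= 0)) abort("embryo peak mean must be positive")
  ifelse(is.na(endo), NA_real_, endo / emb)
}

#' Assign embryo, endosperm and standard roles to extracted peaks
#'
#' Internal standards are identified by proximity to their configured nominal
#' positions; among the remaining peaks the embryo is the lowest-mean peak
#' and the endosperm the next peak above it whose ratio to the embryo lies in
#' `(endo_lo, endo_hi]`. A peak ratio at or below `endo_lo` is treated as
#' unresolvable from the embryo peak and ignored (flagged).
#'
#' @param peaks Peak tibble from [extract_peaks()].
#' @param standard_positions Numeric vector of nominal standard peak means.
#' @param standard_tol Relative window for standard identification (default 0.1).
#' @param endo_lo,endo_hi Peak-index window for a distinct endosperm peak
#'   (defaults 1.2 and 8).
#' @return A one-row tibble: `embryo_mean`, `embryo_cv`, `endosperm_mean`,
#'   `endosperm_cv`, `standard_mean`, `n_standards`, `flag` (empty string,
#'   `"no_embryo"`, `"no_standard"` or `"endosperm_unresolved"`).
#' @export
assign_seed_peaks <- function(peaks, standard_positions,
                              standard_tol = 0.1,
                              endo_lo = 1.2, endo_hi = 8) {
  out <- tibble::tibble(
    embryo_mean = NA_real_, embryo_cv = NA_real_,
    endosperm_mean = NA_real_, endosperm_cv = NA_real_,
    standard_mean = NA_real_, n_standards = 0L, flag = "")
  if (nrow(peaks) == 0) { out$flag <- "no_embryo"; return(out) }

  is_std <- purrr::map_lgl(peaks$mean, function(m)
    any(abs(m - standard_positions) <= standard_tol * standard_positions))
  std <- peaks[is_std, ]
  smp <- peaks[!is_std, ]
  out$n_standards <- nrow(std)
  if (nrow(std) > 0) out$standard_mean <- std$mean[[1]] else out$flag <- "no_standard"
  if (nrow(smp) == 0) { out$flag <- "no_embryo"; return(out) }

  out$embryo_mean <- smp$mean[[1]]
  out$embryo_cv <- smp$cv[[1]]
  if (nrow(smp) > 1) {
    ratios <- smp$mean[-1] / out$embryo_mean
    cand <- which(ratios > endo_lo & ratios <= endo_hi)
    if (length(cand) > 0) {
      out$endosperm_mean <- smp$mean[[cand[[1]] + 1L]]
      out$endosperm_cv <- smp$cv[[cand[[1]] + 1L]]
    } else if (any(ratios <= endo_lo)) {
      out$flag <- "endosperm_unresolved"
    }
  }
  out
}
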
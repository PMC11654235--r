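#' Consolidate two detector gains into one intensity per colony
#'
#' The plate reader records each colony at two detector gains so that both
#' dim and bright colonies fall in the linear range. The two channels are
#' related by an affine map; this function fits it by least squares on
#' colonies unsaturated in both channels (`fluor_high = gain_factor *
#' fluor_low + offset`) and reports, per colony, the high-gain value where
#' unsaturated and the calibrated low-gain value where the high gain
#' saturated.
#'
#' @param plate Plate data frame with `fluor_low`, `fluor_high`,
#'   `saturated_high`.
#' @param min_points Minimum number of doubly-unsaturated calibration
#'   colonies (default 3).
#' @return The plate with an added column `fluor` (consolidated intensity,
#'   `NA` where no channel is usable), and the calibration attached as
#'   attribute `calibration` (a list `gain_factor`, `offset`, `n_points`).
#' @export
consolidate_gains <- function(plate, min_points = 3L) {
  stopifnot(all(c("fluor_low", "fluor_high", "saturated_high") %in%
                  names(plate)))
  ok <- plate$saturated_high == 0 & is.finite(plate$fluor_low) &
    is.finite(plate$fluor_high)
  if (sum(ok) < min_points)
    stop(sprintf("only %d unsaturated calibration colonies (need >= %d)",
                 sum(ok), min_points))
  fit <- stats::lm.fit(cbind(1, plate$fluor_low[ok]), plate$fluor_high[ok])
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] <= 0)
    stop("gain calibration failed: non-positive gain factor")
  fl <- ifelse(plate$saturated_high == 0, plate$fluor_high,
               b[2] * plate$fluor_low + b[1])
  fl[!is.finite(fl)] <- NA_real_
  plate$fluor <- fl
  attr(plate, "calibration") <- list(gain_factor = unname(b[2]),
                                     offset = unname(b[1]),
                                     n_points = sum(ok))
  plate
}

#' Normalize colony fluorescence within replicate groups
#'
#' Each 4x4 group contains four reference colonies (an abundant mNG-tagged
#' strain) and three non-fluorescent background colonies. Every colony in
#' the group is divided by the mean of its reference colonies, correcting
#' spatial and plate effects; the mean of the (reference-normalized)
#' background colonies is attached per group for background subtraction or
#' division downstream.
#'
#' @param plate Plate data frame with a `fluor` column (see
#'   [consolidate_gains()]).
#' @param layout Matching `fluor4x4` layout.
#' @return Data frame of non-dummy colonies with columns `orf`, `role`,
#'   `group`, `nfluor` (reference-normalized intensity) and `bkg` (group
#'   background mean on the same scale); groups with a missing or
#'   non-positive reference mean are dropped with a warning.
#' @export
normalize_group <- function(plate, layout) {
  stopifnot("fluor" %in% names(plate))
  m <- merge(plate, layout, by = c("plate", "row", "col"), sort = FALSE)
  m <- m[!is.na(m$group), , drop = FALSE]
  out <- vector("list", 0L)
  dropped <- 0L
  for (g in unique(m$group)) {
    gi <- m[m$group == g, , drop = FALSE]
    refm <- mean(gi$fluor[gi$role == "reference"], na.rm = TRUE)
    if (!is.finite(refm) || refm <= 0) { dropped <- dropped + 1L; next }
    nf <- gi$fluor / refm
    bkg <- mean(nf[gi$role == "background"], na.rm = TRUE)
    out[[length(out) + 1L]] <- data.frame(
      orf = gi$orf, role = gi$role, group = g, nfluor = nf, bkg = bkg)
  }
  if (dropped > 0L)
    warning(sprintf("%d group(s) dropped for unusable reference mean",
                    dropped))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize one strain's normalized fluorescence
#'
#' Computes the per-genotype summary used by the degradation classifier:
#' mean and SD of the normalized intensities of OsTIR1+ and OsTIR1-
#' replicates, the background-relative levels mNG/bkg (division) and
#' mNG-bkg (subtraction), the degradation fold
#' `rho = (mNG-bkg)(+) / (mNG-bkg)(-)` clipped at 0, and a two-sided Welch
#' t-test comparing the background-corrected replicate values. A negative
#' background-corrected OsTIR1- mean leaves the fold `NA` (the strain is
#' effectively undetected).
#'
#' @param plus,minus Numeric vectors of reference-normalized replicate
#'   intensities for the OsTIR1+ and OsTIR1- genotype.
#' @param bkg Group background mean on the same scale.
#' @return One-row data frame with the summary fields (`p` is `NA` with
#'   fewer than 2 replicates on either side; `q` is filled in by the caller
#'   across the strain family).
#' @export
summarize_strain <- function(plus, minus, bkg) {
  plus <- plus[is.finite(plus)]
  minus <- minus[is.finite(minus)]
  mp <- mean(plus); mm <- mean(minus)
  num <- mp - bkg; den <- mm - bkg
  fold <- if (is.na(den) || den <= 0) NA_real_ else max(0, num) / den
  p <- if (length(plus) >= 2L && length(minus) >= 2L)
    welch_t(plus - bkg, minus - bkg)$p else NA_real_
  data.frame(
    mean_plus = mp, sd_plus = stats::sd(plus),
    mean_minus = mm, sd_minus = stats::sd(minus),
    n_plus = length(plus), n_minus = length(minus),
    mng_over_bkg_plus = mp / bkg, mng_over_bkg_minus = mm / bkg,
    mng_minus_bkg_plus = num, mng_minus_bkg_minus = den,
    fold = fold, p = p, q = NA_real_)
}

#' Thresholds for the degradation classifier
#'
#' @param detect Detection threshold on mNG/bkg (default 1.2).
#' @param fold_max Maximum degradation fold counted as depletion (default
#'   0.5).
#' @param q_max Significance threshold on the (BH-adjusted) p-value
#'   (default 0.05).
#' @return An object of class `degradation_thresholds`.
#' @export
degradation_thresholds <- function(detect = 1.2, fold_max = 0.5,
                                   q_max = 0.05) {
  stopifnot(detect > 1, fold_max > 0, fold_max < 1, q_max > 0, q_max < 1)
  structure(list(detect = detect, fold_max = fold_max, q_max = q_max),
            class = "degradation_thresholds")
}

#' Four-way degradation classification
#'
#' Applies the rule set, with `d = detect`, `f = fold_max`, `a = q_max`:
#' * not_detected: mNG/bkg(-) <= d;
#' * degraded: mNG/bkg(-) > d, mNG/bkg(+) <= d, fold < f and q < a;
#' * partially_degraded: mNG/bkg(-) > d, mNG/bkg(+) > d, fold < f and q < a;
#' * not_affected: mNG/bkg(-) > d and (fold >= f or q >= a).
#'
#' A missing fold (non-positive background-corrected OsTIR1- level) routes
#' the strain to not_detected. The rules partition: every strain receives
#' exactly one label.
#'
#' @param s Summary data frame (rows from [summarize_strain()], with `q`
#'   filled in).
#' @param thr A [degradation_thresholds()].
#' @return Character vector of categories, one per row of `s`.
#' @export
classify_degradation <- function(s, thr = degradation_thresholds()) {
  n <- nrow(s)
  out <- character(n)
  for (i in seq_len(n)) {
    rm_ <- s$mng_over_bkg_minus[i]
    rp <- s$mng_over_bkg_plus[i]
    fold <- s$fold[i]
    q <- s$q[i]
    out[i] <-
      if (is.na(rm_) || rm_ <= thr$detect || is.na(fold)) "not_detected"
      else if (!is.na(q) && q < thr$q_max && fold < thr$fold_max) {
        if (rp <= thr$detect) "degraded" else "partially_degraded"
      } else "not_affected"
  }
  out
}

#' Analyze a colony-fluorescence array end to end
#'
#' Runs gain consolidation, group normalization, per-strain summary, BH
#' adjustment across all strains and the four-way degradation
#' classification.
#'
#' @param plates Plate data frame (possibly several plates stacked) with the
#'   dual-gain columns.
#' @param layout Matching `fluor4x4` layout.
#' @param thr A [degradation_thresholds()].
#' @param min_points Passed to [consolidate_gains()].
#' @return Data frame with one row per ORF: the [summarize_strain()] fields
#'   plus `orf`, `q` and `category`.
#' @export
analyze_fluor <- function(plates, layout, thr = degradation_thresholds(),
                          min_points = 3L) {
  by_plate <- split(plates, plates$plate)
  cons <- do.call(rbind, lapply(by_plate, consolidate_gains,
                                min_points = min_points))
  norm <- normalize_group(cons, layout)
  samp <- norm[norm$role %in% c("sample_plus", "sample_minus") &
                 !is.na(norm$orf), , drop = FALSE]
  orfs <- unique(samp$orf)
  rows <- lapply(orfs, function(o) {
    oi <- samp[samp$orf == o, , drop = FALSE]
    s <- summarize_strain(oi$nfluor[oi$role == "sample_plus"],
                          oi$nfluor[oi$role == "sample_minus"],
                          oi$bkg[1])
    cbind(data.frame(orf = o), s)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res$category <- classify_degradation(res, thr)
  rownames(res) <- NULL
  res
}

#' Calibrate the detection limit of the colony assay
#'
#' Regresses log normalized fluorescence on log absolute abundance
#' (molecules/cell) over calibration strains and inverts the fit at a
#' fluorescence threshold: the detection limit is the abundance at which the
#' fitted fluorescence equals `threshold`. The confidence interval comes
#' from a parametric bootstrap (refitting on responses resampled from the
#' fitted line plus Gaussian residual noise).
#'
#' @param abundance Positive abundances (molecules/cell).
#' @param fluor Positive normalized fluorescence values (e.g. mNG/bkg).
#' @param threshold Fluorescence level defining detectability (default 1.2,
#'   the not-detected boundary).
#' @param n_boot Bootstrap draws (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return A list with `slope`, `intercept` (log-log scale), `limit`,
#'   `ci_low`, `ci_high` (molecules/cell) and `n`.
#' @export
calibrate_detection_limit <- function(abundance, fluor, threshold = 1.2,
                                      n_boot = 2000L, level = 0.95,
                                      seed = NULL) {
  if (length(abundance) < 5L || length(abundance) != length(fluor))
    stop("need >= 5 calibration pairs")
  if (any(abundance <= 0) || any(fluor <= 0))
    stop("abundance and fluorescence must be positive")
  if (!is.null(seed)) set.seed(seed)
  x <- log(abundance); y <- log(fluor)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  if (slope <= 0) stop("non-positive calibration slope")
  intercept <- mean(y) - slope * mean(x)
  inv <- function(b0, b1) exp((log(threshold) - b0) / b1)
  limit <- inv(intercept, slope)
  resid <- y - intercept - slope * x
  sigma <- sqrt(sum(resid^2) / (n - 2))
  if (sigma == 0) {
    ci <- c(limit, limit)
  } else {
    fitted <- intercept + slope * x
    ystar <- matrix(fitted, n, n_boot) +
      matrix(stats::rnorm(n * n_boot, 0, sigma), n, n_boot)
    xc <- x - mean(x)
    b1s <- colSums(xc * ystar) / sxx
    b0s <- colMeans(ystar) - b1s * mean(x)
    lims <- inv(b0s, b1s)
    lims <- lims[is.finite(lims) & b1s > 0]
    ci <- unname(stats::quantile(lims, c((1 - level) / 2,
                                         1 - (1 - level) / 2)))
  }
  list(slope = slope, intercept = intercept, limit = limit,
       ci_low = ci[1], ci_high = ci[2], n = n)
}
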
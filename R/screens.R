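#' Plate-normalization configuration
#'
#' @param border_depth Dummy border rows/columns removed before analysis
#'   (default 4).
#' @param percentile_window Percentile bounds of the robust plate median
#'   (default `c(40, 80)`): the normalizing median is computed over colonies
#'   between these percentiles only, which keeps it anchored on healthy
#'   strains when many strains have impaired fitness.
#' @param spatial_window Side of the square local-median window for spatial
#'   correction (odd, default 7).
#' @return An object of class `plate_norm_config`.
#' @export
plate_norm_config <- function(border_depth = 4L,
                              percentile_window = c(40, 80),
                              spatial_window = 7L) {
  stopifnot(border_depth >= 0,
            percentile_window[1] >= 0, percentile_window[2] <= 100,
            percentile_window[1] < percentile_window[2],
            spatial_window >= 3L, spatial_window %% 2L == 1L)
  structure(list(border_depth = as.integer(border_depth),
                 percentile_window = percentile_window,
                 spatial_window = as.integer(spatial_window)),
            class = "plate_norm_config")
}

plate_dims <- function(plate) {
  c(max(plate$row), max(plate$col))
}

#' Remove the dummy border of a plate
#'
#' @param plate Plate data frame with `row`, `col` (single plate).
#' @param cfg A [plate_norm_config()]; its `border_depth` rows and columns
#'   are removed on every side.
#' @return The trimmed plate data frame.
#' @export
trim_border <- function(plate, cfg = plate_norm_config()) {
  d <- cfg$border_depth
  if (d == 0L) return(plate)
  dm <- plate_dims(plate)
  if (dm[1] <= 2L * d || dm[2] <= 2L * d)
    stop(sprintf("plate %dx%d too small for border depth %d",
                 dm[1], dm[2], d))
  plate[plate$row > d & plate$row <= dm[1] - d &
          plate$col > d & plate$col <= dm[2] - d, , drop = FALSE]
}

# local median filter on a matrix; windows are clipped at the edges
local_median <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - h):min(nr, i + h)
    for (j in seq_len(nc)) {
      cj <- max(1L, j - h):min(nc, j + h)
      out[i, j] <- stats::median(m[ri, cj], na.rm = TRUE)
    }
  }
  out
}

#' Correct smooth spatial effects on a plate
#'
#' Estimates a smooth multiplicative surface as the local median of colony
#' sizes in a `spatial_window` x `spatial_window` neighbourhood, rescales
#' the surface to plate median 1 (so the plate median is preserved), and
#' divides each colony by it. The median is robust to isolated outlier
#' colonies, which are therefore preserved relative to their neighbours.
#'
#' @param plate Trimmed plate data frame with `row`, `col`, and the value
#'   column.
#' @param cfg A [plate_norm_config()].
#' @param value Name of the measurement column (default `"size"`).
#' @return The plate with the value column spatially corrected.
#' @export
spatial_correct <- function(plate, cfg = plate_norm_config(),
                            value = "size") {
  w <- cfg$spatial_window
  rows <- sort(unique(plate$row)); cols <- sort(unique(plate$col))
  if (w > length(rows) || w > length(cols))
    stop("spatial window larger than the plate")
  m <- matrix(NA_real_, length(rows), length(cols))
  ri <- match(plate$row, rows); ci <- match(plate$col, cols)
  m[cbind(ri, ci)] <- plate[[value]]
  surf <- local_median(m, w)
  surf <- surf / stats::median(surf, na.rm = TRUE)
  surf[!is.finite(surf) | surf <= 0] <- NA_real_
  plate[[value]] <- plate[[value]] / surf[cbind(ri, ci)]
  plate
}

#' Restricted-percentile median
#'
#' Median of the values lying (inclusively) between the given percentiles of
#' the sample; the default 40th-80th window ignores both the many small
#' colonies of impaired strains and the largest colonies.
#'
#' @param x Numeric vector.
#' @param window Percentile bounds, default `c(40, 80)`.
#' @return The restricted median (falls back to the full median, with a
#'   warning, if the band is empty).
#' @export
restricted_median <- function(x, window = c(40, 80)) {
  x <- x[is.finite(x)]
  qs <- stats::quantile(x, window / 100, type = 7, names = FALSE)
  band <- x[x >= qs[1] & x <= qs[2]]
  if (length(band) == 0L) {
    warning("empty percentile band; falling back to the full median")
    return(stats::median(x))
  }
  stats::median(band)
}

#' Normalize a plate by its restricted-percentile median
#'
#' @param plate Plate data frame (single plate or condition).
#' @param cfg A [plate_norm_config()].
#' @param value Measurement column (default `"size"`).
#' @return The plate with the value column divided by the restricted
#'   median.
#' @export
robust_plate_normalize <- function(plate, cfg = plate_norm_config(),
                                   value = "size") {
  x <- plate[[value]]
  if (sum(is.finite(x)) < 10L)
    stop("need >= 10 non-missing colonies to normalize a plate")
  plate[[value]] <- x / restricted_median(x, cfg$percentile_window)
  plate
}

#' Full plate normalization chain
#'
#' Border trim, spatial correction and restricted-median plate
#' normalization, in that order, applied per plate.
#'
#' @param plate Plate data frame (may hold several plates).
#' @param cfg A [plate_norm_config()].
#' @param value Measurement column.
#' @return Normalized plate data frame.
#' @export
normalize_plate <- function(plate, cfg = plate_norm_config(),
                            value = "size") {
  out <- lapply(split(plate, plate$plate), function(p) {
    p <- trim_border(p, cfg)
    p <- spatial_correct(p, cfg, value)
    robust_plate_normalize(p, cfg, value)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Estimate the OsTir1 expression fitness effect
#'
#' The degron machinery itself costs fitness: the OsTir1 factor tau is the
#' colony size of an OsTIR1+ strain relative to its OsTIR1- counterpart,
#' averaged across non-essential ORFs (which are unaffected by the tagged
#' protein's depletion under permissive interpretation). Per-ORF ratios with
#' a non-positive OsTIR1- size are excluded.
#'
#' @param plus,minus Per-ORF mean normalized sizes of the two genotypes
#'   (same length and order).
#' @param estimator `"mean"` (default) or `"median"` of the per-ORF ratios.
#' @param min_pairs Minimum usable pairs (default 10).
#' @return A list with `tau`, `n_orfs`, `estimator`.
#' @export
estimate_tir1_effect <- function(plus, minus,
                                 estimator = c("mean", "median"),
                                 min_pairs = 10L) {
  estimator <- match.arg(estimator)
  stopifnot(length(plus) == length(minus))
  ok <- is.finite(plus) & is.finite(minus) & minus > 0
  if (sum(ok) < min_pairs)
    stop(sprintf("only %d usable pairs (need >= %d)", sum(ok), min_pairs))
  ratios <- plus[ok] / minus[ok]
  tau <- if (estimator == "mean") mean(ratios) else stats::median(ratios)
  if (tau <= 0) stop("non-positive tau estimate")
  list(tau = tau, n_orfs = sum(ok), estimator = estimator)
}

#' Correct OsTIR1+ sizes for the OsTir1 expression cost
#'
#' Under the multiplicative fitness model the machinery cost is independent
#' of the depletion effect, so corrected sizes are `size / tau`.
#'
#' @param sizes Numeric vector of OsTIR1+ sizes.
#' @param correction Result of [estimate_tir1_effect()], or a number.
#' @return Corrected sizes.
#' @export
correct_tir1 <- function(sizes, correction) {
  tau <- if (is.list(correction)) correction$tau else correction
  stopifnot(tau > 0)
  sizes / tau
}

#' Thresholds for impaired-fitness calls
#'
#' @param ratio_max Maximum OsTIR1+/OsTIR1- size ratio of a healthy strain
#'   (default 0.8).
#' @param q_max Significance threshold (default 0.05).
#' @return An object of class `fitness_call_thresholds`.
#' @export
fitness_call_thresholds <- function(ratio_max = 0.8, q_max = 0.05) {
  stopifnot(ratio_max > 0, ratio_max < 1, q_max > 0, q_max < 1)
  structure(list(ratio_max = ratio_max, q_max = q_max),
            class = "fitness_call_thresholds")
}

#' Call a strain's fitness impaired
#'
#' A strain is impaired when its (corrected) OsTIR1+/OsTIR1- size ratio
#' falls below `ratio_max` and the Welch t-test comparing the replicate
#' sizes is significant at `q_max` (on the BH-adjusted p where a family is
#' analyzed jointly).
#'
#' @param plus,minus Replicate (corrected) sizes of the two genotypes.
#' @param thr A [fitness_call_thresholds()].
#' @param q Optional adjusted p-value to use for the call; defaults to the
#'   raw Welch p (callers analyzing many strains adjust first).
#' @return A list with `ratio`, `p`, `q`, `impaired` (`NA` with fewer than 2
#'   replicates on either side).
#' @export
call_impaired <- function(plus, minus, thr = fitness_call_thresholds(),
                          q = NULL) {
  plus <- plus[is.finite(plus)]; minus <- minus[is.finite(minus)]
  ratio <- mean(plus) / mean(minus)
  if (length(plus) < 2L || length(minus) < 2L)
    return(list(ratio = ratio, p = NA_real_, q = NA_real_, impaired = NA))
  p <- welch_t(plus, minus)$p
  if (is.null(q)) q <- p
  list(ratio = ratio, p = p, q = q,
       impaired = ratio < thr$ratio_max && q < thr$q_max)
}

#' Analyze an OsTIR1+/OsTIR1- fitness array
#'
#' Normalizes the colony-size plate(s) of an array carrying both genotypes
#' (the `fluor4x4` design: 6 OsTIR1+ and 3 OsTIR1- replicates per ORF),
#' estimates the OsTir1 effect tau on non-essential ORFs, corrects OsTIR1+
#' sizes by tau, and calls impaired strains with BH adjustment across all
#' ORFs.
#'
#' @param plates Plate data frame with `size` (dual-genotype array).
#' @param layout Matching `fluor4x4` layout.
#' @param essential Data frame `orf`, `essential` (0/1) used for the tau
#'   estimate.
#' @param cfg A [plate_norm_config()].
#' @param thr A [fitness_call_thresholds()].
#' @param estimator Passed to [estimate_tir1_effect()].
#' @return A list with `tau` (the [estimate_tir1_effect()] result) and
#'   `strains`, a data frame `orf`, `ratio`, `p`, `q`, `impaired` (ratio of
#'   tau-corrected OsTIR1+ mean to OsTIR1- mean).
#' @export
analyze_fitness <- function(plates, layout, essential,
                            cfg = plate_norm_config(),
                            thr = fitness_call_thresholds(),
                            estimator = "mean") {
  norm <- normalize_plate(plates, cfg)
  m <- merge(norm, layout, by = c("plate", "row", "col"), sort = FALSE)
  m <- m[m$role %in% c("sample_plus", "sample_minus") & !is.na(m$orf), ,
         drop = FALSE]
  orfs <- sort(unique(m$orf))
  pl <- lapply(orfs, function(o) m$size[m$orf == o & m$role == "sample_plus"])
  mi <- lapply(orfs, function(o) m$size[m$orf == o & m$role == "sample_minus"])
  plus_mean <- vapply(pl, mean, numeric(1))
  minus_mean <- vapply(mi, mean, numeric(1))
  ess <- essential$essential[match(orfs, essential$orf)]
  nonzero <- !is.na(ess) & ess == 0
  tau <- estimate_tir1_effect(plus_mean[nonzero], minus_mean[nonzero],
                              estimator = estimator)
  rows <- mapply(function(p_, m_) {
    r <- call_impaired(correct_tir1(p_, tau), m_, thr)
    c(ratio = r$ratio, p = r$p)
  }, pl, mi)
  res <- data.frame(orf = orfs, ratio = rows["ratio", ], p = rows["p", ])
  res$q <- bh_adjust(res$p)
  res$impaired <- res$ratio < thr$ratio_max & res$q < thr$q_max
  rownames(res) <- NULL
  list(tau = tau, strains = res)
}

#' Chemical-genetic interaction score
#'
#' Deviation of double-perturbation fitness from the multiplicative
#' expectation: `score = W_IG - W_I * W_GA`, where the W are normalized
#' median-centered colony sizes under the degron inducer (I), the genotoxic
#' agent (GA) and their combination (IG). Zero means the two perturbations
#' combine independently; negative scores flag synergistic sickness.
#'
#' @param w_i,w_ga,w_ig Non-negative normalized sizes.
#' @return The interaction score.
#' @examples
#' cgi_score(0.8, 0.9, 0.5) # -0.22
#' @export
cgi_score <- function(w_i, w_ga, w_ig) {
  stopifnot(all(w_i >= 0), all(w_ga >= 0), all(w_ig >= 0))
  w_ig - w_i * w_ga
}

#' Test a CGI against the multiplicative null
#'
#' Forms a product distribution by pairing replicate sizes of the two single
#' perturbations (replicate order is shuffled within condition under the
#' given seed, then products are taken index-wise up to the shorter length)
#' and compares the double-perturbation replicates against those products
#' with a two-sided Welch t-test. The default `"all_pairs"` uses all n*m
#' products, which stabilizes the product sample's spread at typical
#' replicate counts (n = 4); `pairing = "paired"` instead pairs replicates
#' index-wise after a seeded within-condition shuffle, keeping the product
#' sample the same size as the data.
#'
#' @param reps_i,reps_ga,reps_ig Replicate normalized sizes per condition
#'   (>= 2 each).
#' @param pairing `"all_pairs"` (default) or `"paired"`.
#' @param seed Optional integer seed for the within-condition shuffle
#'   (`"paired"` only).
#' @return Two-sided p-value (`p = 1` when both sides are degenerate with
#'   equal means).
#' @export
cgi_test <- function(reps_i, reps_ga, reps_ig,
                     pairing = c("all_pairs", "paired"), seed = NULL) {
  pairing <- match.arg(pairing)
  reps_i <- reps_i[is.finite(reps_i)]
  reps_ga <- reps_ga[is.finite(reps_ga)]
  reps_ig <- reps_ig[is.finite(reps_ig)]
  if (min(length(reps_i), length(reps_ga), length(reps_ig)) < 2L)
    stop("need >= 2 replicates per condition")
  if (pairing == "paired") {
    if (length(reps_i) != length(reps_ga))
      warning("unequal replicate counts; pairing up to the minimum")
    if (!is.null(seed)) set.seed(seed)
    n <- min(length(reps_i), length(reps_ga))
    prod <- sample(reps_i)[seq_len(n)] * sample(reps_ga)[seq_len(n)]
  } else {
    prod <- as.vector(outer(reps_i, reps_ga))
  }
  welch_t(reps_ig, prod)$p
}

#' Thresholds for negative-CGI calls
#'
#' @param w_max Maximum double-perturbation size of a hit (default 0.9).
#' @param score_max Maximum (most positive) CGI score of a hit (default
#'   -0.2).
#' @param q_max Significance threshold on the BH-adjusted p (default 0.05).
#' @return An object of class `cgi_call_thresholds`.
#' @export
cgi_call_thresholds <- function(w_max = 0.9, score_max = -0.2,
                                q_max = 0.05) {
  stopifnot(score_max < 0, w_max > 0, q_max > 0, q_max < 1)
  structure(list(w_max = w_max, score_max = score_max, q_max = q_max),
            class = "cgi_call_thresholds")
}

#' Call a significant negative chemical-genetic interaction
#'
#' A hit requires all three of: double-perturbation size `W_IG <= w_max`,
#' `score <= score_max`, and adjusted p below `q_max`.
#'
#' @param w_ig,score,q Vectors of double-perturbation size, CGI score and
#'   adjusted p.
#' @param thr A [cgi_call_thresholds()].
#' @return Logical vector of hit calls (`NA` where `q` is missing).
#' @export
call_negative_cgi <- function(w_ig, score, q, thr = cgi_call_thresholds()) {
  w_ig <= thr$w_max & score <= thr$score_max & q < thr$q_max
}

#' Run a chemical-genetic interaction screen end to end
#'
#' Normalizes the four condition plates (border trim, spatial correction,
#' restricted-median plate and condition normalization), median-centers each
#' condition at the strain level (so that the typical, unaffected strain
#' sits at exactly W = 1 — the anchor the multiplicative score assumes),
#' collects per-ORF replicate sizes, computes CGI scores, tests each ORF
#' against the multiplicative null, BH-adjusts across the screen and calls
#' negative interactions.
#'
#' @param plates Named list of plate data frames `control`, `iaa`, `ga`,
#'   `both` (from [simulate_screen()] or read from disk).
#' @param layout Matching `fitness2x2` layout.
#' @param cfg A [plate_norm_config()].
#' @param thr A [cgi_call_thresholds()].
#' @param pairing Passed to [cgi_test()].
#' @param seed Seed for the replicate pairing shuffle.
#' @return Data frame with one row per ORF: `orf`, `w_ctrl`, `w_i`, `w_ga`,
#'   `w_ig`, the replicate SDs, `score`, `p`, `q`, `call`.
#' @export
cgi_screen <- function(plates, layout, cfg = plate_norm_config(),
                       thr = cgi_call_thresholds(), pairing = "all_pairs",
                       seed = NULL) {
  stopifnot(all(c("control", "iaa", "ga", "both") %in% names(plates)))
  if (!is.null(seed)) set.seed(seed)
  norm <- lapply(plates[c("control", "iaa", "ga", "both")], function(p) {
    np <- normalize_plate(p, cfg)
    # per-condition re-normalization with the same restricted median
    np$size <- np$size / restricted_median(np$size, cfg$percentile_window)
    m <- merge(np, layout, by = c("plate", "row", "col"), sort = FALSE)
    m[m$role == "sample_plus" & !is.na(m$orf), c("orf", "size")]
  })
  orfs <- sort(unique(norm$control$orf))
  reps <- lapply(norm, function(df) {
    r <- lapply(orfs, function(o) df$size[df$orf == o])
    # strain-level median centering: the median ORF of each condition is
    # placed at W = 1
    ctr <- stats::median(vapply(r, mean, numeric(1)), na.rm = TRUE)
    lapply(r, function(v) v / ctr)
  })
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  sd_or_na <- function(v) if (length(v) > 1L) stats::sd(v) else NA_real_
  res <- data.frame(
    orf = orfs,
    w_ctrl = vapply(reps$control, mean_or_na, numeric(1)),
    w_i = vapply(reps$iaa, mean_or_na, numeric(1)),
    w_ga = vapply(reps$ga, mean_or_na, numeric(1)),
    w_ig = vapply(reps$both, mean_or_na, numeric(1)),
    sd_i = vapply(reps$iaa, sd_or_na, numeric(1)),
    sd_ga = vapply(reps$ga, sd_or_na, numeric(1)),
    sd_ig = vapply(reps$both, sd_or_na, numeric(1)))
  res$score <- cgi_score(res$w_i, res$w_ga, res$w_ig)
  res$p <- mapply(function(i, g, ig) {
    if (min(length(i), length(g), length(ig)) < 2L) NA_real_
    else cgi_test(i, g, ig, pairing = pairing)
  }, reps$iaa, reps$ga, reps$both)
  res$q <- bh_adjust(res$p)
  res$call <- call_negative_cgi(res$w_ig, res$score, res$q, thr)
  rownames(res) <- NULL
  res
}
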
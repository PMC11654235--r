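#' Smooth multiplicative spatial field over a plate
#'
#' Generates a strictly positive, mean-one surface emulating smooth plate
#' artifacts (nutrient gradients, uneven illumination): either a linear
#' gradient or a sum of Gaussian bumps.
#'
#' @param nrow,ncol Grid dimensions.
#' @param type `"flat"`, `"gradient"` or `"bumps"`.
#' @param amplitude Approximate peak deviation from 1 (e.g. 0.2 for ±20%).
#' @param n_bumps Number of Gaussian bumps for `type = "bumps"`.
#' @param seed Optional integer seed (used by `"bumps"` and to orient the
#'   gradient).
#' @return A `nrow x ncol` matrix, strictly positive, mean 1.
#' @export
make_spatial_field <- function(nrow, ncol, type = c("flat", "gradient",
                                                    "bumps"),
                               amplitude = 0.2, n_bumps = 3L, seed = NULL) {
  type <- match.arg(type)
  stopifnot(amplitude >= 0, amplitude < 1)
  if (!is.null(seed)) set.seed(seed)
  if (type == "flat" || amplitude == 0)
    return(matrix(1, nrow, ncol))
  r <- (seq_len(nrow) - 1) / max(1, nrow - 1) - 0.5
  cc <- (seq_len(ncol) - 1) / max(1, ncol - 1) - 0.5
  if (type == "gradient") {
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- outer(r, rep(1, ncol)) * cos(theta) +
      outer(rep(1, nrow), cc) * sin(theta)
    f <- 1 + amplitude * proj / max(abs(proj))  # peak deviation = amplitude
  } else {
    f <- matrix(0, nrow, ncol)
    for (b in seq_len(n_bumps)) {
      cr <- stats::runif(1, -0.5, 0.5)
      ccn <- stats::runif(1, -0.5, 0.5)
      s <- stats::runif(1, 0.15, 0.35)
      a <- stats::runif(1, -1, 1)
      f <- f + a * exp(-(outer((r - cr)^2, (cc - ccn)^2, "+")) / (2 * s^2))
    }
    mx <- max(abs(f))
    f <- 1 + if (mx > 0) amplitude * f / mx else 0
  }
  f / mean(f)
}

#' Ground truth for a synthetic AID colony array
#'
#' Assigns each ORF an abundance, a degradation state with its true
#' OsTIR1+ / OsTIR1- protein-level fold, an OsTir1 colony-size effect and an
#' essentiality flag. Abundances are expressed in units of background
#' autofluorescence: not-detected ORFs sit below 0.2 x background (so their
#' expected mNG/bkg is at most 1.2), detected ORFs between `abundance_range`
#' multiples of background.
#'
#' @param n_orfs Number of ORFs.
#' @param state_probs Named probabilities for
#'   `not_detected`, `degraded`, `partially_degraded`, `not_affected`.
#' @param folds Named true protein-level folds for the three detected states
#'   (defaults 0.02, 0.3, 1.0).
#' @param abundance_range Range of detected abundances, in background units.
#' @param tir1_effect Multiplicative OsTir1 colony-size effect (default
#'   0.93, a 7% size reduction).
#' @param frac_essential Fraction of ORFs flagged essential.
#' @param seed Optional integer seed.
#' @return Data frame with columns `orf`, `abundance`, `state`, `fold`,
#'   `tir1_effect`, `essential`.
#' @export
make_array_truth <- function(n_orfs,
                             state_probs = c(not_detected = 0.15,
                                             degraded = 0.5,
                                             partially_degraded = 0.15,
                                             not_affected = 0.2),
                             folds = c(degraded = 0.02,
                                       partially_degraded = 0.3,
                                       not_affected = 1.0),
                             abundance_range = c(2, 8),
                             tir1_effect = 0.93,
                             frac_essential = 0.2,
                             seed = NULL) {
  stopifnot(n_orfs >= 1, abs(sum(state_probs) - 1) < 1e-8,
            all(folds >= 0), tir1_effect > 0)
  if (!is.null(seed)) set.seed(seed)
  states <- sample(names(state_probs), n_orfs, replace = TRUE,
                   prob = state_probs)
  # not-detected strains carry essentially no signal (at most 5% of
  # background autofluorescence), as for untagged or unexpressed proteins
  ab <- ifelse(states == "not_detected",
               stats::runif(n_orfs, 0, 0.05),
               stats::runif(n_orfs, abundance_range[1], abundance_range[2]))
  fold <- ifelse(states == "not_detected", 1, folds[states])
  data.frame(orf = sprintf("ORF%04d", seq_len(n_orfs)),
             abundance = ab, state = states, fold = unname(fold),
             tir1_effect = tir1_effect,
             essential = as.integer(stats::runif(n_orfs) < frac_essential))
}

#' Simulate a dual-gain colony-fluorescence array
#'
#' Fills a `fluor4x4` layout with colony sizes and two-gain fluorescence
#' measurements. Per colony, the true fluorescence is background
#' autofluorescence plus the strain's abundance (scaled by its degradation
#' fold in OsTIR1+ positions); colony size carries the OsTir1 effect for
#' OsTIR1+ positions. Both are multiplied by a shared smooth spatial field
#' and independent lognormal noise. The two detector channels are fixed
#' affine transforms of the true intensity, the high-gain channel hard-
#' saturating at `ceiling`.
#'
#' @param truth Truth table from [make_array_truth()].
#' @param layout A `fluor4x4` layout from [make_layout()].
#' @param bkg_level Background autofluorescence, arbitrary units.
#' @param ref_abundance Reference-strain abundance in background units (an
#'   abundant mNG-tagged protein).
#' @param size_base Baseline colony size, arbitrary units.
#' @param noise_cv Lognormal measurement noise CV applied to size and
#'   fluorescence.
#' @param spatial_type,spatial_amplitude Spatial field settings (see
#'   [make_spatial_field()]).
#' @param gain_low,gain_high,offset_low,offset_high Affine channel
#'   parameters.
#' @param ceiling Saturation ceiling of the high-gain channel.
#' @param seed Optional integer seed.
#' @return Plate data frame with `plate`, `row`, `col`, `size`, `fluor_low`,
#'   `fluor_high`, `saturated_high`.
#' @export
simulate_fluor_array <- function(truth, layout,
                                 bkg_level = 100, ref_abundance = 20,
                                 size_base = 1, noise_cv = 0.1,
                                 spatial_type = "bumps",
                                 spatial_amplitude = 0.15,
                                 gain_low = 1, gain_high = 4,
                                 offset_low = 0, offset_high = 0,
                                 ceiling = Inf, seed = NULL) {
  if (!identical(attr(layout, "group_type"), "fluor4x4"))
    stop("layout must use the fluor4x4 group geometry")
  if (!is.null(seed)) set.seed(seed)
  dims <- attr(layout, "dim_plate")
  lay <- merge(layout, truth, by = "orf", all.x = TRUE, sort = FALSE)
  lay <- lay[order(lay$plate, lay$row, lay$col), , drop = FALSE]

  fl <- ifelse(lay$role %in% c("dummy", "background"), bkg_level,
        ifelse(lay$role == "reference", bkg_level * (1 + ref_abundance),
        ifelse(lay$role == "sample_minus",
               bkg_level * (1 + lay$abundance),
               bkg_level * (1 + lay$abundance * lay$fold))))
  sz <- ifelse(lay$role == "sample_plus",
               size_base * lay$tir1_effect, size_base)

  out <- vector("list", length(unique(lay$plate)))
  for (p in sort(unique(lay$plate))) {
    idx <- lay$plate == p
    field <- make_spatial_field(dims[1], dims[2], spatial_type,
                                spatial_amplitude)
    fcell <- field[cbind(lay$row[idx], lay$col[idx])]
    n <- sum(idx)
    itrue <- fl[idx] * fcell * rlnorm_cv(n, 1, noise_cv)
    strue <- sz[idx] * fcell * rlnorm_cv(n, 1, noise_cv)
    high_raw <- gain_high * itrue + offset_high
    out[[p]] <- data.frame(
      plate = p, row = lay$row[idx], col = lay$col[idx],
      size = strue,
      fluor_low = gain_low * itrue + offset_low,
      fluor_high = pmin(high_raw, ceiling),
      saturated_high = as.integer(high_raw > ceiling))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ground truth for a chemical-genetic interaction screen
#'
#' Each ORF gets a fitness under degron induction (`w_i`), a fitness under
#' the genotoxic agent (`w_ga`) and an interaction term `eps`; the expected
#' relative colony size in the double-perturbation condition is
#' `w_i * w_ga * (1 + eps)`. A configurable fraction of strains has impaired
#' single-condition fitness, emulating a library rich in sick strains.
#'
#' @param n_orfs Number of ORFs.
#' @param n_interactors Number of planted interactors.
#' @param eps Interaction term of planted interactors (0 elsewhere).
#' @param frac_impaired Fraction of ORFs with impaired `w_i`.
#' @param impaired_range Uniform range of impaired `w_i` values.
#' @param seed Optional integer seed.
#' @return Data frame with `orf`, `w_i`, `w_ga`, `eps`, `interactor`.
#' @export
make_screen_truth <- function(n_orfs, n_interactors = 0L, eps = -0.4,
                              frac_impaired = 0.15,
                              impaired_range = c(0.4, 0.9),
                              seed = NULL) {
  stopifnot(n_orfs >= 1, n_interactors <= n_orfs)
  if (!is.null(seed)) set.seed(seed)
  w_i <- rep(1, n_orfs)
  imp <- stats::runif(n_orfs) < frac_impaired
  w_i[imp] <- stats::runif(sum(imp), impaired_range[1], impaired_range[2])
  w_ga <- rep(1, n_orfs)
  impg <- stats::runif(n_orfs) < frac_impaired / 2
  w_ga[impg] <- stats::runif(sum(impg), 0.7, 0.95)
  e <- rep(0, n_orfs)
  # interactors are planted on strains with healthy single-condition
  # fitness: genuine resistance factors grow normally without the agent,
  # and an interaction on a strain with w_i * w_ga < 0.5 is below the
  # score threshold by construction
  healthy <- which(w_i == 1 & w_ga == 1)
  if (n_interactors > length(healthy))
    stop("not enough healthy strains to plant interactors on")
  hit <- if (n_interactors > 0L) sample(healthy, n_interactors)
         else integer(0)
  e[hit] <- eps
  data.frame(orf = sprintf("ORF%04d", seq_len(n_orfs)),
             w_i = w_i, w_ga = w_ga, eps = e,
             interactor = as.integer(seq_len(n_orfs) %in% hit))
}

#' Simulate colony-size plates for the four screen conditions
#'
#' Produces one plate per condition (control, degron inducer `iaa`,
#' genotoxic agent `ga`, and the combination `both`) on a `fitness2x2`
#' layout. Before spatial effects and noise, the expected colony size of an
#' ORF is `size_base` in control, `size_base * w_i` under the inducer,
#' `size_base * w_ga` under the agent and `size_base * w_i * w_ga * (1+eps)`
#' under both — the multiplicative fitness model with interaction `eps`.
#'
#' @param truth Truth table from [make_screen_truth()].
#' @param layout A `fitness2x2` layout from [make_layout()].
#' @param size_base Baseline colony size.
#' @param noise_cv Lognormal noise CV.
#' @param spatial_type,spatial_amplitude Spatial field settings.
#' @param seed Optional integer seed.
#' @return Named list of plate data frames (`control`, `iaa`, `ga`, `both`),
#'   each with `plate`, `row`, `col`, `size`.
#' @export
simulate_screen <- function(truth, layout, size_base = 1, noise_cv = 0.05,
                            spatial_type = "bumps", spatial_amplitude = 0.15,
                            seed = NULL) {
  if (!identical(attr(layout, "group_type"), "fitness2x2"))
    stop("layout must use the fitness2x2 group geometry")
  if (!is.null(seed)) set.seed(seed)
  dims <- attr(layout, "dim_plate")
  lay <- merge(layout, truth, by = "orf", all.x = TRUE, sort = FALSE)
  lay <- lay[order(lay$plate, lay$row, lay$col), , drop = FALSE]
  w <- cbind(control = rep(1, nrow(lay)),
             iaa = lay$w_i,
             ga = lay$w_ga,
             both = lay$w_i * lay$w_ga * (1 + lay$eps))
  w[is.na(w)] <- 1  # dummy border colonies grow normally
  conds <- colnames(w)
  out <- stats::setNames(vector("list", length(conds)), conds)
  for (cond in conds) {
    plates <- vector("list", length(unique(lay$plate)))
    for (p in sort(unique(lay$plate))) {
      idx <- lay$plate == p
      field <- make_spatial_field(dims[1], dims[2], spatial_type,
                                  spatial_amplitude)
      fcell <- field[cbind(lay$row[idx], lay$col[idx])]
      plates[[p]] <- data.frame(
        plate = p, row = lay$row[idx], col = lay$col[idx],
        size = size_base * w[idx, cond] * fcell *
          rlnorm_cv(sum(idx), 1, noise_cv))
    }
    df <- do.call(rbind, plates)
    rownames(df) <- NULL
    out[[cond]] <- df
  }
  out
}
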
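# Seeded generators for the two assay inputs: broth-microdilution plates
# (step OD profile around a true MIC) and four-parameter logistic
# dose-response curves (percent viability vs concentration).

#' Standard twofold microdilution series
#'
#' Descending twofold dilution series of the kind used in broth
#' microdilution MIC testing, e.g. 128, 64, ..., 0.06 ug/mL.
#'
#' @param max_conc Highest concentration in ug/mL.
#' @param n_wells Number of wells (dilution steps).
#' @return Numeric vector, strictly descending, each step half the previous.
#' @export
twofold_series <- function(max_conc = 128, n_wells = 12L) {
  stopifnot(max_conc > 0, is_count(n_wells))
  max_conc / 2^(0:(n_wells - 1L))
}

#' Simulate a broth-microdilution plate
#'
#' Wells at concentrations at or above the true MIC read blank OD (no
#' growth); wells below read the growth OD; Gaussian noise is added to all.
#'
#' @param concentrations Descending twofold series in ug/mL (each step
#'   within 1% of half the previous).
#' @param mic_true True MIC in ug/mL (may lie outside the series).
#' @param od_growth OD of a well with full growth.
#' @param od_blank OD of a sterile/no-growth well.
#' @param noise_sd SD of Gaussian OD noise.
#' @param growth_margin OD margin above blank that counts as visible growth
#'   when the plate is read (stored on the plate).
#' @param seed Integer seed.
#' @return An object of class `plate_assay`: list with `concentrations`,
#'   `od` (named by concentration), `od_blank`, `growth_margin`.
#' @export
gen_plate <- function(concentrations = twofold_series(), mic_true,
                      od_growth = 0.5, od_blank = 0.05, noise_sd = 0,
                      growth_margin = 0.05, seed = 1) {
  concentrations <- check_series(concentrations)
  stopifnot(mic_true > 0, od_growth > 0, od_blank >= 0, noise_sd >= 0)
  od <- ifelse(concentrations >= mic_true, od_blank, od_growth)
  if (noise_sd > 0)
    od <- with_seed(seed, od + stats::rnorm(length(od), 0, noise_sd))
  plate_assay(concentrations, od, od_blank = od_blank,
              growth_margin = growth_margin)
}

# Validate the descending twofold invariant (1% tolerance per step).
check_series <- function(concentrations) {
  stopifnot(is.numeric(concentrations), length(concentrations) >= 2L,
            all(concentrations > 0))
  ratio <- concentrations[-length(concentrations)] / concentrations[-1L]
  if (any(abs(ratio - 2) > 0.02))
    stop("concentrations must form a descending twofold series",
         call. = FALSE)
  concentrations
}

#' Construct a microdilution plate record
#'
#' @inheritParams gen_plate
#' @param od Optical densities, one per concentration (same order).
#' @return A `plate_assay` object.
#' @export
plate_assay <- function(concentrations, od, od_blank = 0.05,
                        growth_margin = 0.05) {
  concentrations <- check_series(concentrations)
  stopifnot(length(od) == length(concentrations), is.finite(od),
            od_blank >= 0, growth_margin > 0)
  structure(list(concentrations = concentrations,
                 od = stats::setNames(as.numeric(od),
                                      format(concentrations, trim = TRUE)),
                 od_blank = od_blank, growth_margin = growth_margin),
            class = "plate_assay")
}

#' Simulate a four-parameter logistic dose-response curve
#'
#' Viability follows
#' \eqn{v(c) = bottom + (top - bottom) / (1 + (c/IC_{50})^{hill})}
#' with additive Gaussian noise, mimicking an ATP viability assay
#' normalized to vehicle control.
#'
#' @param ic50_true True IC50 in uM.
#' @param hill Hill slope (positive for viability decreasing with dose).
#' @param top,bottom Upper and lower asymptotes in percent viability.
#' @param concentrations Concentration series in uM.
#' @param noise_sd SD of Gaussian noise in percentage points.
#' @param seed Integer seed.
#' @return An object of class `dose_response`: data frame with columns
#'   `concentration` and `viability`.
#' @export
gen_dose_response <- function(ic50_true, hill = 1, top = 100, bottom = 0,
                              concentrations = 2218 / 2^(0:11),
                              noise_sd = 0, seed = 1) {
  stopifnot(ic50_true > 0, is.finite(hill), top >= bottom,
            all(concentrations > 0), noise_sd >= 0)
  v <- bottom + (top - bottom) / (1 + (concentrations / ic50_true)^hill)
  if (noise_sd > 0)
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
  dose_response(concentrations, v)
}

#' Construct a dose-response record
#'
#' @param concentrations Concentrations in uM.
#' @param viability Percent viability relative to vehicle control.
#' @return A `dose_response` data frame.
#' @export
dose_response <- function(concentrations, viability) {
  stopifnot(all(concentrations > 0), is.finite(viability),
            length(concentrations) == length(viability))
  structure(data.frame(concentration = as.numeric(concentrations),
                       viability = as.numeric(viability)),
            class = c("dose_response", "data.frame"))
}
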
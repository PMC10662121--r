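# Assay arithmetic: CFU/mL from plate counts, broth-microdilution MIC
# calls, vehicle-control viability normalization and variable-slope
# four-parameter logistic (4PL) IC50 fitting.

#' Colony-forming units per millilitre
#'
#' `CFU/mL = dilution factor x mean colony count / volume plated (mL)`.
#'
#' @param dilution_factor Fold dilution of the plated culture.
#' @param mean_colonies Mean number of distinct colonies counted.
#' @param volume_plated_ml Volume plated in mL.
#' @return CFU per mL.
#' @examples
#' cfu_per_ml(1e5, 120, 0.1)  # 1.2e8
#' @export
cfu_per_ml <- function(dilution_factor, mean_colonies, volume_plated_ml) {
  stopifnot(dilution_factor > 0, mean_colonies >= 0)
  if (!is.numeric(volume_plated_ml) || volume_plated_ml <= 0)
    stop("volume plated must be positive", call. = FALSE)
  dilution_factor * mean_colonies / volume_plated_ml
}

#' Call the MIC from a microdilution plate
#'
#' A well shows growth when its OD exceeds `od_blank + growth_margin`
#' (the numeric proxy for "visible growth"). The MIC is the lowest
#' concentration with no growth and no growth at any higher concentration.
#' All-growth plates are right-censored (`"> max"`); all-clear plates are
#' left-censored (`"<= min"`). A growth well above a no-growth well is a
#' non-monotone pattern: the call is flagged with a warning and the MIC is
#' the lowest concentration above the highest growth well.
#'
#' @param plate A [plate_assay()].
#' @return An object of class `mic_call`: `value` (ug/mL, `NA` when
#'   right-censored), `operator` (`"="`, `">"`, `"<="`), `call` (printed
#'   form such as `"> 128 ug/mL"`), `flagged`.
#' @export
read_mic <- function(plate) {
  stopifnot(inherits(plate, "plate_assay"))
  conc <- plate$concentrations             # descending
  growth <- unname(plate$od) > plate$od_blank + plate$growth_margin
  mk <- function(value, operator, flagged = FALSE) {
    txt <- switch(operator,
                  "=" = format(value, trim = TRUE),
                  ">" = paste(">", format(max(conc), trim = TRUE)),
                  "<=" = paste("<=", format(min(conc), trim = TRUE)))
    structure(list(value = value, operator = operator,
                   call = paste(txt, "ug/mL"), flagged = flagged),
              class = "mic_call")
  }
  if (all(growth)) return(mk(NA_real_, ">"))
  if (!any(growth)) return(mk(min(conc), "<="))
  hi_growth <- min(which(growth))          # highest concentration with growth
  # non-monotone: a no-growth well at a concentration below a growth well
  flagged <- any(!growth[seq(hi_growth, length(conc))])
  if (flagged)
    warning("non-monotone growth pattern; MIC taken above the highest ",
            "growth well", call. = FALSE)
  if (hi_growth == 1L) return(mk(NA_real_, ">", flagged))
  mk(conc[hi_growth - 1L], "=", flagged)
}

#' @export
print.mic_call <- function(x, ...) {
  cat("MIC:", x$call, if (x$flagged) "(flagged: non-monotone plate)" else "",
      "\n")
  invisible(x)
}

#' Normalize viability readouts to a vehicle control
#'
#' `viability% = 100 x treated / vehicle`, the percent-of-control scale of
#' an ATP-based cytotoxicity assay.
#'
#' @param concentrations Concentrations in uM.
#' @param treated_readouts Raw readouts (e.g. luminescence) of treated
#'   wells, one per concentration.
#' @param vehicle_readout Readout of the paired vehicle control.
#' @return A [dose_response()] object.
#' @export
normalize_viability <- function(concentrations, treated_readouts,
                                vehicle_readout) {
  stopifnot(vehicle_readout > 0,
            length(treated_readouts) == length(concentrations))
  dose_response(concentrations, 100 * treated_readouts / vehicle_readout)
}

#' Fit a variable-slope four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' \deqn{v(c) = bottom + \frac{top - bottom}{1 + (c/IC_{50})^{hill}}}
#' with the IC50 parameterized on the log-concentration scale. The fit is
#' deterministic: a fixed multi-start grid over log-IC50 (data quantiles)
#' and Hill slope, each refined by Levenberg-Marquardt
#' ([minpack.lm::nlsLM]), keeping the lowest residual sum of squares.
#' The Hill slope is unconstrained in sign.
#'
#' @param dr A [dose_response()] (or data frame with `concentration`,
#'   `viability`).
#' @param flat_tol Fits are refused when the viability range is below this
#'   (IC50 unidentifiable on flat data).
#' @return An object of class `four_pl`: `ic50`, `hill`, `top`, `bottom`,
#'   `residual_norm`, plus the fitted [stats::nls] object and the data.
#' @examples
#' dr <- gen_dose_response(ic50_true = 500, hill = 1.2)
#' fit <- fit_4pl(dr)
#' coef(fit)
#' @export
fit_4pl <- function(dr, flat_tol = 1) {
  stopifnot(is.data.frame(dr),
            all(c("concentration", "viability") %in% names(dr)))
  conc <- dr$concentration; v <- dr$viability
  if (length(unique(conc)) < 5L)
    stop("need at least 5 distinct concentrations", call. = FALSE)
  if (diff(range(v)) < flat_tol)
    stop("flat dose-response data: IC50 unidentifiable", call. = FALSE)
  lc <- log(conc)
  dat <- data.frame(lc = lc, v = v)
  starts <- expand.grid(
    logic50 = stats::quantile(lc, c(0.2, 0.35, 0.5, 0.65, 0.8),
                              names = FALSE),
    hill = c(-3, -1.5, -0.7, 0.7, 1.5, 3))
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + exp(hill * (lc - logic50))),
        data = dat,
        start = list(bottom = min(v), top = max(v),
                     hill = starts$hill[i], logic50 = starts$logic50[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss - 1e-12) { best <- fit; best_rss <- rss }
  }
  if (is.null(best))
    stop("4PL fit failed to converge from every start; check the data",
         call. = FALSE)
  cf <- stats::coef(best)
  top <- max(cf[["top"]], cf[["bottom"]])
  bottom <- min(cf[["top"]], cf[["bottom"]])
  hill <- if (cf[["top"]] >= cf[["bottom"]]) cf[["hill"]] else -cf[["hill"]]
  structure(list(ic50 = exp(cf[["logic50"]]), hill = hill, top = top,
                 bottom = bottom,
                 residual_norm = sqrt(best_rss / length(v)),
                 fit = best, data = dat),
            class = "four_pl")
}

#' @export
coef.four_pl <- function(object, ...) {
  c(ic50 = object$ic50, hill = object$hill, top = object$top,
    bottom = object$bottom)
}

#' @export
print.four_pl <- function(x, ...) {
  cat("Four-parameter logistic fit\n")
  cat(sprintf("  IC50: %.4g   Hill: %.3g   top: %.4g   bottom: %.4g\n",
              x$ic50, x$hill, x$top, x$bottom))
  cat(sprintf("  RMS residual: %.3g\n", x$residual_norm))
  invisible(x)
}

#' @export
predict.four_pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) exp(object$data$lc)
          else if (is.data.frame(newdata)) newdata$concentration
          else as.numeric(newdata)
  object$bottom + (object$top - object$bottom) /
    (1 + (conc / object$ic50)^object$hill)
}

#' @export
residuals.four_pl <- function(object, ...) {
  object$data$v - predict(object)
}

#' @export
plot.four_pl <- function(x, ...) {
  conc <- exp(x$data$lc)
  graphics::plot(conc, x$data$v, log = "x", xlab = "Concentration",
                 ylab = "Viability (%)", pch = 16, ...)
  grid_c <- exp(seq(min(x$data$lc), max(x$data$lc), length.out = 200))
  graphics::lines(grid_c, predict(x, grid_c), col = "firebrick", lwd = 2)
  graphics::abline(v = x$ic50, lty = 2, col = "grey40")
  invisible(x)
}
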
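# Light climate inside a dense algal suspension.
#
# All intensities are photosynthetically active radiation in
# umol photons m^-2 s^-1; dry matter is ug mL^-1. No unit conversion layer.

#' Mean light intensity in a cell suspension
#'
#' Computes the Lambert-Beer average of light across a vessel from the
#' incident intensity at the front face and the transmitted intensity at the
#' rear face: `I_m = (I_i - I_t) / ln(I_i / I_t)`. As the suspension clears
#' (`I_t -> I_i`) the formula tends continuously to `I_i`; inputs with
#' `|I_i - I_t| / I_i < 1e-9` are treated as that limit.
#'
#' @param I_i Incident intensity (umol photons m^-2 s^-1), `> 0`. Vectorised.
#' @param I_t Transmitted intensity, `0 < I_t <= I_i`. Vectorised.
#' @return Mean intensity, same units; always in `[I_t, I_i]`.
#' @examples
#' mean_light_intensity(500, 250)  # 360.67
#' mean_light_intensity(110, 55)   # 79.35
#' @export
mean_light_intensity <- function(I_i, I_t) {
  if (length(I_i) != length(I_t)) {
    n <- max(length(I_i), length(I_t))
    I_i <- rep_len(I_i, n)
    I_t <- rep_len(I_t, n)
  }
  if (any(I_i <= 0)) stop("incident intensity must be positive")
  if (any(I_t <= 0)) stop("transmitted intensity must be positive")
  if (any(I_t > I_i * (1 + 1e-12))) {
    stop("transmitted intensity cannot exceed incident intensity")
  }
  out <- numeric(length(I_i))
  lim <- abs(I_i - I_t) / I_i < 1e-9
  out[lim] <- I_i[lim]
  out[!lim] <- (I_i[!lim] - I_t[!lim]) / log(I_i[!lim] / I_t[!lim])
  out
}

#' Invert the mean-light formula for the transmitted intensity
#'
#' Given `I_i` and a measured mean intensity `I_m`, finds the transmitted
#' intensity `I_t` such that [mean_light_intensity()]`(I_i, I_t) == I_m`.
#' The mean is strictly increasing in `I_t`, so monotone bisection on
#' `(0, I_i]` converges; tolerance 1e-10 absolute on `I_t`, at most 200
#' iterations.
#'
#' @param I_i Incident intensity, `> 0`.
#' @param I_m Mean intensity, `0 < I_m < I_i` (equality `I_m = I_i` returns
#'   `I_i` exactly).
#' @return Transmitted intensity solving the formula.
#' @export
invert_mean_light <- function(I_i, I_m) {
  if (length(I_i) > 1L || length(I_m) > 1L) {
    return(mapply(invert_mean_light, I_i, I_m))
  }
  if (I_i <= 0) stop("incident intensity must be positive")
  if (I_m <= 0) stop("mean intensity must be positive")
  if (I_m > I_i) stop("mean intensity cannot exceed incident intensity")
  if (abs(I_i - I_m) / I_i < 1e-9) return(I_i)
  lo <- I_i * .Machine$double.xmin
  hi <- I_i
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (mean_light_intensity(I_i, mid) < I_m) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  if (hi - lo >= 1e-10) stop("bisection did not converge")
  (lo + hi) / 2
}

#' Saturating optical-depth attenuation model
#'
#' The optical depth of the suspension as a function of dry-matter density X
#' is modelled as `tau(X) = c1 * X / (1 + c2 * X)`, with transmitted fraction
#' `exp(-tau(X))`. A pure Beer-Lambert law (constant specific attenuation,
#' `c2 = 0`) overestimates shading at high density; the saturating form
#' accounts for the package effect and scattering in dense cultures.
#'
#' @param c1 Optical-depth scale (per ug mL^-1), `> 0`.
#' @param c2 Saturation constant (per ug mL^-1), `>= 0`.
#' @param residuals Optional fit residuals (in optical depth), kept for
#'   provenance when the model comes from [calibrate_attenuation()].
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(c1, c2, residuals = numeric(0)) {
  stopifnot(is.numeric(c1), length(c1) == 1L, is.finite(c1),
            is.numeric(c2), length(c2) == 1L, is.finite(c2))
  if (c1 <= 0) stop("c1 must be positive")
  if (c2 < 0) stop("c2 must be nonnegative")
  structure(list(c1 = c1, c2 = c2, residuals = as.numeric(residuals)),
            class = "attenuation_model")
}

#' @export
print.attenuation_model <- function(x, ...) {
  cat("Saturating optical-depth model: tau(X) = c1*X / (1 + c2*X)\n")
  cat(sprintf("  c1 = %.6g per ug/mL, c2 = %.6g per ug/mL\n", x$c1, x$c2))
  if (length(x$residuals)) {
    cat(sprintf("  calibration RMS residual (optical depth): %.4g\n",
                sqrt(mean(x$residuals^2))))
  }
  invisible(x)
}

#' Optical depth at a given dry-matter density
#'
#' @param X Dry matter (ug mL^-1), `>= 0`. Vectorised.
#' @param model An [attenuation_model()].
#' @return Optical depth `tau(X)`; zero at `X = 0`, nondecreasing in X.
#' @export
optical_depth <- function(X, model) {
  stopifnot(inherits(model, "attenuation_model"))
  if (any(X < 0)) stop("dry matter must be nonnegative")
  model$c1 * X / (1 + model$c2 * X)
}

#' Transmitted intensity through a suspension of given density
#'
#' @param I_i Incident intensity, `> 0`.
#' @param X Dry matter (ug mL^-1), `>= 0`. Vectorised.
#' @param model An [attenuation_model()].
#' @return `I_i * exp(-tau(X))`; equals `I_i` at `X = 0`.
#' @export
transmitted_intensity <- function(I_i, X, model) {
  if (any(I_i <= 0)) stop("incident intensity must be positive")
  I_i * exp(-optical_depth(X, model))
}

#' Calibrate the attenuation model from (incident, mean, dry-matter) anchors
#'
#' Each anchor is first inverted with [invert_mean_light()] to obtain the
#' implied optical depth `tau* = ln(I_i / I_t)`; the two parameters of the
#' saturating model are then fitted to the `tau*` values by least squares
#' (Gauss-Newton via [stats::nls()], started from the linearisation
#' `1/tau = c2/c1 + (1/c1)(1/X)`).
#'
#' @param anchors Data frame with columns `incident`, `mean`, `dry_matter`
#'   (at least two rows with distinct `dry_matter`).
#' @return A fitted [attenuation_model()] carrying the fit residuals.
#' @export
calibrate_attenuation <- function(anchors) {
  anchors <- as.data.frame(anchors)
  need <- c("incident", "mean", "dry_matter")
  if (!all(need %in% names(anchors))) {
    stop("anchors must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(anchors) < 2L || length(unique(anchors$dry_matter)) < 2L) {
    stop("at least two anchors with distinct dry matter are required")
  }
  if (any(anchors$mean <= 0)) stop("mean intensities must be positive")
  if (any(anchors$mean > anchors$incident)) {
    stop("mean intensity cannot exceed incident intensity")
  }
  I_t <- invert_mean_light(anchors$incident, anchors$mean)
  tau <- log(anchors$incident / I_t)
  X <- anchors$dry_matter
  dat <- data.frame(tau = tau, X = X)
  # linearised start; fall back to a Beer-Lambert slope if degenerate
  start <- tryCatch({
    lin <- stats::lm(I(1 / tau) ~ I(1 / X), data = dat)
    c1 <- 1 / stats::coef(lin)[[2]]
    c2 <- stats::coef(lin)[[1]] * c1
    if (!is.finite(c1) || c1 <= 0) stop("degenerate")
    list(c1 = c1, c2 = max(c2, 0))
  }, error = function(e) list(c1 = mean(tau / X), c2 = 0))
  fit <- stats::nls(tau ~ c1 * X / (1 + c2 * X), data = dat,
                    start = start,
                    control = stats::nls.control(maxiter = 200,
                                                 scaleOffset = 1,
                                                 warnOnly = TRUE))
  cf <- stats::coef(fit)
  attenuation_model(cf[["c1"]], max(cf[["c2"]], 0),
                    residuals = as.numeric(stats::resid(fit)))
}

#' Packaged calibration anchors and the default attenuation model
#'
#' `light_anchors()` returns the six (incident, mean, dry-matter) endpoint
#' anchors measured at the start (dry matter 100 ug/mL) and end of the cell
#' cycle at incident intensities 500, 250 and 110 umol photons m^-2 s^-1.
#' `default_attenuation_model()` calibrates the saturating model on them.
#'
#' @return `light_anchors()`: a data frame with columns `incident`, `mean`,
#'   `dry_matter`; `default_attenuation_model()`: an [attenuation_model()].
#' @export
light_anchors <- function() {
  path <- system.file("extdata", "light_anchors.csv",
                      package = "multifission", mustWork = TRUE)
  utils::read.csv(path)
}

#' @rdname light_anchors
#' @export
default_attenuation_model <- function() {
  calibrate_attenuation(light_anchors())
}

#' Mean light intensity along a dry-matter time series
#'
#' Elementwise composition of [transmitted_intensity()] and
#' [mean_light_intensity()]: the self-shading feedback used by the culture
#' engine. Strictly nonincreasing when the dry-matter series is nondecreasing.
#'
#' @param I_i Incident intensity, `> 0`.
#' @param X_series Numeric vector of dry-matter densities, all `>= 0`.
#' @param model An [attenuation_model()].
#' @return Numeric vector of mean intensities, same length as `X_series`.
#' @export
mean_light_trajectory <- function(I_i, X_series, model) {
  if (length(X_series) == 0L) return(numeric(0))
  bad <- which(X_series < 0)
  if (length(bad)) {
    stop("negative dry matter at index ", bad[1L])
  }
  I_t <- transmitted_intensity(I_i, X_series, model)
  mean_light_intensity(rep_len(I_i, length(I_t)), I_t)
}

#' Read anchors / write a fitted model to disk
#'
#' `read_light_anchors()` reads a CSV with header
#' `incident,mean,dry_matter`. `write_attenuation_model()` serialises a
#' fitted model as JSON (`{c1, c2, residuals}`);
#' `read_attenuation_model()` reads it back.
#'
#' @param path File path.
#' @param model An [attenuation_model()].
#' @return The anchors data frame, the path (invisibly), or the model.
#' @export
read_light_anchors <- function(path) {
  anchors <- utils::read.csv(path)
  need <- c("incident", "mean", "dry_matter")
  if (!all(need %in% names(anchors))) {
    stop("anchor file must have columns: ", paste(need, collapse = ", "))
  }
  anchors
}

#' @rdname read_light_anchors
#' @export
write_attenuation_model <- function(model, path) {
  stopifnot(inherits(model, "attenuation_model"))
  jsonlite::write_json(list(c1 = model$c1, c2 = model$c2,
                            residuals = model$residuals),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_light_anchors
#' @export
read_attenuation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  attenuation_model(x$c1, x$c2, residuals = x$residuals)
}
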
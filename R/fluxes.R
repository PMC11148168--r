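# Extracellular glucose/lactate flux arithmetic, normalised to well area.

#' Medium assay for one well
#'
#' Start/end glucose and lactate concentrations for a labelling/culture
#' window, with the volume, duration and plate needed to convert
#' concentration changes into per-area fluxes. "Start" is typically the naive
#' medium baseline.
#'
#' @param start_glucose,end_glucose Glucose, mM.
#' @param start_lactate,end_lactate Lactate, mM.
#' @param volume Medium volume, uL.
#' @param duration Assay duration, h.
#' @param plate A [plate_format()] or catalogue name.
#' @return A list of class `medium_assay`.
#' @examples
#' medium_assay(25, 13, 0, 8, volume = 1000, duration = 16, plate = "12-well")
#' @export
medium_assay <- function(start_glucose, end_glucose, start_lactate,
                         end_lactate, volume, duration, plate) {
  conc <- c(start_glucose, end_glucose, start_lactate, end_lactate)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0 (mM)", call. = FALSE)
  }
  if (!is.finite(volume) || volume <= 0) stop("'volume' must be > 0 (uL)", call. = FALSE)
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0 (h)", call. = FALSE)
  structure(
    list(start_glucose = start_glucose, end_glucose = end_glucose,
         start_lactate = start_lactate, end_lactate = end_lactate,
         volume = volume, duration = duration, plate = as_plate_format(plate)),
    class = "medium_assay"
  )
}

#' Glucose uptake and lactate production fluxes
#'
#' Converts concentration changes to per-area fluxes
#' (mM * uL = nmol; divided by growth area in mm^2 and duration in h):
#' uptake = (startG - endG) * V / (A * t), production = (endL - startL) *
#' V / (A * t), both in nmol/mm^2/h.
#'
#' The headline lactate/glucose summary, `lactate_glucose_fraction`, is
#' defined as lactate production / (2 * glucose uptake): the fraction of
#' consumed glucose carbon exported as lactate, since each glucose yields at
#' most two lactates. On this convention fully anaerobic glycolysis gives
#' 1.0; the raw molar ratio (which can reach 2.0) is also returned as
#' `lactate_glucose_molar_ratio`.
#'
#' Fluxes can come out negative when a concentration moved the "wrong" way
#' (net glucose release or lactate consumption); these are reported as-is and
#' flagged. A zero or negative uptake makes the fraction undefined (NA,
#' flagged).
#'
#' @param a A [medium_assay()].
#' @return A list of class `flux_record` with fields `glucose_uptake`,
#'   `lactate_production` (nmol/mm^2/h), `lactate_glucose_fraction`,
#'   `lactate_glucose_molar_ratio` and `flags`.
#' @examples
#' compute_fluxes(medium_assay(25, 13, 0, 8, 1000, 16, "12-well"))
#' @export
compute_fluxes <- function(a) {
  stopifnot(inherits(a, "medium_assay"))
  area <- a$plate$growth_area
  per <- a$volume / (area * a$duration)
  uptake <- (a$start_glucose - a$end_glucose) * per
  production <- (a$end_lactate - a$start_lactate) * per
  flags <- character(0)
  if (uptake < 0) flags <- c(flags, "negative_glucose_uptake")
  if (production < 0) flags <- c(flags, "negative_lactate_production")
  if (uptake > 0) {
    ratio <- production / uptake
    fraction <- ratio / 2
  } else {
    ratio <- NA_real_
    fraction <- NA_real_
    flags <- c(flags, "fraction_undefined")
  }
  structure(
    list(glucose_uptake = uptake, lactate_production = production,
         lactate_glucose_fraction = fraction,
         lactate_glucose_molar_ratio = ratio, flags = flags),
    class = "flux_record"
  )
}

#' @export
print.flux_record <- function(x, ...) {
  cat(sprintf(
    "<flux_record> glucose uptake %.3f, lactate production %.3f nmol/mm^2/h; lactate fraction %.3f%s\n",
    x$glucose_uptake, x$lactate_production, x$lactate_glucose_fraction,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""
  ))
  invisible(x)
}

#' Fluxes for a table of medium assays
#'
#' @param tab Data frame with columns `start_glucose`, `end_glucose`,
#'   `start_lactate`, `end_lactate`, `volume_ul`, `duration_h`, `plate`.
#' @return The input with flux columns appended.
#' @export
compute_fluxes_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  need <- c("start_glucose", "end_glucose", "start_lactate", "end_lactate",
            "volume_ul", "duration_h", "plate")
  if (!all(need %in% names(tab))) {
    stop("input table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    r <- compute_fluxes(medium_assay(
      tab$start_glucose[i], tab$end_glucose[i], tab$start_lactate[i],
      tab$end_lactate[i], tab$volume_ul[i], tab$duration_h[i], tab$plate[i]
    ))
    data.frame(
      glucose_uptake = r$glucose_uptake,
      lactate_production = r$lactate_production,
      lactate_glucose_fraction = r$lactate_glucose_fraction,
      lactate_glucose_molar_ratio = r$lactate_glucose_molar_ratio,
      flags = paste(r$flags, collapse = ";")
    )
  })
  cbind(tab, do.call(rbind, recs))
}
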
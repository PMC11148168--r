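#' Multiwell plate formats
#'
#' A plate format records the growth area and well diameter of one well of a
#' standard multiwell culture plate. The growth area converts a medium volume
#' into the depth of the medium column, which is the diffusion length that
#' controls oxygen delivery to the monolayer.
#'
#' @param name Label for the format, e.g. `"12-well"`.
#' @param growth_area Growth area of one well, in mm^2.
#' @param well_diameter Well diameter, in mm.
#'
#' @details The growth area must be consistent with a circular well of the
#'   stated diameter to within 20%; vendor catalogues quote slightly different
#'   areas for the same nominal format, but a gross mismatch indicates a unit
#'   error.
#'
#' @return An object of class `plate_format`.
#' @examples
#' plate_format("12-well", growth_area = 380, well_diameter = 22.1)
#' @export
plate_format <- function(name, growth_area, well_diameter) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(growth_area) || growth_area <= 0) {
    stop("'growth_area' must be a positive number (mm^2)", call. = FALSE)
  }
  if (!is.finite(well_diameter) || well_diameter <= 0) {
    stop("'well_diameter' must be a positive number (mm)", call. = FALSE)
  }
  circ <- pi * (well_diameter / 2)^2
  if (abs(circ - growth_area) / growth_area > 0.20) {
    stop(sprintf(
      "growth_area (%.1f mm^2) inconsistent with diameter %.1f mm (circular area %.1f mm^2)",
      growth_area, well_diameter, circ
    ), call. = FALSE)
  }
  structure(
    list(name = name, growth_area = growth_area, well_diameter = well_diameter),
    class = "plate_format"
  )
}

#' @export
print.plate_format <- function(x, ...) {
  cat(sprintf(
    "<plate_format> %s: growth area %.1f mm^2, diameter %.1f mm\n",
    x$name, x$growth_area, x$well_diameter
  ))
  invisible(x)
}

#' Built-in plate catalogue
#'
#' Growth areas and well diameters for common multiwell formats, using typical
#' vendor values (96-well 32 mm^2, 24-well 190 mm^2, 12-well 380 mm^2, 6-well
#' 960 mm^2). Vendors differ by a few percent; pass a custom
#' [plate_format()] anywhere a plate is accepted, or supply a catalogue CSV
#' with columns `name, growth_area_mm2, well_diameter_mm` via `file`.
#'
#' @param file Optional path to a catalogue CSV overriding the built-in table.
#' @return A named list of [plate_format()] objects.
#' @examples
#' plate_catalogue()[["12-well"]]
#' @export
plate_catalogue <- function(file = NULL) {
  if (is.null(file)) {
    tab <- data.frame(
      name = c("6-well", "12-well", "24-well", "96-well"),
      growth_area_mm2 = c(960, 380, 190, 32),
      well_diameter_mm = c(34.8, 22.1, 15.5, 6.4),
      stringsAsFactors = FALSE
    )
  } else {
    tab <- utils::read.csv(file, stringsAsFactors = FALSE)
    need <- c("name", "growth_area_mm2", "well_diameter_mm")
    if (!all(need %in% names(tab))) {
      stop("catalogue file must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    plate_format(tab$name[i], tab$growth_area_mm2[i], tab$well_diameter_mm[i])
  })
  names(out) <- tab$name
  out
}

#' Look up a plate format by name
#'
#' @param plate A [plate_format()] object or the name of a catalogue entry.
#' @param catalogue Catalogue list, defaulting to [plate_catalogue()].
#' @return A `plate_format` object.
#' @export
as_plate_format <- function(plate, catalogue = plate_catalogue()) {
  if (inherits(plate, "plate_format")) return(plate)
  if (is.character(plate) && length(plate) == 1L) {
    if (!plate %in% names(catalogue)) {
      stop(sprintf("unknown plate format '%s' (catalogue has: %s)",
                   plate, paste(names(catalogue), collapse = ", ")),
           call. = FALSE)
    }
    return(catalogue[[plate]])
  }
  stop("'plate' must be a plate_format or a catalogue name", call. = FALSE)
}

#' Medium specification for one well
#'
#' Combines a medium volume with a plate format and a meniscus depression.
#' The meniscus pulls the medium surface down at the well centre, so the
#' column above the cells is shallower there than the flat-fill (nominal)
#' depth. The default depression of 0.23 mm is a calibration chosen so that
#' 1 mL in a 12-well plate gives a minimum depth of ~2.4 mm, matching direct
#' measurement of that configuration; it is not a capillary-physics model.
#'
#' @param volume Medium volume in uL (1 uL = 1 mm^3).
#' @param plate A [plate_format()] or catalogue name.
#' @param meniscus_depression Depth reduction at the well centre, mm.
#' @return An object of class `medium_spec`.
#' @examples
#' medium_spec(1000, "12-well")
#' @export
medium_spec <- function(volume, plate, meniscus_depression = 0.23) {
  plate <- as_plate_format(plate)
  if (!is.finite(volume) || volume <= 0) {
    stop("'volume' must be a positive number (uL)", call. = FALSE)
  }
  if (!is.finite(meniscus_depression) || meniscus_depression < 0) {
    stop("'meniscus_depression' must be >= 0 (mm)", call. = FALSE)
  }
  structure(
    list(volume = volume, plate = plate,
         meniscus_depression = meniscus_depression),
    class = "medium_spec"
  )
}

#' @export
print.medium_spec <- function(x, ...) {
  cat(sprintf(
    "<medium_spec> %.0f uL in %s (meniscus depression %.2f mm)\n",
    x$volume, x$plate$name, x$meniscus_depression
  ))
  invisible(x)
}

#' Flat-fill depth of the medium column
#'
#' Depth the medium would have if its surface were flat:
#' volume (mm^3) / growth area (mm^2). 1 uL = 1 mm^3.
#'
#' @param spec A [medium_spec()].
#' @return Depth in mm.
#' @examples
#' nominal_depth(medium_spec(1000, "12-well"))  # 1000/380 = 2.63 mm
#' @export
nominal_depth <- function(spec) {
  stopifnot(inherits(spec, "medium_spec"))
  spec$volume / spec$plate$growth_area
}

#' Minimum depth of the medium column at the well centre
#'
#' Nominal depth minus the meniscus depression. This is the shortest
#' diffusion path from the air-medium interface to the monolayer and hence
#' the depth the oxygen model uses for best-case delivery.
#'
#' @param spec A [medium_spec()].
#' @return Depth in mm.
#' @examples
#' minimum_depth(medium_spec(1000, "12-well"))  # ~2.40 mm
#' @export
minimum_depth <- function(spec) {
  stopifnot(inherits(spec, "medium_spec"))
  nom <- nominal_depth(spec)
  if (spec$meniscus_depression >= nom) {
    stop(sprintf(
      "meniscus depression (%.2f mm) >= nominal depth (%.2f mm): degenerate geometry",
      spec$meniscus_depression, nom
    ), call. = FALSE)
  }
  nom - spec$meniscus_depression
}
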
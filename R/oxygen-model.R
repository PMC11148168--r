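# Steady-state diffusion-consumption model of the medium column.
#
# Unit convention, fixed package-wide:
#   length mm, time s, flux fmol/mm^2/s, concentration uM.
#   1 uM = 1 nmol/cm^3 = 1000 fmol/mm^3, so a gradient of C uM over x mm
#   carries a diffusive flux J = D * C * 1000 / x fmol/mm^2/s.
UM_TO_FMOL_PER_MM3 <- 1000

#' Default oxygen diffusion coefficient in culture medium at 37 C
#'
#' 2.69e-3 mm^2/s (2.69e-5 cm^2/s), within the literature range for oxygen in
#' aqueous media at 37 C (~2.7-3.0e-5 cm^2/s) and calibrated so that a 181 uM
#' interface concentration over a 2.43 mm column delivers 200 fmol/mm^2/s.
#' @export
DEFAULT_D_O2 <- 2.69e-3

#' Default Henry solubility coefficient for oxygen at 37 C
#'
#' 181/140 = 1.2929 uM per mmHg, calibrated from the dissolved-concentration /
#' partial-pressure pair for humidified incubator air at 37 C (181 uM at
#' 140 mmHg).
#' @export
DEFAULT_ALPHA_O2 <- 181 / 140

#' Default critical oxygen concentration
#'
#' Concentration below which the monolayer can no longer respire maximally.
#' Closed-system respirometry of adipocyte monolayers shows maximal
#' respiration down to ~4 uM, supporting a near-step oxygen dependence.
#' @export
DEFAULT_CRITICAL_O2 <- 4

#' Medium column above a respiring monolayer
#'
#' @param depth_x Column depth (diffusion length) in mm.
#' @param diffusion_D Oxygen diffusion coefficient in mm^2/s.
#' @param c_interface Dissolved oxygen at the air-medium interface, uM.
#' @return An object of class `medium_column`.
#' @examples
#' medium_column(depth_x = 2.43)
#' @export
medium_column <- function(depth_x, diffusion_D = DEFAULT_D_O2,
                          c_interface = 181) {
  if (!is.finite(depth_x) || depth_x <= 0) {
    stop("'depth_x' must be a positive depth in mm", call. = FALSE)
  }
  if (!is.finite(diffusion_D) || diffusion_D <= 0) {
    stop("'diffusion_D' must be positive (mm^2/s)", call. = FALSE)
  }
  if (!is.finite(c_interface) || c_interface <= 0) {
    stop("'c_interface' must be positive (uM)", call. = FALSE)
  }
  structure(
    list(depth_x = depth_x, diffusion_D = diffusion_D,
         c_interface = c_interface),
    class = "medium_column"
  )
}

#' @export
print.medium_column <- function(x, ...) {
  cat(sprintf(
    "<medium_column> depth %.3f mm, D %.3g mm^2/s, interface O2 %.1f uM\n",
    x$depth_x, x$diffusion_D, x$c_interface
  ))
  invisible(x)
}

#' Oxygen demand of the monolayer
#'
#' Zero-order (oxygen-independent) areal consumption with a hard critical-O2
#' cutoff: the monolayer consumes `ocr_demand` as long as pericellular oxygen
#' stays above `critical_o2`, and delivery caps consumption otherwise.
#'
#' @param ocr_demand Demanded oxygen consumption rate, fmol/mm^2/s.
#' @param critical_o2 Concentration below which respiration cannot be
#'   sustained, uM.
#' @return An object of class `monolayer_demand`.
#' @export
monolayer_demand <- function(ocr_demand, critical_o2 = DEFAULT_CRITICAL_O2) {
  if (!is.finite(ocr_demand) || ocr_demand < 0) {
    stop("'ocr_demand' must be >= 0 (fmol/mm^2/s)", call. = FALSE)
  }
  if (!is.finite(critical_o2) || critical_o2 < 0) {
    stop("'critical_o2' must be >= 0 (uM)", call. = FALSE)
  }
  structure(list(ocr_demand = ocr_demand, critical_o2 = critical_o2),
            class = "monolayer_demand")
}

#' Maximum sustainable OCR through a medium column
#'
#' The steady-state diffusive flux when pericellular oxygen is drawn down to
#' zero: J_max = D * c_interface / depth, with 1 uM = 1000 fmol/mm^3. This is
#' the ceiling that diffusion places on monolayer respiration.
#'
#' @param col A [medium_column()].
#' @return Flux in fmol/mm^2/s.
#' @examples
#' max_ocr(medium_column(2.43))  # ~200 fmol/mm^2/s
#' max_ocr(medium_column(5))     # ~97 fmol/mm^2/s
#' @export
max_ocr <- function(col) {
  stopifnot(inherits(col, "medium_column"))
  col$diffusion_D * col$c_interface * UM_TO_FMOL_PER_MM3 / col$depth_x
}

#' Maximum medium depth that can sustain a demanded OCR
#'
#' Inverse of [max_ocr()]: x_max = D * c_interface / J. A column deeper than
#' this cannot deliver oxygen fast enough even with pericellular oxygen at
#' zero.
#'
#' @param ocr Demanded OCR, fmol/mm^2/s; must be > 0.
#' @param diffusion_D Diffusion coefficient, mm^2/s.
#' @param c_interface Interface oxygen, uM.
#' @return Depth in mm.
#' @examples
#' max_depth(200)  # ~2.43 mm
#' @export
max_depth <- function(ocr, diffusion_D = DEFAULT_D_O2, c_interface = 181) {
  if (!is.finite(ocr) || ocr <= 0) {
    stop("'ocr' must be > 0: zero demand has no finite depth limit",
         call. = FALSE)
  }
  diffusion_D * c_interface * UM_TO_FMOL_PER_MM3 / ocr
}

#' Solve pericellular oxygen for a demanded OCR
#'
#' At steady state with consumption confined to the monolayer, the flux
#' through the column is constant and the concentration profile linear. The
#' column can deliver at most
#' `capacity = D * (c_interface - critical_o2) / depth` while keeping
#' pericellular oxygen at or above the critical concentration. If demand is
#' within capacity the monolayer respires at its demand and pericellular
#' oxygen settles at `c_interface - demand * depth / D`; otherwise delivery
#' caps respiration at capacity and pericellular oxygen sits at the critical
#' concentration.
#'
#' @param col A [medium_column()].
#' @param demand A [monolayer_demand()].
#' @return An object of class `oxygen_solution` with fields `realised_ocr`
#'   (fmol/mm^2/s), `c_pericellular` (uM) and `limited` (logical).
#' @examples
#' solve_pericellular(medium_column(2.43), monolayer_demand(200, critical_o2 = 0))
#' @export
solve_pericellular <- function(col, demand) {
  stopifnot(inherits(col, "medium_column"), inherits(demand, "monolayer_demand"))
  if (col$c_interface <= demand$critical_o2) {
    # interface already below the respiration threshold: nothing can respire
    sol <- list(realised_ocr = 0, c_pericellular = col$c_interface,
                limited = demand$ocr_demand > 0)
    return(structure(sol, class = "oxygen_solution"))
  }
  k <- col$diffusion_D * UM_TO_FMOL_PER_MM3  # fmol/mm^2/s per (uM/mm)
  # same evaluation order as max_ocr() so that demand == capacity holds
  # exactly when the demand came from max_ocr() with critical_o2 = 0
  capacity <- col$diffusion_D * (col$c_interface - demand$critical_o2) *
    UM_TO_FMOL_PER_MM3 / col$depth_x
  if (demand$ocr_demand <= capacity) {
    sol <- list(
      realised_ocr = demand$ocr_demand,
      c_pericellular = col$c_interface - demand$ocr_demand * col$depth_x / k,
      limited = FALSE
    )
  } else {
    sol <- list(
      realised_ocr = capacity,
      c_pericellular = demand$critical_o2,
      limited = TRUE
    )
  }
  structure(sol, class = "oxygen_solution")
}

#' @export
print.oxygen_solution <- function(x, ...) {
  cat(sprintf(
    "<oxygen_solution> realised OCR %.1f fmol/mm^2/s, pericellular O2 %.1f uM%s\n",
    x$realised_ocr, x$c_pericellular,
    if (x$limited) " [diffusion-limited]" else ""
  ))
  invisible(x)
}

#' Oxygen concentration at a height above the monolayer
#'
#' With consumption confined to the monolayer the steady-state flux is the
#' same at every height, so the profile is linear:
#' c(h) = c_pericellular + realised_ocr * h / D. Optical sensor lids sample
#' this profile over a window (typically 0.55-0.95 mm above the cells) to
#' estimate both the gradient (hence OCR) and pericellular oxygen by
#' extrapolation.
#'
#' @param sol An [solve_pericellular()] solution.
#' @param col The [medium_column()] the solution was computed for.
#' @param h Height above the monolayer, mm; vectorised. Must lie in
#'   `[0, depth]`.
#' @return Concentration(s) in uM.
#' @export
profile_at_height <- function(sol, col, h) {
  stopifnot(inherits(sol, "oxygen_solution"), inherits(col, "medium_column"))
  if (any(!is.finite(h)) || any(h < 0) || any(h > col$depth_x + 1e-12)) {
    stop(sprintf("height(s) must lie within [0, %.3f] mm", col$depth_x),
         call. = FALSE)
  }
  k <- col$diffusion_D * UM_TO_FMOL_PER_MM3
  sol$c_pericellular + sol$realised_ocr * h / k
}

#' Convert oxygen partial pressure to dissolved concentration
#'
#' Henry's law: c = alpha * p.
#'
#' @param p Partial pressure, mmHg; vectorised, must be >= 0.
#' @param alpha Solubility coefficient, uM per mmHg.
#' @return Concentration in uM.
#' @examples
#' mmhg_to_um(140)  # 181 uM
#' @export
mmhg_to_um <- function(p, alpha = DEFAULT_ALPHA_O2) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("partial pressure must be >= 0", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  alpha * p
}

#' Convert dissolved oxygen concentration to partial pressure
#'
#' Henry's law: p = c / alpha. Use `round_mmhg()` to match the integer-mmHg
#' reporting convention.
#'
#' @param c Concentration, uM; vectorised, must be >= 0.
#' @param alpha Solubility coefficient, uM per mmHg.
#' @return Partial pressure in mmHg.
#' @examples
#' round_mmhg(um_to_mmhg(38))  # 29 mmHg
#' @export
um_to_mmhg <- function(c, alpha = DEFAULT_ALPHA_O2) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("concentration must be >= 0", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be > 0", call. = FALSE)
  c / alpha
}

#' Round a partial pressure to integer mmHg (half away from zero)
#'
#' @param p mmHg values.
#' @return Integer mmHg.
#' @export
round_mmhg <- function(p) {
  sign(p) * floor(abs(p) + 0.5)
}

#' Dissolved oxygen for a given incubator oxygen percentage
#'
#' Converts a headspace oxygen fraction to dissolved concentration assuming
#' water-saturated gas at 37 C: c = alpha * (pct/100) * (baro - p_h2o).
#'
#' @param pct Incubator oxygen, percent of the gas phase.
#' @param alpha Henry coefficient, uM/mmHg.
#' @param barometric Total pressure, mmHg.
#' @param p_h2o Water vapour pressure at 37 C, mmHg.
#' @return Concentration in uM.
#' @export
incubator_o2_um <- function(pct, alpha = DEFAULT_ALPHA_O2,
                            barometric = 760, p_h2o = 47) {
  if (!is.finite(pct) || pct < 0 || pct > 100) {
    stop("'pct' must be in [0, 100]", call. = FALSE)
  }
  mmhg_to_um(pct / 100 * (barometric - p_h2o), alpha)
}

#' Full oxygen report for a culture condition
#'
#' Convenience wrapper wiring plate geometry into the column model: computes
#' nominal and minimum depths from the medium spec, solves the pericellular
#' oxygen problem at both depths, and evaluates the profile over a sensor
#' window.
#'
#' @param spec A [medium_spec()].
#' @param ocr_demand Demanded OCR, fmol/mm^2/s.
#' @param c_interface Interface oxygen, uM.
#' @param diffusion_D Diffusion coefficient, mm^2/s.
#' @param critical_o2 Critical oxygen, uM.
#' @param sensor_heights Heights above the monolayer for the profile, mm.
#' @return A list of class `oxygen_report` with one entry per depth
#'   (`minimum`, `nominal`), each holding the column, solution, capacity and a
#'   data frame `profile` with columns `height_mm`, `o2_um`.
#' @examples
#' oxygen_report(medium_spec(1000, "12-well"), ocr_demand = 200)
#' @export
oxygen_report <- function(spec, ocr_demand,
                          c_interface = 181,
                          diffusion_D = DEFAULT_D_O2,
                          critical_o2 = DEFAULT_CRITICAL_O2,
                          sensor_heights = seq(0.55, 0.95, length.out = 5)) {
  stopifnot(inherits(spec, "medium_spec"))
  demand <- monolayer_demand(ocr_demand, critical_o2)
  depths <- c(minimum = minimum_depth(spec), nominal = nominal_depth(spec))
  out <- lapply(names(depths), function(nm) {
    col <- medium_column(depths[[nm]], diffusion_D, c_interface)
    sol <- solve_pericellular(col, demand)
    hts <- sensor_heights[sensor_heights <= col$depth_x]
    list(
      depth_mm = col$depth_x,
      capacity_fmol_mm2_s = max_ocr(col),
      realised_ocr = sol$realised_ocr,
      c_pericellular_um = sol$c_pericellular,
      limited = sol$limited,
      profile = data.frame(height_mm = hts,
                           o2_um = profile_at_height(sol, col, hts))
    )
  })
  names(out) <- names(depths)
  structure(out, class = "oxygen_report")
}

#' @export
print.oxygen_report <- function(x, ...) {
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf(
      "%s depth %.2f mm: capacity %.1f, realised OCR %.1f fmol/mm^2/s, pericellular O2 %.1f uM%s\n",
      nm, e$depth_mm, e$capacity_fmol_mm2_s, e$realised_ocr,
      e$c_pericellular_um, if (e$limited) " [limited]" else ""
    ))
  }
  invisible(x)
}
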
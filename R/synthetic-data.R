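# Seeded generators for every input the pipeline consumes. All generators
# are pure functions of (spec, seed): the seed is mandatory and the global
# RNG state is left untouched.

# run expr with a local RNG seeded at `seed`, restoring global state after
.with_local_seed <- function(seed, expr) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("'seed' is required for synthetic-data generation", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# lognormal multiplicative noise factors with mean 1 and coefficient of
# variation cv (sdlog^2 = log(1 + cv^2))
.lognormal_factors <- function(n, cv) {
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic MIDA observation table
#'
#' Forward-simulates GC-MS isotopologue envelopes of a fatty-acid methyl
#' ester under deuterated-water labelling: the true fractional pattern from
#' [predict_observed()] at (f, p, N), scaled to raw intensities and
#' perturbed by per-ion multiplicative lognormal noise (mean 1, given CV) —
#' the standard noise model for GC-MS peak areas. Rows are emitted raw;
#' window normalisation is the analysis pipeline's job.
#'
#' @param f,p,N True fractional synthesis, precursor enrichment and
#'   exchangeable-site number.
#' @param formula Formula of the measured derivative (default methyl
#'   palmitate, `"C17H34O2"`).
#' @param noise_cv Per-ion multiplicative noise CV (0 = noise-free).
#' @param n_replicates Number of replicate rows.
#' @param seed RNG seed (required).
#' @param fatty_acid Fatty-acid label for the table.
#' @param amount_nmol Optional true fatty-acid amount per well, nmol.
#' @param intensity_scale Total raw intensity per row (arbitrary units).
#' @param window Ion window size.
#' @return A data frame in the [run_mida_table()] input format.
#' @examples
#' gen_mida_dataset(f = 0.25, p = 0.08, N = 14, noise_cv = 0.01,
#'                  n_replicates = 3, seed = 1)
#' @export
gen_mida_dataset <- function(f, p, N, formula = "C17H34O2", noise_cv = 0,
                             n_replicates = 1L, seed,
                             fatty_acid = "palmitate",
                             amount_nmol = NA_real_,
                             intensity_scale = 1e6, window = 5L) {
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  nat <- natural_pattern(formula, window)
  truth <- predict_observed(f, p, N, nat)$fractions
  .with_local_seed(seed, {
    rows <- lapply(seq_len(n_replicates), function(i) {
      noisy <- truth * intensity_scale * .lognormal_factors(window, noise_cv)
      row <- data.frame(sample = sprintf("sim%03d", i),
                        fatty_acid = fatty_acid,
                        formula = paste0(names(molecular_formula(formula)),
                                         as.integer(molecular_formula(formula)),
                                         collapse = ""),
                        stringsAsFactors = FALSE)
      for (k in seq_len(window)) row[[paste0("m", k - 1L)]] <- noisy[k]
      row$amount_nmol <- amount_nmol
      row
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic oxygen sensor trace
#'
#' Solves the steady-state column model for the stated culture condition and
#' samples the linear concentration profile at the probe heights, adding
#' Gaussian measurement noise (the noise model for optical oxygen sensing).
#' Default heights span the 0.55-0.95 mm window that sensor-lid micro-probes
#' scan above the monolayer.
#'
#' @param ocr_demand Demanded OCR, fmol/mm^2/s.
#' @param plate Plate format or catalogue name.
#' @param volume_ul Medium volume, uL.
#' @param heights Probe heights above the monolayer, mm.
#' @param noise_sd Additive Gaussian noise SD, uM (0 = noise-free).
#' @param seed RNG seed (required).
#' @param c_interface Interface oxygen, uM.
#' @param diffusion_D Diffusion coefficient, mm^2/s.
#' @param critical_o2 Critical oxygen, uM.
#' @param meniscus_depression Meniscus depression for the depth calculation, mm.
#' @return A data frame with columns `height_mm`, `o2_um`, plus the realised
#'   OCR and limitation flag as attributes `realised_ocr` and `limited`.
#' @examples
#' gen_oxygen_trace(200, "96-well", 100, noise_sd = 0, seed = 1)
#' @export
gen_oxygen_trace <- function(ocr_demand, plate, volume_ul,
                             heights = seq(0.55, 0.95, length.out = 5),
                             noise_sd = 0, seed,
                             c_interface = 181, diffusion_D = DEFAULT_D_O2,
                             critical_o2 = DEFAULT_CRITICAL_O2,
                             meniscus_depression = 0.23) {
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  spec <- medium_spec(volume_ul, plate, meniscus_depression)
  col <- medium_column(minimum_depth(spec), diffusion_D, c_interface)
  if (any(heights < 0) || any(heights > col$depth_x)) {
    stop(sprintf("probe heights must lie within the column [0, %.3f mm]",
                 col$depth_x), call. = FALSE)
  }
  sol <- solve_pericellular(col, monolayer_demand(ocr_demand, critical_o2))
  clean <- profile_at_height(sol, col, heights)
  o2 <- .with_local_seed(seed, clean + stats::rnorm(length(heights), 0, noise_sd))
  out <- data.frame(height_mm = heights, o2_um = o2)
  attr(out, "realised_ocr") <- sol$realised_ocr
  attr(out, "limited") <- sol$limited
  out
}

#' Generate a synthetic medium assay
#'
#' Computes the endpoint glucose and lactate concentrations produced by the
#' stated true per-area fluxes over the assay window, then applies
#' multiplicative lognormal noise (mean 1, given CV) to the four measured
#' concentrations. With `noise_cv = 0`, [compute_fluxes()] on the result
#' returns the true fluxes exactly.
#'
#' @param glucose_uptake True glucose uptake, nmol/mm^2/h.
#' @param lactate_production True lactate production, nmol/mm^2/h.
#' @param volume_ul Medium volume, uL.
#' @param duration_h Assay duration, h.
#' @param plate Plate format or catalogue name.
#' @param start_glucose,start_lactate Starting concentrations, mM.
#' @param noise_cv Assay noise CV (0 = noise-free).
#' @param seed RNG seed (required).
#' @return A [medium_assay()].
#' @examples
#' gen_medium_assay(2, 1.3, 1000, 16, "12-well", noise_cv = 0, seed = 1)
#' @export
gen_medium_assay <- function(glucose_uptake, lactate_production, volume_ul,
                             duration_h, plate, start_glucose = 25,
                             start_lactate = 0, noise_cv = 0, seed) {
  plate <- as_plate_format(plate)
  per <- plate$growth_area * duration_h / volume_ul  # mm^2 h / uL
  end_glucose <- start_glucose - glucose_uptake * per
  end_lactate <- start_lactate + lactate_production * per
  if (end_glucose < 0) {
    stop("true fluxes exhaust glucose before the end of the assay", call. = FALSE)
  }
  conc <- .with_local_seed(
    seed,
    c(start_glucose, end_glucose, start_lactate, end_lactate) *
      .lognormal_factors(4L, noise_cv)
  )
  medium_assay(conc[1], conc[2], conc[3], conc[4], volume_ul, duration_h, plate)
}
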
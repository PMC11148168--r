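# Exact arithmetic on mass-isotopomer distributions.
#
# A pattern is the vector of fractional abundances of the ions M+0 .. M+k
# over a fixed window (default 5, M0-M4). Truncated patterns are kept
# UN-normalised internally: the mass beyond the window is real and simply not
# represented, so truncated windows sum to <= 1. Observed instrument data, by
# contrast, arrive as fractional concentrations over the window and are
# window-normalised on ingestion; model predictions are window-normalised
# only at the point where they are compared with observations.

# Fixed isotope abundances (IUPAC representative values), pinned as constants
# for reproducibility. Each element maps to the abundance vector over mass
# shifts +0, +1, +2, ...
.ISOTOPE_ABUNDANCES <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  O = c(0.99757, 0.00038, 0.00205),
  N = c(0.99636, 0.00364),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

.INTEGER_MASSES <- c(C = 12, H = 1, O = 16, N = 14, S = 32)

#' Parse a molecular formula
#'
#' Accepts Hill-like strings such as `"C17H34O2"`. Supported elements:
#' C, H, O, N, S.
#'
#' @param x Formula string, or an already-parsed `molecular_formula`.
#' @return A named integer vector of element counts with class
#'   `molecular_formula`.
#' @examples
#' molecular_formula("C17H34O2")  # methyl palmitate
#' @export
molecular_formula <- function(x) {
  if (inherits(x, "molecular_formula")) return(x)
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  parts <- regmatches(x, list(tokens))[[1]]
  if (sum(nchar(parts)) != nchar(x)) {
    stop(sprintf("cannot parse formula '%s'", x), call. = FALSE)
  }
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!el %in% names(.INTEGER_MASSES)) {
      stop(sprintf("unsupported element '%s' (supported: %s)",
                   el, paste(names(.INTEGER_MASSES), collapse = ", ")),
           call. = FALSE)
    }
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  if (sum(counts) < 1L) stop("formula must contain at least one atom", call. = FALSE)
  structure(counts, class = "molecular_formula")
}

#' @export
print.molecular_formula <- function(x, ...) {
  nz <- x[x > 0]
  cat("<molecular_formula> ",
      paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = ""),
      " (nominal mass ", nominal_mass(x), " Da)\n", sep = "")
  invisible(x)
}

#' Nominal (integer) mass of a formula
#'
#' Sum of integer isotope masses (C = 12, H = 1, O = 16, N = 14, S = 32).
#' Anchors the M+0 ion of the extracted window, e.g. m/z 270 for methyl
#' palmitate (C17H34O2).
#'
#' @param f Formula string or [molecular_formula()].
#' @return Integer mass in Da.
#' @examples
#' nominal_mass("C17H34O2")  # 270
#' @export
nominal_mass <- function(f) {
  f <- molecular_formula(f)
  sum(.INTEGER_MASSES[names(f)] * as.integer(f))
}

#' Construct an isotope pattern
#'
#' @param fractions Numeric vector of abundances for M+0, M+1, ... in order.
#' @param normalise If `TRUE`, rescale to sum to 1 over the window (use for
#'   observed fractional concentrations; raw intensities are accepted and
#'   normalised). If `FALSE` (default) the values are kept as given, which is
#'   how truncated theoretical patterns retain their implicit tail mass.
#' @return An object of class `isotope_pattern`.
#' @export
isotope_pattern <- function(fractions, normalise = FALSE) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 2L) stop("window size must be >= 2", call. = FALSE)
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("pattern fractions must be finite and >= 0", call. = FALSE)
  }
  if (normalise) {
    s <- sum(fractions)
    if (s <= 0) stop("cannot normalise an all-zero pattern", call. = FALSE)
    fractions <- fractions / s
  }
  structure(
    list(fractions = fractions, window_size = length(fractions)),
    class = "isotope_pattern"
  )
}

#' @export
print.isotope_pattern <- function(x, ...) {
  v <- sprintf("%.4f", x$fractions)
  names(v) <- paste0("M", seq_along(v) - 1L)
  cat("<isotope_pattern> ")
  print(v, quote = FALSE)
  invisible(x)
}

#' Window-normalise a pattern
#'
#' Rescales the fractions to sum to 1 over the window: the operation applied
#' to observed fractional concentrations on ingestion and to model
#' predictions at the comparison step of a fit.
#'
#' @param x An [isotope_pattern()].
#' @return A normalised `isotope_pattern`.
#' @export
normalise_pattern <- function(x) {
  stopifnot(inherits(x, "isotope_pattern"))
  isotope_pattern(x$fractions, normalise = TRUE)
}

# truncated Cauchy product of two abundance vectors; coefficients below the
# window are exact regardless of truncation of the operands
.convolve_vec <- function(a, b, window) {
  out <- numeric(window)
  for (i in seq_len(window)) {
    j <- seq_len(i)
    ai <- a[j]
    bi <- b[i - j + 1L]
    ai[is.na(ai)] <- 0
    bi[is.na(bi)] <- 0
    out[i] <- sum(ai * bi)
  }
  out
}

#' Convolve two isotope patterns
#'
#' Cauchy product truncated to the common window. This is the operation that
#' superimposes independent isotope sources: for window 5 it reproduces
#' exactly the ion-by-ion expansion
#' `Mxn = sum_{i+j=x} M'i * Mj` used to correct a deuterium labelling
#' pattern for natural carbon/oxygen isotopes.
#'
#' @param a,b [isotope_pattern()] objects with equal windows.
#' @return An `isotope_pattern` over the same window.
#' @export
convolve_patterns <- function(a, b) {
  stopifnot(inherits(a, "isotope_pattern"), inherits(b, "isotope_pattern"))
  if (a$window_size != b$window_size) {
    stop("patterns have different windows: ", a$window_size, " vs ",
         b$window_size, call. = FALSE)
  }
  isotope_pattern(.convolve_vec(a$fractions, b$fractions, a$window_size))
}

#' Binomial deuterium labelling pattern
#'
#' Relative abundances of the ions of a molecule that drew `N` hydrogens from
#' a water pool with deuterium fraction `p`:
#' `M'x = choose(N, x) * p^x * (1-p)^(N-x)`. The full distribution over
#' x = 0..N sums to 1; the returned window keeps the leading terms without
#' renormalising, so the tail mass beyond the window stays implicit.
#'
#' @param p Precursor deuterium enrichment, in `[0, 1)`.
#' @param N Number of exchangeable hydrogen sites (integer >= 1).
#' @param window Window size (number of ions), default 5.
#' @return An `isotope_pattern`.
#' @examples
#' deuterium_pattern(0.08, 14)
#' @export
deuterium_pattern <- function(p, N, window = 5L) {
  if (!is.finite(p) || p < 0 || p >= 1) {
    stop("'p' must lie in [0, 1)", call. = FALSE)
  }
  if (!is.finite(N) || N < 1 || N != round(N)) {
    stop("'N' must be a positive integer", call. = FALSE)
  }
  x <- seq_len(window) - 1L
  isotope_pattern(stats::dbinom(x, size = N, prob = p))
}

#' Natural-abundance isotope envelope of a formula
#'
#' Theoretical isotopologue distribution from fixed natural abundances
#' (13C 1.07%, 2H 0.0115%, 17O 0.038%, 18O 0.205%, plus N and S), computed by
#' per-element polynomial expansion and convolution, truncated to the window.
#' Leading coefficients are exact despite the truncation.
#'
#' @param f Formula string or [molecular_formula()].
#' @param window Window size, default 5.
#' @param abundances Optional override of the per-element abundance vectors
#'   (a named list like the built-in table).
#' @return An `isotope_pattern` (unnormalised; sums to <= 1).
#' @examples
#' natural_pattern("C17H34O2")  # M0 ~ 0.826, M1 ~ 0.156
#' @export
natural_pattern <- function(f, window = 5L, abundances = NULL) {
  f <- molecular_formula(f)
  abund <- .ISOTOPE_ABUNDANCES
  if (!is.null(abundances)) abund[names(abundances)] <- abundances
  acc <- c(1, numeric(window - 1L))
  for (el in names(f)) {
    n <- as.integer(f[[el]])
    if (n == 0L) next
    base <- abund[[el]]
    for (i in seq_len(n)) acc <- .convolve_vec(acc, base, window)
  }
  isotope_pattern(acc)
}
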
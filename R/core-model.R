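#' Arcsine-square-root transform of a signal fraction
#'
#' Variance-stabilising transform applied to allele signal ratios before
#' mixture fitting: `asr(f) = asin(sqrt(f))`. Fractions in `[0, 1]` map
#' monotonically onto `[0, pi/2]`.
#'
#' @param f Numeric vector of fractions in `[0, 1]`. `NA` is passed through.
#' @return Numeric vector of transformed values in `[0, pi/2]`.
#' @seealso [asr_inv()] for the inverse.
#' @examples
#' asr(c(0, 0.02, 0.5, 0.98, 1))
#' @export
asr <- function(f) {
  bad <- !is.na(f) & (f < 0 | f > 1)
  if (any(bad)) {
    stop("asr(): fraction outside [0, 1]: ", paste(utils::head(f[bad], 3), collapse = ", "))
  }
  asin(sqrt(f))
}

#' Inverse arcsine-square-root transform
#'
#' @param y Numeric vector on the transformed scale, in `[0, pi/2]`.
#' @return Fractions in `[0, 1]`: `sin(y)^2`.
#' @export
asr_inv <- function(y) {
  bad <- !is.na(y) & (y < -1e-12 | y > pi / 2 + 1e-12)
  if (any(bad)) {
    stop("asr_inv(): value outside [0, pi/2]")
  }
  pmin(1, pmax(0, sin(y)^2))
}

#' Allele signal ratio and total intensity from raw two-channel signals
#'
#' For raw channel intensities `s_a` (allele a, e.g. GoldenGate `Raw_X`) and
#' `s_b` (allele b, `Raw_Y`) computes the allele signal ratio
#' `s_a / (s_a + s_b)` and the total signal intensity
#' `sqrt(s_a^2 + s_b^2)` used by the low-intensity pre-filter. Records with
#' zero total signal have no defined ratio and are returned as `NA` (callers
#' drop them and count them as invalid).
#'
#' @param s_a,s_b Non-negative numeric vectors of raw channel intensities.
#' @return A tibble with columns `ratio` and `intensity`.
#' @examples
#' signal_ratio(c(3000, 3200, 0), c(1000, 0, 0))
#' @export
signal_ratio <- function(s_a, s_b) {
  if (length(s_a) != length(s_b)) {
    stop("signal_ratio(): s_a and s_b must have equal length")
  }
  bad <- (!is.na(s_a) & s_a < 0) | (!is.na(s_b) & s_b < 0)
  if (any(bad)) {
    stop("signal_ratio(): negative intensity")
  }
  tot <- s_a + s_b
  ratio <- ifelse(!is.na(tot) & tot > 0, s_a / tot, NA_real_)
  tibble::tibble(ratio = ratio, intensity = sqrt(s_a^2 + s_b^2))
}

#' Dosage-response mean model parameters
#'
#' Constructs the parameter set of one of the four parametric models relating
#' allele dosage to the expected signal fraction. All parameters are ratios of
#' the physical per-channel signal coefficients: `c1` and `c2` are the a- and
#' b-channel backgrounds relative to the a-channel sensitivity, `r` is the
#' ratio of b- to a-channel sensitivity, and `d` is the relative quadratic
#' curvature of the dose response (models 3 and 4 only). Models 2 and 4 share
#' a single background `c1 = c2 = c`.
#'
#' @param model Integer model id in `1:4`.
#' @param c1 Non-negative a-channel background (models 1 and 3).
#' @param c2 Non-negative b-channel background (models 1 and 3).
#' @param c Non-negative common background (models 2 and 4); if supplied it
#'   overrides `c1`/`c2`.
#' @param r Positive sensitivity ratio of the b to the a channel.
#' @param d Non-negative curvature coefficient (models 3 and 4; forced to 0
#'   for models 1 and 2).
#' @return An object of class `mean_model_params` (a named list).
#' @examples
#' mean_model_params(2, c = 0.1, r = 1.2)
#' @export
mean_model_params <- function(model, c1 = 0, c2 = 0, c = NULL, r = 1, d = 0) {
  if (!model %in% 1:4) stop("mean_model_params(): model must be in 1:4")
  if (model %in% c(2, 4)) {
    if (!is.null(c)) c1 <- c2 <- c
    if (c1 != c2) stop("mean_model_params(): models 2 and 4 require c1 == c2")
  } else if (!is.null(c)) {
    c1 <- c2 <- c
  }
  if (model %in% c(1, 2)) d <- 0
  if (c1 < 0 || c2 < 0) stop("mean_model_params(): backgrounds must be >= 0")
  if (r <= 0) stop("mean_model_params(): r must be > 0")
  if (d < 0) stop("mean_model_params(): d must be >= 0")
  structure(
    list(model = as.integer(model), c1 = c1, c2 = c2, r = r, d = d),
    class = "mean_model_params"
  )
}

#' @export
print.mean_model_params <- function(x, ...) {
  cat(sprintf(
    "<mean_model_params> model %d: c1 = %.4g, c2 = %.4g, r = %.4g, d = %.4g\n",
    x$model, x$c1, x$c2, x$r, x$d
  ))
  invisible(x)
}

#' Expected transformed signal for a given allele dosage
#'
#' Evaluates the dosage-response model on the transformed scale. With `x` the
#' dosage of allele a (0-4) the expected a-channel share is
#' `(c1 + x + d*x^2) / (c1 + x + d*x^2 + c2 + r*(4 - x) + r*d*(4 - x)^2)`
#' (models 1 and 2 have `d = 0`), and the component mean is its
#' arcsine-square-root transform. Both channels share the same relative
#' curvature `d`, scaled by the channel sensitivity.
#'
#' @param params A [mean_model_params()] object.
#' @param dosage Integer vector of allele-a dosages in `0:4`.
#' @return Numeric vector of component means on the transformed scale.
#' @examples
#' mean_model(mean_model_params(1, r = 1), 0:4)
#' @export
mean_model <- function(params, dosage = 0:4) {
  stopifnot(inherits(params, "mean_model_params"))
  if (any(!dosage %in% 0:4)) stop("mean_model(): dosage must be in 0:4")
  x <- dosage
  num <- params$c1 + x + params$d * x^2
  den <- num + params$c2 + params$r * (4 - x) + params$r * params$d * (4 - x)^2
  if (any(den <= 0)) stop("mean_model(): non-positive denominator")
  asr(num / den)
}

#' Hardy-Weinberg mixing proportions for a tetraploid
#'
#' Returns the five genotype-class probabilities implied by Hardy-Weinberg
#' equilibrium at allele frequency `p`, ordered by ascending dosage of allele
#' a (nulliplex to quadruplex). `p` is the frequency of allele b, so the
#' nulliplex-a class has probability `p^4` and the quadruplex-a class
#' `(1 - p)^4`; the a-allele frequency is `1 - p`.
#'
#' @param p Allele-b frequency in `[0, 1]`.
#' @return Numeric 5-vector summing to 1.
#' @examples
#' hwe_proportions(0.5)
#' @export
hwe_proportions <- function(p) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("hwe_proportions(): p must be a single value in [0, 1]")
  }
  dbinom(0:4, size = 4, prob = 1 - p)
}

#' Number of free parameters of a mixture variant
#'
#' Parameter count used in the BIC penalty: mean-model parameters (3, 2, 4
#' and 3 for models 1-4), plus one for the common standard deviation, plus 4
#' for free mixing proportions or 1 for the HWE allele frequency.
#'
#' @param model Integer model id in `1:4`.
#' @param hwe Logical; are the mixing proportions HWE-constrained?
#' @return Integer parameter count `k`.
#' @examples
#' n_parameters(2, hwe = TRUE)
#' @export
n_parameters <- function(model, hwe) {
  if (!model %in% 1:4) stop("n_parameters(): model must be in 1:4")
  mean_k <- c(3L, 2L, 4L, 3L)[model]
  mean_k + 1L + if (isTRUE(hwe)) 1L else 4L
}
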
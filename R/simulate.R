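#' Ground-truth simulation settings for one marker
#'
#' Describes one synthetic bi-allelic marker assayed on a tetraploid panel:
#' the dosage-response model and its parameters, the genotype-class
#' proportions (Hardy-Weinberg at allele-b frequency `p`, or explicit), the
#' noise level and where the noise acts, the raw-intensity distribution, and
#' optional planted failure modes mirroring the patterns seen in real arrays.
#'
#' Failure modes override parts of the configuration:
#' \describe{
#'   \item{`monomorphic`}{all samples share one dosage (quadruplex).}
#'   \item{`diffuse`}{noise raised to `sigma = 0.25`, far above the
#'     dispersion filter, producing an unclear ratio histogram.}
#'   \item{`wide_gap`}{sensitivity ratio `r` set to 5 so a wide gap opens
#'     between the quadruplex peak and its neighbour while the remaining
#'     peaks crowd together; the allele-b frequency is set to 0.1, emptying
#'     the dosage classes beyond the crowded side that would otherwise
#'     anchor the correct fit, and `sigma` to 0.035, a well-performing
#'     assay. Under these conditions the generic EM starts settle with a
#'     component inside the gap and the rescue start is what recovers the
#'     correct fit.}
#' }
#'
#' @param n_samples Number of samples.
#' @param model Dosage-response model id in `1:4`.
#' @param params A [mean_model_params()] object (defaults to model 2 with
#'   `c = 0.05` and `r` of 1).
#' @param p Allele-b frequency for HWE class proportions (used unless `pi` is
#'   given). Default 0.5.
#' @param pi Optional explicit 5-vector of genotype-class proportions
#'   (overrides `p`).
#' @param sigma Noise standard deviation on the transformed scale. Default
#'   0.04, typical of a well-performing assay.
#' @param noise_mode `"transformed"` (normal noise added to the transformed
#'   ratio, matching the fitted model exactly) or `"raw"` (multiplicative
#'   log-normal noise on the two raw channels).
#' @param intensity_scale Median total raw intensity. Default 10000.
#' @param intensity_cv Coefficient of variation of the total intensity.
#'   Default 0.3.
#' @param low_intensity_fraction Fraction of observations planted below the
#'   3200 intensity threshold. Default 0.
#' @param failure_mode `"none"`, `"monomorphic"`, `"diffuse"` or
#'   `"wide_gap"`.
#' @param seed Integer RNG seed; the same configuration and seed always
#'   reproduce the same records.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 224,
                       model = 2,
                       params = NULL,
                       p = 0.5,
                       pi = NULL,
                       sigma = 0.04,
                       noise_mode = c("transformed", "raw"),
                       intensity_scale = 10000,
                       intensity_cv = 0.3,
                       low_intensity_fraction = 0,
                       failure_mode = c("none", "monomorphic", "diffuse", "wide_gap"),
                       seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  failure_mode <- match.arg(failure_mode)
  if (is.null(params)) params <- mean_model_params(model, c = 0.05, r = 1)
  if (params$model != model) stop("sim_config(): params model id disagrees with model")
  if (failure_mode == "diffuse") sigma <- 0.25
  if (failure_mode == "wide_gap") {
    # the gap misfit is a start-configuration pathology: it needs a wide gap
    # (r far from 1) and no samples anchoring the dosage classes beyond the
    # crowded side (allele-b frequency 0.1 leaves the nulliplex- and
    # simplex-a classes empty), at the tight noise of a well-performing
    # assay. With anchoring samples present, or diffuse peaks, the generic
    # EM starts find the correct optimum directly and no rescue is needed.
    params <- mean_model_params(model,
      c1 = params$c1, c2 = params$c2,
      r = 5, d = params$d
    )
    if (is.null(pi)) p <- 0.1
    sigma <- 0.035
  }
  if (!is.null(pi)) {
    if (length(pi) != 5 || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
      stop("sim_config(): pi must be 5 non-negative values summing to 1")
    }
  }
  if (sigma < 0 || n_samples < 1) stop("sim_config(): invalid sigma or n_samples")
  if (low_intensity_fraction < 0 || low_intensity_fraction > 1) {
    stop("sim_config(): low_intensity_fraction must be in [0, 1]")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), model = as.integer(model),
      params = params, p = p, pi = pi, sigma = sigma,
      noise_mode = noise_mode, intensity_scale = intensity_scale,
      intensity_cv = intensity_cv,
      low_intensity_fraction = low_intensity_fraction,
      failure_mode = failure_mode, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate one marker's two-channel records with known truth
#'
#' Draws dosages from the configured class proportions, generates signal
#' ratios around the dosage-response means (noise either on the transformed
#' scale or multiplicatively on the raw channels), assigns each observation a
#' log-normally distributed total intensity, and emits raw two-channel
#' records in the assay dialect read by [read_assay()]. A configured fraction
#' of records is scaled below the intensity threshold to exercise the
#' pre-filter.
#'
#' @param config A [sim_config()] object.
#' @param marker_id Marker name for the emitted records.
#' @return A list with `data` (tibble: `marker`, `sample`, `X`, `Y`, `ratio`,
#'   `intensity`), `truth` (tibble: `marker`, `sample`, true `dosage`,
#'   `low_intensity` flag) and `config`.
#' @examples
#' sim <- simulate_marker(sim_config(n_samples = 50, seed = 42))
#' head(sim$data)
#' @export
simulate_marker <- function(config, marker_id = "SNP001") {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  withr_seed <- config$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  class_pi <- if (!is.null(config$pi)) config$pi else hwe_proportions(config$p)
  dosage <- if (config$failure_mode == "monomorphic") {
    rep(4L, n)
  } else {
    sample(0:4, n, replace = TRUE, prob = class_pi)
  }

  prm <- config$params
  if (config$noise_mode == "transformed") {
    mu <- mean_model(prm, 0:4)
    y <- mu[dosage + 1L] + rnorm(n, 0, config$sigma)
    y <- pmin(pi / 2, pmax(0, y))
    ratio <- asr_inv(y)
    # split a planted total intensity into the two channels at that ratio
    sdlog <- sqrt(log(1 + config$intensity_cv^2))
    intensity <- rlnorm(n, log(config$intensity_scale), sdlog)
    low <- .plant_low(n, config$low_intensity_fraction)
    intensity[low] <- runif(sum(low), 200, 3000)
    s_sum <- intensity / sqrt(ratio^2 + (1 - ratio)^2)
    X <- ratio * s_sum
    Y <- (1 - ratio) * s_sum
  } else {
    x <- dosage
    ea <- prm$c1 + x + prm$d * x^2
    eb <- prm$c2 + prm$r * (4 - x) + prm$r * prm$d * (4 - x)^2
    # scale so the median expected total intensity matches intensity_scale
    a1 <- config$intensity_scale / stats::median(sqrt(ea^2 + eb^2))
    sdlog <- sqrt(log(1 + config$sigma^2)) # sigma acts as per-channel CV here
    X <- a1 * ea * rlnorm(n, -sdlog^2 / 2, sdlog)
    Y <- a1 * eb * rlnorm(n, -sdlog^2 / 2, sdlog)
    low <- .plant_low(n, config$low_intensity_fraction)
    scl <- runif(sum(low), 200, 3000) / sqrt(X[low]^2 + Y[low]^2)
    X[low] <- X[low] * scl
    Y[low] <- Y[low] * scl
    ratio <- X / (X + Y)
    intensity <- sqrt(X^2 + Y^2)
  }

  samples <- sprintf("S%03d", seq_len(n))
  list(
    data = tibble::tibble(
      marker = marker_id, sample = samples,
      X = X, Y = Y, ratio = ratio, intensity = intensity
    ),
    truth = tibble::tibble(
      marker = marker_id, sample = samples,
      dosage = as.integer(dosage), low_intensity = low
    ),
    config = config
  )
}

.plant_low <- function(n, fraction) {
  n_low <- round(fraction * n)
  low <- rep(FALSE, n)
  if (n_low > 0) low[sample.int(n, n_low)] <- TRUE
  low
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a multi-marker assay panel
#'
#' Generates one long-format dataset covering several markers, each from its
#' own [sim_config()], in the exact dialect [read_assay()] reads, together
#' with a companion truth table. Per-marker seeds are derived
#' deterministically from `seed`, so the same call always produces identical
#' records.
#'
#' @param configs List of [sim_config()] objects, optionally named by marker.
#' @param seed Integer master seed; overrides the per-config seeds.
#' @return A list with `data` (rows of `marker`, `sample`, `X`, `Y`, `ratio`,
#'   `intensity`) and `truth` (rows of `marker`, `sample`, `dosage`,
#'   `low_intensity`).
#' @examples
#' panel <- simulate_panel(
#'   list(a = sim_config(n_samples = 60), b = sim_config(n_samples = 60, p = 0.2)),
#'   seed = 3
#' )
#' dplyr::count(panel$truth, marker, dosage)
#' @export
simulate_panel <- function(configs, seed = 1L) {
  stopifnot(length(configs) >= 1)
  ids <- names(configs)
  if (is.null(ids) || any(ids == "")) {
    ids <- sprintf("SNP%03d", seq_along(configs))
  }
  if (anyDuplicated(ids)) stop("simulate_panel(): duplicate marker ids")
  sims <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    cfg$seed <- (as.integer(seed) * 1009L + i * 7919L) %% .Machine$integer.max
    simulate_marker(cfg, marker_id = ids[i])
  })
  list(
    data = dplyr::bind_rows(lapply(sims, function(s) s$data)),
    truth = dplyr::bind_rows(lapply(sims, function(s) s$truth))
  )
}
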
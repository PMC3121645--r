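#' Options controlling marker fitting, calling and rejection
#'
#' Bundles the tunable thresholds of the calling pipeline. Defaults follow the
#' values used for Illumina GoldenGate potato data; the intensity threshold is
#' assay-specific and is skipped entirely for ratio-only input.
#'
#' @param intensity_threshold Observations with total signal intensity
#'   (`sqrt(s_a^2 + s_b^2)`) below this raw-unit threshold are removed before
#'   fitting. Default 3200.
#' @param min_intensity_fraction Minimum fraction of samples that must pass
#'   the intensity threshold for a marker to be fitted at all. Default 0.60.
#' @param call_prob Minimum posterior probability required to assign a dosage
#'   to a sample. Default 0.99.
#' @param min_call_fraction Minimum fraction of used samples that must receive
#'   a dosage for the marker to be retained. Default 0.60.
#' @param max_sigma Maximum fitted common standard deviation (transformed
#'   scale). Default 0.1.
#' @param max_peak_fraction Maximum fraction of the *assigned* samples allowed
#'   in a single dosage class. Default 0.85.
#' @param valley_check Reject fitted solutions in which a lower peak lies
#'   between higher peaks (not expected in a cross progeny or HWE population).
#'   Default `TRUE`; can be disabled.
#' @param min_n Minimum number of usable samples per marker. Default 10.
#' @param em See [em_control()].
#' @return A list of class `calling_options`.
#' @export
calling_options <- function(intensity_threshold = 3200,
                            min_intensity_fraction = 0.60,
                            call_prob = 0.99,
                            min_call_fraction = 0.60,
                            max_sigma = 0.1,
                            max_peak_fraction = 0.85,
                            valley_check = TRUE,
                            min_n = 10,
                            em = em_control(min_n = min_n)) {
  fr <- c(min_intensity_fraction, min_call_fraction, max_peak_fraction, call_prob)
  if (any(fr <= 0 | fr > 1)) stop("calling_options(): fractions must be in (0, 1]")
  if (intensity_threshold < 0 || max_sigma <= 0) {
    stop("calling_options(): thresholds must be positive")
  }
  structure(
    list(
      intensity_threshold = intensity_threshold,
      min_intensity_fraction = min_intensity_fraction,
      call_prob = call_prob,
      min_call_fraction = min_call_fraction,
      max_sigma = max_sigma,
      max_peak_fraction = max_peak_fraction,
      valley_check = valley_check,
      min_n = min_n,
      em = em
    ),
    class = "calling_options"
  )
}

#' Low-intensity pre-filter for one marker
#'
#' Drops observations whose total signal intensity falls below the threshold
#' and decides whether enough samples remain to fit the marker. Rows with no
#' `intensity` column (ratio-only input) are all retained.
#'
#' @param data Tibble of one marker's records with at least a `ratio` column
#'   and optionally `intensity`.
#' @param options A [calling_options()] object.
#' @return A list with `data` (retained rows), `pass` (logical), `n_total`
#'   and `n_used`.
#' @export
intensity_prefilter <- function(data, options = calling_options()) {
  n_total <- nrow(data)
  keep <- if ("intensity" %in% names(data)) {
    !is.na(data$intensity) & data$intensity >= options$intensity_threshold
  } else {
    rep(TRUE, n_total)
  }
  keep <- keep & !is.na(data$ratio)
  kept <- data[keep, , drop = FALSE]
  pass <- n_total > 0 &&
    nrow(kept) / n_total >= options$min_intensity_fraction &&
    nrow(kept) >= options$min_n
  list(data = kept, pass = pass, n_total = n_total, n_used = nrow(kept))
}

# the 8 model variants: 4 mean models x {HWE, free}
.variant_grid <- function() {
  tidyr::expand_grid(model = 1:4, hwe = c(TRUE, FALSE))
}

#' Fit all mixture variants from one or more start configurations
#'
#' Fits the eight model variants (four dosage-response mean models, each with
#' free or HWE-constrained mixing proportions) from every supplied start
#' configuration. Individual numerical failures are recorded, never fatal.
#'
#' @param y Transformed ratios for one marker.
#' @param options A [calling_options()] object.
#' @param starts Named list of start-mean 5-vectors, e.g.
#'   `list(clustering = ..., equidistant = ...)`.
#' @return A list of `mixture_fit` objects (failures omitted) with an
#'   attribute `n_failures`.
#' @export
fit_all_variants <- function(y, options = calling_options(),
                             starts = list(
                               clustering = tryCatch(
                                 start_means_clustering(y),
                                 error = function(e) NULL
                               ),
                               equidistant = start_means_equidistant()
                             )) {
  starts <- starts[!vapply(starts, is.null, logical(1))]
  grid <- .variant_grid()
  fits <- list()
  n_fail <- 0
  for (s in seq_along(starts)) {
    for (i in seq_len(nrow(grid))) {
      fit <- tryCatch(
        fit_mixture(y,
          model = grid$model[i], hwe = grid$hwe[i],
          start_means = starts[[s]], start_label = names(starts)[s],
          control = options$em
        ),
        tetradose_fit_failure = function(e) NULL
      )
      if (is.null(fit)) n_fail <- n_fail + 1 else fits[[length(fits) + 1]] <- fit
    }
  }
  attr(fits, "n_failures") <- n_fail
  fits
}

# assigned-sample counts per dosage class at the call threshold
.assigned_counts <- function(fit, call_prob) {
  calls <- assign_genotypes(fit$posteriors, call_prob)
  tabulate(calls + 1L, nbins = 5)
}

#' Detect a simplex or triplex component fitted into a wide signal gap
#'
#' When the channel sensitivities are very unequal a wide gap separates the
#' nulliplex or quadruplex peak from its neighbour, and EM sometimes parks the
#' simplex or triplex component inside that empty gap. The symptom tested
#' here: the triplex component has a lower mixing proportion *or* fewer
#' assigned samples than the components on both of its sides (and analogously
#' for the simplex component). The triplex side is checked first.
#'
#' @param fit A `mixture_fit`.
#' @param call_prob Posterior threshold used for provisional assignment.
#' @return `"none"`, `"simplex_in_gap"` or `"triplex_in_gap"`.
#' @export
detect_gap_misfit <- function(fit, call_prob = 0.99) {
  counts <- .assigned_counts(fit, call_prob)
  pi <- fit$pi
  in_gap <- function(j) {
    (pi[j] < pi[j - 1] && pi[j] < pi[j + 1]) ||
      (counts[j] < counts[j - 1] && counts[j] < counts[j + 1])
  }
  if (in_gap(4)) return("triplex_in_gap")
  if (in_gap(2)) return("simplex_in_gap")
  "none"
}

#' Rescue start means after a gap misfit
#'
#' Builds the third EM start configuration used after [detect_gap_misfit()]
#' flags a fit. If the triplex component sat in the gap, the duplex, simplex
#' and nulliplex means are promoted to triplex, duplex and simplex, and the
#' new nulliplex mean is placed halfway between the new simplex mean and 0.
#' The simplex case is the mirror image towards `pi/2`.
#'
#' @param means Numeric 5-vector of the flagged fit's component means.
#' @param which_gap `"simplex_in_gap"` or `"triplex_in_gap"`.
#' @return Numeric 5-vector of new start means.
#' @export
rescue_start_means <- function(means, which_gap) {
  stopifnot(length(means) == 5)
  switch(which_gap,
    triplex_in_gap = c(means[1] / 2, means[1], means[2], means[3], means[5]),
    simplex_in_gap = c(means[1], means[3], means[4], means[5], (means[5] + pi / 2) / 2),
    stop("rescue_start_means(): which_gap must name a gap side")
  )
}

#' Reject fitted solutions showing a valley pattern
#'
#' A fitted solution in which an interior dosage class has fewer assigned
#' samples than at least one class on each side (a lower peak between higher
#' peaks) is not expected in a cross progeny or an HWE population, and is
#' removed from the candidate set — unless every candidate is flagged, or the
#' check is disabled, in which case no solutions are rejected in this step.
#'
#' @param fits List of `mixture_fit` objects.
#' @param call_prob Posterior threshold for the assigned-sample counts.
#' @param enabled Logical; is the valley check active?
#' @return The surviving fits (same class of list).
#' @export
reject_valley_fits <- function(fits, call_prob = 0.99, enabled = TRUE) {
  if (!enabled || length(fits) == 0) return(fits)
  flagged <- vapply(fits, function(f) {
    counts <- .assigned_counts(f, call_prob)
    any(vapply(2:4, function(j) {
      max(counts[seq_len(j - 1)]) > counts[j] &&
        max(counts[(j + 1):5]) > counts[j]
    }, logical(1)))
  }, logical(1))
  if (all(flagged)) fits else fits[!flagged]
}

#' Assign dosages from posterior probabilities
#'
#' A sample is assigned the dosage with the highest posterior probability
#' only when that probability exceeds the threshold; otherwise the call is
#' missing (`NA`).
#'
#' @param post Posterior matrix (`n x 5`) from [e_step()].
#' @param call_prob Posterior probability threshold (default 0.99).
#' @return Integer vector of dosages `0:4`, `NA` where unassigned.
#' @export
assign_genotypes <- function(post, call_prob = 0.99) {
  mx <- apply(post, 1, max)
  dose <- max.col(post, ties.method = "first") - 1L
  dose[mx <= call_prob] <- NA_integer_
  dose
}

# deterministic ordering for BIC ties: model asc, HWE before free, start order
.fit_order <- function(fits) {
  start_rank <- c(clustering = 1, equidistant = 2, rescue = 3)
  order(
    vapply(fits, function(f) f$bic, numeric(1)),
    vapply(fits, function(f) f$model, integer(1)),
    vapply(fits, function(f) if (f$hwe) 0 else 1, numeric(1)),
    vapply(fits, function(f) start_rank[[f$start_label]], numeric(1))
  )
}

.reject <- function(marker_id, reason, n_total, n_used, calls_tbl = NULL,
                    candidates = NULL) {
  structure(
    list(
      marker_id = marker_id, status = "rejected", reason = reason,
      fit = NULL, calls = calls_tbl, n_total = n_total, n_used = n_used,
      call_fraction = NA_real_, peak_fractions = rep(NA_real_, 5),
      rescue_applied = FALSE, candidates = candidates
    ),
    class = "marker_call"
  )
}

#' Fit and call one marker
#'
#' Runs the full per-marker procedure: intensity pre-filter; sixteen EM fits
#' (eight model variants from two start configurations); provisional
#' selection by minimum BIC; gap-misfit detection and, if triggered, eight
#' further fits from a rescue start; valley-pattern rejection across all
#' completed fits; final minimum-BIC selection; posterior-threshold genotype
#' assignment; and the marker-level quality filters (call fraction, sigma,
#' peak dominance). Ties in BIC are broken deterministically (model id
#' ascending, HWE before free, clustering/equidistant/rescue start order).
#' Rejections are reported as statuses with a single reason code, never as
#' errors.
#'
#' @param data Tibble of one marker's records: columns `sample`, `ratio` and
#'   optionally `intensity` and `marker`.
#' @param options A [calling_options()] object.
#' @param marker_id Marker name; taken from a `marker` column if present.
#' @return An object of class `marker_call`: marker id, `status`
#'   (`"called"`/`"rejected"`), `reason`, the selected `mixture_fit` (or
#'   `NULL`), a per-sample `calls` tibble (posteriors, max posterior, dosage),
#'   sample counts, call fraction, per-class peak fractions, whether the
#'   rescue start was used, and a `candidates` tibble of all fitted variants.
#' @examples
#' sim <- simulate_marker(sim_config(n_samples = 120, seed = 7))
#' res <- call_marker(sim$data)
#' res
#' @export
call_marker <- function(data, options = calling_options(),
                        marker_id = NULL) {
  if (is.null(marker_id)) {
    marker_id <- if ("marker" %in% names(data) && nrow(data) > 0) {
      as.character(data$marker[1])
    } else {
      "marker"
    }
  }
  if ("marker" %in% names(data) && length(unique(data$marker)) > 1) {
    stop("call_marker(): records span multiple markers; use call_markers()")
  }

  pre <- intensity_prefilter(data, options)
  if (!pre$pass) {
    return(.reject(marker_id, "low_intensity_coverage", pre$n_total, pre$n_used))
  }
  used <- pre$data
  y <- asr(used$ratio)

  fits <- fit_all_variants(y, options)
  rescue_applied <- FALSE
  if (length(fits) == 0) {
    return(.reject(marker_id, "all_fits_failed", pre$n_total, pre$n_used))
  }

  provisional <- fits[[.fit_order(fits)[1]]]
  gap <- detect_gap_misfit(provisional, options$call_prob)
  if (gap != "none") {
    rescue_applied <- TRUE
    rmeans <- rescue_start_means(provisional$mu, gap)
    rfits <- fit_all_variants(y, options, starts = list(rescue = rmeans))
    fits <- c(fits, rfits)
  }

  surviving <- reject_valley_fits(fits, options$call_prob, options$valley_check)
  best <- surviving[[.fit_order(surviving)[1]]]

  candidates <- dplyr::bind_rows(lapply(fits, glance))
  dose <- assign_genotypes(best$posteriors, options$call_prob)
  calls_tbl <- tibble::tibble(
    marker = marker_id,
    sample = if ("sample" %in% names(used)) used$sample else seq_along(y),
    ratio = used$ratio,
    y = y
  )
  post <- best$posteriors
  colnames(post) <- paste0("p", 0:4)
  calls_tbl <- dplyr::bind_cols(calls_tbl, tibble::as_tibble(post))
  calls_tbl$max_post <- apply(post, 1, max)
  calls_tbl$dosage <- dose

  n_assigned <- sum(!is.na(dose))
  call_fraction <- n_assigned / length(dose)
  peak_fractions <- if (n_assigned > 0) {
    tabulate(dose + 1L, nbins = 5) / n_assigned
  } else {
    rep(NA_real_, 5)
  }

  reason <- if (call_fraction < options$min_call_fraction) {
    "low_call_fraction"
  } else if (best$sigma > options$max_sigma) {
    "sigma_too_high"
  } else if (max(peak_fractions) > options$max_peak_fraction) {
    "one_peak_dominant"
  } else {
    "none"
  }

  structure(
    list(
      marker_id = marker_id,
      status = if (reason == "none") "called" else "rejected",
      reason = reason,
      fit = best, calls = calls_tbl,
      n_total = pre$n_total, n_used = pre$n_used,
      call_fraction = call_fraction, peak_fractions = peak_fractions,
      rescue_applied = rescue_applied, candidates = candidates
    ),
    class = "marker_call"
  )
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf(
    "<marker_call> %s: %s%s (n used %d/%d%s)\n",
    x$marker_id, x$status,
    if (x$status == "rejected") paste0(" [", x$reason, "]") else "",
    x$n_used, x$n_total,
    if (!is.na(x$call_fraction)) {
      sprintf(", %.1f%% assigned", 100 * x$call_fraction)
    } else {
      ""
    }
  ))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Call dosages for every marker in a long-format assay table
#'
#' Splits the table by marker, runs [call_marker()] on each, and collects the
#' results. Markers are processed independently, so the result does not
#' depend on their order.
#'
#' @param data Long-format tibble with columns `marker`, `sample`, `ratio`
#'   and optionally `intensity` (as produced by [read_assay()] or
#'   [simulate_panel()]).
#' @param options A [calling_options()] object.
#' @return An object of class `dosage_calls`: a named list of `marker_call`
#'   results with the options attached. Use [tidy()] for the per-marker model
#'   table, [score_table()] for per-sample calls and [glance()] for run
#'   totals.
#' @examples
#' panel <- simulate_panel(list(sim_config(n_samples = 100)), seed = 1)
#' calls <- call_markers(panel$data)
#' glance(calls)
#' @export
call_markers <- function(data, options = calling_options()) {
  stopifnot(all(c("marker", "sample", "ratio") %in% names(data)))
  split_data <- split(data, data$marker)
  results <- lapply(names(split_data), function(m) {
    call_marker(split_data[[m]], options, marker_id = m)
  })
  names(results) <- names(split_data)
  structure(list(markers = results, options = options), class = "dosage_calls")
}

#' @export
print.dosage_calls <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dosage_calls> %d markers: %d called, %d rejected\n",
    g$n_markers, g$n_called, g$n_markers - g$n_called
  ))
  invisible(x)
}

#' Per-marker model table of a calling run
#'
#' @param x A `dosage_calls` object.
#' @param ... Unused.
#' @return A tibble with one row per marker: status, rejection reason, the
#'   selected model and its parameters, component means on both scales,
#'   mixing proportions, allele frequency, log-likelihood, BIC, sample counts
#'   and call fraction.
#' @method tidy dosage_calls
#' @export
tidy.dosage_calls <- function(x, ...) {
  dplyr::bind_rows(lapply(x$markers, .model_row))
}

.model_row <- function(mc) {
  base <- tibble::tibble(
    marker = mc$marker_id, status = mc$status, reason = mc$reason,
    n_total = mc$n_total, n_used = mc$n_used,
    call_fraction = mc$call_fraction,
    max_peak_fraction = suppressWarnings(max(mc$peak_fractions)),
    rescue_applied = mc$rescue_applied
  )
  # rejected markers report QC statistics only; the model columns stay empty
  # even when a fit was selected before the quality filters fired
  if (is.null(mc$fit) || mc$status == "rejected") {
    return(dplyr::bind_cols(base, tibble::tibble(
      model = NA_integer_, hwe = NA,
      c1 = NA_real_, c2 = NA_real_, r = NA_real_, d = NA_real_,
      sigma = NA_real_, p_allele_b = NA_real_, p_allele_a = NA_real_,
      loglik = NA_real_, k = NA_integer_, bic = NA_real_,
      mu0 = NA_real_, mu1 = NA_real_, mu2 = NA_real_, mu3 = NA_real_,
      mu4 = NA_real_,
      ratio0 = NA_real_, ratio1 = NA_real_, ratio2 = NA_real_,
      ratio3 = NA_real_, ratio4 = NA_real_,
      pi0 = NA_real_, pi1 = NA_real_, pi2 = NA_real_, pi3 = NA_real_,
      pi4 = NA_real_
    )))
  }
  f <- mc$fit
  dplyr::bind_cols(base, tibble::tibble(
    model = f$model, hwe = f$hwe,
    c1 = f$params$c1, c2 = f$params$c2, r = f$params$r, d = f$params$d,
    sigma = f$sigma, p_allele_b = f$p, p_allele_a = 1 - f$p,
    loglik = f$loglik, k = f$k, bic = f$bic,
    mu0 = f$mu[1], mu1 = f$mu[2], mu2 = f$mu[3], mu3 = f$mu[4], mu4 = f$mu[5],
    ratio0 = asr_inv(f$mu[1]), ratio1 = asr_inv(f$mu[2]),
    ratio2 = asr_inv(f$mu[3]), ratio3 = asr_inv(f$mu[4]),
    ratio4 = asr_inv(f$mu[5]),
    pi0 = f$pi[1], pi1 = f$pi[2], pi2 = f$pi[3], pi3 = f$pi[4], pi4 = f$pi[5]
  ))
}

#' Per-sample score table of a calling run
#'
#' @param x A `dosage_calls` object.
#' @return A tibble with one row per marker-sample pair that passed the
#'   intensity pre-filter: the five posterior probabilities, the maximum
#'   posterior and the assigned dosage (`NA` when below the call threshold).
#' @export
score_table <- function(x) {
  stopifnot(inherits(x, "dosage_calls"))
  dplyr::bind_rows(lapply(x$markers, function(mc) mc$calls))
}

#' Run summary of a calling run
#'
#' @param x A `dosage_calls` object.
#' @param ... Unused.
#' @return A one-row tibble with marker counts per outcome (called and each
#'   rejection reason), the number of rescue starts used, and the overall
#'   fraction of used data points assigned a dosage across called markers.
#' @method glance dosage_calls
#' @export
glance.dosage_calls <- function(x, ...) {
  st <- vapply(x$markers, function(m) m$status, character(1))
  rs <- vapply(x$markers, function(m) m$reason, character(1))
  called <- x$markers[st == "called"]
  n_pts <- sum(vapply(called, function(m) nrow(m$calls), numeric(1)))
  n_assigned <- sum(vapply(
    called,
    function(m) sum(!is.na(m$calls$dosage)), numeric(1)
  ))
  tibble::tibble(
    n_markers = length(x$markers),
    n_called = sum(st == "called"),
    n_low_intensity = sum(rs == "low_intensity_coverage"),
    n_all_fits_failed = sum(rs == "all_fits_failed"),
    n_low_call_fraction = sum(rs == "low_call_fraction"),
    n_sigma_too_high = sum(rs == "sigma_too_high"),
    n_one_peak_dominant = sum(rs == "one_peak_dominant"),
    n_rescue_applied = sum(vapply(
      x$markers,
      function(m) m$rescue_applied, logical(1)
    )),
    n_hwe_selected = sum(vapply(
      called,
      function(m) m$fit$hwe, logical(1)
    )),
    assigned_fraction = if (n_pts > 0) n_assigned / n_pts else NA_real_
  )
}
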
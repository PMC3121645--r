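#' Read a two-channel assay export
#'
#' Reads a delimited text export of a bi-allelic assay in either raw mode
#' (two channel-intensity columns, GoldenGate-style `Raw_X`/`Raw_Y` defaults)
#' or ratio mode (a precomputed allele signal ratio). Column names are
#' remappable; the delimiter is auto-detected among comma, tab and semicolon.
#' Allele signal ratios and total intensities are computed on load in raw
#' mode. Rows with missing, non-numeric or negative intensities, or a zero
#' total signal, are rejected, counted and reported (attribute `n_rejected`
#' and a message), never silently dropped. An optional ploidy roster splits
#' samples into the tetraploid set (fitted) and a diploid set (plot overlay
#' only); samples absent from the roster are treated as tetraploid with a
#' warning.
#'
#' @param path Path to the delimited text file.
#' @param mode `"raw"` (two intensity columns) or `"ratio"`.
#' @param columns Named list remapping input columns; defaults
#'   `list(marker = "SNP_Name", sample = "Sample_ID", x = "Raw_X",
#'   y = "Raw_Y", ratio = "ratio")`.
#' @param ploidy Optional two-column data frame or file path (`sample`,
#'   `ploidy` with values `2` or `4`).
#' @return A tibble with columns `marker`, `sample`, `X`, `Y` (raw mode),
#'   `ratio`, `intensity` (raw mode) and `ploidy`, with attributes
#'   `n_rejected` and `mode`. In ratio mode there is no `intensity` column,
#'   so the intensity pre-filter is skipped downstream (a notice is issued).
#' @export
read_assay <- function(path, mode = c("raw", "ratio"),
                       columns = list(), ploidy = NULL) {
  mode <- match.arg(mode)
  cols <- modifyList(
    list(
      marker = "SNP_Name", sample = "Sample_ID",
      x = "Raw_X", y = "Raw_Y", ratio = "ratio"
    ),
    columns
  )
  delim <- .detect_delim(path)
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  needed <- if (mode == "raw") {
    c(cols$marker, cols$sample, cols$x, cols$y)
  } else {
    c(cols$marker, cols$sample, cols$ratio)
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "read_assay(): missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }

  out <- tibble::tibble(
    marker = raw[[cols$marker]],
    sample = raw[[cols$sample]]
  )
  if (mode == "raw") {
    X <- suppressWarnings(as.numeric(raw[[cols$x]]))
    Y <- suppressWarnings(as.numeric(raw[[cols$y]]))
    bad <- is.na(X) | is.na(Y) | X < 0 | Y < 0 | (X + Y) == 0
    if (any(bad)) {
      message(
        "read_assay(): rejected ", sum(bad), " row(s) at line(s) ",
        paste(utils::head(which(bad) + 1L, 10), collapse = ", "),
        if (sum(bad) > 10) ", ..." else ""
      )
    }
    rs <- signal_ratio(pmax(X, 0), pmax(Y, 0))
    out$X <- X
    out$Y <- Y
    out$ratio <- rs$ratio
    out$intensity <- rs$intensity
    out <- out[!bad, , drop = FALSE]
    n_rejected <- sum(bad)
  } else {
    ratio <- suppressWarnings(as.numeric(raw[[cols$ratio]]))
    bad <- is.na(ratio) | ratio < 0 | ratio > 1
    if (any(bad)) {
      message(
        "read_assay(): rejected ", sum(bad), " row(s) with invalid ratio"
      )
    }
    out$ratio <- ratio
    out <- out[!bad, , drop = FALSE]
    n_rejected <- sum(bad)
    message("read_assay(): ratio mode, intensity pre-filter will be skipped")
  }

  if (anyDuplicated(out[, c("marker", "sample")])) {
    stop("read_assay(): duplicate (marker, sample) pairs in input")
  }

  out$ploidy <- .apply_roster(out$sample, ploidy)
  attr(out, "n_rejected") <- n_rejected
  attr(out, "mode") <- mode
  out
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1)
  counts <- c(
    "," = lengths(regmatches(first, gregexpr(",", first, fixed = TRUE))),
    "\t" = lengths(regmatches(first, gregexpr("\t", first, fixed = TRUE))),
    ";" = lengths(regmatches(first, gregexpr(";", first, fixed = TRUE)))
  )
  if (all(counts == 0)) stop("read_assay(): could not detect delimiter")
  names(counts)[which.max(counts)]
}

.apply_roster <- function(samples, ploidy) {
  if (is.null(ploidy)) {
    return(rep(4L, length(samples)))
  }
  if (is.character(ploidy) && length(ploidy) == 1) {
    ploidy <- readr::read_delim(ploidy,
      delim = .detect_delim(ploidy),
      show_col_types = FALSE
    )
  }
  stopifnot(all(c("sample", "ploidy") %in% names(ploidy)))
  map <- setNames(as.integer(ploidy$ploidy), as.character(ploidy$sample))
  out <- map[samples]
  if (anyNA(out)) {
    warning(
      "read_assay(): ", sum(is.na(out)),
      " sample record(s) absent from ploidy roster; treated as tetraploid"
    )
    out[is.na(out)] <- 4L
  }
  unname(out)
}

#' Write the per-marker model table
#'
#' One row per marker with the selected model specification (parameters,
#' means on the transformed and ratio scales, mixing proportions, allele
#' frequency, likelihood, BIC) or the rejection reason.
#'
#' @param x A `dosage_calls` object (or the tibble from [tidy()]).
#' @param path Output file path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return The written tibble, invisibly.
#' @export
write_model_table <- function(x, path) {
  tbl <- if (inherits(x, "dosage_calls")) tidy(x) else x
  .write_delim(tbl, path)
  invisible(tbl)
}

#' Write the per-sample score table
#'
#' One row per marker-sample pair: the five posterior membership
#' probabilities, the maximum posterior, and the assigned dosage (empty when
#' no dosage reached the call threshold).
#'
#' @inheritParams write_model_table
#' @export
write_score_table <- function(x, path) {
  tbl <- if (inherits(x, "dosage_calls")) score_table(x) else x
  .write_delim(tbl, path)
  invisible(tbl)
}

.write_delim <- function(tbl, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tbl, path, na = "")
  } else {
    readr::write_tsv(tbl, path, na = "")
  }
}

#' Write a simulated panel in the assay export dialect
#'
#' @param panel A list from [simulate_panel()].
#' @param data_path Output path for the assay table (columns `SNP_Name`,
#'   `Sample_ID`, `Raw_X`, `Raw_Y`).
#' @param truth_path Optional output path for the tab-separated truth table.
#' @return `data_path`, invisibly.
#' @export
write_panel <- function(panel, data_path, truth_path = NULL) {
  out <- tibble::tibble(
    SNP_Name = panel$data$marker,
    Sample_ID = panel$data$sample,
    Raw_X = panel$data$X,
    Raw_Y = panel$data$Y
  )
  readr::write_csv(out, data_path)
  if (!is.null(truth_path)) readr::write_tsv(panel$truth, truth_path)
  invisible(data_path)
}
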
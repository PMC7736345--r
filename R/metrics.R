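#' Confusion pixel counts
#'
#' @param TP,FN,FP,TN Non-negative integer pixel tallies: lesion predicted
#'   as lesion (TP), lesion as normal (FN), normal as lesion (FP), normal as
#'   normal (TN).
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP = 0, FN = 0, FP = 0, TN = 0) {
  vals <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(vals), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> TP %d, FN %d, FP %d, TN %d (total %d px)\n",
    x$TP, x$FN, x$FP, x$TN, x$TP + x$FN + x$FP + x$TN
  ))
  invisible(x)
}

#' Tally a prediction map against ground truth
#'
#' Counts TP/FN/FP/TN over the evaluation domain: pixels that are retained
#' by the validity mask, retained by the boundary-exclusion mask, and not
#' background. GIST-labeled pixels contribute TP (predicted gist) or FN;
#' normal-labeled pixels contribute FP (predicted gist) or TN.
#'
#' @param pred Prediction map: factor/character/integer matrix over the
#'   grid; entries compared against `"gist"` (or code 2).
#' @param labels A `label_image` from [rasterize_labels()].
#' @param valid A [pixel_mask] of valid pixels (highlight/shadow etc.).
#' @param excl A [pixel_mask] from [exclusion_mask()] (`TRUE` = retained).
#' @return A [confusion_counts].
#' @export
confusion <- function(pred, labels, valid, excl) {
  shape <- dim(labels)
  if (!identical(dim(pred), shape) ||
    !identical(dim(valid$values), shape) ||
    !identical(dim(excl$values), shape)) {
    stop("prediction, labels and masks must share one spatial shape", call. = FALSE)
  }
  pred_gist <- prediction_is_gist(pred, shape)
  domain <- valid$values & excl$values & labels != 0L
  is_gist <- labels == 2L
  confusion_counts(
    TP = sum(domain & is_gist & pred_gist, na.rm = TRUE),
    FN = sum(domain & is_gist & !pred_gist, na.rm = TRUE),
    FP = sum(domain & !is_gist & pred_gist, na.rm = TRUE),
    TN = sum(domain & !is_gist & !pred_gist, na.rm = TRUE)
  )
}

prediction_is_gist <- function(pred, shape) {
  if (is.factor(pred)) pred <- matrix(as.character(pred), shape[1], shape[2])
  if (is.character(pred)) {
    return(matrix(pred == "gist", shape[1], shape[2]))
  }
  matrix(pred == 2L, shape[1], shape[2])
}

#' Pool confusion counts across specimens
#'
#' Elementwise sum, matching the pooled accounting of the study: pooled
#' metrics are count-weighted, not averages of per-specimen metrics.
#'
#' @param per_specimen List of [confusion_counts].
#' @return A single [confusion_counts].
#' @export
pool_counts <- function(per_specimen) {
  out <- confusion_counts()
  for (cc in per_specimen) {
    out$TP <- out$TP + cc$TP
    out$FN <- out$FN + cc$FN
    out$FP <- out$FP + cc$FP
    out$TN <- out$TN + cc$TN
  }
  out
}

#' Classification metrics from confusion counts
#'
#' \deqn{Specificity = TN / (FP + TN) \times 100}
#' \deqn{Sensitivity = TP / (TP + FN) \times 100}
#' \deqn{Accuracy = (TP + TN) / (TP + TN + FP + FN) \times 100}
#' with `FPR = 100 - specificity` and `FNR = 100 - sensitivity`. A specimen
#' with no normal pixels in its evaluation domain (`FP + TN = 0`) has
#' undefined FPR/specificity (reported `NA`); likewise `TP + FN = 0` leaves
#' FNR/sensitivity undefined.
#'
#' @param counts A [confusion_counts] (total > 0).
#' @return One-row tibble: `total_px`, `fpr`, `fnr`, `specificity`,
#'   `sensitivity`, `accuracy` (percent, unrounded), plus logical
#'   `specificity_defined`, `sensitivity_defined`.
#' @export
metrics <- function(counts) {
  total <- counts$TP + counts$FN + counts$FP + counts$TN
  if (total == 0) stop("empty evaluation domain (total = 0)", call. = FALSE)
  neg <- counts$FP + counts$TN
  pos <- counts$TP + counts$FN
  spec <- if (neg > 0) 100 * counts$TN / neg else NA_real_
  sens <- if (pos > 0) 100 * counts$TP / pos else NA_real_
  tibble::tibble(
    total_px = total,
    fpr = 100 - spec,
    fnr = 100 - sens,
    specificity = spec,
    sensitivity = sens,
    accuracy = 100 * (counts$TP + counts$TN) / total,
    specificity_defined = neg > 0,
    sensitivity_defined = pos > 0
  )
}

#' Round half away from zero
#'
#' Decimal rounding matching the presentation of the study's result table
#' (e.g. 73.025 to one decimal is 73.0, 91.25 is 91.3), as opposed to R's
#' round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-specimen results table
#'
#' Builds the study-style summary: one row per specimen with its total
#' evaluated pixel count and FPR/FNR/specificity/sensitivity/accuracy in
#' percent, rounded half-up to one decimal. Undefined entries (specimens
#' whose evaluation domain has only GIST pixels) are `NA`; [write_report_csv()]
#' renders them as an en dash.
#'
#' @param per_specimen Either a `gist_loocv` result or a list of
#'   `list(id = , counts = )` entries.
#' @return A tibble with columns `specimen`, `total_px`, `fpr`, `fnr`,
#'   `specificity`, `sensitivity`, `accuracy`.
#' @export
report_table <- function(per_specimen) {
  if (inherits(per_specimen, "gist_loocv")) {
    per_specimen <- purrr::map2(
      per_specimen$ids, per_specimen$counts,
      function(id, cc) list(id = id, counts = cc)
    )
  }
  if (!length(per_specimen)) {
    return(tibble::tibble(
      specimen = character(), total_px = integer(), fpr = numeric(),
      fnr = numeric(), specificity = numeric(), sensitivity = numeric(),
      accuracy = numeric()
    ))
  }
  purrr::map_dfr(per_specimen, function(entry) {
    m <- metrics(entry$counts)
    tibble::tibble(
      specimen = as.character(entry$id),
      total_px = m$total_px,
      fpr = round_half_up(m$fpr),
      fnr = round_half_up(m$fnr),
      specificity = round_half_up(m$specificity),
      sensitivity = round_half_up(m$sensitivity),
      accuracy = round_half_up(m$accuracy)
    )
  })
}

#' Write a results table as CSV
#'
#' Metric columns are rendered to one decimal; undefined entries (GIST-only
#' specimens) are written as an en dash.
#'
#' @param tbl Tibble from [report_table()].
#' @param path Output CSV path.
#' @param na_string Replacement for undefined entries (default `"-"`).
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(tbl, path, na_string = "-") {
  out <- tbl
  for (col in c("fpr", "fnr", "specificity", "sensitivity", "accuracy")) {
    out[[col]] <- ifelse(is.na(tbl[[col]]), na_string, sprintf("%.1f", tbl[[col]]))
  }
  readr::write_csv(out, path, na = na_string)
  invisible(path)
}

#' Write pooled confusion counts as JSON
#'
#' @param counts A [confusion_counts].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_counts_json <- function(counts, path) {
  jsonlite::write_json(
    list(
      TP = counts$TP, FN = counts$FN, FP = counts$FP, TN = counts$TN,
      total = counts$TP + counts$FN + counts$FP + counts$TN
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
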
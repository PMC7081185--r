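#' Classify tissue by mean ADC
#'
#' Ischemic edema is defined by a mean apparent diffusion coefficient below
#' the threshold (default 650 um^2/s); tissue at or above the threshold is
#' normal (exact equality resolves to normal, a boundary the strict
#' inequalities of the definition leave open).
#'
#' @param mean_adc Mean ROI ADC (um^2/s); vectorized.
#' @param threshold Classification threshold (um^2/s).
#' @return Character vector, `"edema"` or `"normal"`.
#' @examples
#' classify_tissue(c(500, 750, 650))
#' @export
classify_tissue <- function(mean_adc, threshold = 650) {
  stopifnot(all(mean_adc >= 0), threshold > 0)
  ifelse(mean_adc < threshold, "edema", "normal")
}

#' Summarize a parameter map over an ROI
#'
#' Statistics over the valid voxels of a map inside an ROI mask; the raw
#' value vector is retained for histogram and test operations.
#'
#' @param map A [parameter_map()].
#' @param roi_mask 3D logical array of the same geometry.
#' @param roi_id ROI name used in error messages and outputs.
#' @param metric Metric name (e.g. `"adc"`, `"vsi"`).
#' @return An object of class `roi_summary`: list with `roi_id`, `metric`,
#'   `mean`, `median`, `sd`, `n_voxels` (valid voxels only) and `values`.
#' @export
roi_metric_summary <- function(map, roi_mask, roi_id = "roi",
                               metric = "metric") {
  stopifnot(inherits(map, "parameter_map"))
  if (!all(dim(roi_mask) == dim(map$values)))
    stop(sprintf("ROI '%s' does not match map geometry", roi_id))
  sel <- (roi_mask != 0) & map$valid_mask & !is.na(map$values)
  if (!any(sel))
    stop(sprintf("ROI '%s' contains no valid voxels", roi_id))
  v <- map$values[sel]
  structure(
    list(roi_id = roi_id, metric = metric, mean = mean(v),
         median = median(v), sd = if (length(v) > 1) sd(v) else 0,
         n_voxels = length(v), values = v),
    class = "roi_summary"
  )
}

#' Fraction of values strictly above a cutoff
#'
#' Used for the histogram proportions of large vessels (VSI > 10 um) and
#' high vessel densities (MVD > 200 mm^-2).
#'
#' @param values Non-empty numeric vector.
#' @param cutoff Cutoff value.
#' @return Fraction in `[0, 1]`.
#' @examples
#' proportion_above(c(5, 12, 15), 10)  # 2/3
#' @export
proportion_above <- function(values, cutoff) {
  if (!length(values)) stop("empty value vector")
  mean(values > cutoff)
}

#' Student's t-test from first principles
#'
#' Classical two-sided Student's t statistic computed directly from group
#' means and variances: pooled-variance for unpaired groups, difference
#' scores for paired data; p from the t distribution function. Degenerate
#' zero-variance data with equal means gives t = 0, p = 1; zero variance
#' with unequal means is flagged degenerate with p = 0.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each; equal lengths when
#'   paired).
#' @param paired Paired test?
#' @return An object of class `t_result`: list with `statistic`, `p_value`,
#'   `df`, `paired`, `n_per_group`, `degenerate`.
#' @examples
#' students_t(c(1, 2, 3, 4), c(2, 3, 4, 5))  # t ~ -1.095
#' @export
students_t <- function(group_a, group_b, paired = FALSE) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  if (paired && n1 != n2) stop("paired test requires equal group sizes")

  if (paired) {
    d <- group_a - group_b
    md <- mean(d)
    vd <- var_or_zero(d)
    df <- n1 - 1
    if (vd == 0) {
      return(t_degenerate(md, df, paired, c(n1, n2)))
    }
    tstat <- md / sqrt(vd / n1)
  } else {
    m1 <- mean(group_a); m2 <- mean(group_b)
    v1 <- var_or_zero(group_a); v2 <- var_or_zero(group_b)
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    if (sp2 == 0) {
      return(t_degenerate(m1 - m2, df, paired, c(n1, n2)))
    }
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * pt(-abs(tstat), df)
  structure(
    list(statistic = tstat, p_value = p, df = df, paired = paired,
         n_per_group = c(n1, n2), degenerate = FALSE),
    class = "t_result"
  )
}

var_or_zero <- function(x) if (length(x) > 1) stats::var(x) else 0

t_degenerate <- function(mean_diff, df, paired, n) {
  if (mean_diff == 0)
    structure(list(statistic = 0, p_value = 1, df = df, paired = paired,
                   n_per_group = n, degenerate = FALSE), class = "t_result")
  else
    structure(list(statistic = sign(mean_diff) * Inf, p_value = 0, df = df,
                   paired = paired, n_per_group = n, degenerate = TRUE),
              class = "t_result")
}

#' @export
print.t_result <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %g, p = %.4g%s\n",
              if (x$paired) "paired" else "unpaired (pooled)",
              x$statistic, x$df, x$p_value,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Long-format table for double box plots (metric vs ADC)
#'
#' Pairs voxel-wise ADC values with a co-localized microvascular metric,
#' labelled by ROI and by the ADC-derived tissue class of the ROI, ready
#' for a double box plot against the edema threshold.
#'
#' @param adc_values,metric_values Equal-length numeric vectors.
#' @param roi_labels ROI label per element (length 1 or equal length).
#' @param side Optional hemisphere label per element.
#' @param metric_name Name for the metric column content.
#' @param threshold ADC classification threshold (um^2/s); stored in the
#'   `adc_reference` attribute for the plot's reference line.
#' @return A tibble with columns roi, side, adc, metric, metric_name,
#'   tissue_class (class assigned from each ROI's mean ADC).
#' @export
export_double_box <- function(adc_values, metric_values, roi_labels,
                              side = NA_character_, metric_name = "metric",
                              threshold = 650) {
  if (!length(adc_values)) stop("empty input")
  if (length(adc_values) != length(metric_values))
    stop("adc and metric vectors must have equal length")
  roi_labels <- rep_len(as.character(roi_labels), length(adc_values))
  side <- rep_len(as.character(side), length(adc_values))
  out <- tibble::tibble(roi = roi_labels, side = side,
                        adc = as.double(adc_values),
                        metric = as.double(metric_values),
                        metric_name = metric_name)
  cls <- vapply(split(out$adc, out$roi), mean, numeric(1))
  out$tissue_class <- classify_tissue(cls[out$roi], threshold)
  attr(out, "adc_reference") <- threshold
  out
}

#' Combine longitudinal vessel diameters into early/late phase summaries
#'
#' Aggregation rule for macrovascular remodeling analysis: per animal,
#' vessel and hemisphere, the early-phase diameter is the maximum over
#' early reperfusion days for venous vessels (capturing peak dilation) and
#' the minimum for arterial vessels (capturing peak thinning); the
#' late-phase diameter is the value at the late day.
#'
#' @param diam_tbl Tibble with columns `animal`, `day`, `vessel`, `type`
#'   (`"venous"` or `"arterial"`), `side`, `diameter`.
#' @param early_days Days counted as early phase (default 1-4).
#' @param late_day The late reperfusion day (default 7).
#' @return Tibble with one row per animal x vessel x side x phase.
#' @export
combine_vessel_diameters <- function(diam_tbl, early_days = c(1, 4),
                                     late_day = 7) {
  need <- c("animal", "day", "vessel", "type", "side", "diameter")
  if (!all(need %in% names(diam_tbl)))
    stop("diam_tbl must have columns ", paste(need, collapse = ", "))
  if (!all(diam_tbl$type %in% c("venous", "arterial")))
    stop("type must be 'venous' or 'arterial'")
  early <- diam_tbl |>
    dplyr::filter(day >= min(early_days), day <= max(early_days)) |>
    dplyr::group_by(animal, vessel, type, side) |>
    dplyr::summarise(
      diameter = if (type[1] == "venous") max(diameter) else min(diameter),
      .groups = "drop") |>
    dplyr::mutate(phase = "early")
  late <- diam_tbl |>
    dplyr::filter(day == late_day) |>
    dplyr::select(animal, vessel, type, side, diameter) |>
    dplyr::mutate(phase = "late")
  dplyr::bind_rows(early, late)
}
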
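#' The six-class leaf damage vocabulary
#'
#' Standing leaf damage is scored visually into six ordered percentage
#' classes. The classes partition the damage fraction scale \[0, 1\] into a
#' singleton at zero plus five left-open, right-closed intervals, so a leaf
#' with exactly 5% of its area removed falls in the `"1-5%"` class.
#'
#' @return A tibble with one row per class: `class_label`, `lower`, `upper`
#'   (interval bounds on the damage fraction) and `rank` (1 = undamaged).
#' @export
#' @examples
#' damage_classes()
damage_classes <- function() {
  tibble::tibble(
    class_label = c("0%", "<1%", "1-5%", ">5-15%", ">15-35%", ">35%"),
    lower = c(0, 0, 0.01, 0.05, 0.15, 0.35),
    upper = c(0, 0.01, 0.05, 0.15, 0.35, 1),
    rank = 1:6
  )
}

#' Assign damage fractions to classes
#'
#' @param fraction Numeric vector of per-leaf damage fractions in \[0, 1\].
#' @return Character vector of class labels from [damage_classes()].
#' @export
#' @examples
#' damage_class_of(c(0, 0.004, 0.05, 0.051, 0.9))
damage_class_of <- function(fraction) {
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1)) {
    hd_abort("damage fractions must be finite and within [0, 1]", "bad_fraction")
  }
  cls <- damage_classes()
  out <- as.character(cut(fraction,
    breaks = c(0, cls$upper[-1]),
    labels = cls$class_label[-1], right = TRUE
  ))
  out[fraction == 0] <- "0%"
  out
}

#' Calibrate damage classes against scanned leaves
#'
#' Visual damage classes are coarse; a sample of leaves per class is scanned
#' and the removed-to-total leaf area ratio measured exactly. The calibrated
#' value of a class is the arithmetic mean of its scanned fractions. The
#' `"0%"` class is fixed at 0 by definition, with or without scans.
#' Calibration is pooled over species (one set of scans per class).
#'
#' @param scans A data frame with columns `class_label` and `damage_fraction`
#'   (measured removed-area fraction per scanned leaf, in \[0, 1\]).
#' @return A tibble (`class_label`, `mean_fraction`, `n_scans`), one row per
#'   class in scheme order. Calibrated means are strictly increasing across
#'   classes and each lies inside its class interval.
#' @export
#' @examples
#' scans <- data.frame(
#'   class_label = rep(c("<1%", "1-5%", ">5-15%", ">15-35%", ">35%"), each = 2),
#'   damage_fraction = c(0.004, 0.006, 0.02, 0.04, 0.08, 0.12, 0.2, 0.3, 0.5, 0.7)
#' )
#' calibrate_classes(scans)
calibrate_classes <- function(scans) {
  scans <- tibble::as_tibble(scans)
  if (!all(c("class_label", "damage_fraction") %in% names(scans))) {
    hd_abort("scans need columns class_label and damage_fraction", "format")
  }
  cls <- damage_classes()
  unknown <- setdiff(unique(scans$class_label), cls$class_label)
  if (length(unknown) > 0) {
    hd_abort(paste0("unknown damage class label(s): ",
                    paste(unknown, collapse = ", ")), "vocabulary")
  }
  if (any(!is.finite(scans$damage_fraction)) ||
      any(scans$damage_fraction < 0 | scans$damage_fraction > 1)) {
    hd_abort("scanned damage fractions must lie in [0, 1]", "bad_fraction")
  }
  nonzero <- cls$class_label[-1]
  missing_cls <- setdiff(nonzero, unique(scans$class_label))
  if (length(missing_cls) > 0) {
    hd_abort(paste0("no scans for non-zero damage class(es): ",
                    paste(missing_cls, collapse = ", ")), "calibration")
  }
  # scans whose measured fraction falls outside their labelled interval are
  # kept (the label is the field datum) but counted and reported
  chk <- scans |>
    dplyr::left_join(cls, by = "class_label") |>
    dplyr::mutate(outside = ifelse(.data$class_label == "0%",
      .data$damage_fraction != 0,
      .data$damage_fraction <= .data$lower | .data$damage_fraction > .data$upper
    ))
  n_out <- sum(chk$outside)
  if (n_out > 0) {
    rlang::warn(paste0(n_out, " scan(s) fall outside their labelled class interval; kept"))
  }
  cal <- scans |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(mean_fraction = mean(.data$damage_fraction),
                     n_scans = dplyr::n(), .groups = "drop")
  out <- cls |>
    dplyr::select("class_label") |>
    dplyr::left_join(cal, by = "class_label") |>
    dplyr::mutate(
      n_scans = ifelse(is.na(.data$n_scans), 0L, .data$n_scans),
      mean_fraction = ifelse(.data$class_label == "0%", 0, .data$mean_fraction)
    )
  if (any(diff(out$mean_fraction) <= 0)) {
    hd_abort("calibrated class means are not strictly increasing", "calibration")
  }
  out
}

#' Per-sapling mean damage from calibrated classes
#'
#' Converts each sapling's per-leaf damage classes into a mean damage
#' proportion: the mean over its leaves of the calibrated class means.
#' Saplings recorded in the pre-aggregated dialect (a `mean_damage` value
#' instead of leaf classes) pass through unchanged.
#'
#' @param survey A sapling survey tibble as returned by
#'   [read_sapling_survey()] or [simulate_study()]: one row per sapling with
#'   `leaf_count`, a `leaf_classes` list column (or `NULL` entries for
#'   aggregated records) and `mean_damage` (`NA` where classes are present).
#' @param calibration A calibration tibble from [calibrate_classes()].
#' @return The survey with `mean_damage` filled in for every sapling.
#' @export
sapling_mean_damage <- function(survey, calibration) {
  survey <- tibble::as_tibble(survey)
  lut <- setNames(calibration$mean_fraction, calibration$class_label)
  filled <- purrr::map2_dbl(survey$leaf_classes, survey$mean_damage, function(cl, md) {
    if (is.null(cl)) {
      return(md)
    }
    if (any(!cl %in% names(lut))) {
      hd_abort(paste0("leaf class not covered by calibration: ",
                      paste(setdiff(cl, names(lut)), collapse = ", ")),
               "calibration")
    }
    mean(lut[cl])
  })
  survey$mean_damage <- filled
  survey
}
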
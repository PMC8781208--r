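#' Convert a crystallographic B factor to an RMS displacement
#'
#' The isotropic temperature factor B (in square angstroms) corresponds to a
#' root-mean-square atomic displacement `<U> = sqrt(B / (8 * pi^2))` in
#' angstroms. Vectorized; full precision is returned and rounding (1 decimal
#' place) is left to the reporting layer.
#'
#' @param B Numeric vector of B factors in square angstroms (>= 0).
#' @return RMS displacement(s) in angstroms.
#' @export
#' @examples
#' round(b_to_u(51), 1) # 0.8
b_to_u <- function(B) {
  if (any(B < 0, na.rm = TRUE)) {
    abort("B factors must be non-negative")
  }
  sqrt(B / (8 * pi^2))
}

#' Summarize the mobility of a group of atoms
#'
#' Arithmetic mean, range and count of B factors for one or more atom groups,
#' together with two displacement summaries: `u_of_mean_b`, the displacement
#' of the group's mean B (the convention used when a single `<U>` is quoted
#' for a group), and `mean_u`, the mean of the per-atom displacements.
#'
#' @param data Data frame with a B-factor column.
#' @param b Column name holding B factors (default `"b"`).
#' @param group Optional column name to group by (e.g. a shell label or an
#'   atom-set tag); `NULL` summarizes all rows as one group.
#' @return Tibble with one row per group: `n`, `mean_b`, `min_b`, `max_b`,
#'   `u_of_mean_b`, `mean_u`.
#' @export
#' @examples
#' group_mobility(data.frame(b = c(64, 46, 40, 48, 58)))
group_mobility <- function(data, b = "b", group = NULL) {
  data <- tibble::as_tibble(data)
  if (!b %in% names(data)) abort(paste0("no column '", b, "' in data"))
  if (nrow(data) == 0) abort("cannot summarize an empty atom set")
  bv <- data[[b]]
  if (any(is.na(bv))) abort("missing B factors in group")
  if (!is.null(group)) {
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
      dplyr::summarise(
        n = dplyr::n(),
        mean_b = mean(.data[[b]]),
        min_b = min(.data[[b]]),
        max_b = max(.data[[b]]),
        u_of_mean_b = b_to_u(mean(.data[[b]])),
        mean_u = mean(b_to_u(.data[[b]])),
        .groups = "drop")
  } else {
    tibble::tibble(
      n = length(bv),
      mean_b = mean(bv),
      min_b = min(bv),
      max_b = max(bv),
      u_of_mean_b = b_to_u(mean(bv)),
      mean_u = mean(b_to_u(bv)))
  }
}

#' Round a mobility summary to report precision
#'
#' B means to the nearest integer and displacements to one decimal place,
#' the precision at which these quantities are conventionally quoted.
#'
#' @param summary Output of [group_mobility()].
#' @return The same tibble with `mean_b` rounded to integer and the
#'   displacement columns to 1 decimal place.
#' @export
format_mobility <- function(summary) {
  summary |>
    dplyr::mutate(mean_b = round(.data$mean_b),
                  u_of_mean_b = round(.data$u_of_mean_b, 1),
                  mean_u = round(.data$mean_u, 1))
}
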
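#' Pearson correlation with significance
#'
#' Product-moment correlation between two numeric vectors, with the p-value
#' from the t distribution on `n - 2` degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A one-row tibble: `r`, `p`, `n`.
#' @examples
#' ee_pearson(c(1, 2, 3), c(2, 1, 3)) # r = 0.5
#' @export
ee_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation screen of candidate variables against energy expenditure
#'
#' Runs [ee_pearson()] of each candidate column against the target column,
#' returning the correlation table used to compare pre-selected variables.
#'
#' @param data Candidate table (e.g. [candidate_table_exercise()]).
#' @param variables Candidate column names; defaults to the period preset.
#' @param target Target column name.
#' @param period Label recorded on each row.
#' @return Tibble: `variable`, `r`, `p`, `n`, `period`.
#' @export
ee_correlation <- function(data, variables = NULL, target = "ee",
                           period = c("exercise", "interval")) {
  period <- match.arg(period)
  if (is.null(variables)) variables <- candidate_preset(period)
  missing_cols <- setdiff(c(variables, target), names(data))
  if (length(missing_cols) > 0) {
    stop("columns not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(variables, function(v) {
    dplyr::mutate(ee_pearson(data[[v]], data[[target]]), variable = v,
                  .before = 1)
  }) |>
    dplyr::mutate(period = period)
}

#' Rank screened variables by absolute correlation
#'
#' Descending by `|r|`; ties are broken alphabetically by variable name.
#'
#' @param table A correlation table from [ee_correlation()] (needs columns
#'   `variable` and `r`).
#' @return Character vector of variable names, strongest first.
#' @export
rank_variables <- function(table) {
  if (nrow(table) == 0) stop("empty correlation table", call. = FALSE)
  table |>
    dplyr::arrange(dplyr::desc(abs(.data$r)), .data$variable) |>
    dplyr::pull("variable")
}
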
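#' Overall satisfaction from a three-level response table
#'
#' Combines the "satisfied" and "generally satisfied" counts and expresses
#' them as a percentage of all responses:
#' overall satisfaction = (satisfied + generally satisfied) / total x 100.
#'
#' @param satisfied,generally_satisfied,dissatisfied Non-negative integer
#'   counts. Alternatively pass a single data frame / list with these three
#'   columns as `satisfied`.
#' @return One-row tibble: `combined`, `total`, `percent` (full precision)
#'   and `percent_display` (half-up rounded to 2 decimals).
#' @examples
#' overall_satisfaction(85, 193, 56) # combined 278
#' @export
overall_satisfaction <- function(satisfied, generally_satisfied = NULL, dissatisfied = NULL) {
  if (is.list(satisfied)) {
    x <- satisfied
    satisfied <- x$satisfied
    generally_satisfied <- x$generally_satisfied
    dissatisfied <- x$dissatisfied
  }
  counts <- c(satisfied, generally_satisfied, dissatisfied)
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0)) {
    abort_input("need three non-negative counts: satisfied, generally_satisfied, dissatisfied")
  }
  total <- sum(counts)
  if (total == 0) abort_input("satisfaction table has zero total responses")
  combined <- satisfied + generally_satisfied
  pct <- combined / total * 100
  tibble(
    combined = combined, total = total,
    percent = pct, percent_display = round_half_up(pct, 2)
  )
}

#' Simple proportion expressed as a percentage
#'
#' Used for compensation and petition rates: `count / n x 100`.
#'
#' @param count Event count, `0 <= count <= n`.
#' @param n Group size, > 0.
#' @return One-row tibble: `count`, `n`, `percent`, `percent_display`.
#' @export
proportion_rate <- function(count, n) {
  if (is.na(n) || n <= 0) abort_input("n must be > 0")
  if (is.na(count) || count < 0 || count > n) abort_input("count must satisfy 0 <= count <= n")
  pct <- count / n * 100
  tibble(count = count, n = n, percent = pct, percent_display = round_half_up(pct, 2))
}

# round() alone is banker's rounding; tables use half-up at 2 dp
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Chi-square test for a 2x2 contingency table
#'
#' Closed-form Pearson statistic for a 2x2 table with rows = groups and
#' columns = outcome / non-outcome:
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#' With `yates = TRUE` the continuity correction subtracts `N/2` from
#' `|ad - bc|` (floored at 0) before squaring. The p-value comes from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param a,b,c,d Non-negative integer cell counts (row 1: a, b; row 2: c,
#'   d). A length-4 vector or 2x2 matrix may be passed as `a`.
#' @param yates Apply the Yates continuity correction.
#' @return One-row tibble: `statistic`, `p_value`, `df`, `yates`.
#' @examples
#' chi_square_2x2(278, 56, 318, 23)
#' @export
chi_square_2x2 <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  if (length(a) == 4) {
    cells <- as.numeric(if (is.matrix(a)) t(a) else a)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) abort_input("cell counts must be non-negative")
  margins <- c(`row 1` = a + b, `row 2` = c + d, `column 1` = a + c, `column 2` = b + d)
  if (any(margins == 0)) {
    abort_input(paste0(
      "chi-square undefined: zero margin (",
      paste(names(margins)[margins == 0], collapse = ", "), ")"
    ))
  }
  n <- sum(cells)
  delta <- abs(a * d - b * c)
  if (yates) delta <- max(delta - n / 2, 0)
  statistic <- n * delta^2 / prod(margins)
  tibble(
    statistic = statistic,
    p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
    df = 1L,
    yates = yates
  )
}

#' Per-group service-quality indicators
#'
#' Tidies a table of per-case outcomes into the observation indicators:
#' overall satisfaction, compensation rate and petition rate per group, plus
#' the between-group 2x2 chi-square comparison for each binary indicator.
#'
#' @param outcomes Tibble with one row per complaint case: a `group` column
#'   (two levels) plus any of `satisfaction` (levels `"satisfied"`,
#'   `"generally_satisfied"`, `"dissatisfied"`), `compensated`,
#'   `petitioned` (logical or 0/1).
#' @param group_col Name of the grouping column.
#' @param yates Passed to [chi_square_2x2()].
#' @return A list with `by_group` (tibble of indicators per group) and
#'   `comparisons` (tibble: `indicator`, `statistic`, `p_value`).
#' @export
service_indicators <- function(outcomes, group_col = "group", yates = FALSE) {
  if (!group_col %in% names(outcomes)) {
    abort_config(paste0("grouping column '", group_col, "' not found"))
  }
  groups <- sort(unique(as.character(outcomes[[group_col]])))
  if (length(groups) != 2) abort_input("service_indicators expects exactly two groups")
  per_group <- function(g) {
    sub <- outcomes[outcomes[[group_col]] == g, , drop = FALSE]
    row <- tibble(group = g, n = nrow(sub))
    if ("satisfaction" %in% names(sub)) {
      cnt <- function(lev) sum(sub$satisfaction == lev, na.rm = TRUE)
      os <- overall_satisfaction(cnt("satisfied"), cnt("generally_satisfied"), cnt("dissatisfied"))
      row$satisfied <- cnt("satisfied")
      row$generally_satisfied <- cnt("generally_satisfied")
      row$dissatisfied <- cnt("dissatisfied")
      row$overall_satisfaction_pct <- os$percent
    }
    for (col in c("compensated", "petitioned")) {
      if (col %in% names(sub)) {
        k <- sum(as.logical(sub[[col]]), na.rm = TRUE)
        row[[paste0(col, "_n")]] <- k
        row[[paste0(col, "_pct")]] <- proportion_rate(k, nrow(sub))$percent
      }
    }
    row
  }
  by_group <- dplyr::bind_rows(lapply(groups, per_group))
  comparisons <- list()
  add_cmp <- function(name, success) {
    # success: per-group vector of event counts
    tab <- chi_square_2x2(
      success[1], by_group$n[1] - success[1],
      success[2], by_group$n[2] - success[2],
      yates = yates
    )
    comparisons[[length(comparisons) + 1]] <<- tibble(
      indicator = name, statistic = tab$statistic, p_value = tab$p_value
    )
  }
  if ("overall_satisfaction_pct" %in% names(by_group)) {
    add_cmp("overall_satisfaction", by_group$satisfied + by_group$generally_satisfied)
  }
  if ("compensated_n" %in% names(by_group)) add_cmp("compensation_rate", by_group$compensated_n)
  if ("petitioned_n" %in% names(by_group)) add_cmp("petition_rate", by_group$petitioned_n)
  list(by_group = by_group, comparisons = dplyr::bind_rows(comparisons))
}
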
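#' Build the benchmark panel for one indicator
#'
#' The decision matrix is assembled per indicator as a three-row column:
#' the city's value, the positive-ideal benchmark (PI) and the
#' negative-ideal benchmark (NI).  The column is vector-normalized
#' (divided by its Euclidean norm), multiplied by the indicator weight,
#' and the orientation-aware extremes over the three rows become the
#' ideal values \eqn{A^+} and \eqn{A^-} — so a city outperforming its
#' published standard defines its own ideal.  The squared deviations of
#' the city's weighted value from each ideal are the per-indicator terms
#' later pooled into \eqn{S^+}, \eqn{S^-}.
#'
#' @param code Indicator code.
#' @param orientation `"MAX"` or `"MIN"`.
#' @param city_value Observed value for the city.
#' @param pi_value,ni_value Resolved positive and negative ideals.
#' @param weight Indicator weight in `(0, 1]`.
#' @return One-row tibble with the raw, normalized and weighted column,
#'   `a_plus`, `a_minus`, and `dev_plus_sq` / `dev_minus_sq`.
#' @export
build_panel <- function(code, orientation, city_value, pi_value, ni_value, weight) {
  if (!orientation %in% c("MAX", "MIN")) abort("orientation must be MAX or MIN")
  if (!is.finite(weight) || weight <= 0 || weight > 1) {
    abort(sprintf("%s: weight must be in (0, 1], got %g", code, weight))
  }
  x <- c(city_value, pi_value, ni_value)
  if (any(!is.finite(x))) abort(sprintf("%s: non-finite panel value", code))
  if (any(x < 0)) abort(sprintf("%s: panel values must be non-negative", code))
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) abort(sprintf("%s: all-zero column, cannot normalize", code))
  r <- x / nrm
  v <- weight * r
  if (orientation == "MAX") {
    a_plus <- max(v)
    a_minus <- min(v)
  } else {
    a_plus <- min(v)
    a_minus <- max(v)
  }
  tibble(
    code = code, orientation = orientation, weight = weight,
    city = city_value, pi = pi_value, ni = ni_value, norm = nrm,
    r_city = r[1], r_pi = r[2], r_ni = r[3],
    v_city = v[1], v_pi = v[2], v_ni = v[3],
    a_plus = a_plus, a_minus = a_minus,
    dev_plus_sq = (v[1] - a_plus)^2,
    dev_minus_sq = (v[1] - a_minus)^2
  )
}

#' Benchmark panels for every indicator of a framework
#'
#' @param fw A [framework()].
#' @param observation A [city_observation()].
#' @param weights Tibble with `code` and `weight` columns, e.g. from
#'   [weights_for_framework()].
#' @param policy Missing-ideal policy override (see [resolve_ideals()]).
#' @return Tibble of per-indicator panels with `element` and `dimension`
#'   columns attached.
#' @export
build_panels <- function(fw, observation, weights, policy = NULL) {
  stopifnot(inherits(fw, "his_framework"), inherits(observation, "city_observation"))
  ideals <- resolve_ideals(fw, policy)
  w <- setNames(weights$weight, weights$code)
  missing_w <- setdiff(ideals$code, names(w))
  if (length(missing_w)) {
    abort(sprintf("no weight for indicator(s): %s", paste(missing_w, collapse = ", ")))
  }
  panels <- purrr::pmap_dfr(
    list(ideals$code, ideals$orientation, ideals$pi_eff, ideals$ni_eff),
    \(code, orientation, pi_eff, ni_eff) {
      build_panel(code, orientation, observation$values[[code]],
                  pi_eff, ni_eff, w[[code]])
    }
  )
  dplyr::left_join(panels,
                   dplyr::select(ideals, "code", "element", "dimension"),
                   by = "code")
}

#' Pool panels into a relative-closeness score
#'
#' Sums the squared city-to-ideal deviations over the member indicators,
#' takes square roots to obtain the Euclidean separations \eqn{S^+} and
#' \eqn{S^-}, and computes relative closeness
#' \eqn{c^* = S^- / (S^+ + S^-)}, bounded in `[0, 1]`.  When the city
#' sits exactly on both ideals (\eqn{S^+ + S^- = 0}) closeness is
#' defined as 1 — the standard is met — with a warning.
#'
#' @param panels Panel tibble (rows restricted to the member set).
#' @param scope Label for the pooled group (element or dimension code).
#' @return One-row tibble: `scope`, `members`, `s_plus`, `s_minus`,
#'   `closeness`.
#' @export
aggregate_closeness <- function(panels, scope = "group") {
  if (nrow(panels) == 0) abort("cannot aggregate an empty member set")
  s_plus <- sqrt(sum(panels$dev_plus_sq))
  s_minus <- sqrt(sum(panels$dev_minus_sq))
  closeness <- if (s_plus + s_minus == 0) {
    warn(sprintf("%s: city coincides with both ideals; closeness set to 1", scope))
    1
  } else {
    s_minus / (s_plus + s_minus)
  }
  tibble(scope = scope, members = paste(panels$code, collapse = ","),
         s_plus = s_plus, s_minus = s_minus, closeness = closeness)
}

#' Rank closeness results within a peer group
#'
#' Descending closeness gets rank 1..k; exact ties are broken by
#' ascending scope code, so the ordering is deterministic.
#'
#' @param results Tibble with `scope` and `closeness` columns.
#' @return The same tibble with a `rank` column, in original row order.
#' @export
rank_results <- function(results) {
  ord <- order(-results$closeness, results$scope)
  results$rank <- integer(nrow(results))
  results$rank[ord] <- seq_len(nrow(results))
  results
}

#' Evaluate a city against its benchmark framework
#'
#' Runs the full pipeline: per-indicator benchmark panels, element-level
#' and dimension-level closeness with ranks (elements ranked within
#' their dimension, dimensions ranked against each other).  Element
#' deviations pool raw indicator deviations; no second layer of weights
#' enters the aggregation.
#'
#' @param fw A [framework()].
#' @param observation A [city_observation()].
#' @param weights Indicator weights tibble; computed from the
#'   framework's judgment groups via [weights_for_framework()] when
#'   `NULL`.
#' @param policy Missing-ideal policy override.
#' @return An object of class `city_eval` with tibbles `panels`,
#'   `elements`, `dimensions`, the `weights` used, and metadata.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
evaluate_city <- function(fw, observation, weights = NULL, policy = NULL) {
  stopifnot(inherits(fw, "his_framework"))
  if (is.null(weights)) weights <- weights_for_framework(fw)
  panels <- build_panels(fw, observation, weights, policy)

  elements <- panels |>
    dplyr::group_by(.data$dimension, .data$element) |>
    dplyr::group_modify(\(df, key) aggregate_closeness(df, key$element)) |>
    dplyr::ungroup() |>
    dplyr::select(-"scope") |>
    dplyr::group_by(.data$dimension) |>
    dplyr::group_modify(\(df, key) {
      rank_results(dplyr::rename(df, scope = "element")) |>
        dplyr::rename(element = "scope")
    }) |>
    dplyr::ungroup()
  # keep framework element order
  elements <- elements[match(unique(panels$element), elements$element), ]

  dimensions <- panels |>
    dplyr::group_by(.data$dimension) |>
    dplyr::group_modify(\(df, key) aggregate_closeness(df, key$dimension)) |>
    dplyr::ungroup() |>
    dplyr::rename(dimension2 = "scope") |>
    dplyr::select(-"dimension2")
  dimensions <- rank_results(dplyr::rename(dimensions, scope = "dimension")) |>
    dplyr::rename(dimension = "scope")
  dimensions <- dimensions[match(unique(panels$dimension), dimensions$dimension), ]

  structure(
    list(
      city_id = observation$city_id, year = observation$year,
      framework = fw$name, policy = policy %||% fw$missing_ideal_default,
      weights = weights, panels = panels,
      elements = elements, dimensions = dimensions
    ),
    class = "city_eval"
  )
}

#' @export
print.city_eval <- function(x, ...) {
  cat(sprintf("<city_eval> %s (%s) against framework '%s'\n",
              x$city_id, ifelse(is.na(x$year), "year unknown", x$year), x$framework))
  cat(sprintf("  %d indicators, %d elements, %d dimensions\n",
              nrow(x$panels), nrow(x$elements), nrow(x$dimensions)))
  cat("\nDimension closeness:\n")
  print(as.data.frame(x$dimensions[, c("dimension", "s_plus", "s_minus", "closeness", "rank")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy a city evaluation
#'
#' @param x A `city_eval`.
#' @param level `"element"` (default), `"dimension"` or `"indicator"`.
#' @param ... Unused.
#' @return A tibble of the requested result level.
#' @method tidy city_eval
#' @export
tidy.city_eval <- function(x, level = c("element", "dimension", "indicator"), ...) {
  level <- rlang::arg_match(level)
  switch(level,
    element = x$elements,
    dimension = x$dimensions,
    indicator = x$panels
  )
}

#' @method glance city_eval
#' @export
glance.city_eval <- function(x, ...) {
  tibble(
    city_id = x$city_id, year = x$year, framework = x$framework,
    n_indicators = nrow(x$panels), n_elements = nrow(x$elements),
    n_dimensions = nrow(x$dimensions),
    best_dimension = x$dimensions$dimension[x$dimensions$rank == 1],
    worst_dimension = x$dimensions$dimension[x$dimensions$rank == nrow(x$dimensions)],
    mean_closeness = mean(x$dimensions$closeness)
  )
}

#' Plot element closeness by dimension
#'
#' Horizontal bars of relative closeness per element, faceted by
#' dimension; the dashed line marks the midpoint 0.5.
#'
#' @param object A `city_eval`.
#' @param level `"element"` or `"dimension"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot city_eval
#' @export
autoplot.city_eval <- function(object, level = c("element", "dimension"), ...) {
  level <- rlang::arg_match(level)
  if (level == "dimension") {
    df <- object$dimensions
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$closeness,
      y = stats::reorder(.data$dimension, .data$closeness)
    ))
  } else {
    df <- object$elements
    p <- ggplot2::ggplot(df, ggplot2::aes(
      x = .data$closeness,
      y = stats::reorder(.data$element, .data$closeness)
    )) +
      ggplot2::facet_wrap(ggplot2::vars(.data$dimension), scales = "free_y")
  }
  p +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = "relative closeness c*", y = NULL,
      title = sprintf("%s: closeness to health-indicator standards", object$city_id)
    )
}
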
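#' Index of item-objective congruence for one indicator
#'
#' An odd-sized expert panel rates a candidate indicator -1 (unsuitable),
#' 0 (uncertain) or +1 (suitable); the IOC index is the mean rating and
#' the indicator is retained when the index reaches the threshold
#' (conventionally 0.5).
#'
#' @param scores Integer vector of expert ratings in `{-1, 0, 1}`; odd
#'   length, at least 3.
#' @param threshold Retention threshold in `(0, 1]`.
#' @param code Optional indicator code carried through to the result.
#' @return One-row tibble: `code`, `n_experts`, `index`, `retained`.
#' @export
ioc_index <- function(scores, threshold = 0.5, code = NA_character_) {
  if (!all(scores %in% c(-1, 0, 1))) {
    abort("expert scores must be -1, 0 or +1")
  }
  if (length(scores) < 3 || length(scores) %% 2 == 0) {
    abort("expert panel must have an odd size of at least 3")
  }
  if (threshold <= 0 || threshold > 1) abort("threshold must be in (0, 1]")
  idx <- sum(scores) / length(scores)
  tibble(code = code, n_experts = length(scores), index = idx,
         retained = idx >= threshold)
}

#' Screen a table of expert scores
#'
#' @param data Wide tibble: a `code` column plus one integer column per
#'   expert (ratings in `{-1, 0, 1}`).
#' @param threshold Retention threshold, see [ioc_index()].
#' @return Tibble with one row per indicator: `code`, `n_experts`,
#'   `index`, `retained`.
#' @export
ioc_screen <- function(data, threshold = 0.5) {
  data <- as_tibble(data)
  if (!"code" %in% names(data)) abort("score table needs a 'code' column")
  score_cols <- setdiff(names(data), "code")
  if (!length(score_cols)) abort("score table has no expert columns")
  purrr::pmap_dfr(data, \(code, ...) {
    ioc_index(as.numeric(c(...)), threshold = threshold, code = code)
  })
}

#' Classify indicators into three-level improvement strategies
#'
#' Compares each observed value with the *printed* standards only
#' (substitute ideals never act as thresholds).  For a `MAX` indicator
#' with both ideals: at or above PI is Level 1 (growth-maintaining),
#' between NI and PI is Level 2 (monitoring), below NI is Level 3
#' (improvement); `MIN` is symmetric.  With a single printed ideal the
#' rule is two-valued: the good side of the sole standard is Level 1,
#' the other side Level 3.  Explicit overrides (policy placements that a
#' pure value rule cannot express) win and are marked `basis =
#' "override"`.
#'
#' @param fw A [framework()].
#' @param observation A [city_observation()].
#' @param overrides Named integer vector code -> level; defaults to the
#'   framework's `strategy_overrides`.
#' @return Tibble: `code`, `level` (1/2/3), `label`, `basis`.
#' @export
classify_strategy <- function(fw, observation, overrides = NULL) {
  stopifnot(inherits(fw, "his_framework"), inherits(observation, "city_observation"))
  overrides <- overrides %||% fw$strategy_overrides
  labels <- c("growth-maintaining", "monitoring", "improvement")
  ind <- fw$indicators
  rule_level <- function(code, orientation, pi, ni) {
    value <- observation$values[[code]]
    has_pi <- !is.na(pi)
    has_ni <- !is.na(ni)
    if (!has_pi && !has_ni) {
      abort(sprintf("%s: no printed standard to classify against", code))
    }
    if (orientation == "MAX") {
      if (has_pi && has_ni) {
        if (value >= pi) 1L else if (value >= ni) 2L else 3L
      } else if (has_pi) {
        if (value >= pi) 1L else 3L
      } else {
        if (value >= ni) 1L else 3L
      }
    } else {
      if (has_pi && has_ni) {
        if (value <= pi) 1L else if (value <= ni) 2L else 3L
      } else if (has_pi) {
        if (value <= pi) 1L else 3L
      } else {
        if (value <= ni) 1L else 3L
      }
    }
  }
  out <- purrr::pmap_dfr(
    list(ind$code, ind$orientation, ind$positive_ideal, ind$negative_ideal),
    \(code, orientation, pi, ni) {
      if (code %in% names(overrides)) {
        lvl <- as.integer(overrides[[code]])
        tibble(code = code, level = lvl, label = labels[lvl], basis = "override")
      } else {
        lvl <- rule_level(code, orientation, pi, ni)
        tibble(code = code, level = lvl, label = labels[lvl], basis = "rule")
      }
    }
  )
  out
}
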
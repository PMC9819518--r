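#' Construct a hierarchical indicator framework
#'
#' A framework is the three-level hierarchy used throughout the package:
#' dimensions (e.g. health, environment) contain elements (e.g. health
#' status) which contain indicators.  Every indicator carries a
#' measurement orientation (`MAX` = more is better, `MIN` = less is
#' better) and its published benchmark values: the positive ideal (PI,
#' the standard to reach) and the negative ideal (NI, the floor to stay
#' away from).  Standards tables frequently print only one side; the
#' unstated side is then resolved from an explicit per-indicator
#' substitute or from the framework-level `missing_ideal_default`.
#'
#' @param dimensions Tibble/data frame with columns `code`, `name`.
#' @param elements Tibble with columns `code`, `name`, `dimension`.
#' @param indicators Tibble with columns `code`, `name`, `unit`,
#'   `orientation` (`"MAX"`/`"MIN"`), `positive_ideal`, `negative_ideal`
#'   (use `NA` for an unstated ideal), optional `substitute_pi`,
#'   `substitute_ni`, and `element`.
#' @param missing_ideal_default Policy for indicators with an unstated
#'   ideal and no explicit substitute: `"zero"` (use 0), `"one"` (use 1)
#'   or `"omit"` (drop the indicator from evaluation, with a warning).
#' @param pcms Optional named list of [pcm] objects keyed by judgment
#'   group code (an element code, or a dimension code where each element
#'   holds a single indicator).
#' @param strategy_overrides Optional named integer vector mapping
#'   indicator codes to a forced strategy level in `1:3`.
#' @param name Optional framework name.
#'
#' @return An object of class `his_framework`.
#' @seealso [load_framework()], [bundled_fixture()], [resolve_ideals()]
#' @export
framework <- function(dimensions, elements, indicators,
                      missing_ideal_default = c("zero", "one", "omit"),
                      pcms = list(), strategy_overrides = integer(),
                      name = NULL) {
  missing_ideal_default <- rlang::arg_match(missing_ideal_default)
  dimensions <- as_tibble(dimensions)
  elements <- as_tibble(elements)
  indicators <- as_tibble(indicators)
  for (col in c("substitute_pi", "substitute_ni")) {
    if (!col %in% names(indicators)) indicators[[col]] <- NA_real_
  }
  if (!"unit" %in% names(indicators)) indicators$unit <- NA_character_
  num_cols <- c("positive_ideal", "negative_ideal", "substitute_pi", "substitute_ni")
  indicators[num_cols] <- lapply(indicators[num_cols], as.numeric)

  fw <- structure(
    list(
      name = name %||% "framework",
      dimensions = dimensions[, c("code", "name")],
      elements = elements[, c("code", "name", "dimension")],
      indicators = indicators[, c("code", "name", "unit", "orientation",
                                  "positive_ideal", "negative_ideal",
                                  "substitute_pi", "substitute_ni", "element")],
      missing_ideal_default = missing_ideal_default,
      pcms = pcms,
      strategy_overrides = strategy_overrides
    ),
    class = "his_framework"
  )
  validate_framework(fw)
}

validate_framework <- function(fw) {
  ind <- fw$indicators
  ele <- fw$elements
  dim <- fw$dimensions

  dup <- function(x) unique(x[duplicated(x)])
  if (length(d <- dup(ind$code))) {
    abort(sprintf("duplicate indicator code(s): %s", paste(d, collapse = ", ")))
  }
  if (length(d <- dup(ele$code))) {
    abort(sprintf("duplicate element code(s): %s", paste(d, collapse = ", ")))
  }
  if (length(d <- dup(dim$code))) {
    abort(sprintf("duplicate dimension code(s): %s", paste(d, collapse = ", ")))
  }
  orphan_el <- setdiff(ind$element, ele$code)
  if (length(orphan_el)) {
    abort(sprintf("indicator(s) reference unknown element(s): %s",
                  paste(orphan_el, collapse = ", ")))
  }
  orphan_dim <- setdiff(ele$dimension, dim$code)
  if (length(orphan_dim)) {
    abort(sprintf("element(s) reference unknown dimension(s): %s",
                  paste(orphan_dim, collapse = ", ")))
  }
  empty_el <- setdiff(ele$code, ind$element)
  if (length(empty_el)) {
    abort(sprintf("element(s) contain no indicators: %s",
                  paste(empty_el, collapse = ", ")))
  }
  empty_dim <- setdiff(dim$code, ele$dimension)
  if (length(empty_dim)) {
    abort(sprintf("dimension(s) contain no elements: %s",
                  paste(empty_dim, collapse = ", ")))
  }
  if (!all(ind$orientation %in% c("MAX", "MIN"))) {
    bad <- ind$code[!ind$orientation %in% c("MAX", "MIN")]
    abort(sprintf("orientation must be MAX or MIN for: %s",
                  paste(bad, collapse = ", ")))
  }
  # orientation/ideal contradiction only checkable when both sides printed
  both <- !is.na(ind$positive_ideal) & !is.na(ind$negative_ideal)
  bad_max <- both & ind$orientation == "MAX" &
    ind$positive_ideal < ind$negative_ideal
  bad_min <- both & ind$orientation == "MIN" &
    ind$positive_ideal > ind$negative_ideal
  if (any(bad_max | bad_min)) {
    abort(sprintf("PI/NI contradict orientation for: %s",
                  paste(ind$code[bad_max | bad_min], collapse = ", ")))
  }
  fin <- function(x) is.na(x) | is.finite(x)
  if (!all(fin(ind$positive_ideal) & fin(ind$negative_ideal) &
             fin(ind$substitute_pi) & fin(ind$substitute_ni))) {
    abort("ideals and substitutes must be finite")
  }
  if (length(fw$strategy_overrides)) {
    unknown <- setdiff(names(fw$strategy_overrides), ind$code)
    if (length(unknown)) {
      abort(sprintf("strategy override(s) for unknown indicator(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    if (!all(fw$strategy_overrides %in% 1:3)) abort("strategy overrides must be in 1:3")
  }
  fw
}

#' @export
print.his_framework <- function(x, ...) {
  cat(sprintf("<his_framework> %s\n", x$name))
  cat(sprintf("  %d dimensions, %d elements, %d indicators; %d judgment group(s)\n",
              nrow(x$dimensions), nrow(x$elements), nrow(x$indicators),
              length(x$pcms)))
  cat(sprintf("  missing-ideal default: %s\n", x$missing_ideal_default))
  invisible(x)
}

#' Flatten a framework to one row per indicator
#'
#' @param fw A [framework()].
#' @return A tibble with the indicator columns joined to their element and
#'   dimension codes and names.
#' @export
framework_table <- function(fw) {
  stopifnot(inherits(fw, "his_framework"))
  fw$indicators |>
    dplyr::left_join(
      dplyr::rename(fw$elements, element = "code", element_name = "name"),
      by = "element"
    ) |>
    dplyr::left_join(
      dplyr::rename(fw$dimensions, dimension = "code", dimension_name = "name"),
      by = "dimension"
    )
}

#' Resolve effective benchmark ideals for every indicator
#'
#' Printed ideals always win; an unstated ideal falls back to the
#' indicator's explicit substitute, then to the framework policy
#' (`"zero"`, `"one"`, or `"omit"`).  Substitutes never overwrite printed
#' values.
#'
#' @param fw A [framework()].
#' @param policy Override for `fw$missing_ideal_default`.
#' @return `framework_table(fw)` plus columns `pi_eff`, `ni_eff`,
#'   `pi_printed`, `ni_printed`.  Under `"omit"`, indicators with an
#'   unresolvable ideal are dropped with a warning.
#' @export
resolve_ideals <- function(fw, policy = NULL) {
  policy <- policy %||% fw$missing_ideal_default
  policy <- rlang::arg_match0(policy, c("zero", "one", "omit"))
  tbl <- framework_table(fw)
  default <- switch(policy, zero = 0, one = 1, omit = NA_real_)
  tbl <- tbl |>
    dplyr::mutate(
      pi_printed = !is.na(.data$positive_ideal),
      ni_printed = !is.na(.data$negative_ideal),
      pi_eff = dplyr::coalesce(.data$positive_ideal, .data$substitute_pi, default),
      ni_eff = dplyr::coalesce(.data$negative_ideal, .data$substitute_ni, default)
    )
  if (policy == "omit") {
    drop <- is.na(tbl$pi_eff) | is.na(tbl$ni_eff)
    if (any(drop)) {
      warn(sprintf("omitting indicator(s) with unresolvable ideals: %s",
                   paste(tbl$code[drop], collapse = ", ")))
      tbl <- tbl[!drop, ]
    }
  }
  if (anyNA(tbl$pi_eff) || anyNA(tbl$ni_eff)) {
    bad <- tbl$code[is.na(tbl$pi_eff) | is.na(tbl$ni_eff)]
    abort(sprintf("unresolvable ideal(s) for: %s", paste(bad, collapse = ", ")))
  }
  tbl
}

#' Load a framework from a YAML document
#'
#' The document mirrors the framework structure: `dimensions`, `elements`
#' and `indicators` sequences, an optional `missing_ideal_default`,
#' optional `pcm` blocks keyed by group code listing each upper-triangle
#' row (reciprocals and the unit diagonal are derived; entries may be
#' fraction strings such as `"1/3"`), and an optional
#' `strategy_overrides` mapping.
#'
#' @param path Path to a YAML file, or a YAML string.
#' @return A validated [framework()].
#' @export
load_framework <- function(path) {
  doc <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(path)
  }
  for (key in c("dimensions", "elements", "indicators")) {
    if (is.null(doc[[key]])) abort(sprintf("framework document lacks '%s'", key))
  }
  num_or_na <- function(x) if (is.null(x) || (is.character(x) && x == "-")) NA_real_ else as.numeric(x)
  chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)

  dimensions <- purrr::map_dfr(doc$dimensions, \(d) tibble(code = d$code, name = chr(d$name)))
  elements <- purrr::map_dfr(doc$elements, \(e) {
    tibble(code = e$code, name = chr(e$name), dimension = e$dimension)
  })
  indicators <- purrr::map_dfr(doc$indicators, \(i) {
    tibble(
      code = i$code, name = chr(i$name), unit = chr(i$unit),
      orientation = toupper(chr(i$orientation)),
      positive_ideal = num_or_na(i$positive_ideal),
      negative_ideal = num_or_na(i$negative_ideal),
      substitute_pi = num_or_na(i$substitute_pi),
      substitute_ni = num_or_na(i$substitute_ni),
      element = i$element
    )
  })
  pcms <- purrr::imap(doc$pcm %||% list(), \(block, code) {
    pcm_from_upper(block$labels, block$upper)
  })
  overrides <- unlist(doc$strategy_overrides %||% list())
  overrides <- if (length(overrides)) setNames(as.integer(overrides), names(overrides)) else integer()

  framework(
    dimensions, elements, indicators,
    missing_ideal_default = doc$missing_ideal_default %||% "zero",
    pcms = pcms, strategy_overrides = overrides,
    name = doc$name %||% "framework"
  )
}

# Build the full reciprocal matrix from upper-triangle rows
# (row i holds a_{i,i+1} .. a_{i,n}).
pcm_from_upper <- function(labels, upper) {
  n <- length(labels)
  if (length(upper) != n - 1) {
    abort(sprintf("pcm block needs %d upper-triangle rows, got %d", n - 1, length(upper)))
  }
  A <- diag(n)
  for (i in seq_len(n - 1)) {
    vals <- parse_saaty(upper[[i]])
    if (length(vals) != n - i) {
      abort(sprintf("pcm upper row %d needs %d entries, got %d", i, n - i, length(vals)))
    }
    A[i, (i + 1):n] <- vals
    A[(i + 1):n, i] <- 1 / vals
  }
  pcm(A, labels)
}

#' Serialize a framework back to YAML
#'
#' Round-trips with [load_framework()]: loading the returned text yields
#' an identical framework.
#'
#' @param fw A [framework()].
#' @param path Optional file path; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to `path`.
#' @export
framework_to_yaml <- function(fw, path = NULL) {
  stopifnot(inherits(fw, "his_framework"))
  drop_na <- function(lst) lst[!vapply(lst, \(x) is.null(x) || (length(x) == 1 && is.na(x)), logical(1))]
  doc <- list(
    name = fw$name,
    missing_ideal_default = fw$missing_ideal_default,
    dimensions = purrr::pmap(fw$dimensions, \(code, name) drop_na(list(code = code, name = name))),
    elements = purrr::pmap(fw$elements, \(code, name, dimension) {
      drop_na(list(code = code, name = name, dimension = dimension))
    }),
    indicators = purrr::pmap(fw$indicators, \(code, name, unit, orientation,
                                              positive_ideal, negative_ideal,
                                              substitute_pi, substitute_ni, element) {
      drop_na(list(code = code, name = name, unit = unit, orientation = orientation,
                   positive_ideal = positive_ideal, negative_ideal = negative_ideal,
                   substitute_pi = substitute_pi, substitute_ni = substitute_ni,
                   element = element))
    })
  )
  if (length(fw$pcms)) {
    doc$pcm <- purrr::map(fw$pcms, \(p) {
      n <- length(p$labels)
      list(labels = p$labels,
           upper = purrr::map(seq_len(n - 1), \(i) as.list(p$matrix[i, (i + 1):n])))
    })
  }
  if (length(fw$strategy_overrides)) {
    doc$strategy_overrides <- as.list(fw$strategy_overrides)
  }
  txt <- yaml::as.yaml(doc, precision = 15)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Load a city observation table
#'
#' Reads a `code,value` CSV (optionally preceded by `# city_id:` and
#' `# year:` comment lines) and checks it against a framework: every
#' framework indicator must be present with a finite numeric value;
#' codes unknown to the framework are kept out with a warning.
#'
#' @param path CSV file path.
#' @param fw The [framework()] the observation must cover.
#' @param city_id,year Metadata; when `NULL`, taken from the comment
#'   header if present.
#' @return An object of class `city_observation`: list with `city_id`,
#'   `year`, and `values` (named numeric vector in framework indicator
#'   order).
#' @export
load_city_observation <- function(path, fw, city_id = NULL, year = NULL) {
  stopifnot(inherits(fw, "his_framework"))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(sprintf("^#\\s*%s\\s*:", key), meta, value = TRUE)
    if (length(hit)) trimws(sub(sprintf("^#\\s*%s\\s*:", key), "", hit[1])) else NULL
  }
  city_id <- city_id %||% get_meta("city_id") %||% "city"
  year <- year %||% get_meta("year")
  tbl <- readr::read_csv(I(paste(lines, collapse = "\n")), comment = "#",
                         show_col_types = FALSE)
  if (!all(c("code", "value") %in% names(tbl))) {
    abort("observation table needs 'code' and 'value' columns")
  }
  vals <- suppressWarnings(as.numeric(tbl$value))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    abort(sprintf("non-numeric or non-finite value in row(s): %s (%s)",
                  paste(bad, collapse = ", "),
                  paste(tbl$code[bad], collapse = ", ")))
  }
  tbl$value <- vals
  city_observation(setNames(tbl$value, tbl$code), fw,
                   city_id = city_id,
                   year = if (is.null(year)) NA_integer_ else as.integer(year))
}

#' Construct a city observation from a named vector
#'
#' @param values Named numeric vector, indicator code -> value.
#' @param fw The covering [framework()].
#' @param city_id,year Metadata.
#' @return A `city_observation`.
#' @export
city_observation <- function(values, fw, city_id = "city", year = NA_integer_) {
  stopifnot(inherits(fw, "his_framework"))
  codes <- fw$indicators$code
  missing <- setdiff(codes, names(values))
  if (length(missing)) {
    abort(sprintf("observation is missing indicator(s): %s",
                  paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(values), codes)
  if (length(extra)) {
    warn(sprintf("ignoring code(s) not in framework: %s", paste(extra, collapse = ", ")))
  }
  vals <- as.numeric(values[codes])
  if (!all(is.finite(vals))) {
    abort(sprintf("non-finite value(s) for: %s",
                  paste(codes[!is.finite(vals)], collapse = ", ")))
  }
  structure(
    list(city_id = city_id, year = year, values = setNames(vals, codes)),
    class = "city_observation"
  )
}

#' @export
print.city_observation <- function(x, ...) {
  cat(sprintf("<city_observation> %s (%s): %d indicator values\n",
              x$city_id, ifelse(is.na(x$year), "year unknown", x$year),
              length(x$values)))
  invisible(x)
}

#' @method as_tibble city_observation
#' @export
as_tibble.city_observation <- function(x, ...) {
  tibble(code = names(x$values), value = unname(x$values))
}
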
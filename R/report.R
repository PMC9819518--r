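#' Render the printed-table views of an evaluation
#'
#' Produces the three standard report tables at their conventional
#' printed precision: the per-indicator ideal values \eqn{A^+}/\eqn{A^-}
#' (2 decimals), the per-indicator squared deviations (3 decimals), and
#' the element/dimension closeness table with ranks (2 decimals).
#' Rounding is half-away-from-zero and happens only here, at render
#' time; all upstream computation keeps full precision.
#'
#' @param eval A `city_eval` from [evaluate_city()].
#' @return Named list of tibbles: `ideals`, `deviations`, `closeness`,
#'   `weights`.
#' @export
render_printed_tables <- function(eval) {
  stopifnot(inherits(eval, "city_eval"))
  ideals <- eval$panels |>
    dplyr::transmute(
      CODE = .data$code,
      A_plus = round_half_up(.data$a_plus, 2),
      A_minus = round_half_up(.data$a_minus, 2)
    )
  deviations <- eval$panels |>
    dplyr::transmute(
      CODE = .data$code,
      S_plus = round_half_up(.data$dev_plus_sq, 3),
      S_minus = round_half_up(.data$dev_minus_sq, 3)
    )
  el <- eval$elements |>
    dplyr::transmute(
      dimension = .data$dimension, element = .data$element,
      codes = .data$members,
      S_plus = round_half_up(.data$s_plus, 2),
      S_minus = round_half_up(.data$s_minus, 2),
      closeness = round_half_up(.data$closeness, 2),
      rank = .data$rank, level = "element"
    )
  dm <- eval$dimensions |>
    dplyr::transmute(
      dimension = .data$dimension, element = NA_character_,
      codes = .data$members,
      S_plus = round_half_up(.data$s_plus, 2),
      S_minus = round_half_up(.data$s_minus, 2),
      closeness = round_half_up(.data$closeness, 2),
      rank = .data$rank, level = "dimension"
    )
  closeness <- dplyr::bind_rows(
    purrr::map_dfr(unique(el$dimension), \(d) {
      dplyr::bind_rows(el[el$dimension == d, ], dm[dm$dimension == d, ])
    })
  )
  weights <- eval$weights |>
    dplyr::select(dplyr::any_of(c("code", "weight", "group",
                                  "lambda_max", "ci", "ri", "cr")))
  list(ideals = ideals, deviations = deviations, closeness = closeness,
       weights = weights)
}

# canonical machine-readable payload; deterministic for identical inputs
report_payload <- function(eval, strategy = NULL) {
  list(
    metadata = list(
      city_id = eval$city_id,
      year = if (is.na(eval$year)) NULL else eval$year,
      framework = eval$framework,
      policy = eval$policy,
      tool = "benchtopsis",
      version = as.character(utils::packageVersion("benchtopsis"))
    ),
    weights = eval$weights,
    panels = eval$panels,
    elements = eval$elements,
    dimensions = eval$dimensions,
    strategy = strategy
  )
}

#' Write an evaluation report to disk
#'
#' The JSON report is the canonical output; the CSV tables are rounded
#' render-time views of the same payload.  On any failure no partial
#' files are left behind.
#'
#' @param eval A `city_eval`.
#' @param json Path for the JSON report (`NULL` to skip).
#' @param tables_dir Directory for CSV views (`NULL` to skip): writes
#'   `weights.csv`, `ideals.csv`, `deviations.csv`, `closeness.csv`, and
#'   `strategy.csv` when a strategy table is supplied.
#' @param strategy Optional strategy tibble from [classify_strategy()].
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(eval, json = NULL, tables_dir = NULL, strategy = NULL) {
  stopifnot(inherits(eval, "city_eval"))
  payload <- report_payload(eval, strategy)
  written <- character()
  # stage in a temp dir so failures leave nothing behind
  stage <- tempfile("report_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  staged <- list()
  if (!is.null(json)) {
    tmp <- file.path(stage, basename(json))
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    staged[[tmp]] <- json
  }
  if (!is.null(tables_dir)) {
    tabs <- render_printed_tables(eval)
    if (!is.null(strategy)) tabs$strategy <- strategy
    for (nm in names(tabs)) {
      tmp <- file.path(stage, paste0(nm, ".csv"))
      readr::write_csv(tabs[[nm]], tmp)
      staged[[tmp]] <- file.path(tables_dir, paste0(nm, ".csv"))
    }
    if (!dir.exists(tables_dir)) dir.create(tables_dir, recursive = TRUE)
  }
  for (tmp in names(staged)) {
    dest <- staged[[tmp]]
    if (!file.copy(tmp, dest, overwrite = TRUE)) {
      abort(sprintf("failed to write %s", dest))
    }
    written <- c(written, dest)
  }
  invisible(written)
}

#' Read back a JSON evaluation report
#'
#' @param path Path written by [write_report()].
#' @return The report payload as a list of tibbles plus metadata.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("weights", "panels", "elements", "dimensions", "strategy")) {
    if (!is.null(doc[[nm]])) doc[[nm]] <- as_tibble(doc[[nm]])
  }
  doc
}
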
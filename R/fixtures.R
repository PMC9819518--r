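#' Bundled worked-example fixtures
#'
#' `"khon_kaen_2019"` is the package's reference case: the 45-indicator
#' health-sustainability framework (four dimensions, fifteen elements)
#' with its published health-indicator standards, the nine
#' expert-consensus judgment matrices, the strategy-override table, and
#' the Khon Kaen province observation for 2019.  Unstated standards
#' cells resolve to the zero default except the two mortality floors
#' (VR03, VR13) that carry an explicit substitute positive ideal of 1;
#' substitutes are stored separately and never overwrite published
#' values.
#'
#' @param name Fixture identifier; currently `"khon_kaen_2019"`.
#' @return A list with components `framework` ([framework()]),
#'   `observation` ([city_observation()]) and `pcms` (named list of
#'   [pcm] judgment groups, also attached to the framework).
#' @export
bundled_fixture <- function(name = "khon_kaen_2019") {
  known <- c("khon_kaen_2019")
  if (!name %in% known) {
    abort(sprintf("unknown fixture '%s'; available: %s",
                  name, paste(known, collapse = ", ")))
  }
  fw <- load_framework(system.file("extdata", paste0(name, ".yaml"),
                                   package = "benchtopsis", mustWork = TRUE))
  obs <- load_city_observation(
    system.file("extdata", paste0(name, "_city.csv"),
                package = "benchtopsis", mustWork = TRUE),
    fw
  )
  list(framework = fw, observation = obs, pcms = fw$pcms)
}

#' @rdname bundled_fixture
#' @return `list_fixtures()` returns the available fixture names.
#' @export
list_fixtures <- function() c("khon_kaen_2019")
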
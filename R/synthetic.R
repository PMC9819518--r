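#' Configuration for the synthetic-data generator
#'
#' The generator emulates the three inputs the evaluator consumes: a
#' hierarchical framework with benchmark ideals, near-consistent Saaty
#' judgment matrices per element, and a city observation positioned
#' relative to the ideals.  `city_position` interpolates linearly
#' between the negative ideal (0) and the positive ideal (1), which
#' makes the closeness anchor properties directly exercisable.
#'
#' @param seed Integer seed fixing the full output stream.
#' @param n_dimensions,elements_per_dimension,indicators_per_element
#'   Framework sizes (each at least 1; at least 2 indicators per element
#'   so judgment matrices are well formed).
#' @param pcm_noise Log-scale perturbation applied to consistent
#'   judgment ratios before snapping to the Saaty scale; 0 gives the
#'   most consistent admissible matrix.
#' @param city_position Position of generated city values in `[0, 1]`
#'   (0 = at NI, 1 = at PI).
#' @param city_jitter Jitter of city values as a fraction of the PI-NI
#'   span.
#' @param missing_ideal_rate Probability that an indicator's
#'   naturally-floored ideal is left unstated (NI for `MAX`, PI for
#'   `MIN`), to be resolved by the zero default policy.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_dimensions = 4L,
                         elements_per_dimension = 4L,
                         indicators_per_element = 3L,
                         pcm_noise = 0.1, city_position = 0.5,
                         city_jitter = 0, missing_ideal_rate = 0) {
  cfg <- list(
    seed = as.integer(seed), n_dimensions = as.integer(n_dimensions),
    elements_per_dimension = as.integer(elements_per_dimension),
    indicators_per_element = as.integer(indicators_per_element),
    pcm_noise = pcm_noise, city_position = city_position,
    city_jitter = city_jitter, missing_ideal_rate = missing_ideal_rate
  )
  if (cfg$n_dimensions < 1 || cfg$elements_per_dimension < 1 ||
        cfg$indicators_per_element < 1) {
    abort("framework sizes must be at least 1")
  }
  if (cfg$pcm_noise < 0) abort("pcm_noise must be non-negative")
  if (cfg$city_position < 0 || cfg$city_position > 1) {
    abort("city_position must be in [0, 1]")
  }
  if (cfg$missing_ideal_rate < 0 || cfg$missing_ideal_rate > 1) {
    abort("missing_ideal_rate must be in [0, 1]")
  }
  structure(cfg, class = "synth_config")
}

# admissible Saaty judgments: 1/9 .. 1/2, 1 .. 9
saaty_values <- function() c(1 / (9:2), 1:9)

snap_saaty <- function(x) {
  s <- saaty_values()
  s[vapply(x, \(v) which.min(abs(log(v) - log(s))), integer(1))]
}

#' Generate a synthetic near-consistent judgment matrix
#'
#' Starts from the perfectly consistent ratios \eqn{w_i / w_j} of the
#' target weights, perturbs each upper-triangle entry multiplicatively
#' by \eqn{\exp(\sigma z)}, snaps to the nearest admissible Saaty value
#' (so every generated matrix is a legal instrument) and fills the lower
#' triangle by reciprocity.
#'
#' @param target_weights Positive weights summing to 1 (length 2..15).
#' @param noise Log-scale perturbation \eqn{\sigma \ge 0}.
#' @param seed Integer seed.
#' @param labels Optional criterion labels.
#' @return A [pcm].
#' @export
generate_pcm <- function(target_weights, noise = 0, seed = 1L, labels = NULL) {
  n <- length(target_weights)
  if (n < 2 || n > 15) abort("target_weights must have length 2..15")
  if (any(target_weights <= 0)) abort("target_weights must be positive")
  w <- target_weights / sum(target_weights)
  labels <- labels %||% paste0("C", seq_len(n))
  withr::with_seed(as.integer(seed), {
    A <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- (w[i] / w[j]) * exp(noise * rnorm(1))
        a <- snap_saaty(a)
        A[i, j] <- a
        A[j, i] <- 1 / a
      }
    }
    pcm(A, labels)
  })
}

#' Generate a synthetic benchmark framework
#'
#' Orientations are split roughly 50/50.  `MAX` indicators draw
#' `0 < NI < PI`, `MIN` indicators `0 < PI < NI`.  With probability
#' `missing_ideal_rate` the ideal whose natural substitute is a zero
#' floor is left unstated (NI for `MAX`, PI for `MIN`), mirroring how
#' standards tables omit the side a zero stands in for; the framework's
#' zero default policy then resolves it.  Each element receives a
#' near-consistent judgment matrix over its indicators.
#'
#' @param cfg A [synth_config()].
#' @return A validated [framework()] with judgment groups attached.
#' @export
generate_framework <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    dims <- tibble(
      code = sprintf("D%02d", seq_len(cfg$n_dimensions)),
      name = sprintf("Dimension %d", seq_len(cfg$n_dimensions))
    )
    elements <- purrr::map_dfr(seq_len(cfg$n_dimensions), \(d) {
      tibble(
        code = sprintf("D%02dE%02d", d, seq_len(cfg$elements_per_dimension)),
        name = sprintf("Element %d.%d", d, seq_len(cfg$elements_per_dimension)),
        dimension = sprintf("D%02d", d)
      )
    })
    n_ind <- nrow(elements) * cfg$indicators_per_element
    codes <- sprintf("SI%03d", seq_len(n_ind))
    element_of <- rep(elements$code, each = cfg$indicators_per_element)
    orientation <- sample(c("MAX", "MIN"), n_ind, replace = TRUE)
    lo <- runif(n_ind, 1, 50)
    hi <- lo * runif(n_ind, 1.5, 4)
    pi_val <- ifelse(orientation == "MAX", hi, lo)
    ni_val <- ifelse(orientation == "MAX", lo, hi)
    drop <- runif(n_ind) < cfg$missing_ideal_rate
    ni_val[orientation == "MAX" & drop] <- NA_real_
    pi_val[orientation == "MIN" & drop] <- NA_real_
    indicators <- tibble(
      code = codes, name = paste("Indicator", codes), unit = "index",
      orientation = orientation, positive_ideal = pi_val,
      negative_ideal = ni_val, element = element_of
    )
    # judgment groups: per element, except that single-indicator elements
    # are pooled into one dimension-level group (the layout used for
    # dimensions whose elements each hold one indicator)
    if (cfg$indicators_per_element >= 2) {
      groups <- split(codes, factor(element_of, levels = elements$code))
    } else {
      if (cfg$elements_per_dimension < 2) {
        abort("cannot form judgment groups: need >= 2 indicators per element or >= 2 elements per dimension")
      }
      dim_of <- elements$dimension[match(element_of, elements$code)]
      groups <- split(codes, factor(dim_of, levels = dims$code))
    }
    pcm_seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
    pcms <- purrr::imap(groups, \(member, g) {
      tw <- as.numeric(stats::rgamma(length(member), shape = 3))
      generate_pcm(tw / sum(tw), noise = cfg$pcm_noise,
                   seed = pcm_seeds[[which(names(groups) == g)]], labels = member)
    })
    crs <- vapply(pcms, \(p) ahp_weights(p)$cr, numeric(1))
    if (any(crs >= 0.1)) {
      inform(sprintf(
        "%d of %d synthetic judgment group(s) fail C.R. < 0.1 (rate %.2f); lower pcm_noise to avoid",
        sum(crs >= 0.1), length(crs), mean(crs >= 0.1)))
    }
    framework(dims, elements, indicators, missing_ideal_default = "zero",
              pcms = pcms, name = sprintf("synthetic-%d", cfg$seed))
  })
}

#' Generate a synthetic city observation
#'
#' Each value is `NI + position * (PI - NI)` on the resolved ideals,
#' plus optional Gaussian jitter scaled by the PI-NI span, truncated at
#' zero.  `position = 1` with zero jitter puts the city exactly on every
#' positive ideal; `position = 0`, exactly on every negative ideal.
#'
#' @param fw A [framework()].
#' @param position Position in `[0, 1]` between NI and PI.
#' @param jitter Jitter fraction of the span (0 = none).
#' @param seed Integer seed.
#' @param city_id Metadata label.
#' @return A [city_observation()].
#' @export
generate_city <- function(fw, position = 0.5, jitter = 0, seed = 1L,
                          city_id = "synthetic-city") {
  stopifnot(inherits(fw, "his_framework"))
  if (position < 0 || position > 1) abort("position must be in [0, 1]")
  ideals <- resolve_ideals(fw)
  withr::with_seed(as.integer(seed), {
    span <- ideals$pi_eff - ideals$ni_eff
    vals <- ideals$ni_eff + position * span
    if (jitter > 0) vals <- vals + jitter * abs(span) * rnorm(nrow(ideals))
    vals <- pmax(vals, 0)
    city_observation(setNames(vals, ideals$code), fw, city_id = city_id)
  })
}
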
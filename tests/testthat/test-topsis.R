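test_that("single-indicator panels reproduce the worked-example columns", {
  # life expectancy: city between its two published standards
  p <- build_panel("VR01", "MAX", 75.20, 85.29, 73.2, 0.48)
  expect_equal(rhu(p$a_plus, 2), 0.30)
  expect_equal(rhu(p$a_minus, 2), 0.26)
  expect_equal(rhu(p$dev_plus_sq, 3), 0.001)
  expect_equal(rhu(p$dev_minus_sq, 3), 0.000)
  # forest-area rate: unstated negative ideal resolved to the zero floor
  p <- build_panel("VR25", "MAX", 11.23, 40, 0, 0.48)
  expect_equal(rhu(p$a_plus, 2), 0.46)
  expect_equal(p$a_minus, 0)
  # diabetes mortality: city beyond the floor defines its own anti-ideal
  p <- build_panel("VR13", "MIN", 30.52, 1, 18.5, 0.33)
  expect_equal(rhu(p$dev_plus_sq, 3), 0.074)
  expect_equal(p$dev_minus_sq, 0)
  expect_equal(p$a_minus, p$v_city)
  # low-birth-weight: deviation fixed by independent recomputation
  # (full-precision weight; the printed table carries a transposed cell here)
  w02 <- unname(priority_vector(bundled_fixture()$pcms$HS)[2])
  p <- build_panel("VR02", "MIN", 6.28, 5, 20, w02)
  expect_equal(p$dev_minus_sq, 0.0067, tolerance = 1e-2)
})

test_that("degenerate and invalid panels are handled explicitly", {
  # city == PI == NI: normalized components collapse to 1/sqrt(3)
  p <- build_panel("X", "MAX", 7, 7, 7, 0.5)
  expect_equal(p$r_city, 1 / sqrt(3))
  expect_equal(p$a_plus, p$a_minus)
  expect_equal(p$dev_plus_sq, 0)
  expect_equal(p$dev_minus_sq, 0)
  expect_error(build_panel("X", "MAX", 0, 0, 0, 0.5), "all-zero")
  expect_error(build_panel("X", "MAX", 1, 2, 0, 1.5), "weight")
  expect_error(build_panel("X", "UP", 1, 2, 0, 0.5), "orientation")
})

test_that("panels match the brute-force oracle on random inputs", {
  withr::with_seed(42, {
    for (i in 1:200) {
      city <- runif(1, 0, 100)
      a <- runif(1, 0, 100)
      b <- runif(1, 0, 100)
      w <- runif(1, 0.01, 1)
      ornt <- sample(c("MAX", "MIN"), 1)
      p <- build_panel("X", ornt, city, max(a, b), min(a, b), w)
      o <- oracle_panel(city, max(a, b), min(a, b), w, ornt)
      expect_equal(p$a_plus, o$a_plus, tolerance = 1e-12)
      expect_equal(p$a_minus, o$a_minus, tolerance = 1e-12)
      expect_equal(p$dev_plus_sq, o$dev_plus_sq, tolerance = 1e-12)
      expect_equal(p$dev_minus_sq, o$dev_minus_sq, tolerance = 1e-12)
      expect_true(all(c(p$r_city, p$r_pi, p$r_ni) >= 0 &
                        c(p$r_city, p$r_pi, p$r_ni) <= 1))
    }
  })
})

test_that("per-indicator scale invariance: normalization cancels units", {
  base <- build_panel("X", "MIN", 6.28, 5, 20, 0.13)
  for (k in c(1e-3, 0.5, 7, 1e4)) {
    scaled <- build_panel("X", "MIN", 6.28 * k, 5 * k, 20 * k, 0.13)
    expect_equal(scaled$r_city, base$r_city, tolerance = 1e-12)
    expect_equal(scaled$v_city, base$v_city, tolerance = 1e-12)
    expect_equal(scaled$dev_plus_sq, base$dev_plus_sq, tolerance = 1e-12)
    expect_equal(scaled$dev_minus_sq, base$dev_minus_sq, tolerance = 1e-12)
  }
})

test_that("moving a city toward its ideal never increases its deviation", {
  withr::with_seed(7, {
    for (i in 1:50) {
      pi_v <- runif(1, 50, 100)
      ni_v <- runif(1, 1, 40)
      w <- runif(1, 0.05, 1)
      vals <- sort(runif(5, ni_v, pi_v))
      # MAX: larger city value is closer to PI
      devs <- vapply(vals, \(v) build_panel("X", "MAX", v, pi_v, ni_v, w)$dev_plus_sq,
                     numeric(1))
      expect_true(all(diff(devs) <= 1e-12))
      # MIN orientation is symmetric: smaller is closer to PI
      devs_min <- vapply(vals, \(v) build_panel("X", "MIN", v, ni_v, pi_v, w)$dev_plus_sq,
                         numeric(1))
      expect_true(all(diff(devs_min) >= -1e-12))
    }
  })
})

test_that("closeness aggregation follows the S-/(S+ + S-) rule", {
  fx <- bundled_fixture()
  ev <- evaluate_city(fx$framework, fx$observation)
  hs <- ev$elements[ev$elements$element == "HS", ]
  expect_equal(rhu(hs$s_plus, 2), 0.13)
  expect_equal(rhu(hs$closeness, 2), 0.47)
  hp <- ev$elements[ev$elements$element == "HP", ]
  expect_equal(rhu(hp$closeness, 2), 0.76)
  # closeness equals the oracle on the same deviations
  panels <- ev$panels[ev$panels$element == "HS", ]
  expect_equal(hs$closeness,
               oracle_closeness(panels$dev_plus_sq, panels$dev_minus_sq),
               tolerance = 1e-12)
  expect_error(aggregate_closeness(panels[0, ]), "empty")
  # a city pinned to its negative ideals scores zero
  ni_panels <- dplyr::bind_rows(
    build_panel("A", "MAX", 2, 10, 2, 0.5),
    build_panel("B", "MIN", 9, 1, 9, 0.5)
  )
  expect_equal(aggregate_closeness(ni_panels)$closeness, 0)
})

test_that("ranking is deterministic with ties broken by code", {
  res <- tibble::tibble(scope = c("B", "A", "C"), closeness = c(0.5, 0.5, 0.9))
  ranked <- rank_results(res)
  expect_equal(ranked$rank, c(3L, 2L, 1L))
  expect_equal(rank_results(res[1, ])$rank, 1L)
  # permuting the input permutes ranks identically
  perm <- c(3, 1, 2)
  expect_equal(rank_results(res[perm, ])$rank, ranked$rank[perm])
})

test_that("full evaluation reproduces the published dimension ordering", {
  fx <- bundled_fixture()
  ev <- evaluate_city(fx$framework, fx$observation)
  dims <- ev$dimensions
  expect_equal(dims$dimension[order(dims$rank)],
               c("ECDm", "SODm", "HEDm", "ENDm"))
  expect_equal(rhu(dims$closeness[dims$dimension == "ENDm"], 2), 0.28)
  hhd <- ev$elements[ev$elements$element == "HHD", ]
  expect_equal(hhd$closeness, 0)
  expect_equal(hhd$rank, 4L)
})

test_that("closeness anchors: a city on its ideals scores 1 (PI) or 0 (NI)", {
  fw <- tiny_framework()
  ideals <- resolve_ideals(fw)
  at_pi <- city_observation(setNames(ideals$pi_eff, ideals$code), fw)
  ev <- evaluate_city(fw, at_pi)
  expect_true(all(abs(ev$elements$closeness - 1) < 1e-12))
  expect_true(all(abs(ev$dimensions$closeness - 1) < 1e-12))
  at_ni <- city_observation(setNames(ideals$ni_eff, ideals$code), fw)
  ev0 <- evaluate_city(fw, at_ni)
  expect_true(all(ev0$elements$closeness < 1e-12))
})

test_that("tidy, glance and autoplot expose the result tree", {
  fx <- bundled_fixture()
  ev <- evaluate_city(fx$framework, fx$observation)
  expect_equal(nrow(tidy(ev)), 15)
  expect_equal(nrow(tidy(ev, "dimension")), 4)
  expect_equal(nrow(tidy(ev, "indicator")), 45)
  g <- glance(ev)
  expect_equal(g$best_dimension, "ECDm")
  expect_equal(g$worst_dimension, "ENDm")
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(autoplot(ev, "dimension"), "ggplot")
})
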
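test_that("pcm validation enforces the Saaty invariants without repair", {
  expect_s3_class(pcm(rbind(c(1, 3), c(1 / 3, 1)), c("a", "b")), "pcm")
  expect_error(pcm(rbind(c(1, 2), c(0.4, 1)), c("a", "b")), "reciprocity")
  expect_error(pcm(rbind(c(1, 2), c(0.5, 2)), c("a", "b")), "diagonal")
  expect_error(pcm(rbind(c(1, 12), c(1 / 12, 1)), c("a", "b")), "Saaty scale")
  expect_error(pcm(matrix(1, 1, 1), "a"), "at least 2")
  expect_error(pcm(rbind(c(1, -3), c(-1 / 3, 1)), c("a", "b")), "positive")
  # the published health-status matrix is a legal instrument
  hs <- bundled_fixture()$pcms$HS
  expect_equal(length(hs$labels), 5)
  expect_equal(hs$matrix[2, 1], 1 / 5)
})

test_that("column-normalize/row-average recovers consistent weights exactly", {
  w <- c(0.6, 0.3, 0.1)
  A <- outer(w, w, `/`)
  p <- pcm(A, c("a", "b", "c"))
  expect_equal(unname(priority_vector(p)), w, tolerance = 1e-15)
  expect_equal(unname(priority_vector(p, "eigen")), w, tolerance = 1e-9)
  expect_equal(ahp_lambda_max(p, priority_vector(p)), 3, tolerance = 1e-12)
  fit <- ahp_weights(p)
  expect_equal(fit$ci, 0, tolerance = 1e-12)
  expect_equal(fit$cr, 0, tolerance = 1e-12)
  # all-ones matrix: symmetry forces equal weights
  ones <- pcm(matrix(1, 3, 3), c("a", "b", "c"))
  expect_equal(unname(priority_vector(ones)), rep(1 / 3, 3))
})

test_that("consistent-matrix recovery holds for random weights", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(3:9, 1)
      w <- runif(n, 0.5, 2)  # ratios stay within the Saaty range
      w <- w / sum(w)
      p <- pcm(outer(w, w, `/`), paste0("c", 1:n))
      expect_lt(max(abs(priority_vector(p) - w)), 1e-12)
      expect_equal(ahp_lambda_max(p, w), n, tolerance = 1e-12)
      expect_equal(ahp_weights(p)$cr, 0, tolerance = 1e-12)
    })
  }
})

test_that("published judgment matrices yield the printed weights", {
  pcms <- bundled_fixture()$pcms
  for (g in names(published_weight_vectors)) {
    w <- priority_vector(pcms[[g]])
    expect_equal(unname(rhu(w, 2)), published_weight_vectors[[g]],
                 info = g)
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("lambda_max matches an independent power-iteration oracle", {
  pcms <- bundled_fixture()$pcms
  for (g in c("HS", "CDC", "HR")) {
    p <- pcms[[g]]
    w <- priority_vector(p)
    expect_equal(ahp_lambda_max(p, w), oracle_lambda_max(p$matrix, w),
                 tolerance = 1e-12)
  }
  # frozen oracle values for the two spot-checked groups
  hs <- pcms$HS
  expect_equal(ahp_lambda_max(hs, priority_vector(hs)), 5.18, tolerance = 1e-2)
  cdc <- pcms$CDC
  expect_equal(ahp_lambda_max(cdc, priority_vector(cdc)), 4.12, tolerance = 1e-2)
})

test_that("consistency report uses the tabulated random index", {
  hs <- bundled_fixture()$pcms$HS
  fit <- ahp_weights(hs)
  expect_equal(fit$ri, 1.12)
  expect_equal(fit$ci, 0.0451, tolerance = 1e-3)
  expect_equal(rhu(fit$cr, 2), 0.04)
  expect_true(fit$acceptable)
  # n = 2 cannot be inconsistent
  two <- ahp_weights(pcm(rbind(c(1, 3), c(1 / 3, 1)), c("a", "b")))
  expect_equal(two$cr, 0)
  expect_true(two$acceptable)
  # beyond the table an explicit random index is required
  big_w <- rep(1 / 16, 16)
  big <- pcm(outer(big_w, big_w, `/`), paste0("c", 1:16))
  expect_error(ahp_weights(big), "supply")
  expect_equal(ahp_weights(big, ri = 1.6)$cr, 0, tolerance = 1e-12)
  # the classic lookup differs at n = 12
  w12 <- rep(1 / 12, 12)
  p12 <- pcm(outer(w12, w12, `/`), paste0("c", 1:12))
  expect_equal(ahp_weights(p12)$ri, 1.48)
  expect_equal(ahp_weights(p12, ri_table = "saaty_classic")$ri, 1.54)
})

test_that("permuting criteria permutes weights and leaves C.R. unchanged", {
  p <- bundled_fixture()$pcms$HSS
  n <- length(p$labels)
  for (seed in 1:5) {
    perm <- withr::with_seed(seed, sample(n))
    pp <- pcm(p$matrix[perm, perm], p$labels[perm])
    expect_equal(unname(priority_vector(pp)),
                 unname(priority_vector(p)[perm]), tolerance = 1e-12)
    expect_equal(ahp_weights(pp)$cr, ahp_weights(p)$cr, tolerance = 1e-12)
  }
})

test_that("framework weighting covers every indicator and gates on C.R.", {
  fx <- bundled_fixture()
  w <- weights_for_framework(fx$framework)
  expect_equal(w$code, fx$framework$indicators$code)
  expect_false(anyNA(w$weight))
  expect_true(all(w$cr < 0.1))
  expect_equal(w$weight[w$code == "VR45"], 0.52)
  # full-precision export on request
  wf <- weights_for_framework(fx$framework, digits = NULL)
  grp <- wf$weight[wf$group == "HS"]
  expect_equal(sum(grp), 1, tolerance = 1e-9)

  # incomplete coverage aborts naming the uncovered indicators
  fw <- tiny_framework()
  expect_error(weights_for_framework(fw, fw$pcms["E1"]), "I3")
  # a contradictory group aborts naming the group
  fw2 <- framework(
    dimensions = tibble::tibble(code = "D1", name = "d"),
    elements = tibble::tibble(code = "E1", name = "e", dimension = "D1"),
    indicators = tibble::tibble(
      code = c("A", "B", "C"), name = c("a", "b", "c"), unit = "u",
      orientation = "MAX", positive_ideal = 1, negative_ideal = 0,
      element = "E1"
    ),
    pcms = list(E1 = pcm(rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9), c(9, 1 / 9, 1)),
                         c("A", "B", "C")))
  )
  expect_error(weights_for_framework(fw2), "consistency")
})
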
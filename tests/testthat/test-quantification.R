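test_that("per-condition totals and counts sum correctly", {
  crys <- toy_crystals(areas = c(50, 50, 50), classes = c(0L, 0L, 0L))
  q <- quantify_wells(crys)
  expect_equal(q$total_area_COM, 150)
  expect_identical(q$count_COM, 3L)
  expect_equal(q$crystal_total_area, 150)

  # noise-only field contributes zero crystal total
  noise <- toy_crystals(areas = c(10, 20), classes = c(3L, 3L))
  qn <- quantify_wells(noise)
  expect_equal(qn$crystal_total_area, 0)
  expect_equal(qn$total_area_noise, 30)

  # unlabeled segments are an error
  bad <- crys; bad$class[2] <- NA
  expect_error(quantify_wells(bad), "unlabeled")
})

test_that("crystal total equals COM + COD + ND exactly", {
  set.seed(3)
  crys <- toy_crystals(areas = runif(40, 5, 200),
                       classes = sample(0:3, 40, replace = TRUE))
  q <- quantify_wells(crys)
  expect_identical(q$crystal_total_area,
                   q$total_area_COM + q$total_area_COD + q$total_area_ND)
})

test_that("normalization is per experiment, control = 100%, and scale invariant", {
  mk <- function(scale, exp_id) rbind(
    toy_crystals(areas = scale * c(60, 40), classes = c(0L, 1L),
                 experiment = exp_id, compound = "control", conc = 0),
    toy_crystals(areas = scale * c(3, 2), classes = c(0L, 1L),
                 experiment = exp_id, compound = "cmpd", conc = 1000))
  q1 <- quantify_wells(mk(1, "E1"))
  n1 <- normalize_to_control(q1)
  expect_equal(n1$normalized_total[n1$concentration_nM == 0], 100)
  expect_equal(n1$normalized_total[n1$concentration_nM == 1000], 5)

  # different absolute control areas, identical ratios -> identical series
  q2 <- quantify_wells(rbind(mk(1, "E1"), mk(7.3, "E2")))
  n2 <- normalize_to_control(q2)
  e1 <- n2[n2$experiment_id == "E1", ]
  e2 <- n2[n2$experiment_id == "E2", ]
  expect_equal(e1$normalized_total, e2$normalized_total)
  expect_equal(e1$normalized_COM, e2$normalized_COM)

  # absent or zero control is an explicit error
  no_ctrl <- toy_crystals(areas = 10, classes = 0L, conc = 100)
  expect_error(normalize_to_control(quantify_wells(no_ctrl)), "no control")
  zero <- rbind(toy_crystals(areas = 5, classes = 3L, compound = "control",
                             conc = 0),
                toy_crystals(areas = 5, classes = 0L, conc = 100,
                             well = "W2"))
  expect_error(normalize_to_control(quantify_wells(zero)), "zero crystal area")
})

test_that("MIC is the lowest grid concentration strictly below threshold", {
  conc <- c(100, 300, 1000, 3000)
  mic <- min_inhibitory_concentration(conc, c(80, 30, 4, 1))
  expect_true(mic$reached)
  expect_equal(mic$concentration_nM, 1000)
  expect_identical(mic$label, "1 µM")

  # all means >= 5% -> sentinel with the grid maximum
  ns <- min_inhibitory_concentration(conc, c(80, 30, 20, 6))
  expect_false(ns$reached)
  expect_identical(ns$label, "> 3 µM")

  # exactly 5.0% everywhere -> not reached (strict inequality)
  ex <- min_inhibitory_concentration(conc, rep(5, 4))
  expect_false(ex$reached)

  expect_error(min_inhibitory_concentration(numeric(0), numeric(0)), "empty")

  # non-monotone series: the definition still picks the lowest qualifying
  nm <- min_inhibitory_concentration(conc, c(4, 30, 2, 1))
  expect_equal(nm$concentration_nM, 100)
})

test_that("pointwise lowering of the series never increases the MIC", {
  set.seed(23)
  conc <- c(40, 100, 300, 1000, 3000, 10000)
  for (k in 1:25) {
    means <- runif(6, 0, 120)
    m0 <- min_inhibitory_concentration(conc, means)
    lower <- pmax(means - runif(6, 0, 50), 0)
    m1 <- min_inhibitory_concentration(conc, lower)
    c0 <- if (m0$reached) m0$concentration_nM else Inf
    c1 <- if (m1$reached) m1$concentration_nM else Inf
    expect_lte(c1, c0)
  }
})

test_that("inhibition_result averages across experiments and calls both MICs", {
  mk <- function(exp_id, f) rbind(
    toy_crystals(areas = c(60, 30, 10), classes = c(0L, 1L, 2L),
                 experiment = exp_id, compound = "control", conc = 0),
    toy_crystals(areas = f * c(60, 30, 10), classes = c(0L, 1L, 2L),
                 experiment = exp_id, compound = "cmpd", conc = 300,
                 well = "W2"),
    toy_crystals(areas = 0.01 * f * c(60, 30, 10), classes = c(0L, 1L, 2L),
                 experiment = exp_id, compound = "cmpd", conc = 1000,
                 well = "W3"))
  crys <- rbind(mk("E1", 0.5), mk("E2", 0.3))
  res <- inhibition_result(normalize_to_control(quantify_wells(crys)), "cmpd")
  expect_s3_class(res, "inhibition_result")
  expect_equal(res$series$mean_normalized_total, c(40, 0.4))
  expect_equal(res$MIC_complete$concentration_nM, 1000)
  # MIC_complete >= MIC_COM when both reached
  expect_gte(res$MIC_complete$concentration_nM,
             res$MIC_COM$concentration_nM)
})

test_that("COM size distribution pools areas and collapses to zero width
           for identical crystals", {
  crys <- toy_crystals(areas = rep(42, 6), classes = rep(0L, 6))
  sd0 <- com_size_distribution(crys)
  expect_equal(sd0$summary$q75 - sd0$summary$q25, 0)
  expect_identical(sd0$summary$n, 6L)

  mixed <- rbind(crys,
                 toy_crystals(areas = c(10, 20), classes = c(1L, 2L),
                              conc = 100, well = "W2"))
  sd1 <- com_size_distribution(mixed)
  # only COM-class crystals pooled
  expect_identical(sum(sd1$summary$n), 6L)
})

test_that("concentration formatting matches screen-report conventions", {
  expect_identical(format_concentration(40), "40 nM")
  expect_identical(format_concentration(300), "300 nM")
  expect_identical(format_concentration(3000), "3 µM")
  expect_identical(format_concentration(1e5), "100 µM")
})
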
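panelOf <- function(ods, antigens = sprintf("AG-%02d", seq_along(ods)),
                    antibody = "polyclonal")
  data.frame(antigen = antigens, antibody = antibody, od1 = ods,
             stringsAsFactors = FALSE)

test_that("background isolation recovers a planted near-background cluster", {
  set.seed(57)
  low <- pmax(rnorm(57, 0.16, 0.12), 0)
  high <- runif(20, 0.45, 1.2)
  panel <- panelOf(c(low, high))
  bg <- determineBackground(panel)
  highNames <- panel$antigen[58:77]
  expect_length(intersect(bg$antigens, highNames), 0L)
  expect_lt(abs(bg$mean - 0.16), 0.03)
  expect_gt(length(bg$antigens), 40L)            # bulk of the 57 retained
})

test_that("degenerate and explicit background modes", {
  flat <- panelOf(rep(0.2, 10))
  bg <- determineBackground(flat)
  expect_length(bg$antigens, 10L)
  expect_identical(bg$sd, 0)
  expect_identical(bg$mean, 0.2)

  explicit <- determineBackground(panelOf(c(0.1, 0.2, 0.9)),
                                  background = c("AG-01", "AG-02"))
  expect_equal(explicit$mean, 0.15)
  expect_identical(explicit$iterations, 0L)
  expect_error(determineBackground(panelOf(c(0.1, 0.2))), "at least 3")
})

test_that("cutoff arithmetic reproduces both published values", {
  expect_equal(determineCutoff(0.16, 0.12, 1), 0.28)
  expect_equal(determineCutoff(0.15, 0.09, 1), 0.24)
  expect_equal(determineCutoff(0.3, 0, 2), 0.3)
  expect_error(determineCutoff(0.1, -0.1), "non-negative")
  expect_error(determineCutoff(0.1, 0.1, 0), "positive")
})

test_that("classification against the published polyclonal cutoff", {
  panel <- panelOf(c(0.26, 0.29, 0.45),
                   antigens = c("Cardiolipin", "TG6", "Somatotropin"))
  res <- classifyAntigens(panel, cutoff = 0.28, backgroundMean = 0.16,
                          backgroundSd = 0.12)
  get <- function(a) res[res$antigen == a, ]
  expect_false(get("Cardiolipin")$reactive)
  expect_true(get("TG6")$reactive)
  expect_true(get("Somatotropin")$reactive)
  expect_lt(get("Somatotropin")$p_value, get("TG6")$p_value)
  expect_identical(res$antigen[1], "Somatotropin")  # sorted by mean OD
})

test_that("classification is monotone and p-values decrease with OD", {
  set.seed(11)
  panel <- panelOf(round(runif(40, 0, 1.2), 3))
  res <- classifyAntigens(panel, 0.28, 0.16, 0.12)
  expect_true(all(diff(res$mean_od) <= 0))
  expect_true(all(diff(res$p_value) >= 0))
  expect_identical(res$reactive, res$mean_od > 0.28)
})

test_that("duplicate-well variation check", {
  m <- data.frame(antigen = c("A", "B", "C", "D"),
                  antibody = "polyclonal",
                  od1 = c(0.30, 0.20, 0.25, 0.40),
                  od2 = c(0.31, 0.30, 0.25, NA),
                  stringsAsFactors = FALSE)
  qc <- duplicateCvCheck(m)
  expect_equal(qc$cv_percent[1], 100 * 0.01 / 0.305, tolerance = 1e-9)
  expect_true(qc$pass[1])
  expect_equal(qc$cv_percent[2], 40)
  expect_false(qc$pass[2])
  expect_identical(qc$cv_percent[3], 0)
  expect_true(qc$pass[3])
  expect_false(qc$assessable[4])                 # single well: not failed
  expect_false(qc$pass[4])
})

test_that("sensitivity and specificity on synthetic panels at a +0.3 OD effect", {
  sens <- spec <- numeric(50)
  for (s in 1:50) {
    sp <- syntheticSpec(seed = 100 + s, reactiveOdShift = 0.3)
    panel <- genElisaPanel(sp)
    truth <- attr(panel, "reactive")
    an <- analyzeReactivity(panel)
    called <- an$reactiveAntigens
    sens[s] <- length(intersect(called, truth)) / length(truth)
    nonre <- setdiff(panel$antigen, truth)
    spec[s] <- length(setdiff(nonre, called)) / length(nonre)
  }
  # a +0.3 shift is only 2.5 background SDs, so the reactive and background
  # OD distributions overlap substantially, and a mean + 1*SD cutoff is a
  # ~z = 1 threshold that Gaussian background necessarily leaks past: both
  # rates are bounded well below 1 by the model itself
  expect_gt(mean(sens), 0.80)
  expect_gt(mean(spec), 0.80)
})

test_that("full reactivity chain emits the reactive list for the intersection", {
  set.seed(5)
  study <- genSyntheticStudy(syntheticSpec(seed = 5))
  an <- analyzeReactivity(study$panel)
  expect_true(all(study$reactiveAntigens %in% an$reactiveAntigens))
  expect_true(all(an$qc$pass[an$qc$assessable]))
  expect_identical(an$results$reactive, an$results$mean_od > an$cutoff)
})
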
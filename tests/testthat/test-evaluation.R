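# independent oracle: trapezoidal area under the 3-point ROC of a hard classifier
trapezoid_auroc <- function(sens, spec) {
  x <- c(0, 1 - spec, 1)
  y <- c(0, sens, 1)
  sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)
}

test_that("binary-prediction AUROC equals the 3-point trapezoid", {
  expect_equal(
    binary_prediction_auroc(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, FALSE, TRUE, FALSE)),
    1.0
  )
  # all-positive predictor on balanced truth: sens 1, spec 0 -> 0.5
  expect_equal(
    binary_prediction_auroc(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE)),
    0.5
  )
  # sens 0.8, spec 0.9: 10 positives with 8 hits, 10 negatives with 9 rejections
  pred <- c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 9), rep(TRUE, 1))
  truth <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(binary_prediction_auroc(pred, truth), trapezoid_auroc(0.8, 0.9))
  expect_equal(binary_prediction_auroc(pred, truth), 0.85)

  expect_error(
    binary_prediction_auroc(c(TRUE, FALSE), c(TRUE, TRUE)),
    class = "resppheno_undefined_metric"
  )
  # symmetry under simultaneous complementation
  set.seed(8)
  p <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  t <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  expect_equal(binary_prediction_auroc(!p, !t), binary_prediction_auroc(p, t))
})

test_that("one-vs-rest metrics match hand-computed confusion arithmetic", {
  # 10 encounters, hand-enumerated confusion for class "IMV Only":
  # truth: 4 IMV Only, 6 other; predictions hit 3 of 4, plus 1 false alarm
  truth <- c(rep("IMV Only", 4), rep("None", 5), "NIPPV Only")
  pred <- c("IMV Only", "IMV Only", "IMV Only", "None", "IMV Only", rep("None", 4), "NIPPV Only")
  m <- one_vs_rest_metrics(pred, truth, "IMV Only")
  # tp=3 fn=1 fp=1 tn=5
  expect_equal(m$n_true, 4L)
  expect_equal(m$n_predicted, 4L)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$auroc, (3 / 4 + 5 / 6) / 2)
  expect_equal(m$auroc, trapezoid_auroc(m$sensitivity, m$specificity))

  exact <- one_vs_rest_metrics(truth, truth, "IMV Only")
  expect_equal(
    c(exact$auroc, exact$sensitivity, exact$specificity),
    c(1, 1, 1)
  )
  # class absent from predictions: sensitivity 0, n_predicted 0
  none_pred <- rep("None", 10)
  m <- one_vs_rest_metrics(none_pred, truth, "IMV Only")
  expect_equal(m$n_predicted, 0L)
  expect_equal(m$sensitivity, 0)
  # class absent from truth: not applicable, never 0 or 1
  m <- one_vs_rest_metrics(pred, truth, "HFNI Failure")
  expect_true(is.na(m$auroc))
})

test_that("macro averages are unweighted means", {
  expect_equal(round(macro_average_auroc(c(0.881, 0.809, 0.825, 0.896)), 3), 0.853)
  expect_equal(round(macro_average_auroc(c(0.717, 0.513, 0.526, 0.659)), 3), 0.604)
  expect_equal(macro_average_auroc(0.7), 0.7)
  expect_error(macro_average_auroc(numeric()), class = "resppheno_undefined_metric")
})

test_that("latency summaries pool correctly", {
  d <- tibble::tibble(
    prompt = c("therapy", "therapy", "medication"),
    latency_seconds = c(1.0, 3.0, 2.0)
  )
  lat <- latency_summary(d)
  expect_equal(lat$mean_latency_seconds[lat$prompt == "therapy"], 2.0)
  # pooled mean equals the call-count-weighted mean of per-prompt means
  per <- lat[lat$prompt != "overall", ]
  expect_equal(
    lat$mean_latency_seconds[lat$prompt == "overall"],
    sum(per$mean_latency_seconds * per$n_calls) / sum(per$n_calls)
  )
})

test_that("evaluate_phenotypes assembles per-class, macro and latency blocks", {
  truth <- c(
    rep("IMV Only", 3), rep("NIPPV Only", 2), rep("HFNI Only", 2),
    rep("NIPPV Failure", 2), rep("None", 6)
  )
  pred <- truth
  pred[1] <- "None" # one miss
  ev <- evaluate_phenotypes(
    tibble::tibble(truth = truth, pred = pred),
    truth = truth, estimate = pred,
    latencies = tibble::tibble(prompt = "phenotype", latency_seconds = c(2, 2))
  )
  td <- tidy(ev)
  expect_equal(nrow(td), 8)
  expect_true(all(td$auroc >= 0 & td$auroc <= 1, na.rm = TRUE))
  # the structural identity holds for every evaluated class
  ok <- !is.na(td$auroc)
  expect_equal(td$auroc[ok], (td$sensitivity[ok] + td$specificity[ok]) / 2)
  g <- glance(ev)
  expect_equal(g$n, length(truth))
  expect_equal(g$agreement, mean(pred == truth))
  expect_equal(
    g$macro_auroc_single_or_none,
    mean(td$auroc[td$class %in% c("IMV Only", "NIPPV Only", "HFNI Only", "None")])
  )
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
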
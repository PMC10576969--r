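# Annotation sets with randomized counts, areas and evidence flags used for
# the rule-engine property tests.
random_annotations <- function(n, seed) {
  fp <- matrix(0.15, 3, 5,
               dimnames = list(c("Yes", "Maybe", "No"),
                               c("reef_present", "chemo_present",
                                 "large_old_present",
                                 "functional_role_visible",
                                 "threatened_present")))
  generateAnnotations(
    generatorConfig(n_images = n, flag_probs = fp,
                    label_probs = c(Yes = 1/3, Maybe = 1/3, No = 1/3)),
    seed = seed)
}

test_that("the tiny fixture exercises every flow-chart branch as designed", {
  res <- classifyImages(makeFixture("tiny"))
  expect_identical(res$step_fired,
                   c("indicator_check", "reef", "chemosynthetic",
                     "large_old", "functional_role", "threatened",
                     "richness_threshold", "monotypic_density",
                     "combined_density", "none", "richness_threshold",
                     "monotypic_density"))
  expect_identical(res$decision[1], "NO_EVIDENCE_EVALUATE_MORE")
  expect_identical(res$decision[10], "NOT_VME_THIS_IMAGE")
  expect_true(all(res$decision[c(2:9, 11:12)] == "VME"))
  # a reef invokes all five FAO criteria; density steps only complexity
  expect_identical(res$fao_criteria[2],
    "uniqueness_rarity,functional_significance,fragility,life_history,structural_complexity")
  expect_identical(res$fao_criteria[9], "structural_complexity")
  # non-VME verdicts advise evaluating more images
  expect_match(res$guidance[1], "more images")
  expect_match(res$guidance[10], "more images")
})

test_that("stated worked example: a 5 /m2 monotypic stand fires step 7", {
  cts <- matrix(10, 1, 1, dimnames = list("Alcyonacea", "w1"))
  x <- VmeImageSet(cts, data.frame(image_id = "w1", area_m2 = 2))
  thr <- thresholdConfig(tau_S = 3, tau_d = c(Alcyonacea = 0.88),
                         tau_D = 4.16)
  res <- classifyImage(x, thresholds = thr)
  expect_identical(res$decision, "VME")
  expect_identical(res$step_fired, "monotypic_density")
  expect_equal(res$max_density, 5.0)
})

test_that("a flagged image with zero counts is still a VME at its step", {
  cts <- matrix(0, 1, 1, dimnames = list("Alcyonacea", "r1"))
  x <- VmeImageSet(cts, data.frame(image_id = "r1", area_m2 = 2,
                                   reef_present = TRUE))
  res <- classifyImage(x)
  expect_identical(res$decision, "VME")
  expect_identical(res$step_fired, "reef")
  # and with the flag off, zero counts mean no evidence at all
  x0 <- VmeImageSet(cts, data.frame(image_id = "r1", area_m2 = 2))
  expect_identical(classifyImage(x0)$decision, "NO_EVIDENCE_EVALUATE_MORE")
})

test_that("classification is total and criteria match the decision", {
  x <- random_annotations(2000, seed = 42)
  res <- classifyImages(x)
  expect_identical(nrow(as.data.frame(res)), 2000L)
  expect_true(all(res$decision %in%
    c("VME", "NOT_VME_THIS_IMAGE", "NO_EVIDENCE_EVALUATE_MORE")))
  # decision is VME iff a positive step fired
  expect_identical(res$decision == "VME",
                   !res$step_fired %in% c("indicator_check", "none"))
  # FAO criteria are attached iff the verdict is VME
  expect_identical(nzchar(res$fao_criteria), res$decision == "VME")
  s <- decisionSummary(res)
  expect_identical(sum(s$by_decision), 2000L)
  expect_identical(sum(s$by_step), 2000L)
})

test_that("the engine is stateless: permuting images permutes results", {
  x <- random_annotations(200, seed = 7)
  res <- classifyImages(x)
  perm <- sample(ncol(x))
  res_p <- classifyImages(x[, perm])
  expect_identical(as.data.frame(res_p), as.data.frame(res[perm, ]))
})

test_that("earlier steps short-circuit later inputs", {
  x <- random_annotations(500, seed = 13)
  res <- classifyImages(x)
  fired_flag <- res$step_fired %in%
    c("reef", "chemosynthetic", "large_old")
  # turn on every later flag and inflate counts: outcomes must not change
  x2 <- x
  SummarizedExperiment::colData(x2)$functional_role_visible <- TRUE
  SummarizedExperiment::colData(x2)$threatened_present <- TRUE
  SummarizedExperiment::assay(x2, "counts") <-
    assay(x2, "counts") * 10 + 1
  res2 <- classifyImages(x2)
  expect_identical(res2$step_fired[fired_flag], res$step_fired[fired_flag])
  expect_identical(res2$decision[fired_flag], res$decision[fired_flag])
})

test_that("more evidence never downgrades a VME verdict", {
  x <- random_annotations(1000, seed = 99)
  res <- classifyImages(x)
  # raise every count; previously-VME images must stay VME
  x_up <- x
  SummarizedExperiment::assay(x_up, "counts") <-
    assay(x_up, "counts") + 2
  res_up <- classifyImages(x_up)
  was_vme <- res$decision == "VME"
  expect_true(all(res_up$decision[was_vme] == "VME"))
  # and nothing may land on NO_EVIDENCE after counts were added
  expect_false(any(res_up$decision == "NO_EVIDENCE_EVALUATE_MORE"))
  # setting any flag true upgrades to VME outright
  x_fl <- x
  SummarizedExperiment::colData(x_fl)$reef_present <- TRUE
  expect_true(all(classifyImages(x_fl)$decision == "VME"))
})

test_that("threshold configs are validated", {
  expect_error(thresholdConfig(tau_S = 0, tau_D = 1), "tau_S")
  expect_error(thresholdConfig(tau_S = 3, tau_D = -1), "tau_D")
  expect_error(thresholdConfig(tau_S = 3, tau_d = c(Alcyonacea = 0),
                               tau_D = 1), "positive")
  f <- tempfile(fileext = ".yaml")
  writeLines(c("tau_S: 3", "tau_d: {Alcyonacea: 0.5}"), f)
  expect_error(readThresholds(f), "tau_D")
  # tau_d names must resolve in the registry used for classification
  thr <- thresholdConfig(tau_S = 3, tau_d = c(Widgetozoa = 1), tau_D = 4)
  expect_error(classifyImages(makeFixture("tiny"), thresholds = thr),
               "unresolvable")
  # defaults load and are the documented midpoints
  def <- defaultThresholds()
  expect_equal(def@tau_D, 4.16)
  expect_equal(unname(def@tau_d["Scleractinia"]), 2.035)
})

test_that("richness step can use taxa per unit area instead of a count", {
  cts <- matrix(c(1, 1, 1), 3, 1,
                dimnames = list(c("Alcyonacea", "Porifera", "Pennatulacea"),
                                "q1"))
  x <- VmeImageSet(cts, data.frame(image_id = "q1", area_m2 = 10))
  thr_count <- thresholdConfig(tau_S = 3, tau_D = 100)
  expect_identical(classifyImage(x, thresholds = thr_count)$step_fired,
                   "richness_threshold")
  thr_area <- thresholdConfig(tau_S = 3, tau_D = 100,
                              richness_metric = "per_area")
  # 0.3 taxa per m2 is far below 3: the step no longer fires
  expect_identical(classifyImage(x, thresholds = thr_area)$decision,
                   "NOT_VME_THIS_IMAGE")
})
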
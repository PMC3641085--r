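tiny_tagged_log <- function() {
  tibble::tibble(
    child_id = "TD01", group = "TD", semester = "S1", scene_id = "sc01",
    duration_s = 60,
    time_s = c(5, 20, 22, 40),
    actor = c("caregiver", "caregiver", "infant", "caregiver"),
    code = c("CG_VOC", "CG_VOC", "INF_LOOK_PERS", "CG_VOC"),
    kind = "point", end_time_s = NA_real_,
    speaker = c("mother", "father", "none", "mother"),
    speech_type = c("parentese", "other_speech", "none", "parentese")
  )
}

test_that("response records carry OR-consistent indicators per vocalisation", {
  log <- tiny_tagged_log()
  bg <- extract_bigrams(log)
  rec <- build_response_dataset(log, bg)
  expect_equal(nrow(rec), 3)
  # vocalisation at t=20 is answered by a receptive event at lag 2
  hit <- rec[rec$cg_time == 20, ]
  expect_equal(hit$receptive, 1L)
  expect_equal(hit$toward_people, 1L)
  expect_equal(hit$any, 1L)
  # unanswered vocalisations carry all-zero indicators
  miss <- rec[rec$cg_time %in% c(5, 40), ]
  expect_true(all(miss$any == 0))
  expect_true(all(miss[, c("object", "receptive", "expressive", "active",
                           "exploratory", "intersubjective")] == 0))
})

test_that("missing speaker or speech type on a vocal event is an error", {
  log <- tiny_tagged_log()
  log$speech_type[1] <- "none"
  bg <- extract_bigrams(tiny_tagged_log())
  expect_error(build_response_dataset(log, bg), "speech type")
  log2 <- tiny_tagged_log()
  log2$speaker[1] <- "none"
  expect_error(build_response_dataset(log2, bg), "speaker")
})

test_that("cell-wise empirical response rates track the design probabilities", {
  d <- glmm_sim_design(intercept = stats::qlogis(0.4), speech_parentese = 0,
                       n_children_per_group = 5, scenes_per_semester = 2,
                       vocalisations_per_scene = 12, vocal_spacing = 7,
                       scene_duration = 90, subject_sd = 0, regup_per_scene = 0,
                       random_seed = 14)
  st <- synth_interaction_study(d)
  rec <- build_response_dataset(st$events, extract_bigrams(st$events),
                                include_other_speakers = TRUE)
  n <- nrow(rec)
  phat <- mean(rec$any)
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / n))
})

test_that("with no between-child heterogeneity the GLMM reduces to logistic regression", {
  d <- glmm_sim_design(intercept = -0.2, speech_parentese = 0.6,
                       n_children_per_group = 10, scenes_per_semester = 2,
                       vocalisations_per_scene = 15, vocal_spacing = 7,
                       scene_duration = 120, subject_sd = 0,
                       random_seed = 15)
  st <- synth_interaction_study(d)
  rec <- build_response_dataset(st$events, extract_bigrams(st$events))
  mix <- fit_response_glmm(rec, "any")
  glm_ <- fit_response_glmm(rec, "any", random_intercept = FALSE)
  expect_lt(mix$random_intercept_var, 0.02)
  expect_equal(tidy(mix)$estimate, tidy(glm_)$estimate, tolerance = 1e-3)
  expect_equal(glm_$random_intercept_var, 0)
})

test_that("a known speech-type effect is recovered from one large simulated study", {
  d <- glmm_sim_design(intercept = -0.5, speech_parentese = 0.5,
                       n_children_per_group = 10, scenes_per_semester = 2,
                       vocalisations_per_scene = 17, vocal_spacing = 7,
                       scene_duration = 120, subject_sd = 0.4,
                       random_seed = 16)
  st <- synth_interaction_study(d)
  rec <- build_response_dataset(st$events, extract_bigrams(st$events))
  expect_gte(nrow(rec), 1500)
  fit <- fit_response_glmm(rec, "any")
  td <- tidy(fit)
  est <- td$estimate[td$term == "parentese vs other_speech"]
  se <- td$std_error[td$term == "parentese vs other_speech"]
  expect_lt(abs(est - 0.5), 3 * se)
  expect_true(fit$converged)
  expect_true(all(td$std_error > 0))
  expect_true(all(td$p_value > 0 & td$p_value <= 1))
})

test_that("the post-hoc suite stratifies once per group and group-semester", {
  d <- study_design(n_children_per_group = 4, scenes_per_semester = 1,
                    random_seed = 18)
  st <- synth_interaction_study(d)
  rec <- build_response_dataset(st$events, extract_bigrams(st$events))
  ph <- posthoc_suite(rec, response = "any")
  labels <- c(names(ph$fits), ph$skipped$stratum)
  expect_setequal(
    labels,
    c("group=AD", "group=TD",
      as.vector(outer(c("group=AD", "group=TD"),
                      paste0(",semester=", c("S1", "S2", "S3")), paste0)))
  )
  # an empty stratum is reported as skipped, not silently dropped
  rec_s1 <- rec[!(rec$group == "AD" & rec$semester == "S3"), ]
  ph2 <- posthoc_suite(rec_s1, response = "any")
  expect_true("group=AD,semester=S3" %in% ph2$skipped$stratum)
})

test_that("the parentese trend model finds the built-in decline and rejects single semesters", {
  d <- study_design(n_children_per_group = 8, scenes_per_semester = 2,
                    regup_per_scene = 0, random_seed = 19)
  st <- synth_interaction_study(d)
  tr <- parentese_trend(st$events)
  td <- tidy(tr)
  # mother proportions fall 0.60/0.45/0.35, fathers 0.20/0.15/0.15:
  # both successive contrasts must come out negative
  expect_lt(td$estimate[td$term == "S2 vs S1"], 0)
  expect_lt(td$estimate[td$term == "S3 vs S2"], 0)
  one_sem <- st$events[st$events$semester == "S1", ]
  expect_error(parentese_trend(one_sem), "inestimable")
})

test_that("constant response or too few subjects are rejected", {
  log <- tiny_tagged_log()
  rec <- build_response_dataset(log, extract_bigrams(log))
  rec$any <- 1L
  expect_error(fit_response_glmm(rec, "any"), "constant")
  rec2 <- build_response_dataset(log, extract_bigrams(log))
  expect_error(fit_response_glmm(rec2, "any"), "2 subjects")
})

test_that("tidy and glance return the documented shapes", {
  d <- glmm_sim_design(n_children_per_group = 4, scenes_per_semester = 1,
                       speech_parentese = 0.4, random_seed = 20)
  st <- synth_interaction_study(d)
  rec <- build_response_dataset(st$events, extract_bigrams(st$events))
  fit <- fit_response_glmm(rec, "any", fixed = c("semester", "speech_type"))
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std_error", "z", "p_value"))
  expect_true(all(c("S2 vs S1", "S3 vs S2",
                    "parentese vs other_speech") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_subjects, 8)
  tab <- model_summary_table(list(any = fit))
  expect_true("any" %in% names(tab))
})
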
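scene_log <- function(cg_times, inf_times, cg_code = "CG_VOC",
                      inf_code = "INF_LOOK_PERS", speech = "parentese") {
  n_cg <- length(cg_times); n_inf <- length(inf_times)
  tibble::tibble(
    child_id = "TD01", group = "TD", semester = "S1", scene_id = "sc01",
    duration_s = 60,
    time_s = c(cg_times, inf_times),
    actor = rep(c("caregiver", "infant"), c(n_cg, n_inf)),
    code = c(rep(cg_code, n_cg), rep(inf_code, n_inf)),
    kind = "point", end_time_s = NA_real_,
    speaker = rep(c("mother", "none"), c(n_cg, n_inf)),
    speech_type = rep(c(speech, "none"), c(n_cg, n_inf))
  )
}

test_that("the 3-second window keeps lags 0..3 and drops lag 4", {
  log <- scene_log(10, c(10, 12, 13, 14))
  bg <- extract_bigrams(log)
  expect_equal(nrow(bg), 3)
  expect_equal(sort(bg$lag), c(0, 2, 3))
})

test_that("one infant event may answer several caregiver events", {
  log <- scene_log(c(10, 11), 12)
  bg <- extract_bigrams(log)
  expect_equal(nrow(bg), 2)
  expect_equal(sort(bg$lag), c(1, 2))
  # nearest-only pairing keeps both (one infant event per caregiver event)
  bg_n <- extract_bigrams(log, pairing = "nearest")
  expect_equal(nrow(bg_n), 2)
})

test_that("logs without infant events produce no bi-grams", {
  log <- scene_log(c(5, 10), numeric(0))
  expect_equal(nrow(extract_bigrams(log)), 0)
})

test_that("unmapped behaviour codes are rejected", {
  log <- scene_log(5, 6, inf_code = "INF_UNKNOWN")
  expect_error(extract_bigrams(log), "unmapped")
})

test_that("extraction equals the brute-force all-pairs oracle on random logs", {
  for (seed in 1:50) {
    ev <- random_event_log(seed)
    bg <- extract_bigrams(ev)
    expect_equal(bigram_key(bg), bigram_key(oracle_bigrams(ev)),
                 ignore_attr = TRUE)
    if (nrow(bg)) {
      expect_true(all(bg$lag >= 0 & bg$lag <= 3))
    }
  }
})

test_that("bi-gram counts are invariant to permutation of event rows", {
  ev <- random_event_log(99, n_cg = 12, n_inf = 15)
  set.seed(1)
  shuffled <- ev[sample(nrow(ev)), ]
  expect_equal(bigram_key(extract_bigrams(ev)),
               bigram_key(extract_bigrams(shuffled)), ignore_attr = TRUE)
})

test_that("recovered responses match the generator's linkage when windows cannot overlap", {
  d <- study_design(n_children_per_group = 3, scenes_per_semester = 1,
                    vocalisations_per_scene = 12, vocal_spacing = 7,
                    scene_duration = 90, regup_per_scene = 0, random_seed = 13)
  st <- synth_interaction_study(d)
  bg <- extract_bigrams(st$events)
  got <- dplyr::arrange(
    bg[, c("scene_id", "cg_time", "infant_time", "subtype")],
    scene_id, cg_time, infant_time, subtype
  )
  want <- dplyr::arrange(
    st$truth$links[, c("scene_id", "cg_time", "infant_time", "subtype")],
    scene_id, cg_time, infant_time, subtype
  )
  expect_equal(as.data.frame(got), as.data.frame(want))
})

test_that("speech-type tagging touches exactly the vocal events", {
  log <- dplyr::bind_rows(
    scene_log(c(1, 5, 9, 13), numeric(0), speech = "none"),
    scene_log(c(20, 25), numeric(0), cg_code = "CG_TOUCH", speech = "none")
  )
  tagged <- tag_vocalisations(log, rep("parentese", 4))
  voc <- tagged$code == "CG_VOC"
  expect_true(all(tagged$speech_type[voc] == "parentese"))
  expect_true(all(tagged$speech_type[!voc] == "none"))
  expect_error(tag_vocalisations(log, rep("parentese", 3)), "4 caregiver")
  empty <- scene_log(numeric(0), numeric(0))
  expect_equal(nrow(tag_vocalisations(empty, character(0))), 0)
})

test_that("count tables satisfy the margin identities on arbitrary counts", {
  set.seed(21)
  for (i in 1:10) {
    tbl <- tibble::tibble(
      group = "AD", semester = "S1",
      object = rpois(1, 50), receptive = rpois(1, 50),
      expressive = rpois(1, 50), active = rpois(1, 20),
      exploratory = rpois(1, 20), intersubjective = rpois(1, 20)
    )
    out <- response_margins(tbl)
    expect_equal(out$toward_people,
                 tbl$receptive + tbl$expressive + tbl$active +
                   tbl$exploratory + tbl$intersubjective)
    expect_equal(out$total, out$toward_people + tbl$object)
  }
})

test_that("count_responses aggregates both counting units with denominators", {
  log <- dplyr::bind_rows(
    scene_log(10, c(10, 11), inf_code = "INF_LOOK_PERS"),
    scene_log(30, numeric(0))[1, ]
  )
  bg <- extract_bigrams(log)
  raw <- count_responses(bg, log)
  expect_equal(raw$receptive, 2)       # two bi-grams
  expect_equal(raw$vocalisations, 2)   # two vocal events in the log
  expect_equal(raw$total, 2)
  bin <- count_responses(bg, log, unit = "responses")
  expect_equal(bin$receptive, 1)       # one vocalisation responded
  expect_equal(bin$toward_people, 1)
})

test_that("parentese proportions are exact on a constructed fixture", {
  log <- scene_log(seq(1, 43, by = 6), numeric(0), speech = "none")
  log <- tag_vocalisations(log, rep(c("parentese", "other_speech"),
                                    c(2, 6)))
  pp <- parentese_proportions(log)
  all_cell <- pp[pp$context == "all" & pp$speaker == "mother", ]
  expect_equal(all_cell$proportion, 0.25)
  expect_equal(all_cell$n_vocalisations, 8)
  # no regulation-up states: that context has no rows rather than zeros
  expect_equal(nrow(pp[pp$context == "regulation_up", ]), 0)
  # untagged vocal events are rejected
  expect_error(parentese_proportions(scene_log(1, numeric(0), speech = "none")),
               "tagged")
})

test_that("all-parentese studies give proportion one in every non-empty cell", {
  d <- study_design(n_children_per_group = 2, scenes_per_semester = 1,
                    random_seed = 8)
  d$parentese_proportion$prob <- 1
  st <- synth_interaction_study(d)
  pp <- parentese_proportions(st$events)
  expect_true(all(pp$proportion == 1))
})
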
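# Shared fixtures: cached small detector, random event-log generator and the
# brute-force bi-gram oracle used by the property tests.

.fixture_cache <- new.env(parent = emptyenv())

# Small trained detector shared across classifier tests (20 + 20 utterances,
# reduced mixture sizes to suit the corpus size).
small_detector <- function() {
  if (is.null(.fixture_cache$detector)) {
    corp <- synth_corpus(20, seed = 101)
    .fixture_cache$detector <-
      train_parentese_detector(corp, fusion_config(0.4, 8, 10), seed = 7)
  }
  .fixture_cache$detector
}

small_test_corpus <- function() {
  if (is.null(.fixture_cache$test_corpus)) {
    .fixture_cache$test_corpus <- synth_corpus(10, seed = 909)
  }
  .fixture_cache$test_corpus
}

# Random single-scene event log over the shipped ICBS map: caregiver point and
# state events plus infant events at integer seconds.
random_event_log <- function(seed, n_cg = 8, n_inf = 10, duration = 60) {
  set.seed(seed)
  map <- load_meta_map()
  cg_codes <- map$code[map$actor == "caregiver"]
  inf_codes <- map$code[map$actor == "infant"]
  cg_code <- sample(cg_codes, n_cg, replace = TRUE)
  cg_kind <- ifelse(cg_code %in% c("CG_REGUP", "CG_REGDOWN"), "state", "point")
  cg_time <- sample(0:(duration - 6), n_cg, replace = TRUE)
  tibble::tibble(
    child_id = "X01", group = "TD", semester = "S1",
    scene_id = sprintf("X01_S1_sc%02d", seed %% 97), duration_s = duration,
    time_s = c(cg_time, sample(0:duration, n_inf, replace = TRUE)),
    actor = rep(c("caregiver", "infant"), c(n_cg, n_inf)),
    code = c(cg_code, sample(inf_codes, n_inf, replace = TRUE)),
    kind = c(cg_kind, rep("point", n_inf)),
    end_time_s = c(ifelse(cg_kind == "state", cg_time + 5, NA_real_),
                   rep(NA_real_, n_inf)),
    speaker = c(sample(c("mother", "father"), n_cg, replace = TRUE),
                rep("none", n_inf)),
    speech_type = c(ifelse(cg_kind == "point",
                           sample(c("parentese", "other_speech"), n_cg,
                                  replace = TRUE), "none"),
                    rep("none", n_inf))
  ) |> dplyr::arrange(time_s, actor, code)
}

# Brute-force all-pairs oracle: double loop over caregiver x infant events.
oracle_bigrams <- function(events, window = 3) {
  map <- load_meta_map()
  cg <- events[events$actor == "caregiver", ]
  inf <- events[events$actor == "infant", ]
  out <- list()
  for (i in seq_len(nrow(cg))) {
    for (j in seq_len(nrow(inf))) {
      if (cg$scene_id[i] != inf$scene_id[j]) next
      lag <- inf$time_s[j] - cg$time_s[i]
      if (lag >= 0 && lag <= window) {
        out[[length(out) + 1L]] <- tibble::tibble(
          scene_id = cg$scene_id[i], cg_time = cg$time_s[i],
          cg_code = cg$code[i], infant_time = inf$time_s[j],
          infant_code = inf$code[j], lag = lag
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(scene_id = character(), cg_time = numeric(),
                          cg_code = character(), infant_time = numeric(),
                          infant_code = character(), lag = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), scene_id, cg_time, infant_time,
                 infant_code)
}

# Canonical sort used when comparing bi-gram sets with the oracle.
bigram_key <- function(bg) {
  dplyr::arrange(
    bg[, c("scene_id", "cg_time", "cg_code", "infant_time", "infant_code",
           "lag")],
    scene_id, cg_time, infant_time, infant_code
  )
}
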
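# Synthetic interaction studies: caregiver vocalisation streams with
# probabilistically triggered infant responses, with full ground truth.

#' Published per-semester response count table
#'
#' Reference table of caregiver vocalisation counts and infant response counts
#' by subtype from a home-movie study of infants later diagnosed with autistic
#' disorder (AD) versus typically developing (TD) controls, aggregated per
#' 6-month semester. It serves two purposes here: its per-cell empirical rates
#' (count / vocalisations) seed the default response probabilities of
#' [study_design()], and its internal margin identities ("toward people" =
#' sum of the five people-directed subtypes; total = object + people) are the
#' reference for [response_margins()].
#'
#' @return A tibble with columns `group`, `semester`, `vocalisations`, and the
#'   six response subtypes `object`, `receptive`, `expressive`, `active`,
#'   `exploratory`, `intersubjective`.
#' @export
reference_response_counts <- function() {
  tibble::tribble(
    ~group, ~semester, ~vocalisations, ~object, ~receptive, ~expressive,
    ~active, ~exploratory, ~intersubjective,
    "AD", "S1",  652,  44,  88, 128, 13, 32,  10,
    "AD", "S2",  983, 116, 121, 217, 35, 88,  42,
    "AD", "S3",  672, 127,  44, 102, 49, 42,  54,
    "TD", "S1",  950, 115, 126, 229, 27, 57,  24,
    "TD", "S2", 1170, 167, 154, 253, 60, 76, 114,
    "TD", "S3",  769, 146,  32, 155, 30, 31, 136
  )
}

#' Default generative probability tables
#'
#' `default_parentese_proportion()` gives the parentese proportion per
#' (group, semester, speaker) cell: mothers 0.60/0.45/0.35 over the three
#' semesters, fathers 0.20/0.15/0.15, other caregivers 0.30 throughout.
#' `default_response_probability()` gives the per-subtype infant response
#' probability per (group, semester, speaker, speech type) cell, set to the
#' empirical rates of [reference_response_counts()] (identical across
#' speakers and speech types). Copy and modify these tables to configure a
#' [study_design()].
#'
#' @return A tibble with the cell columns and `prob`.
#' @export
default_parentese_proportion <- function() {
  expand_grid_tbl <- tidyr::expand_grid(
    group = c("AD", "TD"), semester = c("S1", "S2", "S3"),
    speaker = c("mother", "father", "other")
  )
  base <- c(mother_S1 = 0.60, mother_S2 = 0.45, mother_S3 = 0.35,
            father_S1 = 0.20, father_S2 = 0.15, father_S3 = 0.15,
            other_S1 = 0.30, other_S2 = 0.30, other_S3 = 0.30)
  mutate(expand_grid_tbl,
         prob = unname(base[paste(.data$speaker, .data$semester, sep = "_")]))
}

#' @rdname default_parentese_proportion
#' @export
default_response_probability <- function() {
  ref <- reference_response_counts()
  long <- tidyr::pivot_longer(ref, all_of(unname(SUBTYPE_OF_META)),
                              names_to = "subtype", values_to = "count")
  long <- mutate(long, prob = .data$count / .data$vocalisations)
  tidyr::expand_grid(
    speaker = c("mother", "father", "other"),
    speech_type = c("parentese", "other_speech")
  ) |>
    tidyr::expand_grid(long[, c("group", "semester", "subtype", "prob")]) |>
    select(all_of(c("group", "semester", "speaker", "speech_type",
                    "subtype", "prob")))
}

#' Design of a synthetic interaction study
#'
#' Collects the generative parameters of a synthetic study: cohort size,
#' scenes and vocalisations per scene, the parentese proportion per
#' (group, semester, speaker) cell, and the per-subtype infant response
#' probability per (group, semester, speaker, speech type) cell. Defaults
#' emulate the study conditions of the home-movie corpus this package's
#' methods mirror: 15 children per group, mother parentese proportions
#' falling 0.60/0.45/0.35 over the three semesters against 0.20/0.15/0.15
#' for fathers, and per-subtype response rates taken from
#' [reference_response_counts()].
#'
#' @param n_children_per_group Children per group (>= 1).
#' @param scenes_per_semester Scenes per child and semester.
#' @param vocalisations_per_scene Caregiver vocalisations per scene.
#' @param scene_duration Scene duration in seconds (>= 40).
#' @param parentese_proportion Tibble `(group, semester, speaker, prob)`;
#'   probabilities in `[0, 1]`.
#' @param response_probability Tibble
#'   `(group, semester, speaker, speech_type, subtype, prob)`.
#' @param speaker_probs Named probabilities for `mother`, `father`, `other`.
#' @param subject_sd SD of the child-level random intercept applied to the
#'   response log-odds (0 disables heterogeneity between children).
#' @param vocal_spacing Minimum spacing between vocalisation onsets, in whole
#'   seconds; spacing above 6 s precludes overlapping 3-s response windows.
#' @param regup_per_scene Regulation-up state events per scene.
#' @param regup_duration Duration of each regulation-up state, seconds.
#' @param regup_parentese_boost Log-odds increase of parentese for
#'   vocalisations inside a regulation-up state (default 0.9, which roughly
#'   doubles moderate proportions).
#' @param response_lags Possible response lags in whole seconds.
#' @param random_seed Master seed; the whole study is deterministic given it.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_children_per_group = 15,
                         scenes_per_semester = 3,
                         vocalisations_per_scene = 20,
                         scene_duration = 90,
                         parentese_proportion = default_parentese_proportion(),
                         response_probability = default_response_probability(),
                         speaker_probs = c(mother = 0.6, father = 0.3, other = 0.1),
                         subject_sd = 0.4,
                         vocal_spacing = 1,
                         regup_per_scene = 2,
                         regup_duration = 6,
                         regup_parentese_boost = 0.9,
                         response_lags = 0:3,
                         random_seed = 1L) {
  if (n_children_per_group < 1) abort("`n_children_per_group` must be >= 1.")
  if (scene_duration < 40) abort("`scene_duration` must be >= 40 s.")
  for (p in parentese_proportion$prob) {
    if (p < 0 || p > 1) abort("parentese proportions must be in [0, 1].")
  }
  if (any(response_probability$prob < 0 | response_probability$prob > 1)) {
    abort("response probabilities must be in [0, 1].")
  }
  n_slots <- floor((scene_duration - 4) / vocal_spacing) + 1
  if (n_slots < vocalisations_per_scene) {
    abort("scene too short for the requested vocalisation count and spacing")
  }
  structure(
    list(
      n_children_per_group = n_children_per_group,
      scenes_per_semester = scenes_per_semester,
      vocalisations_per_scene = vocalisations_per_scene,
      scene_duration = scene_duration,
      parentese_proportion = parentese_proportion,
      response_probability = response_probability,
      speaker_probs = speaker_probs / sum(speaker_probs),
      subject_sd = subject_sd,
      vocal_spacing = vocal_spacing,
      regup_per_scene = regup_per_scene,
      regup_duration = regup_duration,
      regup_parentese_boost = regup_parentese_boost,
      response_lags = response_lags,
      random_seed = random_seed
    ),
    class = "study_design"
  )
}

#' Study design with response probabilities from a logistic model
#'
#' Convenience constructor for simulation studies: a single responding infant
#' subtype (`receptive`) whose response probability per cell is
#' `plogis(intercept + semester + group + speaker + speech_type)` on the
#' log-odds scale, so mixed-model estimates can be compared directly with the
#' generating coefficients. All other subtypes are silent, hence the `any`
#' indicator coincides with the active subtype.
#'
#' @param intercept Log-odds intercept.
#' @param semester_s2,semester_s3 Log-odds shifts of S2 vs S1 and S3 vs S2
#'   (successive differences, cumulated onto the cells).
#' @param group_ad Log-odds shift of group AD vs TD.
#' @param speaker_mother Log-odds shift of mother vs father.
#' @param speech_parentese Log-odds shift of parentese vs other speech.
#' @param ... Passed to [study_design()] (e.g. cohort sizes, `subject_sd`,
#'   `random_seed`).
#' @return A `study_design`.
#' @export
glmm_sim_design <- function(intercept = -0.5, semester_s2 = 0, semester_s3 = 0,
                            group_ad = 0, speaker_mother = 0,
                            speech_parentese = 0, ...) {
  cells <- tidyr::expand_grid(
    group = c("AD", "TD"), semester = c("S1", "S2", "S3"),
    speaker = c("mother", "father", "other"),
    speech_type = c("parentese", "other_speech"),
    subtype = unname(SUBTYPE_OF_META)
  )
  sem_shift <- c(S1 = 0, S2 = semester_s2, S3 = semester_s2 + semester_s3)
  cells <- mutate(
    cells,
    eta = intercept +
      unname(sem_shift[.data$semester]) +
      ifelse(.data$group == "AD", group_ad, 0) +
      ifelse(.data$speaker == "mother", speaker_mother, 0) +
      ifelse(.data$speech_type == "parentese", speech_parentese, 0),
    prob = ifelse(.data$subtype == "receptive", stats::plogis(.data$eta), 0)
  )
  study_design(response_probability = cells[, c("group", "semester", "speaker",
                                                "speech_type", "subtype", "prob")],
               ...)
}

lookup_prob <- function(tbl, keys) {
  idx <- match(
    do.call(paste, c(keys, sep = "\r")),
    do.call(paste, c(tbl[names(keys)], sep = "\r"))
  )
  if (anyNA(idx)) abort("design probability table does not cover all cells")
  tbl$prob[idx]
}

meta_codes <- function(map, meta) map$code[map$meta == meta]

#' Simulate a full interaction study
#'
#' For each child, semester and scene, caregiver vocalisations are placed at
#' distinct integer seconds, assigned a speaker and a speech type by the
#' design's probabilities, and each vocalisation independently triggers infant
#' meta-behaviour events (one Bernoulli draw per subtype) at lags drawn from
#' the design's lag set within the 3-second response window. Regulation-up
#' states are placed as intervals and raise the parentese odds of
#' vocalisations they cover. A child-level random intercept perturbs response
#' log-odds when `subject_sd > 0`. Deterministic given the design's seed.
#'
#' @param design A [study_design()].
#' @param map Meta-behaviour map from [load_meta_map()].
#' @return A list with `events` (one validated event tibble across all
#'   scenes, identical in layout to [read_interaction_log()] output) and
#'   `truth` (the design, per-child random intercepts, and `links`, the
#'   ground-truth vocalisation-to-response linkage with lags).
#' @export
synth_interaction_study <- function(design, map = load_meta_map()) {
  stopifnot(inherits(design, "study_design"))
  d <- design
  subtype_meta <- setNames(names(SUBTYPE_OF_META), unname(SUBTYPE_OF_META))
  subtypes <- unname(SUBTYPE_OF_META)
  n_voc <- d$vocalisations_per_scene

  with_seed(d$random_seed, {
    children <- tibble(
      group = rep(c("AD", "TD"), each = d$n_children_per_group),
      child_id = c(sprintf("AD%02d", seq_len(d$n_children_per_group)),
                   sprintf("TD%02d", seq_len(d$n_children_per_group))),
      b = stats::rnorm(2 * d$n_children_per_group, 0, d$subject_sd)
    )
    scenes <- tidyr::expand_grid(
      children, semester = c("S1", "S2", "S3"),
      scene = seq_len(d$scenes_per_semester)
    )
    scenes$scene_id <- sprintf("%s_%s_sc%02d", scenes$child_id,
                               scenes$semester, scenes$scene)
    n_scenes <- nrow(scenes)

    # regulation-up states: k non-overlapping intervals per scene on a coarse grid
    regup_slots <- seq(0, d$scene_duration - d$regup_duration,
                       by = d$regup_duration)
    k <- min(d$regup_per_scene, length(regup_slots))
    regup_start <- if (k > 0) {
      vapply(seq_len(n_scenes),
             function(i) sort(sample(regup_slots, k)), numeric(k))
    } else NULL
    if (k == 1 && !is.null(regup_start)) regup_start <- matrix(regup_start, 1)

    # caregiver vocalisations at distinct integer-spaced onsets
    slot_grid <- seq(0, d$scene_duration - 4, by = d$vocal_spacing)
    vt <- vapply(seq_len(n_scenes),
                 function(i) sort(sample(slot_grid, n_voc)), numeric(n_voc))
    scene_idx <- rep(seq_len(n_scenes), each = n_voc)
    voc_time <- as.vector(vt)
    n_all <- length(voc_time)
    speaker <- sample(names(d$speaker_probs), n_all, replace = TRUE,
                      prob = d$speaker_probs)

    p_par <- lookup_prob(
      d$parentese_proportion,
      list(group = scenes$group[scene_idx],
           semester = scenes$semester[scene_idx], speaker = speaker)
    )
    in_regup <- rep(FALSE, n_all)
    if (k > 0) {
      for (j in seq_len(k)) {
        st_j <- regup_start[j, scene_idx]
        in_regup <- in_regup |
          (voc_time >= st_j & voc_time <= st_j + d$regup_duration)
      }
    }
    p_par <- stats::plogis(stats::qlogis(pmin(pmax(p_par, 1e-9), 1 - 1e-9)) +
                             ifelse(in_regup, d$regup_parentese_boost, 0))
    speech <- ifelse(stats::rbinom(n_all, 1, p_par) == 1,
                     "parentese", "other_speech")

    cg <- tibble(
      child_id = scenes$child_id[scene_idx], group = scenes$group[scene_idx],
      semester = scenes$semester[scene_idx],
      scene_id = scenes$scene_id[scene_idx], duration_s = d$scene_duration,
      time_s = voc_time, actor = "caregiver",
      code = sample(meta_codes(map, "Vocal solicitation"), n_all, replace = TRUE),
      kind = "point", end_time_s = NA_real_,
      speaker = speaker, speech_type = speech
    )
    regup_ev <- if (k > 0) {
      ridx <- rep(seq_len(n_scenes), each = k)
      tibble(
        child_id = scenes$child_id[ridx], group = scenes$group[ridx],
        semester = scenes$semester[ridx], scene_id = scenes$scene_id[ridx],
        duration_s = d$scene_duration,
        time_s = as.vector(regup_start), actor = "caregiver",
        code = "CG_REGUP", kind = "state",
        end_time_s = as.vector(regup_start) + d$regup_duration,
        speaker = sample(c("mother", "father"), k * n_scenes, replace = TRUE),
        speech_type = "none"
      )
    } else NULL

    # infant responses: one Bernoulli draw per (vocalisation, subtype)
    n_sub <- length(subtypes)
    vidx <- rep(seq_len(n_all), each = n_sub)
    sub_all <- rep(subtypes, times = n_all)
    cell_p <- lookup_prob(
      d$response_probability,
      list(group = scenes$group[scene_idx][vidx],
           semester = scenes$semester[scene_idx][vidx],
           speaker = speaker[vidx], speech_type = speech[vidx],
           subtype = sub_all)
    )
    b_all <- scenes$b[scene_idx][vidx]
    p_adj <- ifelse(cell_p %in% c(0, 1), cell_p,
                    stats::plogis(stats::qlogis(cell_p) + b_all))
    hit <- stats::rbinom(length(p_adj), 1, p_adj) == 1

    inf <- NULL
    links <- tibble(
      child_id = character(), group = character(), semester = character(),
      scene_id = character(), cg_time = numeric(), subtype = character(),
      lag = numeric(), infant_time = numeric()
    )
    if (any(hit)) {
      hv <- vidx[hit]
      sub_hit <- sub_all[hit]
      lag <- if (length(d$response_lags) == 1) {
        rep(d$response_lags, sum(hit))
      } else {
        sample(d$response_lags, sum(hit), replace = TRUE)
      }
      inf_meta <- unname(subtype_meta[sub_hit])
      # pick one item code uniformly among the codes of each meta-behaviour
      code_pool <- split(map$code[map$actor == "infant"],
                         map$meta[map$actor == "infant"])
      pick <- stats::runif(sum(hit))
      inf_code <- vapply(seq_along(inf_meta), function(i) {
        cds <- code_pool[[inf_meta[i]]]
        cds[1L + floor(pick[i] * length(cds))]
      }, character(1))
      sidx <- scene_idx[hv]
      inf <- tibble(
        child_id = scenes$child_id[sidx], group = scenes$group[sidx],
        semester = scenes$semester[sidx], scene_id = scenes$scene_id[sidx],
        duration_s = d$scene_duration,
        time_s = voc_time[hv] + lag, actor = "infant", code = inf_code,
        kind = "point", end_time_s = NA_real_,
        speaker = "none", speech_type = "none"
      )
      links <- tibble(
        child_id = scenes$child_id[sidx], group = scenes$group[sidx],
        semester = scenes$semester[sidx], scene_id = scenes$scene_id[sidx],
        cg_time = voc_time[hv], subtype = sub_hit, lag = lag,
        infant_time = voc_time[hv] + lag
      )
    }

    events <- bind_rows(cg, regup_ev, inf) |>
      arrange(.data$child_id, .data$semester, .data$scene_id,
              .data$time_s, .data$actor, .data$code)
    list(
      events = events,
      truth = list(design = d, child_intercepts = children, links = links)
    )
  })
}
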
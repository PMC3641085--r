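# Binomial mixed-effects models of infant response probability and
# parentese-use trends, with a child-level random intercept.

RESPONSE_SUBTYPES <- c("any", "toward_people", unname(SUBTYPE_OF_META))

#' Build the per-vocalisation response dataset
#'
#' One record per caregiver vocalisation, with binary indicators per response
#' subtype set from the bi-grams: a subtype indicator is 1 when at least one
#' bi-gram of that subtype follows the vocalisation within the window.
#' `toward_people` is the OR of the five people-directed subtypes and `any`
#' the OR of object- and people-directed responses. Vocalisations by "other"
#' caregivers are excluded from the mother/father contrasts unless
#' `include_other_speakers = TRUE`.
#'
#' @param events Tagged event tibble.
#' @param bigrams Output of [extract_bigrams()] on the same events.
#' @param include_other_speakers Keep vocalisations whose speaker is neither
#'   mother nor father.
#' @param map Meta-behaviour map.
#' @return Tibble: context columns (`child_id`, `group`, `semester`,
#'   `scene_id`, `speaker`, `speech_type`, `cg_time`) and the binary
#'   indicators `any`, `toward_people` and the six subtypes.
#' @export
build_response_dataset <- function(events, bigrams,
                                   include_other_speakers = FALSE,
                                   map = load_meta_map()) {
  voc <- events[is_vocal_event(events, map), ]
  if (any(is.na(voc$speaker) | voc$speaker == "none")) {
    abort("caregiver vocal events must carry a speaker")
  }
  if (any(!voc$speech_type %in% c("parentese", "other_speech"))) {
    abort("caregiver vocal events must carry a speech type")
  }
  hits <- dplyr::distinct(
    bigrams[bigrams$cg_meta == "Vocal solicitation", ],
    .data$scene_id, .data$cg_time, .data$cg_code, .data$subtype
  ) |> mutate(hit = 1L)
  wide <- tidyr::pivot_wider(hits, names_from = "subtype",
                             values_from = "hit", values_fill = 0L)
  for (s in unname(SUBTYPE_OF_META)) {
    if (!s %in% names(wide)) wide[[s]] <- 0L
  }
  rec <- voc |>
    select(all_of(c("child_id", "group", "semester", "scene_id",
                    "speaker", "speech_type")), cg_time = "time_s",
           cg_code = "code") |>
    left_join(wide, by = c("scene_id", "cg_time", "cg_code")) |>
    mutate(across(all_of(unname(SUBTYPE_OF_META)), ~ tidyr::replace_na(.x, 0L)))
  rec$toward_people <- as.integer(rowSums(rec[, PEOPLE_SUBTYPES]) > 0)
  rec$any <- as.integer(rec$toward_people + rec$object > 0)
  if (!include_other_speakers) {
    rec <- rec[rec$speaker %in% c("mother", "father"), ]
  }
  rec
}

# Factor coding shared by all model fits: semester as ordered categorical with
# successive-difference contrasts (effects read as S2 vs S1, S3 vs S2), group
# with TD as reference, speaker with father as reference, speech type with
# other speech as reference.
prepare_model_frame <- function(records, fixed) {
  d <- as.data.frame(records)
  if ("semester" %in% fixed) {
    lev <- intersect(c("S1", "S2", "S3"), unique(as.character(d$semester)))
    if (length(lev) < 2) abort("semester contrast inestimable: need >= 2 semesters")
    d$semester <- factor(as.character(d$semester), levels = lev)
    stats::contrasts(d$semester) <- MASS::contr.sdif(length(lev))
  }
  if ("group" %in% fixed) d$group <- factor(d$group, levels = c("TD", "AD"))
  if ("speaker" %in% fixed) {
    d$speaker <- factor(d$speaker, levels = c("father", "mother"))
  }
  if ("speech_type" %in% fixed) {
    d$speech_type <- factor(d$speech_type,
                            levels = c("other_speech", "parentese"))
  }
  d
}

relabel_terms <- function(terms) {
  lev <- c("semester2-1" = "S2 vs S1", "semester3-2" = "S3 vs S2",
           "groupAD" = "AD vs TD", "speakermother" = "mother vs father",
           "speech_typeparentese" = "parentese vs other_speech")
  ifelse(terms %in% names(lev), unname(lev[terms]), terms)
}

#' Fit a binomial GLMM of infant response probability
#'
#' Logit-link binomial mixed model of a binary response indicator on the
#' requested fixed effects with a child-level random intercept, fitted by
#' Laplace-approximate maximum likelihood ([lme4::glmer()]). Semester enters
#' with successive-difference contrasts so the reported effects are S2 vs S1
#' and S3 vs S2; reference levels are TD (group), father (speaker) and other
#' speech (speech type). Wald z tests per coefficient, two-tailed.
#'
#' @param records Response dataset from [build_response_dataset()] (or any
#'   tibble with the response column, the fixed-effect columns and
#'   `child_id`).
#' @param response Response column name (e.g. `"any"`, `"toward_people"`,
#'   `"receptive"`).
#' @param fixed Fixed-effect columns.
#' @param random_intercept Fit the child-level random intercept; set `FALSE`
#'   for the ordinary logistic reduction.
#' @param ... Passed to [lme4::glmer()].
#' @return Object of class `glmm_fit`: coefficient table, random-intercept
#'   variance, convergence flag, sizes, and the underlying fit.
#' @export
fit_response_glmm <- function(records, response = "any",
                              fixed = c("semester", "group", "speaker",
                                        "speech_type"),
                              random_intercept = TRUE, ...) {
  if (!response %in% names(records)) {
    abort(paste0("no response column '", response, "'"))
  }
  y <- records[[response]]
  if (length(unique(y)) < 2) abort("response is constant; model not estimable")
  fixed <- fixed[vapply(fixed, function(f) {
    length(unique(records[[f]])) > 1
  }, logical(1))]
  if (!length(fixed)) abort("no estimable fixed effects")
  if (random_intercept && length(unique(records$child_id)) < 2) {
    abort("need >= 2 subjects for a random intercept")
  }
  d <- prepare_model_frame(records, fixed)
  # Pool Bernoulli rows sharing covariates and child into binomial counts:
  # the likelihood (hence estimates, SEs, Wald tests) is unchanged and the
  # optimiser sees far fewer rows.
  d$.y <- d[[response]]
  agg <- d |>
    group_by(across(all_of(c(fixed, "child_id")))) |>
    summarise(.successes = sum(.data$.y), .trials = dplyr::n(),
              .groups = "drop")
  rhs <- paste(fixed, collapse = " + ")
  lhs <- "cbind(.successes, .trials - .successes)"
  fit <- NULL
  converged <- TRUE
  messages <- character(0)
  if (random_intercept) {
    form <- stats::as.formula(paste0(lhs, " ~ ", rhs, " + (1 | child_id)"))
    fit <- withCallingHandlers(
      lme4::glmer(form, data = agg, family = stats::binomial(), ...),
      warning = function(w) {
        messages <<- c(messages, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        messages <<- c(messages, conditionMessage(m))
        invokeRestart("muffleMessage")
      }
    )
    converged <- length(fit@optinfo$conv$lme4) == 0 &&
      !any(grepl("failed to converge", messages))
    co <- summary(fit)$coefficients
    re_var <- as.numeric(lme4::VarCorr(fit)$child_id[1, 1])
  } else {
    form <- stats::as.formula(paste0(lhs, " ~ ", rhs))
    fit <- stats::glm(form, data = agg, family = stats::binomial())
    converged <- fit$converged
    co <- summary(fit)$coefficients
    re_var <- 0
  }
  # complete-separation symptom: enormous coefficients with huge SEs
  separation <- any(abs(co[, 1]) > 15 & co[, 2] > 50)

  coefs <- tibble(
    term = relabel_terms(rownames(co)),
    estimate = co[, 1], std_error = co[, 2],
    z = co[, 1] / co[, 2],
    p_value = 2 * stats::pnorm(-abs(co[, 1] / co[, 2]))
  )
  structure(
    list(
      response = response, coefficients = coefs,
      random_intercept_var = re_var, converged = converged,
      separation = separation, messages = messages,
      n_obs = nrow(d),
      n_subjects = length(unique(d$child_id)),
      fit = fit
    ),
    class = "glmm_fit"
  )
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "<glmm_fit> response=%s  n=%d obs, %d subjects  RE var=%.3f%s\n",
    x$response, x$n_obs, x$n_subjects, x$random_intercept_var,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Tidy a fitted response model
#'
#' @param x A `glmm_fit`.
#' @param ... Unused.
#' @return `tidy()`: the coefficient tibble (`term`, `estimate`, `std_error`,
#'   `z`, `p_value`); `glance()`: a one-row model summary.
#' @method tidy glmm_fit
#' @export
tidy.glmm_fit <- function(x, ...) x$coefficients

#' @rdname tidy.glmm_fit
#' @method glance glmm_fit
#' @export
glance.glmm_fit <- function(x, ...) {
  tibble(
    response = x$response, n_obs = x$n_obs, n_subjects = x$n_subjects,
    random_intercept_var = x$random_intercept_var,
    converged = x$converged, separation = x$separation
  )
}

#' Coefficient plot of one or more fitted response models
#'
#' @param object A `glmm_fit`.
#' @param ... Unused.
#' @return A ggplot object: point estimates with ~95% Wald intervals.
#' @method autoplot glmm_fit
#' @export
autoplot.glmm_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std_error,
                   xmax = .data$estimate + 1.96 * .data$std_error),
      height = 0.15
    ) +
    ggplot2::labs(x = "log-odds estimate", y = NULL,
                  title = paste0("response: ", object$response)) +
    ggplot2::theme_minimal()
}

#' Post-hoc stratified model suite
#'
#' Two stratified re-fits mirroring the main analysis: (a) within each group,
#' a model with semester, speaker and speech type; (b) within each group and
#' semester, a model with speaker and speech type. Strata with insufficient
#' data (constant response, a single subject, or inestimable effects) are
#' skipped and reported.
#'
#' @param records Response dataset.
#' @param response Response column.
#' @param ... Passed to [fit_response_glmm()].
#' @return List with `fits` (named list of `glmm_fit`) and `skipped`
#'   (tibble of stratum, reason).
#' @export
posthoc_suite <- function(records, response = "any", ...) {
  fits <- list()
  skipped <- list()
  try_fit <- function(dat, label, fixed) {
    res <- tryCatch(
      fit_response_glmm(dat, response = response, fixed = fixed, ...),
      error = function(e) conditionMessage(e)
    )
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <<- tibble(stratum = label, reason = res)
    } else {
      fits[[label]] <<- res
    }
  }
  for (g in unique(records$group)) {
    try_fit(records[records$group == g, ], paste0("group=", g),
            c("semester", "speaker", "speech_type"))
  }
  for (g in unique(records$group)) {
    for (s in c("S1", "S2", "S3")) {
      dat <- records[records$group == g & records$semester == s, ]
      label <- paste0("group=", g, ",semester=", s)
      if (nrow(dat) == 0) {
        skipped[[length(skipped) + 1L]] <- tibble(stratum = label,
                                                  reason = "empty stratum")
        next
      }
      try_fit(dat, label, c("speaker", "speech_type"))
    }
  }
  list(
    fits = fits,
    skipped = if (length(skipped)) bind_rows(skipped) else
      tibble(stratum = character(), reason = character())
  )
}

#' Trend model of parentese use over time
#'
#' Binomial GLMM of the per-vocalisation parentese indicator on semester
#' (successive-difference contrasts) and group, with a child-level random
#' intercept: negative semester contrasts indicate declining parentese use.
#'
#' @param events Tagged event tibble (or any tibble with one row per
#'   vocalisation carrying `speech_type`, `semester`, `group`, `child_id`).
#' @param fixed Fixed effects (subset of `semester`, `group`, `speaker`).
#' @param speakers Restrict to these speakers (default mother and father).
#' @param map Meta-behaviour map.
#' @param ... Passed to [fit_response_glmm()].
#' @return A `glmm_fit` for the parentese indicator.
#' @export
parentese_trend <- function(events, fixed = c("semester", "group"),
                            speakers = c("mother", "father"),
                            map = load_meta_map(), ...) {
  voc <- if ("time_s" %in% names(events)) {
    events[is_vocal_event(events, map), ]
  } else {
    events
  }
  voc <- voc[voc$speaker %in% speakers, ]
  if (length(unique(as.character(voc$semester))) < 2 && "semester" %in% fixed) {
    abort("semester contrast inestimable: need >= 2 semesters")
  }
  voc$parentese <- as.integer(voc$speech_type == "parentese")
  fit_response_glmm(voc, response = "parentese", fixed = fixed, ...)
}

#' Arrange fitted models as a contrasts-by-responses summary table
#'
#' One row per fixed-effect contrast, one column per response subtype, each
#' cell formatted as `beta (SE) sig`, mirroring the conventional reporting
#' layout of multi-response mixed-model analyses.
#'
#' @param fits Named list of `glmm_fit`s (names become columns).
#' @param alpha Significance threshold for the star.
#' @return A tibble, rows = contrasts, columns = response subtypes.
#' @export
model_summary_table <- function(fits, alpha = 0.05) {
  cols <- imap(fits, function(f, nm) {
    td <- tidy(f)
    td <- td[td$term != "(Intercept)", ]
    tibble(
      term = td$term,
      !!nm := sprintf("b=%.2f (SE=%.3f)%s", td$estimate, td$std_error,
                      ifelse(td$p_value < alpha, " *", ""))
    )
  })
  purrr::reduce(cols, function(a, b) dplyr::full_join(a, b, by = "term"))
}
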
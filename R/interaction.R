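# Interaction database: speech-type tagging of caregiver vocalisations,
# caregiver-to-infant response bi-grams within the 3-second window, count
# tables with margins, and parentese-use proportions.

is_vocal_event <- function(events, map = load_meta_map()) {
  events$actor == "caregiver" &
    map_meta_safe(events$code, map) == "Vocal solicitation"
}

map_meta_safe <- function(code, map) {
  m <- map$meta[match(code, map$code)]
  ifelse(is.na(m), "", m)
}

#' Tag caregiver vocalisations with their speech type
#'
#' Attaches per-vocalisation speech-type labels (parentese vs other speech),
#' e.g. the output of the acoustic detector, back onto the event log. Only
#' caregiver vocal-solicitation events are touched; `labels` must have
#' exactly one entry per such event, in event-time order.
#'
#' @param events Event tibble (one or more scenes).
#' @param labels Character vector of `"parentese"` / `"other_speech"`.
#' @param map Meta-behaviour map.
#' @return The event tibble with `speech_type` set on vocal events.
#' @export
tag_vocalisations <- function(events, labels, map = load_meta_map()) {
  voc <- is_vocal_event(events, map)
  if (sum(voc) != length(labels)) {
    abort(sprintf("%d labels supplied for %d caregiver vocal events",
                  length(labels), sum(voc)))
  }
  events$speech_type[voc] <- labels
  events
}

#' Extract caregiver-to-infant response bi-grams
#'
#' A response bi-gram is an ordered pair (caregiver event, infant event) with
#' the infant event occurring within the response window after the caregiver
#' event: `0 <= t_infant - t_caregiver <= window` (the closed lower bound
#' keeps same-second responses). All qualifying pairs are emitted — one
#' infant event may answer several caregiver events — unless
#' `pairing = "nearest"`, which keeps only the nearest infant event per
#' caregiver event and subtype. For caregiver state events the window anchors
#' at the state's start time. Output order is deterministic: by scene, then
#' caregiver time, then infant time.
#'
#' @param events Event tibble.
#' @param window Response window in seconds (default 3).
#' @param pairing `"all"` (default) or `"nearest"`.
#' @param map Meta-behaviour map.
#' @return Tibble of bi-grams: scene context columns, `cg_time`, `cg_code`,
#'   `cg_meta`, `speaker`, `speech_type`, `infant_time`, `infant_code`,
#'   `infant_meta`, `subtype`, `lag`.
#' @export
extract_bigrams <- function(events, window = 3, pairing = c("all", "nearest"),
                            map = load_meta_map()) {
  pairing <- match.arg(pairing)
  if (window <= 0) abort("`window` must be positive")
  metas <- map_meta(events$code, map)  # errors on unmapped codes

  empty <- tibble(
    child_id = character(), group = character(), semester = character(),
    scene_id = character(), cg_time = numeric(), cg_code = character(),
    cg_meta = character(), speaker = character(), speech_type = character(),
    infant_time = numeric(), infant_code = character(),
    infant_meta = character(), subtype = character(), lag = numeric()
  )
  is_cg <- events$actor == "caregiver"
  cg <- tibble(
    child_id = events$child_id[is_cg], group = events$group[is_cg],
    semester = events$semester[is_cg], scene_id = events$scene_id[is_cg],
    cg_time = events$time_s[is_cg], cg_code = events$code[is_cg],
    cg_meta = metas[is_cg], speaker = events$speaker[is_cg],
    speech_type = events$speech_type[is_cg]
  )
  is_inf <- events$actor == "infant"
  inf <- tibble(
    scene_id = events$scene_id[is_inf], infant_time = events$time_s[is_inf],
    infant_code = events$code[is_inf], infant_meta = metas[is_inf],
    subtype = unname(SUBTYPE_OF_META[metas[is_inf]])
  )
  if (nrow(cg) == 0 || nrow(inf) == 0) return(empty)
  bg <- dplyr::inner_join(cg, inf, by = "scene_id",
                          relationship = "many-to-many") |>
    mutate(lag = .data$infant_time - .data$cg_time) |>
    filter(.data$lag >= 0, .data$lag <= window)
  if (pairing == "nearest") {
    bg <- bg |>
      group_by(.data$scene_id, .data$cg_time, .data$cg_code, .data$subtype) |>
      filter(.data$lag == min(.data$lag)) |>
      dplyr::slice(1) |>
      ungroup()
  }
  if (nrow(bg) == 0) return(empty)
  arrange(bg, .data$child_id, .data$semester, .data$scene_id,
          .data$cg_time, .data$infant_time, .data$subtype)
}

#' Add the response-margin columns to a subtype count table
#'
#' Computes the two margin identities of the per-semester count table:
#' `toward_people` is the sum of the five people-directed subtypes
#' (receptive, expressive, active, exploratory, inter-subjective) and
#' `total` adds the object-directed counts.
#'
#' @param counts Tibble with the six subtype count columns.
#' @return The tibble with `toward_people` and `total` appended.
#' @examples
#' response_margins(reference_response_counts())
#' @export
response_margins <- function(counts) {
  missing <- setdiff(unname(SUBTYPE_OF_META), names(counts))
  if (length(missing)) {
    abort(paste0("missing subtype column(s): ", paste(missing, collapse = ", ")))
  }
  counts$toward_people <- rowSums(counts[, PEOPLE_SUBTYPES])
  counts$total <- counts$toward_people + counts$object
  counts
}

#' Aggregate bi-grams into a response count table
#'
#' Cross-classifies responses by context and infant response subtype and
#' appends the margin columns. Two counting views are produced: `bigrams`
#' (raw bi-gram counts) and `responses` (binary per caregiver vocalisation:
#' a vocalisation with at least one bi-gram of a subtype counts once for that
#' subtype — the unit used by the response models). Caregiver vocalisation
#' denominators are counted from the event log independently of responses.
#'
#' @param bigrams Output of [extract_bigrams()].
#' @param events The event tibble the bi-grams came from (for denominators);
#'   optional.
#' @param by Context columns to keep (default group and semester).
#' @param unit `"bigrams"` or `"responses"`.
#' @param map Meta-behaviour map.
#' @return A wide tibble: context columns, `vocalisations` (if `events`
#'   given), the six subtype counts, `toward_people`, `total`.
#' @export
count_responses <- function(bigrams, events = NULL,
                            by = c("group", "semester"),
                            unit = c("bigrams", "responses"),
                            map = load_meta_map()) {
  unit <- match.arg(unit)
  missing <- setdiff(c(by, "subtype"), names(bigrams))
  if (length(missing)) {
    abort(paste0("bigrams lack context column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bg <- bigrams
  if (unit == "responses") {
    bg <- dplyr::distinct(
      bg, across(all_of(c(by, "scene_id", "cg_time", "cg_code", "subtype")))
    )
  }
  long <- bg |>
    count(across(all_of(c(by, "subtype"))), name = "count")
  wide <- tidyr::pivot_wider(
    long, names_from = "subtype", values_from = "count", values_fill = 0L
  )
  for (s in unname(SUBTYPE_OF_META)) {
    if (!s %in% names(wide)) wide[[s]] <- 0L
  }
  wide <- wide[, c(by, unname(SUBTYPE_OF_META))]
  if (!is.null(events)) {
    den <- events |>
      filter(is_vocal_event(events, map)) |>
      count(across(all_of(by)), name = "vocalisations")
    wide <- left_join(den, wide, by = by) |>
      mutate(across(all_of(unname(SUBTYPE_OF_META)),
                    ~ tidyr::replace_na(.x, 0L)))
  }
  response_margins(wide) |> arrange(across(all_of(by)))
}

#' Proportion of parentese in caregiver vocalisations
#'
#' For each (group, semester, speaker) cell, the proportion of tagged
#' caregiver vocalisations classified as parentese, in two contexts: over all
#' vocalisations, and restricted to vocalisations overlapping a regulation-up
#' state interval (caregiver arousal-raising solicitation). Cells with an
#' empty denominator are reported as missing, not zero.
#'
#' @param events Tagged event tibble (every vocal event carries a
#'   speech type).
#' @param by Context columns (default group, semester, speaker).
#' @param map Meta-behaviour map.
#' @return Tibble of class `parentese_proportions`: context columns,
#'   `context` (`"all"` / `"regulation_up"`), `n_vocalisations`,
#'   `n_parentese`, `proportion`.
#' @export
parentese_proportions <- function(events, by = c("group", "semester", "speaker"),
                                  map = load_meta_map()) {
  voc <- events[is_vocal_event(events, map), ]
  if (any(!voc$speech_type %in% c("parentese", "other_speech"))) {
    abort("all caregiver vocal events must be tagged with a speech type")
  }
  regup <- events[events$actor == "caregiver" & events$kind == "state" &
                    map_meta_safe(events$code, map) == "Regulation up", ]
  in_regup <- vapply(seq_len(nrow(voc)), function(i) {
    ru <- regup[regup$scene_id == voc$scene_id[i], ]
    nrow(ru) > 0 && any(voc$time_s[i] >= ru$time_s & voc$time_s[i] <= ru$end_time_s)
  }, logical(1))

  summarise_cells <- function(v, label) {
    if (nrow(v) == 0) {
      return(tibble())
    }
    v |>
      group_by(across(all_of(by))) |>
      summarise(
        context = label,
        n_vocalisations = dplyr::n(),
        n_parentese = sum(.data$speech_type == "parentese"),
        proportion = .data$n_parentese / .data$n_vocalisations,
        .groups = "drop"
      )
  }
  out <- bind_rows(
    summarise_cells(voc, "all"),
    summarise_cells(voc[in_regup, ], "regulation_up")
  )
  class(out) <- c("parentese_proportions", class(out))
  out
}

#' Plot parentese proportions by semester
#'
#' Line-and-point display of the proportion of parentese per semester,
#' faceted by context (all vocalisations vs regulation-up), coloured by
#' speaker, with line type by group.
#'
#' @param object A [parentese_proportions()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot parentese_proportions
#' @export
autoplot.parentese_proportions <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$semester, y = .data$proportion,
                 colour = .data$speaker, linetype = .data$group,
                 group = interaction(.data$speaker, .data$group))
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~context) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "semester", y = "proportion of parentese") +
    ggplot2::theme_minimal()
}
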
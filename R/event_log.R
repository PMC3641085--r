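# Behavioural event-log data model: ICBS-coded caregiver and infant events,
# semester binning, meta-behaviour mapping and inter-rater agreement.

LOG_COLUMNS <- c("time_s", "actor", "code", "kind", "end_time_s",
                 "speaker", "speech_type")
META_COLUMNS <- c("child_id", "group", "semester", "scene_id", "duration_s")

CG_META <- c("Vocal solicitation", "Touching", "Gestural solicitation",
             "Regulation up", "Regulation down")
INFANT_META <- c("Behavior with object", "Vocalizations/Expressive",
                 "Inter-subjective", "Seeking people/Active", "Receptive",
                 "Orienting/Exploratory")

# Infant meta-behaviour -> response-subtype key used in count tables. The
# "toward people" subtypes carry the aliases used in published count tables
# (Expressive <-> Vocalizations, Active <-> Seeking people, Exploratory <->
# Orienting).
SUBTYPE_OF_META <- c(
  "Behavior with object"     = "object",
  "Vocalizations/Expressive" = "expressive",
  "Inter-subjective"         = "intersubjective",
  "Seeking people/Active"    = "active",
  "Receptive"                = "receptive",
  "Orienting/Exploratory"    = "exploratory"
)
PEOPLE_SUBTYPES <- c("receptive", "expressive", "active", "exploratory",
                     "intersubjective")

#' Load the ICBS item to meta-behaviour map
#'
#' The map groups coding-grid items into five caregiver meta-behaviours
#' (Vocal solicitation, Touching, Gestural solicitation, Regulation up,
#' Regulation down) and six infant meta-behaviours (Behavior with object,
#' Vocalizations/Expressive, Inter-subjective, Seeking people/Active,
#' Receptive, Orienting/Exploratory). The default shipped map uses synthetic
#' item codes and can be replaced by any JSON file with the same
#' `{"caregiver": {...}, "infant": {...}}` layout.
#'
#' @param path Path to a JSON map; default: the map shipped with the package.
#' @return A tibble with columns `code`, `actor`, `meta`.
#' @export
load_meta_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "icbs_meta_map.json",
                                package = "parentese")
  raw <- jsonlite::read_json(path)
  out <- list_rbind(lapply(c("caregiver", "infant"), function(actor) {
    m <- raw[[actor]]
    tibble(code = names(m), actor = actor, meta = unlist(m, use.names = FALSE))
  }))
  bad <- out$meta[out$actor == "caregiver" & !out$meta %in% CG_META]
  bad <- c(bad, out$meta[out$actor == "infant" & !out$meta %in% INFANT_META])
  if (length(bad)) {
    abort(paste0("unknown meta-behaviour label(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  if (anyDuplicated(out$code)) abort("duplicated item codes in meta map")
  out
}

#' Map an ICBS item code to its meta-behaviour
#'
#' @param code Character vector of item codes.
#' @param map Meta map tibble from [load_meta_map()].
#' @return Character vector of meta-behaviour labels.
#' @examples
#' map_meta("CG_TOUCH")
#' @export
map_meta <- function(code, map = load_meta_map()) {
  idx <- match(code, map$code)
  if (anyNA(idx)) {
    abort(paste0("unmapped ICBS code(s): ",
                 paste(unique(code[is.na(idx)]), collapse = ", ")))
  }
  map$meta[idx]
}

#' Assign an age in months to a semester bin
#'
#' The first 18 months of life are binned into three 6-month semesters:
#' S1 for ages up to and including 6 months, S2 for ages above 6 and up to
#' and including 12 months, S3 above 12 months.
#'
#' @param age_months Numeric vector of ages in `[0, 18]` months.
#' @return Factor with levels `S1`, `S2`, `S3`.
#' @examples
#' assign_semester(c(6, 12, 12.5))
#' @export
assign_semester <- function(age_months) {
  if (any(age_months < 0 | age_months > 18)) {
    abort("`age_months` must be in [0, 18].")
  }
  factor(
    ifelse(age_months <= 6, "S1", ifelse(age_months <= 12, "S2", "S3")),
    levels = c("S1", "S2", "S3")
  )
}

validate_log <- function(log, min_duration = 40, allow_short = FALSE) {
  missing <- setdiff(c(META_COLUMNS, LOG_COLUMNS), names(log))
  if (length(missing)) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(log) == 0) return(log)
  if (any(log$time_s < 0)) abort("event times must be non-negative")
  bad_actor <- setdiff(unique(log$actor), c("caregiver", "infant"))
  if (length(bad_actor)) {
    abort(paste0("unknown actor(s): ", paste(bad_actor, collapse = ", ")))
  }
  st <- log$kind == "state"
  if (any(st & (is.na(log$end_time_s) | log$end_time_s <= log$time_s))) {
    abort("state events must have end_time_s > time_s")
  }
  if (any(log$time_s > log$duration_s)) {
    abort("event times must not exceed the scene duration")
  }
  if (any(log$duration_s < min_duration) && !allow_short) {
    abort(sprintf("scene shorter than %g s (set allow_short = TRUE to keep)",
                  min_duration))
  }
  sp <- !is.na(log$speech_type) & log$speech_type != "none"
  if (any(sp & log$actor != "caregiver")) {
    abort("speech_type may be set only on caregiver vocal events")
  }
  arrange(log, .data$time_s, .data$actor, .data$code)
}

#' Read and write behavioural event logs
#'
#' The on-disk dialect is UTF-8 tab-delimited text with a header row of
#' columns `time_s, actor, code, kind, end_time_s, speaker, speech_type`;
#' scene metadata (`child_id`, `group`, `semester`, `scene_id`, `duration_s`)
#' is carried in leading `#key: value` comment lines. One file is one scene.
#' On read, events are validated (actors, state intervals, 40 s minimum scene
#' duration) and sorted by time; malformed data rows are reported with their
#' line numbers.
#'
#' @param path File path.
#' @param min_duration Minimum scene duration in seconds (default 40,
#'   the inclusion threshold for analysable scenes).
#' @param allow_short Keep scenes shorter than `min_duration` instead of
#'   erroring.
#' @return A tibble with the metadata columns repeated on every event row, so
#'   logs from many scenes can be row-bound into one study table.
#' @export
read_interaction_log <- function(path, min_duration = 40, allow_short = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_idx)) abort("no header row found")
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (!setequal(header, LOG_COLUMNS)) {
    abort(paste0("missing required column(s): ",
                 paste(setdiff(LOG_COLUMNS, header), collapse = ", ")))
  }
  rows_idx <- body_idx[-1]
  parsed <- lapply(rows_idx, function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      abort(sprintf("line %d: expected %d fields, found %d",
                    i, length(header), length(fields)))
    }
    setNames(as.list(fields), header)
  })
  ev <- if (length(parsed)) {
    as_tibble(do.call(rbind, lapply(parsed, as.data.frame))) |>
      mutate(
        time_s = as.numeric(.data$time_s),
        end_time_s = suppressWarnings(as.numeric(.data$end_time_s))
      )
  } else {
    tibble(time_s = numeric(), actor = character(), code = character(),
           kind = character(), end_time_s = numeric(),
           speaker = character(), speech_type = character())
  }
  ev <- mutate(
    ev,
    child_id = meta$child_id %||% NA_character_,
    group = meta$group %||% NA_character_,
    semester = meta$semester %||% NA_character_,
    scene_id = meta$scene_id %||% NA_character_,
    duration_s = as.numeric(meta$duration_s %||% NA_real_),
    .before = 1
  )
  validate_log(ev, min_duration = min_duration, allow_short = allow_short)
}

#' @rdname read_interaction_log
#' @param log Event tibble for a single scene (as returned by
#'   [read_interaction_log()] or built by [synth_interaction_study()]).
#' @export
write_interaction_log <- function(log, path) {
  stopifnot(all(c(META_COLUMNS, LOG_COLUMNS) %in% names(log)))
  if (length(unique(log$scene_id)) > 1) {
    abort("write one scene per file (multiple scene_id values found)")
  }
  meta_vals <- lapply(META_COLUMNS, function(cl) as.character(log[[cl]][1]))
  hdr <- paste0("# ", META_COLUMNS, ": ", unlist(meta_vals))
  body <- log[, LOG_COLUMNS]
  fmt_num <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE, scientific = FALSE))
  rows <- apply(
    cbind(
      fmt_num(body$time_s), body$actor, body$code, body$kind,
      fmt_num(body$end_time_s), body$speaker, body$speech_type
    ),
    1, paste, collapse = "\t"
  )
  writeLines(c(hdr, paste(LOG_COLUMNS, collapse = "\t"), rows), path,
             useBytes = TRUE)
  invisible(path)
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two raters assigning categorical codes
#' to the same items: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o` and chance agreement `p_e` from the raters' marginal label
#' frequencies. Coding-scheme training conventionally requires kappa >= 0.7.
#'
#' @param ratings_a,ratings_b Equal-length vectors of labels.
#' @return Kappa in `[-1, 1]`. When chance agreement is 1 (both raters use a
#'   single identical label) the sequences are necessarily identical and 1 is
#'   returned; a degenerate disagreeing case cannot occur there.
#' @examples
#' cohens_kappa(c("a", "a", "b"), c("a", "b", "b"))
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    abort("rating sequences must have equal length")
  }
  n <- length(ratings_a)
  if (n < 1) abort("rating sequences must be non-empty")
  levels_all <- union(unique(ratings_a), unique(ratings_b))
  a <- factor(ratings_a, levels = levels_all)
  b <- factor(ratings_b, levels = levels_all)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    if (p_o == 1) return(1)
    abort("kappa undefined: chance agreement is 1 but raters disagree")
  }
  (p_o - p_e) / (1 - p_e)
}
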
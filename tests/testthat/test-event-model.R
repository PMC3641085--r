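write_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

header <- "time_s\tactor\tcode\tkind\tend_time_s\tspeaker\tspeech_type"
meta_lines <- c("# child_id: AD01", "# group: AD", "# semester: S1",
                "# scene_id: AD01_S1_sc01", "# duration_s: 60")

test_that("an empty-events file with a valid header loads as a zero-event log", {
  p <- write_fixture(c(meta_lines, header))
  log <- read_interaction_log(p)
  expect_equal(nrow(log), 0)
  expect_true(all(c("time_s", "actor", "code", "speech_type") %in% names(log)))
})

test_that("a five-row fixture with one state event parses fully", {
  rows <- c(
    "3\tcaregiver\tCG_VOC\tpoint\tNA\tmother\tparentese",
    "5\tinfant\tINF_LOOK_PERS\tpoint\tNA\tnone\tnone",
    "10\tcaregiver\tCG_REGUP\tstate\t16\tmother\tnone",
    "12\tcaregiver\tCG_VOC\tpoint\tNA\tfather\tother_speech",
    "14\tinfant\tINF_VOCAL\tpoint\tNA\tnone\tnone"
  )
  log <- read_interaction_log(write_fixture(c(meta_lines, header, rows)))
  expect_equal(nrow(log), 5)
  st <- log[log$kind == "state", ]
  expect_equal(nrow(st), 1)
  expect_equal(st$end_time_s, 16)
  expect_equal(log$child_id[1], "AD01")
  expect_equal(log$duration_s[1], 60)
  expect_true(!is.unsorted(log$time_s))
})

test_that("malformed logs are rejected with informative errors", {
  # wrong field count reports the offending line number
  bad <- c(meta_lines, header, "3\tcaregiver\tCG_VOC\tpoint\tNA\tmother")
  expect_error(read_interaction_log(write_fixture(bad)), "line 7")
  # missing required column
  expect_error(
    read_interaction_log(write_fixture(c(
      meta_lines, "time_s\tactor\tcode\tkind\tend_time_s\tspeaker"
    ))),
    "speech_type"
  )
  # unknown actor
  expect_error(
    read_interaction_log(write_fixture(c(
      meta_lines, header, "3\trobot\tCG_VOC\tpoint\tNA\tmother\tparentese"
    ))),
    "actor"
  )
  # non-monotone state interval
  expect_error(
    read_interaction_log(write_fixture(c(
      meta_lines, header, "10\tcaregiver\tCG_REGUP\tstate\t8\tmother\tnone"
    ))),
    "state"
  )
})

test_that("scenes shorter than 40 s are rejected unless explicitly allowed", {
  short_meta <- sub("60", "30", meta_lines)
  p <- write_fixture(c(short_meta, header,
                       "3\tcaregiver\tCG_VOC\tpoint\tNA\tmother\tparentese"))
  expect_error(read_interaction_log(p), "40")
  log <- read_interaction_log(p, allow_short = TRUE)
  expect_equal(nrow(log), 1)
})

test_that("save then load is the identity on valid logs", {
  st <- synth_interaction_study(study_design(n_children_per_group = 1,
                                             scenes_per_semester = 1,
                                             random_seed = 3))
  one <- st$events[st$events$scene_id == st$events$scene_id[1], ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_log(one, path)
  back <- read_interaction_log(path)
  expect_equal(as.data.frame(back), as.data.frame(one))
})

test_that("semester binning partitions the first 18 months", {
  expect_equal(as.character(assign_semester(6)), "S1")
  expect_equal(as.character(assign_semester(12)), "S2")
  expect_equal(as.character(assign_semester(12.5)), "S3")
  ages <- seq(0, 18, by = 0.25)
  sems <- assign_semester(ages)
  expect_false(anyNA(sems))
  expect_true(all(diff(as.integer(sems)) >= 0))  # monotone, no overlap
  expect_setequal(levels(sems), c("S1", "S2", "S3"))
  expect_error(assign_semester(-1), "\\[0, 18\\]")
})

test_that("the meta map is total and maps each item to exactly one label", {
  map <- load_meta_map()
  expect_equal(map_meta("CG_TOUCH", map), "Touching")
  expect_error(map_meta("NOT_A_CODE", map), "unmapped")
  inf <- map[map$actor == "infant", ]
  expect_true(all(inf$meta %in% parentese:::INFANT_META))
  expect_equal(anyDuplicated(inf$code), 0)
  expect_length(unique(inf$meta), 6)
  cg <- map[map$actor == "caregiver", ]
  expect_true(all(cg$meta %in% parentese:::CG_META))
  expect_length(unique(cg$meta), 5)
})

test_that("Cohen's kappa matches hand computation and behaves at the limits", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # 2x2 agreement table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  a <- rep(c("A", "A", "B", "B"), c(20, 5, 10, 15))
  b <- rep(c("A", "B", "A", "B"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(a, b), 0.4)
  # independent labels at large n sit near zero
  set.seed(42)
  x <- sample(c("A", "B"), 4000, replace = TRUE)
  y <- sample(c("A", "B"), 4000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 0.06)
  expect_error(cohens_kappa(c("a", "b"), c("a")), "equal length")
  # degenerate: a single shared label
  expect_equal(cohens_kappa(c("a", "a"), c("a", "a")), 1)
})

test_that("kappa stays in [-1, 1] on random label sequences", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    x <- sample(letters[1:3], n, replace = TRUE)
    y <- sample(letters[1:3], n, replace = TRUE)
    pe1 <- isTRUE(all.equal(
      sum((table(factor(x, levels = letters[1:3])) / n) *
            (table(factor(y, levels = letters[1:3])) / n)), 1))
    if (pe1) next
    k <- cohens_kappa(x, y)
    expect_gte(k, -1)
    expect_lte(k, 1)
    if (identical(x, y)) expect_equal(k, 1)
  }
})
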
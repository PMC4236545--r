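test_that("degenerate configurations produce the forced survey structures", {
  empty <- generate_township(township_config(n_population = 0))
  expect_identical(nrow(empty$roster), 0L)
  expect_identical(nrow(empty$surveys$alters), 0L)
  expect_identical(nrow(empty$truth$identity_map), 0L)

  ## everyone married, nobody names discussion alters: every ego network is
  ## exactly the spouse
  t <- generate_township(township_config(n_population = 100, p_married = 1,
                                         mean_alters = 0, p_response = 1, seed = 11))
  sizes <- table(t$surveys$alters$ego_id)
  expect_true(all(sizes == 1))
  expect_true(all(t$surveys$alters$slot == "spouse"))
  expect_identical(length(sizes), 100L)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(township_config(district_weights = c(0.5, 0.4), n_districts = 2),
               "district_weights")
  expect_error(township_config(mean_alters = 7), "mean_alters")
  expect_error(township_config(p_married = 1.4), "p_married")
  expect_error(township_config(age_report_noise_max = 5), "age_report_noise_max")
  expect_error(township_config(segregated_district = 99), "segregated_district")
})

test_that("equal seeds give byte-identical CSV output; different seeds differ", {
  cfg <- township_config(n_population = 150, seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  write_survey_csv(generate_township(cfg), path = d1)
  write_survey_csv(generate_township(cfg), path = d2)
  write_survey_csv(generate_township(township_config(n_population = 150, seed = 43)), path = d3)
  for (f in c("roster.csv", "egonet.csv", "acquaint.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "roster.csv")),
                         readLines(file.path(d3, "roster.csv"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(500)
  before <- .Random.seed
  invisible(generate_township(township_config(n_population = 50, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("survey CSV round-trip is the identity, including the empty case", {
  t <- generate_township(township_config(n_population = 120, seed = 1))
  d <- withr::local_tempdir()
  write_survey_csv(t$roster, t$surveys, d)
  back <- read_survey_csv(d)
  expect_identical(back$roster, t$roster)
  expect_identical(back$surveys$alters, t$surveys$alters)
  expect_identical(back$surveys$acquaint, t$surveys$acquaint)

  e <- generate_township(township_config(n_population = 0))
  d2 <- withr::local_tempdir()
  write_survey_csv(e$roster, e$surveys, d2)
  back2 <- read_survey_csv(d2)
  expect_identical(nrow(back2$roster), 0L)
  expect_identical(names(back2$roster), names(e$roster))
})

test_that("malformed survey files raise parse errors with location", {
  t <- generate_township(township_config(n_population = 30, seed = 2))
  d <- withr::local_tempdir()
  write_survey_csv(t, path = d)

  ## drop a required column
  r <- read.csv(file.path(d, "roster.csv"))
  write.csv(r[, setdiff(names(r), "district")], file.path(d, "roster.csv"),
            row.names = FALSE)
  expect_error(read_survey_csv(d), "district")

  ## ragged row
  write_survey_csv(t, path = d)
  lines <- readLines(file.path(d, "egonet.csv"))
  lines[3] <- paste0(lines[3], ",stray")
  writeLines(lines, file.path(d, "egonet.csv"))
  expect_error(read_survey_csv(d), "line 3")
})

test_that("the planted segregated block draws alters internally and has lower SRH", {
  cfg <- township_config(n_population = 800, segregated_district = 4,
                         segregated_srh_penalty = 1.0, seed = 7)
  t <- generate_township(cfg)
  planted <- t$truth$planted_component_members
  expect_true(length(planted) > 0)
  expect_true(all(t$roster$district[match(planted, t$roster$person_id)] == "R04"))

  ## recompute means directly from the emitted roster
  srh_in <- mean(t$roster$srh[t$roster$person_id %in% planted])
  srh_all <- mean(t$roster$srh)
  expect_lt(srh_in, srh_all)

  ## block members name only block members; outsiders never name the block
  im <- t$truth$identity_map
  ego_district <- t$roster$district[match(im$ego_id, t$roster$person_id)]
  alter_internal <- im$true_id %in% t$roster$person_id
  alter_in_block <- im$true_id %in% planted
  expect_true(all(alter_in_block[ego_district == "R04"] |
                  !alter_internal[ego_district == "R04"]))
  expect_true(all(!alter_in_block[ego_district != "R04"]))
})

test_that("every planted duplicate mention satisfies the match rule vs its true person", {
  t <- generate_township(township_config(n_population = 400, seed = 9,
                                         p_name_perturbation = 1 / 3,
                                         age_report_noise_max = 4))
  im <- t$truth$identity_map
  internal <- im$true_id %in% t$roster$person_id
  reports <- t$surveys$alters
  key <- paste(reports$ego_id, reports$slot)
  rule <- match_rule()
  for (r in which(internal)) {
    rep_row <- reports[match(paste(im$ego_id[r], im$slot[r]), key), ]
    true_row <- t$roster[match(im$true_id[r], t$roster$person_id), ]
    expect_true(reports_match(rep_row, true_row, rule))
  }
})

test_that("mean ego density tracks the acquaintance density target", {
  for (target in c(0.5, 0.98)) {
    t <- generate_township(township_config(n_population = 400, seed = 13,
                                           acquaintance_density_target = target))
    m <- ego_metrics(t)
    dens <- m$density[!is.na(m$density)]
    expect_gt(length(dens), 200)
    expect_lt(abs(mean(dens) - target), 0.05)
  }
})

test_that("roster marginals reflect the configured population structure", {
  t <- generate_township(township_config(n_population = 1000, seed = 21))
  r <- t$roster
  expect_true(all(r$age >= 55))
  expect_true(all(r$srh %in% 1:5))
  expect_lt(abs(mean(r$marital_status == "living_with_spouse") - 0.76), 0.05)
  ## married persons are paired and list their spouse first
  married <- r$person_id[r$marital_status == "living_with_spouse" & r$is_respondent]
  spouse_slots <- t$surveys$alters[t$surveys$alters$slot == "spouse", ]
  expect_setequal(spouse_slots$ego_id, married)
  m <- ego_metrics(t)
  expect_lt(abs(mean(m$size) - 3.07), 0.25)
})
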
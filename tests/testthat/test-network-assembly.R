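rec <- function(t1, t2, t3, gender = "female", age = 70, district = "R01") {
  list(name_token1 = t1, name_token2 = t2, name_token3 = t3,
       gender = gender, age = age, district = district)
}

test_that("the four-criterion match rule behaves at its boundaries", {
  rule <- match_rule()
  ## two of three tokens, same gender/district, age gap 2 -> match
  expect_true(reports_match(rec("A", "B", "C", age = 71), rec("A", "B", "D", age = 73), rule))
  ## age gap exactly 5 is not "less than five years"
  expect_false(reports_match(rec("A", "B", "C", age = 60), rec("A", "B", "C", age = 65), rule))
  expect_true(reports_match(rec("A", "B", "C", age = 60), rec("A", "B", "C", age = 64.5), rule))
  ## reflexive
  expect_true(reports_match(rec("A", "B", "C"), rec("A", "B", "C"), rule))
  ## one token only, wrong gender, wrong district
  expect_false(reports_match(rec("A", "X", "Y"), rec("A", "B", "C"), rule))
  expect_false(reports_match(rec("A", "B", "C", gender = "male"), rec("A", "B", "C"), rule))
  expect_false(reports_match(rec("A", "B", "C", district = "R02"), rec("A", "B", "C"), rule))
  ## token matching is position-wise, not multiset
  expect_false(reports_match(rec("A", "B", "C"), rec("B", "C", "A"), rule))
  ## relaxed rule options
  loose <- match_rule(min_name_token_matches = 1, require_same_district = FALSE)
  expect_true(reports_match(rec("A", "X", "Y", district = "R02"), rec("A", "B", "C"), loose))
  ## missing field warns and never matches
  expect_warning(res <- reports_match(rec("A", "B", "C", age = NA), rec("A", "B", "C")),
                 "missing")
  expect_false(res)
})

test_that("perturbed mentions of one person collapse onto a single canonical node", {
  roster <- data.frame(
    person_id = c("P1", "P2"),
    name_token1 = c("a", "q"), name_token2 = c("b", "r"), name_token3 = c("c", "s"),
    gender = "female", age = c(70L, 72L), district = "R01",
    marital_status = "separated_divorced_widowed", education = "none",
    srh = 3L, n_chronic = 0L, years_in_village = 10L, is_respondent = TRUE,
    stringsAsFactors = FALSE
  )
  ## both egos name the same outsider with one perturbed token and age +-2
  alters <- data.frame(
    ego_id = c("P1", "P2"), slot = "d1",
    name_token1 = c("x", "x"), name_token2 = c("y", "y"), name_token3 = c("z", "w"),
    gender = "male", age = c(80L, 82L), district = "OUT01",
    relationship = "friend", cohabiting = FALSE, closeness = 3L,
    contact_category = 2L, stringsAsFactors = FALSE
  )
  res <- resolve_duplicates(list(alters = alters), roster)
  expect_identical(res$log$n_new_nodes, 1L)
  expect_identical(res$assignment$node_id[1], res$assignment$node_id[2])
  ## assignment is a total function over reports
  expect_identical(nrow(res$assignment), 2L)
  expect_true(all(res$assignment$node_id %in% res$nodes$node_id))
})

test_that("with no alters the nodes are exactly the roster", {
  t <- generate_township(township_config(n_population = 50, mean_alters = 0,
                                         p_married = 0, seed = 3))
  res <- resolve_duplicates(t$surveys, t$roster)
  expect_setequal(res$nodes$node_id, t$roster$person_id)
})

test_that("zero identifier noise yields exact recovery of planted identities", {
  t <- generate_township(township_config(n_population = 400, seed = 23,
                                         p_name_perturbation = 0,
                                         age_report_noise_max = 0))
  sc <- score_resolution(resolve_duplicates(t$surveys, t$roster), t$truth$identity_map)
  expect_equal(sc$precision, 1)
  expect_equal(sc$recall, 1)
})

test_that("resolution accuracy at default noise exceeds 0.95 (seed 7 township)", {
  t <- generate_township(township_config(n_population = 800, seed = 7))
  sc <- score_resolution(resolve_duplicates(t$surveys, t$roster), t$truth$identity_map)
  expect_gte(sc$precision, 0.95)
  expect_gte(sc$recall, 0.95)
})

test_that("the exclusion filter drops only non-spouse outsiders", {
  nodes <- data.frame(
    node_id = c("A", "B", "C", "D"),
    district = c("R01", "OUT01", "OUT02", "R02"),
    is_respondent = c(TRUE, FALSE, FALSE, FALSE),
    is_spouse_of_respondent = c(FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  kept <- filter_township_nodes(nodes, c("R01", "R02"))
  ## outside spouse retained (conjunction), outside non-spouse dropped
  expect_setequal(kept$node_id, c("A", "B", "D"))

  ## worked example at the published scale: 1,595 merged persons of whom
  ## 583 are non-spouse outsiders -> 1,012 retained
  big <- data.frame(
    node_id = sprintf("M%04d", 1:1595),
    district = c(rep("R01", 1012), rep("OUT01", 583)),
    is_respondent = FALSE,
    is_spouse_of_respondent = FALSE,
    stringsAsFactors = FALSE
  )
  expect_identical(nrow(filter_township_nodes(big, "R01")), 1012L)
})

test_that("tie construction dedupes, drops self-ties and only ever removes", {
  t <- generate_township(township_config(n_population = 300, seed = 29))
  res <- resolve_duplicates(t$surveys, t$roster)
  net <- build_complete_network(res)
  expect_false(any(duplicated(paste(net$ties$src, net$ties$dst))))
  expect_false(any(net$ties$src == net$ties$dst))
  ## per-ego out-ties never exceed the reported network size
  m <- ego_metrics(t)
  out_deg <- table(net$ties$src)
  for (ego in names(out_deg)) {
    expect_lte(unname(out_deg[ego]), m$size[m$ego_id == ego])
  }
  ## all alters inside the township: the filter removes nothing
  t2 <- generate_township(township_config(n_population = 100, seed = 31,
                                          p_external_alter = 0))
  res2 <- resolve_duplicates(t2$surveys, t2$roster)
  net2 <- build_complete_network(res2)
  expect_identical(net2$log$n_excluded, 0L)
})

test_that("retention is monotone: a sub-survey retains a subset of nodes", {
  t <- generate_township(township_config(n_population = 200, seed = 37))
  al <- t$surveys$alters
  egos <- unique(al$ego_id)
  sub_al <- al[al$ego_id %in% egos[1:50], ]
  full <- build_complete_network(resolve_duplicates(list(alters = al), t$roster))
  ## roster is common; compare only nodes arising from the shared reports
  sub <- build_complete_network(resolve_duplicates(list(alters = sub_al), t$roster))
  sub_roster_kept <- sub$nodes$node_id[sub$nodes$node_id %in% t$roster$person_id]
  full_roster_kept <- full$nodes$node_id[full$nodes$node_id %in% t$roster$person_id]
  expect_true(all(sub_roster_kept %in% full_roster_kept))
})
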
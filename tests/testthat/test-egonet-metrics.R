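test_that("network size counts spouse plus discussion alters, 0 to 6", {
  en <- make_ego(list(slot = "spouse", rel = "spouse"), list(), list())
  expect_identical(network_size(en), 3L)
  expect_identical(network_size(make_ego()), 0L)
  full <- do.call(make_ego, c(list(list(slot = "spouse", rel = "spouse")),
                              replicate(5, list(), simplify = FALSE)))
  expect_identical(network_size(full), 6L)
})

test_that("composition counts qualifying members over size", {
  en <- make_ego(
    list(slot = "spouse", rel = "spouse", gender = "female", cohab = TRUE),
    list(rel = "friend", gender = "male", cohab = FALSE)
  )
  expect_equal(unname(composition(en)), c(0.5, 0.5, 0.5))
  ## spouse-as-kin switch moves the kin proportion
  expect_equal(composition(en, default_codebook(spouse_as_kin = FALSE))[["prop_kin"]], 0)

  en4 <- make_ego(list(rel = "child"), list(rel = "friend"),
                  list(rel = "friend"), list(rel = "friend"))
  expect_equal(composition(en4)[["prop_kin"]], 0.25)
  allf <- make_ego(list(gender = "female"), list(gender = "female"))
  expect_equal(composition(allf)[["prop_female"]], 1)
  ## empty network: undefined, not zero
  expect_true(all(is.na(composition(make_ego()))))
})

test_that("average closeness is the plain mean of member codes", {
  expect_equal(average_closeness(make_ego(list(closeness = 4), list(closeness = 4))), 4)
  expect_equal(average_closeness(make_ego(list(closeness = 1), list(closeness = 2),
                                          list(closeness = 3), list(closeness = 4))), 2.5)
  expect_equal(average_closeness(make_ego(list(closeness = 3), list(closeness = 3),
                                          list(closeness = 4))), 10 / 3)
  en <- make_ego(list(closeness = NA), list(closeness = 2))
  expect_warning(v <- average_closeness(en), "missing")
  expect_equal(v, 2)
  expect_true(is.na(average_closeness(make_ego())))
})

test_that("contact volume sums days per year over members and is additive", {
  ## spouse every day + one alter once a month
  en <- make_ego(list(slot = "spouse", rel = "spouse", contact = 1),
                 list(contact = 5))
  expect_equal(contact_volume(en), 365 + 12)
  ## two alters a couple times a year
  expect_equal(contact_volume(make_ego(list(contact = 7), list(contact = 7))), 4)
  expect_equal(contact_volume(make_ego()), 0)
  expect_error(contact_volume(make_ego(list(contact = 9))), "unknown contact category")

  ## additivity under member-list concatenation
  a <- make_ego(list(contact = 1), list(contact = 3))
  b <- make_ego(list(contact = 6))
  ab <- make_ego(list(contact = 1), list(contact = 3), list(contact = 6))
  expect_equal(contact_volume(ab), contact_volume(a) + contact_volume(b))
})

test_that("ego density is acquainted pairs over possible pairs", {
  expect_equal(ego_density(make_ego(list(), list(), list())), 1)
  A <- matrix(0, 3, 3, dimnames = list(paste0("d", 1:3), paste0("d", 1:3)))
  A["d1", "d2"] <- A["d2", "d1"] <- 1
  expect_equal(ego_density(make_ego(list(), list(), list(), acq = A)), 1 / 3)
  B <- matrix(1, 4, 4, dimnames = list(paste0("d", 1:4), paste0("d", 1:4)))
  diag(B) <- 0
  B["d1", "d2"] <- B["d2", "d1"] <- 0
  expect_equal(ego_density(make_ego(list(), list(), list(), list(), acq = B)), 5 / 6)
  ## undefined below two members
  expect_true(is.na(ego_density(make_ego(list()))))
  expect_true(is.na(ego_density(make_ego())))
})

test_that("bridging potential flags members acquainted with nobody else", {
  expect_equal(bridging_potential(make_ego(list(), list(), list())), 0)
  A <- matrix(0, 3, 3, dimnames = list(paste0("d", 1:3), paste0("d", 1:3)))
  A["d1", "d2"] <- A["d2", "d1"] <- 1
  expect_equal(bridging_potential(make_ego(list(), list(), list(), acq = A)), 1)
  expect_true(is.na(bridging_potential(make_ego(list()))))
})

test_that("metrics are invariant to member ordering", {
  specs <- list(list(slot = "spouse", rel = "spouse", contact = 1, closeness = 4,
                     gender = "male", cohab = TRUE),
                list(rel = "child", contact = 3, closeness = 2, gender = "female"),
                list(rel = "friend", contact = 7, closeness = 3, gender = "female"))
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3,
              dimnames = list(c("spouse", "d2", "d3"), c("spouse", "d2", "d3")))
  en <- make_ego(specs[[1]], specs[[2]], specs[[3]], acq = A)
  ## reverse the member rows, keep the named acquaintance matrix
  rev_members <- en$members[3:1, ]
  en_rev <- ego_network("E1", rev_members, A)
  for (f in list(network_size, composition, average_closeness, contact_volume,
                 ego_density, bridging_potential)) {
    expect_equal(unname(f(en)), unname(f(en_rev)))
  }
})

test_that("ego density agrees with an independent graph-theoretic computation", {
  t <- generate_township(township_config(n_population = 500, seed = 17,
                                         acquaintance_density_target = 0.6))
  m <- ego_metrics(t)
  aq <- split(t$surveys$acquaint, t$surveys$acquaint$ego_id)
  checked <- 0
  for (ego in names(aq)) {
    sub <- aq[[ego]]
    slots <- unique(c(sub$slot_a, sub$slot_b))
    g <- igraph::graph_from_data_frame(sub[sub$acquainted == 1, c("slot_a", "slot_b")],
                                       directed = FALSE, vertices = slots)
    expect_equal(m$density[m$ego_id == ego], igraph::edge_density(g))
    checked <- checked + 1
  }
  expect_gt(checked, 200)
})

test_that("density 1 forces bridging potential 0 on every generated ego", {
  t <- generate_township(township_config(n_population = 300, seed = 19))
  m <- ego_metrics(t)
  expect_true(all(m$density >= 0 & m$density <= 1, na.rm = TRUE))
  dense <- !is.na(m$density) & m$density == 1
  expect_true(all(m$bridging_potential[dense] == 0))
  ## undefined markers line up with size < 2
  expect_identical(is.na(m$density), m$size < 2)
})
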
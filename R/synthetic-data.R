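#' Configuration for a synthetic township
#'
#' Collects every knob of the synthetic survey generator. The defaults
#' describe a rural township of older adults and their spouses: roughly
#' three-quarters of respondents live with a spouse, egos name about 2.3
#' discussion partners besides the spouse, ego networks are almost fully
#' interconnected (density target 0.98), and alters are drawn with strong
#' within-district homophily. Identifier noise (one perturbed name token,
#' a few years of age misreporting) is bounded so that a duplicate mention
#' of the same person always stays within the 4-criterion match rule used
#' downstream.
#'
#' @param n_population number of persons on the roster (older adults and
#'   their spouses).
#' @param n_districts number of administrative districts ("Ri" units).
#' @param district_weights proportion of the population per district;
#'   defaults to equal weights. Must sum to 1.
#' @param p_married probability of living with a spouse.
#' @param mean_alters expected number of non-spouse discussion alters per
#'   ego (truncated at 5).
#' @param within_district_tie_prob,between_district_tie_prob relative
#'   weights governing whether an alter is drawn from the ego's own district
#'   or another one (homophily control).
#' @param acquaintance_density_target expected density of each ego's
#'   member-member acquaintance matrix, in \[0, 1\].
#' @param name_token_alphabet_size size of the token pool from which the
#'   3-token names are drawn.
#' @param p_name_perturbation probability that one token of an alter
#'   mention is altered relative to the roster name.
#' @param age_report_noise_max maximum absolute age misreport in years;
#'   must stay below 5 so planted duplicates remain matchable.
#' @param p_external_alter probability that a discussion alter lives
#'   outside the township (e.g. a child in the city). The default 0.30
#'   reproduces the observed share of merged persons who fail the
#'   residence criterion (about a third).
#' @param external_orientation_concentration concentration (sum of Beta
#'   shape parameters) of the household-level external-orientation draw.
#'   Each household receives a propensity `p ~ Beta(c * p_ext, c * (1 -
#'   p_ext))` that its members' alters live outside the township, so the
#'   population mean stays `p_external_alter` while small values of the
#'   concentration make whole households externally oriented -- the
#'   mechanism behind dyadic and isolated components of retained nodes.
#' @param p_response probability that a roster member completes the survey;
#'   default 814/860.
#' @param srh_size_effect strength of the planted association between
#'   network size and self-rated health (latent-scale slope per member).
#'   The default 0.10 reproduces the observed mean network sizes of the
#'   three self-rated-health groups (about 2.85 / 3.21 / 3.42).
#' @param segregated_district optional district index whose members form an
#'   isolated block: they draw alters only among themselves and are never
#'   named by outsiders.
#' @param segregated_srh_penalty decrement applied to the segregated
#'   block's self-rated health (rounded to the integer scale, floored at 1).
#' @param seed random seed; the same seed reproduces the township exactly.
#' @return an object of class `township_config`.
#' @export
township_config <- function(n_population = 860,
                            n_districts = 10,
                            district_weights = NULL,
                            p_married = 0.76,
                            mean_alters = 2.31,
                            within_district_tie_prob = 0.8,
                            between_district_tie_prob = 0.2,
                            acquaintance_density_target = 0.98,
                            name_token_alphabet_size = 60,
                            p_name_perturbation = 0.2,
                            age_report_noise_max = 3,
                            p_external_alter = 0.30,
                            external_orientation_concentration = 0.8,
                            p_response = 814 / 860,
                            srh_size_effect = 0.10,
                            segregated_district = NULL,
                            segregated_srh_penalty = 0,
                            seed = 1) {
  if (is.null(district_weights))
    district_weights <- rep(1 / n_districts, n_districts)
  cfg <- structure(list(
    n_population = as.integer(n_population),
    n_districts = as.integer(n_districts),
    district_weights = district_weights,
    p_married = p_married,
    mean_alters = mean_alters,
    within_district_tie_prob = within_district_tie_prob,
    between_district_tie_prob = between_district_tie_prob,
    acquaintance_density_target = acquaintance_density_target,
    name_token_alphabet_size = as.integer(name_token_alphabet_size),
    p_name_perturbation = p_name_perturbation,
    age_report_noise_max = age_report_noise_max,
    p_external_alter = p_external_alter,
    external_orientation_concentration = external_orientation_concentration,
    p_response = p_response,
    srh_size_effect = srh_size_effect,
    segregated_district = if (is.null(segregated_district)) NULL else as.integer(segregated_district),
    segregated_srh_penalty = segregated_srh_penalty,
    seed = as.integer(seed)
  ), class = "township_config")
  validate_township_config(cfg)
  cfg
}

validate_township_config <- function(cfg) {
  cfg_err <- function(field, msg) stop("invalid township_config: ", field, " ", msg, call. = FALSE)
  if (is.na(cfg$n_population) || cfg$n_population < 0) cfg_err("n_population", "must be >= 0")
  if (cfg$n_districts < 1) cfg_err("n_districts", "must be >= 1")
  if (length(cfg$district_weights) != cfg$n_districts)
    cfg_err("district_weights", "must have one weight per district")
  if (abs(sum(cfg$district_weights) - 1) > 1e-9)
    cfg_err("district_weights", "must sum to 1")
  if (any(cfg$district_weights < 0)) cfg_err("district_weights", "must be non-negative")
  for (f in c("p_married", "p_name_perturbation", "p_external_alter", "p_response",
              "acquaintance_density_target")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) cfg_err(f, "must be a probability in [0, 1]")
  }
  if (cfg$mean_alters < 0 || cfg$mean_alters > 5) cfg_err("mean_alters", "must be in [0, 5]")
  if (cfg$within_district_tie_prob < 0 || cfg$within_district_tie_prob > 1)
    cfg_err("within_district_tie_prob", "must be in [0, 1]")
  if (cfg$between_district_tie_prob < 0 || cfg$between_district_tie_prob > 1)
    cfg_err("between_district_tie_prob", "must be in [0, 1]")
  if (cfg$age_report_noise_max < 0 || cfg$age_report_noise_max >= 5)
    cfg_err("age_report_noise_max", "must be in [0, 5) so duplicates stay matchable")
  if (cfg$name_token_alphabet_size < 2) cfg_err("name_token_alphabet_size", "must be >= 2")
  if (cfg$external_orientation_concentration <= 0)
    cfg_err("external_orientation_concentration", "must be positive")
  if (!is.null(cfg$segregated_district) &&
      (cfg$segregated_district < 1 || cfg$segregated_district > cfg$n_districts))
    cfg_err("segregated_district", "must index an existing district")
  invisible(cfg)
}

.district_labels <- function(k) sprintf("R%02d", seq_len(k))

.draw_tokens <- function(n, alphabet_size) {
  matrix(sprintf("t%03d", sample.int(alphabet_size, 3 * n, replace = TRUE)),
         ncol = 3)
}

## Names identify: resample a person's tokens until no earlier person in the
## same district-and-gender block within `age_buffer` years shares two token
## positions. This makes distinct persons distinguishable under the
## duplicate-identification rule even after bounded age misreporting, which
## is what lets noise-free surveys resolve exactly to the ground truth.
.deduplicate_identities <- function(tokens, gender, age, district,
                                    alphabet_size, age_buffer) {
  key <- paste(district, gender)
  for (i in seq_len(nrow(tokens))[-1]) {
    prev <- which(key[seq_len(i - 1)] == key[i] &
                  abs(age[seq_len(i - 1)] - age[i]) < age_buffer)
    if (!length(prev)) next
    repeat {
      tokmatch <- (tokens[prev, 1] == tokens[i, 1]) +
        (tokens[prev, 2] == tokens[i, 2]) + (tokens[prev, 3] == tokens[i, 3])
      if (all(tokmatch < 2)) break
      tokens[i, ] <- sprintf("t%03d", sample.int(alphabet_size, 3, replace = TRUE))
    }
  }
  tokens
}

.empty_township <- function(config) {
  roster <- .empty_df(.roster_columns,
                      c("character", "character", "character", "character", "character",
                        "integer", "character", "character", "character", "integer",
                        "integer", "integer", "logical"))
  alters <- .empty_df(.alter_columns,
                      c("character", "character", "character", "character", "character",
                        "character", "integer", "character", "character", "logical",
                        "integer", "integer"))
  acquaint <- .empty_df(.acquaint_columns,
                        c("character", "character", "character", "integer"))
  truth <- list(
    identity_map = .empty_df(c("ego_id", "slot", "true_id"),
                             c("character", "character", "character")),
    planted_component_members = character(),
    true_tie_list = .empty_df(c("ego_id", "true_id"), c("character", "character"))
  )
  structure(list(roster = roster, surveys = list(alters = alters, acquaint = acquaint),
                 truth = truth, config = config), class = "township")
}

#' Generate a synthetic township
#'
#' Simulates a roster of older adults and their spouses plus the name-
#' generator survey each respondent would file: a spouse roster entry (if
#' married), up to five discussion alters drawn with within-district
#' homophily, possibly perturbed alter identifiers (name tokens, age), and
#' a member-by-member acquaintance matrix. A planted ground truth records
#' which canonical person every alter mention denotes, so entity-resolution
#' accuracy can be scored exactly.
#'
#' Self-rated health (5-level) is generated with a positive latent
#' association with network size. If `segregated_district` is set, that
#' district's members name alters only among themselves, are never named by
#' outsiders, and have their health scores shifted down by
#' `segregated_srh_penalty` -- a geographically segregated block with worse
#' self-rated health.
#'
#' @param config a [township_config()].
#' @return an object of class `township`: a list with elements `roster`
#'   (data frame), `surveys` (list of `alters` and `acquaint` data frames),
#'   `truth` (identity map, planted block member ids, true tie list) and
#'   `config`.
#' @export
generate_township <- function(config) {
  validate_township_config(config)
  if (config$n_population == 0) return(.empty_township(config))

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- config$n_population
  districts <- .district_labels(config$n_districts)
  seg_lab <- if (is.null(config$segregated_district)) NA_character_ else districts[config$segregated_district]

  ## ---- roster ----
  n_couples <- round(n * config$p_married) %/% 2L
  n_single <- n - 2L * n_couples
  couple_district <- sample(districts, n_couples, replace = TRUE, prob = config$district_weights)
  single_district <- sample(districts, n_single, replace = TRUE, prob = config$district_weights)

  h_age <- .clamp(round(stats::rnorm(n_couples, 73, 7)), 60, 95)
  w_age <- .clamp(h_age - round(stats::rnorm(n_couples, 3, 3)), 55, 95)
  s_age <- .clamp(round(stats::rnorm(n_single, 74, 8)), 60, 95)

  person_id <- sprintf("P%04d", seq_len(n))
  idx_h <- seq_len(n_couples) * 2L - 1L
  idx_w <- idx_h + 1L
  idx_s <- if (n_single > 0) (2L * n_couples + 1L):n else integer()

  age <- integer(n); gender <- character(n); district <- character(n)
  marital <- character(n); spouse_of <- rep(NA_character_, n)
  age[idx_h] <- h_age; age[idx_w] <- w_age; age[idx_s] <- s_age
  gender[idx_h] <- "male"; gender[idx_w] <- "female"
  gender[idx_s] <- sample(c("female", "male"), n_single, replace = TRUE, prob = c(0.78, 0.22))
  district[idx_h] <- couple_district; district[idx_w] <- couple_district
  district[idx_s] <- single_district
  marital[c(idx_h, idx_w)] <- "living_with_spouse"
  marital[idx_s] <- sample(c("separated_divorced_widowed", "never_married"),
                           n_single, replace = TRUE, prob = c(0.95, 0.05))
  spouse_of[idx_h] <- person_id[idx_w]; spouse_of[idx_w] <- person_id[idx_h]

  tokens <- .draw_tokens(n, config$name_token_alphabet_size)
  tokens <- .deduplicate_identities(tokens, gender, age, district,
                                    config$name_token_alphabet_size,
                                    age_buffer = 5 + 2 * config$age_report_noise_max)
  education <- sample(.education_levels, n, replace = TRUE, prob = c(0.30, 0.41, 0.29))
  n_chronic <- stats::rpois(n, 2)
  years_in_village <- .clamp(round(stats::rnorm(n, 45, 18)), 1, 90)
  is_respondent <- stats::runif(n) < config$p_response

  ## Household-level external orientation: couples share one Beta draw of
  ## the propensity that their named alters live outside the township, so
  ## some households are almost fully externally oriented (these become the
  ## dyadic and isolated components of the retained network). Exponential
  ## popularity weights concentrate who gets named, giving the
  ## overdispersed in-degree seen in real name-generator data.
  p_bar <- config$p_external_alter
  nu <- config$external_orientation_concentration
  p_ext <- if (p_bar <= 0 || p_bar >= 1) rep(p_bar, n) else
    stats::rbeta(n, nu * p_bar, nu * (1 - p_bar))
  p_ext[idx_w] <- p_ext[idx_h]
  ## village embeddedness: a household oriented toward the outside both
  ## names fewer insiders and is less visible to be named itself
  popularity <- stats::rexp(n) * (1 - p_ext) + 1e-9

  ## planted alter counts drive both the surveys and the health link
  n_alt <- pmin(5L, stats::rpois(n, config$mean_alters))
  latent <- config$srh_size_effect * (n_alt + (marital == "living_with_spouse") - 3) +
    stats::rnorm(n)
  cuts <- stats::qnorm(c(0.215, 0.43, 0.92, 0.98))
  srh <- findInterval(latent, cuts) + 1L
  in_seg <- !is.na(seg_lab) & district == seg_lab
  if (any(in_seg) && config$segregated_srh_penalty != 0) {
    srh[in_seg] <- pmax(1L, srh[in_seg] - as.integer(round(config$segregated_srh_penalty)))
  }

  roster <- data.frame(
    person_id = person_id,
    name_token1 = tokens[, 1], name_token2 = tokens[, 2], name_token3 = tokens[, 3],
    gender = gender, age = as.integer(age), district = district,
    marital_status = marital, education = education, srh = srh,
    n_chronic = as.integer(n_chronic), years_in_village = as.integer(years_in_village),
    is_respondent = is_respondent,
    stringsAsFactors = FALSE
  )

  ## ---- surveys ----
  by_district <- split(seq_len(n), district)
  ext_districts <- sprintf("OUT%02d", 1:5)
  rel_internal <- c("neighbor", "friend", "child", "sibling", "relative_in_law",
                    "parent", "clergy", "health_professional", "social_worker", "other")
  rel_internal_p <- c(0.45, 0.25, 0.06, 0.07, 0.05, 0.01, 0.02, 0.02, 0.02, 0.05)
  rel_external <- c("child", "relative_in_law", "friend", "sibling", "other")
  rel_external_p <- c(0.50, 0.20, 0.15, 0.05, 0.10)
  closeness_p <- c(0.02, 0.10, 0.46, 0.42)
  contact_internal_p <- c(0.40, 0.35, 0.12, 0.05, 0.04, 0.02, 0.01, 0.01)
  contact_external_p <- c(0.05, 0.15, 0.15, 0.15, 0.20, 0.15, 0.10, 0.05)
  noise_vals <- -config$age_report_noise_max:config$age_report_noise_max

  alter_rows <- list(); acq_rows <- list(); id_rows <- list()
  ext_counter <- 0L
  ## registry of already-invented outsiders so no two distinct external
  ## persons collide under the duplicate-identification rule
  ext_reg <- list(tok = matrix(character(0), 0, 3), key = character(0),
                  age = integer(0))

  perturb_name <- function(toks) {
    if (stats::runif(1) < config$p_name_perturbation) {
      pos <- sample.int(3L, 1L)
      repl <- sprintf("t%03d", sample.int(config$name_token_alphabet_size, 1L))
      while (repl == toks[pos] && config$name_token_alphabet_size > 1)
        repl <- sprintf("t%03d", sample.int(config$name_token_alphabet_size, 1L))
      toks[pos] <- repl
    }
    toks
  }

  for (i in which(is_respondent)) {
    members <- list()  # each: list(slot, true_id, row of report fields)
    ego <- person_id[i]

    if (marital[i] == "living_with_spouse" && !is.na(spouse_of[i])) {
      j <- match(spouse_of[i], person_id)
      members[[length(members) + 1]] <- list(
        slot = "spouse", true_id = person_id[j],
        tokens = perturb_name(tokens[j, ]),
        gender = gender[j], age = age[j] + sample(noise_vals, 1L),
        district = district[j], relationship = "spouse", cohabiting = TRUE,
        closeness = sample(1:4, 1L, prob = closeness_p),
        contact = sample(1:2, 1L, prob = c(0.95, 0.05))
      )
    }

    k_alt <- n_alt[i]
    chosen <- character()
    slot_no <- 0L
    while (slot_no < k_alt) {
      slot_no <- slot_no + 1L
      is_ext <- !in_seg[i] && stats::runif(1) < p_ext[i]
      if (is_ext) {
        ext_counter <- ext_counter + 1L
        e_gender <- sample(c("male", "female"), 1L)
        e_age <- .clamp(round(stats::rnorm(1, 50, 12)), 20, 90)
        e_district <- sample(ext_districts, 1L)
        e_tok <- sprintf("t%03d", sample.int(config$name_token_alphabet_size, 3L, replace = TRUE))
        prev <- which(ext_reg$key == paste(e_district, e_gender) &
                      abs(ext_reg$age - e_age) < 5)
        while (length(prev) &&
               any((ext_reg$tok[prev, 1] == e_tok[1]) +
                   (ext_reg$tok[prev, 2] == e_tok[2]) +
                   (ext_reg$tok[prev, 3] == e_tok[3]) >= 2)) {
          e_tok <- sprintf("t%03d", sample.int(config$name_token_alphabet_size, 3L, replace = TRUE))
        }
        ext_reg$tok <- rbind(ext_reg$tok, e_tok)
        ext_reg$key <- c(ext_reg$key, paste(e_district, e_gender))
        ext_reg$age <- c(ext_reg$age, e_age)
        members[[length(members) + 1]] <- list(
          slot = paste0("d", sum(vapply(members, function(m) m$slot != "spouse", logical(1))) + 1L),
          true_id = sprintf("X%05d", ext_counter),
          tokens = e_tok,
          gender = e_gender,
          age = e_age,
          district = e_district,
          relationship = sample(rel_external, 1L, prob = rel_external_p),
          cohabiting = FALSE,
          closeness = sample(1:4, 1L, prob = closeness_p),
          contact = sample(1:8, 1L, prob = contact_external_p)
        )
        next
      }
      ## internal alter: pick a district, then a person within it
      if (in_seg[i]) {
        d <- seg_lab
      } else {
        w <- config$district_weights *
          ifelse(districts == district[i], config$within_district_tie_prob,
                 config$between_district_tie_prob)
        if (!is.na(seg_lab)) w[districts == seg_lab] <- 0
        if (sum(w) == 0) next
        d <- sample(districts, 1L, prob = w)
      }
      pool <- setdiff(by_district[[d]], c(i, match(spouse_of[i], person_id),
                                          match(chosen, person_id)))
      if (!length(pool)) {
        ## fall back to any permissible district with candidates left
        cand_d <- if (in_seg[i]) seg_lab else setdiff(districts, seg_lab)
        pool <- setdiff(unlist(by_district[cand_d], use.names = FALSE),
                        c(i, match(spouse_of[i], person_id), match(chosen, person_id)))
        if (!length(pool)) next
      }
      j <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = popularity[pool])
      chosen <- c(chosen, person_id[j])
      rel <- sample(rel_internal, 1L, prob = rel_internal_p)
      members[[length(members) + 1]] <- list(
        slot = paste0("d", sum(vapply(members, function(m) m$slot != "spouse", logical(1))) + 1L),
        true_id = person_id[j],
        tokens = perturb_name(tokens[j, ]),
        gender = gender[j], age = age[j] + sample(noise_vals, 1L),
        district = district[j], relationship = rel,
        cohabiting = stats::runif(1) < if (rel == "child") 0.3 else 0.03,
        closeness = sample(1:4, 1L, prob = closeness_p),
        contact = sample(1:8, 1L, prob = contact_internal_p)
      )
    }

    if (!length(members)) next
    m <- length(members)
    alter_rows[[length(alter_rows) + 1]] <- data.frame(
      ego_id = ego,
      slot = vapply(members, `[[`, character(1), "slot"),
      name_token1 = vapply(members, function(x) x$tokens[1], character(1)),
      name_token2 = vapply(members, function(x) x$tokens[2], character(1)),
      name_token3 = vapply(members, function(x) x$tokens[3], character(1)),
      gender = vapply(members, `[[`, character(1), "gender"),
      age = as.integer(vapply(members, `[[`, numeric(1), "age")),
      district = vapply(members, `[[`, character(1), "district"),
      relationship = vapply(members, `[[`, character(1), "relationship"),
      cohabiting = vapply(members, `[[`, logical(1), "cohabiting"),
      closeness = as.integer(vapply(members, `[[`, numeric(1), "closeness")),
      contact_category = as.integer(vapply(members, `[[`, numeric(1), "contact")),
      stringsAsFactors = FALSE
    )
    id_rows[[length(id_rows) + 1]] <- data.frame(
      ego_id = ego,
      slot = vapply(members, `[[`, character(1), "slot"),
      true_id = vapply(members, `[[`, character(1), "true_id"),
      stringsAsFactors = FALSE
    )
    if (m >= 2) {
      slots <- vapply(members, `[[`, character(1), "slot")
      pr <- utils::combn(m, 2)
      acq_rows[[length(acq_rows) + 1]] <- data.frame(
        ego_id = ego,
        slot_a = slots[pr[1, ]], slot_b = slots[pr[2, ]],
        acquainted = stats::rbinom(ncol(pr), 1, config$acquaintance_density_target),
        stringsAsFactors = FALSE
      )
    }
  }

  empty <- .empty_township(config)
  alters <- if (length(alter_rows)) do.call(rbind, alter_rows) else empty$surveys$alters
  acquaint <- if (length(acq_rows)) do.call(rbind, acq_rows) else empty$surveys$acquaint
  identity_map <- if (length(id_rows)) do.call(rbind, id_rows) else empty$truth$identity_map
  rownames(alters) <- rownames(acquaint) <- rownames(identity_map) <- NULL

  truth <- list(
    identity_map = identity_map,
    planted_component_members = person_id[in_seg],
    true_tie_list = if (nrow(identity_map))
      unique(identity_map[, c("ego_id", "true_id")]) else empty$truth$true_tie_list
  )
  rownames(truth$true_tie_list) <- NULL

  structure(list(roster = roster, surveys = list(alters = alters, acquaint = acquaint),
                 truth = truth, config = config), class = "township")
}

#' @export
print.township <- function(x, ...) {
  cat("Synthetic township\n")
  cat("  roster:", nrow(x$roster), "persons in",
      length(unique(x$roster$district)), "districts\n")
  cat("  respondents:", sum(x$roster$is_respondent), "\n")
  cat("  alter reports:", nrow(x$surveys$alters), "\n")
  if (length(x$truth$planted_component_members))
    cat("  planted segregated block:", length(x$truth$planted_component_members), "members\n")
  invisible(x)
}

.roster_colclasses <- c(
  person_id = "character", name_token1 = "character", name_token2 = "character",
  name_token3 = "character", gender = "character", age = "integer",
  district = "character", marital_status = "character", education = "character",
  srh = "integer", n_chronic = "integer", years_in_village = "integer",
  is_respondent = "logical"
)
.alter_colclasses <- c(
  ego_id = "character", slot = "character", name_token1 = "character",
  name_token2 = "character", name_token3 = "character", gender = "character",
  age = "integer", district = "character", relationship = "character",
  cohabiting = "logical", closeness = "integer", contact_category = "integer"
)
.acquaint_colclasses <- c(
  ego_id = "character", slot_a = "character", slot_b = "character",
  acquainted = "integer"
)

#' Write or read a survey data set as CSV
#'
#' Serializes a roster and the ego-network surveys to three UTF-8 CSV files
#' (`roster.csv`, `egonet.csv`, `acquaint.csv`) in a directory, and reads
#' them back. `read_survey_csv()` is the exact inverse of
#' `write_survey_csv()`.
#'
#' @param roster roster data frame, or a `township` object (whose roster and
#'   surveys are then used).
#' @param surveys list with `alters` and `acquaint` data frames; ignored
#'   when `roster` is a `township`.
#' @param path directory to write to / read from.
#' @return `write_survey_csv()` returns `path` invisibly;
#'   `read_survey_csv()` returns `list(roster =, surveys =)`.
#' @export
write_survey_csv <- function(roster, surveys = NULL, path) {
  if (inherits(roster, "township")) {
    surveys <- roster$surveys
    roster <- roster$roster
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  utils::write.csv(roster, file.path(path, "roster.csv"), row.names = FALSE)
  utils::write.csv(surveys$alters, file.path(path, "egonet.csv"), row.names = FALSE)
  utils::write.csv(surveys$acquaint, file.path(path, "acquaint.csv"), row.names = FALSE)
  invisible(path)
}

.read_checked_csv <- function(file, colclasses) {
  if (!file.exists(file)) stop("survey file not found: ", file, call. = FALSE)
  nf <- utils::count.fields(file, sep = ",", quote = "\"")
  if (length(nf) == 0) stop("parse error in ", basename(file), ": empty file", call. = FALSE)
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("parse error in ", basename(file), " at line ", bad[1] + 0L,
         ": expected ", nf[1], " fields, found ", nf[bad[1]], call. = FALSE)
  header <- utils::read.csv(file, nrows = 1, check.names = FALSE)
  missing <- setdiff(names(colclasses), names(header))
  if (length(missing))
    stop("parse error in ", basename(file), ": missing required column \"",
         missing[1], "\"", call. = FALSE)
  utils::read.csv(file, colClasses = colclasses[names(header)],
                  stringsAsFactors = FALSE)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path) {
  roster <- .read_checked_csv(file.path(path, "roster.csv"), .roster_colclasses)
  alters <- .read_checked_csv(file.path(path, "egonet.csv"), .alter_colclasses)
  acquaint <- .read_checked_csv(file.path(path, "acquaint.csv"), .acquaint_colclasses)
  list(roster = roster, surveys = list(alters = alters, acquaint = acquaint))
}
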
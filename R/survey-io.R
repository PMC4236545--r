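#' @keywords internal
"_PACKAGE"

## Category code sets shared by the generator, the parsers and the metric
## stages. Stored once so every stage agrees on the legal levels.

.relationship_levels <- c(
  "spouse", "parent", "child", "sibling", "relative_in_law",
  "neighbor", "friend", "clergy", "health_professional",
  "social_worker", "other"
)

.marital_levels <- c(
  "living_with_spouse", "separated_divorced_widowed", "never_married"
)

.education_levels <- c("none", "elementary_or_seodang", "middle_school_plus")

.slot_levels <- c("spouse", paste0("d", 1:5))

.roster_columns <- c(
  "person_id", "name_token1", "name_token2", "name_token3", "gender",
  "age", "district", "marital_status", "education", "srh", "n_chronic",
  "years_in_village", "is_respondent"
)

.alter_columns <- c(
  "ego_id", "slot", "name_token1", "name_token2", "name_token3", "gender",
  "age", "district", "relationship", "cohabiting", "closeness",
  "contact_category"
)

.acquaint_columns <- c("ego_id", "slot_a", "slot_b", "acquainted")

#' Default category codebook
#'
#' Builds the codebook shared by all pipeline stages: the mapping from the
#' 8-level contact-frequency scale to approximate days of contact per year,
#' the set of relationship labels recoded as kin, the 3-group recode of the
#' 5-level self-rated health scale, and the age bins used in reporting
#' tables.
#'
#' The contact scale runs from "every day" (category 1) down to "less than
#' once per year" (category 8). Four anchors are fixed by the survey coding
#' convention -- every day = 365, several times a week = 182, once a month =
#' 12, a couple times a year = 2 -- and the remaining categories are filled
#' with monotone intermediate values (once a week = 52, a couple times a
#' month = 30, several times a year = 6, less than once a year = 0.5).
#'
#' @param spouse_as_kin should the spouse count toward the proportion-of-kin
#'   numerator? Defaults to `TRUE`.
#' @param contact_days optional replacement for the 8-value days-per-year
#'   mapping; must be strictly decreasing.
#' @return an object of class `codebook`.
#' @export
default_codebook <- function(spouse_as_kin = TRUE, contact_days = NULL) {
  if (is.null(contact_days)) {
    contact_days <- c(
      every_day = 365, several_times_a_week = 182, once_a_week = 52,
      couple_times_a_month = 30, once_a_month = 12,
      several_times_a_year = 6, couple_times_a_year = 2,
      less_than_once_a_year = 0.5
    )
  }
  kin <- c("parent", "child", "sibling", "relative_in_law")
  if (isTRUE(spouse_as_kin)) kin <- c("spouse", kin)
  cb <- structure(list(
    contact_days = contact_days,
    kin_relationships = kin,
    spouse_as_kin = isTRUE(spouse_as_kin),
    srh_3group = c("1" = "poor_somewhat_poor", "2" = "poor_somewhat_poor",
                   "3" = "good", "4" = "very_good_excellent",
                   "5" = "very_good_excellent"),
    age_breaks = c(64, 74)
  ), class = "codebook")
  validate_codebook(cb)
  cb
}

validate_codebook <- function(cb) {
  if (length(cb$contact_days) != 8)
    stop("codebook: contact_days must map all 8 contact categories")
  if (any(diff(unname(cb$contact_days)) >= 0))
    stop("codebook: contact_days must be strictly decreasing from category 1 to 8")
  if (!all(cb$kin_relationships %in% .relationship_levels))
    stop("codebook: unknown relationship label in kin_relationships")
  if (!identical(sort(names(cb$srh_3group)), as.character(1:5)))
    stop("codebook: srh_3group must map codes 1..5")
  invisible(cb)
}

#' @export
print.codebook <- function(x, ...) {
  cat("Survey codebook\n")
  cat("  contact days/year:", paste(unname(x$contact_days), collapse = ", "), "\n")
  cat("  kin relationships:", paste(x$kin_relationships, collapse = ", "), "\n")
  cat("  SRH 3-group recode: {1,2} / {3} / {4,5}\n")
  invisible(x)
}

#' Read or write a codebook as YAML
#'
#' @param cb a `codebook` object.
#' @param path file path of the YAML serialization.
#' @return `read_codebook()` returns a validated `codebook`;
#'   `write_codebook()` returns `path` invisibly.
#' @export
write_codebook <- function(cb, path) {
  validate_codebook(cb)
  lst <- unclass(cb)
  lst$contact_days <- as.list(cb$contact_days)
  lst$srh_3group <- as.list(cb$srh_3group)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  lst <- yaml::read_yaml(path)
  cb <- structure(list(
    contact_days = unlist(lst$contact_days),
    kin_relationships = unlist(lst$kin_relationships),
    spouse_as_kin = isTRUE(lst$spouse_as_kin),
    srh_3group = unlist(lst$srh_3group),
    age_breaks = unlist(lst$age_breaks)
  ), class = "codebook")
  validate_codebook(cb)
  cb
}

#' Survey response rate
#'
#' Completed interviews as a percentage of the eligible population.
#'
#' @param n_completed completed interviews.
#' @param n_eligible eligible persons.
#' @return percentage in \[0, 100\].
#' @export
response_rate <- function(n_completed, n_eligible) {
  stopifnot(n_eligible > 0, n_completed >= 0, n_completed <= n_eligible)
  100 * n_completed / n_eligible
}

.violation <- function(scope, id, rule, detail) {
  data.frame(scope = scope, id = as.character(id), rule = rule,
             detail = detail, stringsAsFactors = FALSE)
}

#' Validate a survey data set
#'
#' Checks the roster and the ego-network reports against the schema
#' invariants: unique person ids, in-range codes, at most one spouse slot and
#' five discussion slots per ego, known ego ids, and symmetry/zero-diagonal
#' of the acquaintance relation. Violations are returned as data, not raised.
#'
#' @param roster roster data frame (see [generate_township()] schema).
#' @param surveys list with elements `alters` and `acquaint`.
#' @return a data frame with columns `scope`, `id`, `rule`, `detail`;
#'   zero rows when the data are clean.
#' @export
validate_survey <- function(roster, surveys) {
  v <- list()
  add <- function(x) v[[length(v) + 1]] <<- x

  dup <- roster$person_id[duplicated(roster$person_id)]
  for (id in unique(dup)) add(.violation("roster", id, "duplicate_person_id", "person_id appears more than once"))
  bad <- roster$person_id[!is.na(roster$age) & roster$age < 0]
  for (id in bad) add(.violation("roster", id, "negative_age", "age < 0"))
  bad <- roster$person_id[!roster$srh %in% 1:5]
  for (id in bad) add(.violation("roster", id, "srh_out_of_range", "srh not in 1..5"))
  bad <- roster$person_id[is.na(roster$district) | !nzchar(roster$district)]
  for (id in bad) add(.violation("roster", id, "empty_district", "district missing"))
  bad <- roster$person_id[!roster$marital_status %in% .marital_levels]
  for (id in bad) add(.violation("roster", id, "bad_marital_status", "unknown marital status level"))

  al <- surveys$alters
  if (nrow(al)) {
    unknown <- unique(al$ego_id[!al$ego_id %in% roster$person_id])
    for (id in unknown) add(.violation("egonet", id, "unknown_ego_id", "ego_id not on roster"))
    for (id in unique(al$ego_id)) {
      slots <- al$slot[al$ego_id == id]
      if (sum(slots == "spouse") > 1)
        add(.violation("egonet", id, "multiple_spouse_slots", "more than one spouse slot"))
      if (sum(slots != "spouse") > 5)
        add(.violation("egonet", id, "too_many_alters", "more than five discussion alters"))
      if (any(duplicated(slots)))
        add(.violation("egonet", id, "duplicate_slot", "slot repeated within ego"))
    }
    bad <- !al$slot %in% .slot_levels
    for (i in which(bad)) add(.violation("egonet", al$ego_id[i], "bad_slot", paste("unknown slot", al$slot[i])))
    bad <- !al$closeness %in% 1:4
    for (i in which(bad)) add(.violation("egonet", al$ego_id[i], "closeness_out_of_range", "closeness not in 1..4"))
    bad <- !al$contact_category %in% 1:8
    for (i in which(bad)) add(.violation("egonet", al$ego_id[i], "contact_out_of_range", "contact_category not in 1..8"))
    bad <- !al$relationship %in% .relationship_levels
    for (i in which(bad)) add(.violation("egonet", al$ego_id[i], "bad_relationship", paste("unknown relationship", al$relationship[i])))
  }

  aq <- surveys$acquaint
  if (nrow(aq)) {
    bad <- aq$slot_a == aq$slot_b
    for (i in which(bad)) add(.violation("acquaint", aq$ego_id[i], "diagonal_entry", "slot paired with itself"))
    bad <- !aq$acquainted %in% c(0, 1)
    for (i in which(bad)) add(.violation("acquaint", aq$ego_id[i], "bad_acquainted", "acquainted not 0/1"))
    ## symmetry: if both orders of a pair are present they must agree
    key_f <- paste(aq$ego_id, aq$slot_a, aq$slot_b)
    key_r <- paste(aq$ego_id, aq$slot_b, aq$slot_a)
    m <- match(key_r, key_f)
    has_rev <- !is.na(m)
    disagree <- has_rev & aq$acquainted != aq$acquainted[m]
    for (i in which(disagree))
      add(.violation("acquaint", aq$ego_id[i], "asymmetric_acquaintance",
                     paste("pair", aq$slot_a[i], aq$slot_b[i], "disagrees with reverse order")))
  }

  if (!length(v))
    return(data.frame(scope = character(), id = character(),
                      rule = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}
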
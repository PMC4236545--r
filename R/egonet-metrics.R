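#' Construct a single ego network
#'
#' Bundles one ego's member reports and the member-member acquaintance
#' relation into the object the per-ego measures operate on. The
#' acquaintance matrix is symmetric with a zero diagonal; entry 1 means the
#' two members have spoken to each other.
#'
#' @param ego_id the ego's person id.
#' @param members data frame of the ego's alter reports (one row per
#'   member, columns as in the `egonet.csv` schema).
#' @param acquaint either a symmetric 0/1 matrix with member slots as
#'   dimnames, or a long data frame (`slot_a`, `slot_b`, `acquainted`)
#'   covering the member pairs.
#' @return an object of class `ego_network`.
#' @export
ego_network <- function(ego_id, members, acquaint = NULL) {
  m <- nrow(members)
  slots <- members$slot
  A <- matrix(0, m, m, dimnames = list(slots, slots))
  if (is.matrix(acquaint)) {
    A[rownames(acquaint), colnames(acquaint)] <- acquaint
  } else if (is.data.frame(acquaint) && nrow(acquaint)) {
    keep <- acquaint$slot_a %in% slots & acquaint$slot_b %in% slots
    aq <- acquaint[keep, , drop = FALSE]
    A[cbind(aq$slot_a, aq$slot_b)] <- aq$acquainted
    A[cbind(aq$slot_b, aq$slot_a)] <- aq$acquainted
  }
  diag(A) <- 0
  if (any(A != t(A))) stop("ego_network: acquaintance matrix must be symmetric")
  structure(list(ego_id = ego_id, members = members, acquaint = A),
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat("Ego network of", x$ego_id, "with", nrow(x$members), "members\n")
  invisible(x)
}

#' Ego-network size
#'
#' Number of named members: the spouse (if listed) plus up to five
#' discussion alters, hence 0 to 6.
#'
#' @param en an [ego_network()].
#' @return integer count.
#' @export
network_size <- function(en) nrow(en$members)

#' Ego-network composition
#'
#' Proportions of members who are female, kin, and cohabiting with the ego.
#' Kin membership is taken from the codebook's `kin_relationships` set
#' (spouse included by default). Undefined (`NA`) when the network is empty
#' -- an empty network has no composition, not a composition of zero.
#'
#' @param en an [ego_network()].
#' @param codebook a [default_codebook()].
#' @return named numeric vector `c(prop_female, prop_kin, prop_cohab)`.
#' @export
composition <- function(en, codebook = default_codebook()) {
  m <- network_size(en)
  if (m == 0)
    return(c(prop_female = NA_real_, prop_kin = NA_real_, prop_cohab = NA_real_))
  c(prop_female = mean(en$members$gender == "female"),
    prop_kin = mean(en$members$relationship %in% codebook$kin_relationships),
    prop_cohab = mean(en$members$cohabiting))
}

#' Average emotional closeness to members
#'
#' Arithmetic mean of the 4-level closeness codes over all members,
#' including the spouse. Members with a missing code are excluded with a
#' warning; `NA` when no codes are available.
#'
#' @param en an [ego_network()].
#' @return mean closeness in \[1, 4\], or `NA`.
#' @export
average_closeness <- function(en) {
  if (network_size(en) == 0) return(NA_real_)
  cl <- en$members$closeness
  if (anyNA(cl)) {
    warning("average_closeness: members with missing closeness excluded")
    cl <- cl[!is.na(cl)]
  }
  if (!length(cl)) return(NA_real_)
  mean(cl)
}

#' Overall volume of contact
#'
#' Sum over members of the approximate days per year of contact implied by
#' each member's 8-level contact-frequency category. Zero for an empty
#' network.
#'
#' @param en an [ego_network()].
#' @param codebook a [default_codebook()]; supplies the category-to-days
#'   mapping.
#' @return days per year, non-negative.
#' @export
contact_volume <- function(en, codebook = default_codebook()) {
  if (network_size(en) == 0) return(0)
  cc <- en$members$contact_category
  if (any(!cc %in% seq_along(codebook$contact_days)))
    stop("contact_volume: unknown contact category")
  sum(unname(codebook$contact_days)[cc])
}

#' Ego-network density
#'
#' Proportion of all possible member pairs who know each other (have spoken
#' to each other). Undefined (`NA`) when the network has fewer than two
#' members, since there are no pairs to evaluate.
#'
#' @param en an [ego_network()].
#' @return density in \[0, 1\], or `NA`.
#' @export
ego_density <- function(en) {
  m <- network_size(en)
  if (m < 2) return(NA_real_)
  sum(en$acquaint[upper.tri(en$acquaint)]) / choose(m, 2)
}

#' Bridging potential
#'
#' Indicator that some member of the ego's network is acquainted with no
#' other member, i.e. the ego bridges that member to the rest. Undefined
#' (`NA`) for networks with fewer than two members. A fully dense network
#' (density 1) necessarily has bridging potential 0.
#'
#' @param en an [ego_network()].
#' @return 0, 1, or `NA`.
#' @export
bridging_potential <- function(en) {
  m <- network_size(en)
  if (m < 2) return(NA_real_)
  as.numeric(any(rowSums(en$acquaint) == 0))
}

#' All ego-centric measures for every respondent
#'
#' Computes size, composition, average closeness, contact volume, density
#' and bridging potential for each respondent ego. Undefined values
#' propagate as `NA` and are never coerced to zero, so grouped means are
#' taken over valid respondents only.
#'
#' @param x a `township` object, or a roster data frame.
#' @param surveys survey list (`alters`, `acquaint`); ignored when `x` is a
#'   `township`.
#' @param codebook a [default_codebook()].
#' @return data frame with one row per respondent ego: `ego_id`, `size`,
#'   `prop_female`, `prop_kin`, `prop_cohab`, `avg_closeness`,
#'   `contact_volume`, `density`, `bridging_potential`.
#' @export
ego_metrics <- function(x, surveys = NULL, codebook = default_codebook()) {
  if (inherits(x, "township")) {
    surveys <- x$surveys
    roster <- x$roster
  } else roster <- x
  egos <- roster$person_id[roster$is_respondent]
  al_split <- split(surveys$alters, surveys$alters$ego_id)
  aq_split <- split(surveys$acquaint, surveys$acquaint$ego_id)
  empty_members <- surveys$alters[0, , drop = FALSE]

  rows <- lapply(egos, function(id) {
    en <- ego_network(id, al_split[[id]] %||% empty_members, aq_split[[id]])
    comp <- composition(en, codebook)
    data.frame(ego_id = id, size = network_size(en),
               prop_female = comp[["prop_female"]],
               prop_kin = comp[["prop_kin"]],
               prop_cohab = comp[["prop_cohab"]],
               avg_closeness = average_closeness(en),
               contact_volume = contact_volume(en, codebook),
               density = ego_density(en),
               bridging_potential = bridging_potential(en),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- .empty_df(c("ego_id", "size", "prop_female", "prop_kin", "prop_cohab",
                       "avg_closeness", "contact_volume", "density", "bridging_potential"),
                     c("character", "integer", rep("numeric", 7)))
  rownames(out) <- NULL
  out
}
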
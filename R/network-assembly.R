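#' Duplicate-identification rule
#'
#' The rule that decides when two alter mentions (or a mention and a roster
#' person) denote the same individual. The default follows the 4-criterion
#' convention for 3-character names: (1) at least two of the three name
#' tokens agree position-wise, (2) same gender, (3) age difference strictly
#' less than 5 years, (4) same district.
#'
#' @param min_name_token_matches minimum number of position-wise equal name
#'   tokens (1, 2 or 3).
#' @param max_age_gap ages must differ by strictly less than this many years.
#' @param require_same_gender,require_same_district switch the gender and
#'   district criteria on or off.
#' @return an object of class `match_rule`.
#' @export
match_rule <- function(min_name_token_matches = 2L, max_age_gap = 5,
                       require_same_gender = TRUE, require_same_district = TRUE) {
  if (!min_name_token_matches %in% 1:3)
    stop("match_rule: min_name_token_matches must be 1, 2 or 3")
  if (max_age_gap <= 0) stop("match_rule: max_age_gap must be positive")
  structure(list(
    min_name_token_matches = as.integer(min_name_token_matches),
    max_age_gap = max_age_gap,
    require_same_gender = isTRUE(require_same_gender),
    require_same_district = isTRUE(require_same_district)
  ), class = "match_rule")
}

.id_fields <- c("name_token1", "name_token2", "name_token3", "gender", "age", "district")

#' Do two person reports denote the same individual?
#'
#' Applies a [match_rule()] to two records carrying name tokens, gender, age
#' and district (alter reports or roster rows). A record with a missing
#' identifier field never matches (with a warning).
#'
#' @param a,b one-row data frames or lists with fields `name_token1..3`,
#'   `gender`, `age`, `district`.
#' @param rule a [match_rule()].
#' @return `TRUE` or `FALSE`.
#' @export
reports_match <- function(a, b, rule = match_rule()) {
  get1 <- function(x, f) {
    v <- if (is.data.frame(x)) x[[f]][1] else x[[f]]
    if (is.null(v)) NA else v
  }
  va <- lapply(.id_fields, function(f) get1(a, f))
  vb <- lapply(.id_fields, function(f) get1(b, f))
  if (any(vapply(c(va, vb), function(x) is.na(x), logical(1)))) {
    warning("reports_match: missing identifier field; treating as non-match")
    return(FALSE)
  }
  names(va) <- names(vb) <- .id_fields
  tok <- sum(va$name_token1 == vb$name_token1,
             va$name_token2 == vb$name_token2,
             va$name_token3 == vb$name_token3)
  if (tok < rule$min_name_token_matches) return(FALSE)
  if (rule$require_same_gender && va$gender != vb$gender) return(FALSE)
  if (abs(va$age - vb$age) >= rule$max_age_gap) return(FALSE)
  if (rule$require_same_district && va$district != vb$district) return(FALSE)
  TRUE
}

## Vectorized rule application over a cross join of two record blocks given
## as parallel row indices ia (into A) and ib (into B).
.match_pairs <- function(A, B, ia, ib, rule) {
  tok <- (A$name_token1[ia] == B$name_token1[ib]) +
    (A$name_token2[ia] == B$name_token2[ib]) +
    (A$name_token3[ia] == B$name_token3[ib])
  ok <- tok >= rule$min_name_token_matches &
    abs(A$age[ia] - B$age[ib]) < rule$max_age_gap
  if (rule$require_same_gender) ok <- ok & A$gender[ia] == B$gender[ib]
  if (rule$require_same_district) ok <- ok & A$district[ia] == B$district[ib]
  ok[is.na(ok)] <- FALSE
  list(ok = ok, tok = tok)
}

## Union-find (transitive closure of matched pairs) with path halving.
.uf_closure <- function(n, pairs_i, pairs_j) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(pairs_i)) {
    ri <- find(pairs_i[k]); rj <- find(pairs_j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

#' Resolve duplicate alter mentions into canonical persons
#'
#' Every alter report is first matched against the respondent roster (so
#' that, e.g., a respondent's spouse who is herself a respondent collapses
#' onto her roster entry). Reports matching no roster person are then
#' matched pairwise among themselves and merged by transitive closure
#' (union-find), since pairwise matching is not transitive. Each resulting
#' cluster becomes one canonical node whose attributes come from the first
#' contributing report; attribute conflicts within a cluster are counted in
#' the resolution log.
#'
#' When a report matches several roster persons, the candidate with the most
#' matching name tokens wins, ties broken by the smallest age gap and then
#' the smallest person id.
#'
#' @param surveys survey list with an `alters` data frame.
#' @param roster roster data frame.
#' @param rule a [match_rule()].
#' @return an object of class `resolution`: list with `nodes` (canonical
#'   person table: `node_id`, identifier fields, `is_respondent`,
#'   `is_spouse_of_respondent`), `assignment` (one row per report:
#'   `ego_id`, `slot`, `node_id`) and `log` (counts, ambiguity and conflict
#'   tallies).
#' @export
resolve_duplicates <- function(surveys, roster, rule = match_rule()) {
  reports <- surveys$alters
  nrep <- nrow(reports)
  node_of_report <- character(nrep)
  n_ambiguous <- 0L

  if (nrep > 0) {
    ## stage 1: match each report against the roster, blocked on district x
    ## gender when those criteria are active (sound: a cross-block pair can
    ## never match).
    block_key <- function(df) {
      k <- rep("", nrow(df))
      if (rule$require_same_district) k <- paste(k, df$district)
      if (rule$require_same_gender) k <- paste(k, df$gender)
      k
    }
    rb <- block_key(reports); sb <- block_key(roster)
    roster_by_block <- split(seq_len(nrow(roster)), sb)
    cand_i <- integer(0); cand_j <- integer(0)
    rep_by_block <- split(seq_len(nrep), rb)
    for (b in names(rep_by_block)) {
      js <- roster_by_block[[b]]
      if (is.null(js)) next
      is <- rep_by_block[[b]]
      cand_i <- c(cand_i, rep(is, each = length(js)))
      cand_j <- c(cand_j, rep(js, times = length(is)))
    }
    if (length(cand_i)) {
      m <- .match_pairs(reports, roster, cand_i, cand_j, rule)
      hit_i <- cand_i[m$ok]; hit_j <- cand_j[m$ok]; hit_tok <- m$tok[m$ok]
      if (length(hit_i)) {
        gap <- abs(reports$age[hit_i] - roster$age[hit_j])
        ord <- order(hit_i, -hit_tok, gap, roster$person_id[hit_j])
        first <- ord[!duplicated(hit_i[ord])]
        node_of_report[hit_i[first]] <- roster$person_id[hit_j[first]]
        n_ambiguous <- sum(tabulate(hit_i, nrep) > 1)
      }
    }

    ## stage 2: cluster the remaining reports among themselves
    un <- which(node_of_report == "")
    if (length(un) > 1) {
      ub <- rb[un]
      pi <- integer(0); pj <- integer(0)
      for (idxs in split(seq_along(un), ub)) {
        if (length(idxs) < 2) next
        pr <- utils::combn(idxs, 2)
        pi <- c(pi, pr[1, ]); pj <- c(pj, pr[2, ])
      }
      if (length(pi)) {
        m <- .match_pairs(reports, reports, un[pi], un[pj], rule)
        comp <- .uf_closure(length(un), pi[m$ok], pj[m$ok])
      } else comp <- seq_along(un)
      node_of_report[un] <- sprintf("N%05d", comp)
    } else if (length(un) == 1) {
      node_of_report[un] <- "N00001"
    }
  }

  ## canonical node table: all roster persons + one node per new cluster,
  ## attributes from the first contributing report (lowest row index)
  new_ids <- unique(node_of_report[!node_of_report %in% roster$person_id & node_of_report != ""])
  n_conflicts <- 0L
  if (length(new_ids)) {
    first_rows <- match(new_ids, node_of_report)
    new_nodes <- data.frame(
      node_id = new_ids,
      reports[first_rows, .id_fields],
      is_respondent = FALSE,
      stringsAsFactors = FALSE
    )
    ## count attribute conflicts inside merged clusters (name/age spread)
    for (id in new_ids[tabulate(match(node_of_report, new_ids), length(new_ids)) > 1]) {
      rows <- which(node_of_report == id)
      nm <- paste(reports$name_token1[rows], reports$name_token2[rows], reports$name_token3[rows])
      if (length(unique(nm)) > 1 || length(unique(reports$age[rows])) > 1)
        n_conflicts <- n_conflicts + 1L
    }
  } else {
    new_nodes <- NULL
  }

  roster_nodes <- data.frame(
    node_id = roster$person_id,
    roster[, .id_fields],
    is_respondent = roster$is_respondent,
    stringsAsFactors = FALSE
  )
  nodes <- rbind(roster_nodes, new_nodes)
  rownames(nodes) <- NULL

  ## a node is a respondent's spouse if any respondent's spouse slot
  ## resolves to it
  spouse_nodes <- unique(node_of_report[reports$slot == "spouse"])
  nodes$is_spouse_of_respondent <- nodes$node_id %in% spouse_nodes

  assignment <- data.frame(
    ego_id = reports$ego_id, slot = reports$slot,
    node_id = node_of_report, stringsAsFactors = FALSE
  )

  structure(list(
    nodes = nodes, assignment = assignment,
    log = list(
      n_reports = nrep,
      n_matched_to_roster = sum(node_of_report %in% roster$person_id),
      n_new_nodes = length(new_ids),
      n_ambiguous_roster_matches = n_ambiguous,
      n_attribute_conflicts = n_conflicts
    )
  ), class = "resolution")
}

#' @export
print.resolution <- function(x, ...) {
  cat("Entity resolution\n")
  cat("  reports:", x$log$n_reports,
      "| matched to roster:", x$log$n_matched_to_roster,
      "| new nodes:", x$log$n_new_nodes, "\n")
  cat("  canonical nodes:", nrow(x$nodes), "\n")
  invisible(x)
}

#' Retention filter for the complete network
#'
#' Applies the node-exclusion conjunction: a node is dropped only when it is
#' *both* not the spouse of any survey respondent *and* living outside the
#' township. Respondents always reside inside the township and are
#' therefore always retained.
#'
#' @param nodes node table with columns `district`,
#'   `is_spouse_of_respondent` and (optionally) `is_respondent`.
#' @param township_districts character vector of district labels counted as
#'   inside the township.
#' @return the retained subset of `nodes`.
#' @export
filter_township_nodes <- function(nodes, township_districts) {
  inside <- nodes$district %in% township_districts
  is_spouse <- nodes$is_spouse_of_respondent
  if (!is.null(nodes$is_respondent)) inside <- inside | nodes$is_respondent
  keep <- inside | is_spouse
  out <- nodes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the complete directed discussion network
#'
#' Turns a resolution of the survey reports into the township's complete
#' network: one directed tie per (ego, canonical member) pair, deduplicated,
#' with nodes failing the retention filter removed together with their
#' incident ties.
#'
#' @param resolution a [resolve_duplicates()] result.
#' @param township_districts district labels counted as inside the
#'   township; defaults to the districts of the respondent nodes.
#' @return an object of class `complete_network`: list with `nodes`,
#'   `ties` (`src`, `dst`), `provenance` (report-to-node assignment of the
#'   retained ties) and `log` (node/tie counts before and after exclusion).
#' @export
build_complete_network <- function(resolution, township_districts = NULL) {
  nodes <- resolution$nodes
  if (is.null(township_districts))
    township_districts <- unique(nodes$district[nodes$is_respondent])

  ties <- data.frame(src = resolution$assignment$ego_id,
                     dst = resolution$assignment$node_id,
                     stringsAsFactors = FALSE)
  ties <- unique(ties[ties$src != ties$dst, , drop = FALSE])
  n_ties_before <- nrow(ties)

  retained <- filter_township_nodes(nodes, township_districts)
  keep <- ties$src %in% retained$node_id & ties$dst %in% retained$node_id
  ties <- ties[keep, , drop = FALSE]
  rownames(ties) <- NULL

  prov <- resolution$assignment
  prov <- prov[prov$node_id %in% retained$node_id, , drop = FALSE]
  rownames(prov) <- NULL

  structure(list(
    nodes = retained, ties = ties, provenance = prov,
    township_districts = township_districts,
    log = list(
      n_nodes_before = nrow(nodes), n_excluded = nrow(nodes) - nrow(retained),
      n_nodes = nrow(retained),
      n_ties_before = n_ties_before, n_ties = nrow(ties)
    )
  ), class = "complete_network")
}

#' @export
print.complete_network <- function(x, ...) {
  cat("Complete network:", nrow(x$nodes), "nodes,", nrow(x$ties), "directed ties\n")
  cat("  exclusion filter removed", x$log$n_excluded, "of",
      x$log$n_nodes_before, "merged persons\n")
  invisible(x)
}

#' Convert a complete network to an igraph graph
#'
#' @param net a `complete_network`.
#' @param projection `"directed"` (as surveyed) or `"undirected"` (ties
#'   collapsed regardless of direction).
#' @return an igraph graph with node attributes.
#' @export
as_igraph <- function(net, projection = c("directed", "undirected")) {
  projection <- match.arg(projection)
  g <- igraph::graph_from_data_frame(net$ties, directed = TRUE,
                                     vertices = net$nodes)
  if (projection == "undirected")
    g <- igraph::as_undirected(g, mode = "collapse")
  g
}

#' Export a complete network
#'
#' Writes `nodes.csv`, `edges.csv` and a GraphML file with node attributes.
#'
#' @param net a `complete_network`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  utils::write.csv(net$nodes, file.path(path, "nodes.csv"), row.names = FALSE)
  utils::write.csv(net$ties, file.path(path, "edges.csv"), row.names = FALSE)
  g <- as_igraph(net)
  igraph::write_graph(g, file.path(path, "network.graphml"), format = "graphml")
  invisible(path)
}

#' Score a resolution against planted ground truth
#'
#' Pairwise precision and recall of the report clustering: over all pairs of
#' reports, a true positive is a pair assigned to the same canonical node
#' that also denotes the same true person.
#'
#' @param resolution a [resolve_duplicates()] result.
#' @param identity_map ground-truth data frame (`ego_id`, `slot`,
#'   `true_id`), as produced by [generate_township()].
#' @return list with `precision`, `recall`, `f1` (all 1 when there are no
#'   true or predicted duplicate pairs).
#' @export
score_resolution <- function(resolution, identity_map) {
  key <- function(df) paste(df$ego_id, df$slot)
  m <- match(key(resolution$assignment), key(identity_map))
  if (anyNA(m)) stop("identity_map does not cover every report")
  pred <- resolution$assignment$node_id
  truth <- identity_map$true_id[m]
  pairs2 <- function(counts) sum(choose(counts, 2))
  pred_pairs <- pairs2(table(pred))
  true_pairs <- pairs2(table(truth))
  tp <- pairs2(table(paste(pred, truth, sep = "\r")))
  precision <- if (pred_pairs == 0) 1 else tp / pred_pairs
  recall <- if (true_pairs == 0) 1 else tp / true_pairs
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
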
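#' Weak or strong components of the complete network
#'
#' Weak components are the connected components of the undirected
#' projection (reachability regardless of tie direction); strong components
#' require mutual reachability along tie directions.
#'
#' @param net a `complete_network`.
#' @param mode `"weak"` (default) or `"strong"`.
#' @return an object of class `component_partition`: list with
#'   `assignment` (named integer vector, node id to component id), `sizes`
#'   (component id to node count) and `mode`.
#' @export
find_components <- function(net, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  g <- as_igraph(net, "directed")
  comp <- igraph::components(g, mode = mode)
  assignment <- stats::setNames(as.integer(comp$membership), igraph::V(g)$name)
  structure(list(assignment = assignment,
                 sizes = stats::setNames(as.integer(comp$csize), seq_along(comp$csize)),
                 mode = mode),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  cat(length(x$sizes), x$mode, "components over", length(x$assignment), "nodes\n")
  cat("  largest sizes:", paste(utils::head(sort(x$sizes, decreasing = TRUE), 5),
                                collapse = ", "), "\n")
  invisible(x)
}

.component_classes <- c("largest", "second_largest", "size_3_7", "dyadic", "isolate")

#' Five-class component typology
#'
#' Ranks the components by size (ties broken by the smallest member id) and
#' labels them: the largest component, the second largest, components of 3
#' to 7 nodes, dyads, and isolates. Any remaining component of 8 or more
#' nodes is folded into the 3-7 class with a warning, and a warning is also
#' emitted when the ranking is degenerate (the top-ranked component itself
#' falls inside the small-size bins).
#'
#' @param partition a [find_components()] result (weak mode intended).
#' @return named character vector mapping node id to class label.
#' @export
classify_components <- function(partition) {
  sizes <- partition$sizes
  comp_ids <- names(sizes)
  min_member <- vapply(comp_ids, function(cid) {
    min(names(partition$assignment)[partition$assignment == as.integer(cid)])
  }, character(1))
  ord <- comp_ids[order(-sizes, min_member)]

  cls <- stats::setNames(rep(NA_character_, length(comp_ids)), comp_ids)
  if (length(ord) >= 1) cls[ord[1]] <- "largest"
  if (length(ord) >= 2) cls[ord[2]] <- "second_largest"
  rest <- ord[-seq_len(min(2, length(ord)))]
  if (length(rest)) {
    s <- sizes[rest]
    cls[rest[s == 1]] <- "isolate"
    cls[rest[s == 2]] <- "dyadic"
    cls[rest[s >= 3]] <- "size_3_7"
    if (any(s >= 8))
      warning("classify_components: component(s) of size >= 8 outside the top two; folded into size_3_7")
  }
  if (length(ord) && sizes[ord[1]] <= 7)
    warning("classify_components: degenerate ranking (largest component has <= 7 nodes)")

  stats::setNames(unname(cls[as.character(partition$assignment)]),
                  names(partition$assignment))
}

#' Per-class component summaries
#'
#' Summarizes each component class: node and respondent counts, mean age
#' and proportion female over all class nodes, and -- over respondents only
#' -- mean chronic-disease count, mean years lived in the village, mean
#' ego-network size, proportion married and mean self-rated health, plus
#' the share of class nodes per district. A one-way ANOVA across classes is
#' reported for each numeric column.
#'
#' @param partition weak [find_components()] partition.
#' @param classes node-to-class labels from [classify_components()].
#' @param nodes node table of the complete network (for age, gender,
#'   district of every node).
#' @param roster roster data frame (respondent attributes).
#' @param metrics ego metrics from [ego_metrics()].
#' @return list with `summary` (one row per class) and `anova` (column,
#'   F, p per summarized variable).
#' @export
summarize_classes <- function(partition, classes, nodes, roster, metrics) {
  stopifnot(identical(names(partition$assignment), names(classes)))
  node_class <- classes[nodes$node_id]
  districts <- sort(unique(nodes$district))

  roster_idx <- match(nodes$node_id, roster$person_id)
  metric_idx <- match(nodes$node_id, metrics$ego_id)
  is_resp <- !is.na(roster_idx) & roster$is_respondent[roster_idx]

  per_node <- data.frame(
    node_id = nodes$node_id, class = node_class,
    age = nodes$age, female = as.numeric(nodes$gender == "female"),
    district = nodes$district,
    is_respondent = is_resp,
    n_chronic = ifelse(is_resp, roster$n_chronic[roster_idx], NA),
    years_in_village = ifelse(is_resp, roster$years_in_village[roster_idx], NA),
    network_size = ifelse(is_resp, metrics$size[metric_idx], NA),
    married = ifelse(is_resp,
                     as.numeric(roster$marital_status[roster_idx] == "living_with_spouse"), NA),
    srh = ifelse(is_resp, roster$srh[roster_idx], NA),
    stringsAsFactors = FALSE
  )

  present <- .component_classes[.component_classes %in% unique(node_class)]
  rows <- lapply(present, function(cl) {
    sub <- per_node[per_node$class == cl, , drop = FALSE]
    shares <- vapply(districts, function(d) mean(sub$district == d), numeric(1))
    names(shares) <- paste0("share_", districts)
    cbind(data.frame(
      class = cl,
      n_nodes = nrow(sub),
      n_respondents = sum(sub$is_respondent),
      mean_age = mean(sub$age, na.rm = TRUE),
      prop_female = mean(sub$female, na.rm = TRUE),
      mean_chronic = if (any(sub$is_respondent)) mean(sub$n_chronic, na.rm = TRUE) else NA_real_,
      mean_years_in_village = if (any(sub$is_respondent)) mean(sub$years_in_village, na.rm = TRUE) else NA_real_,
      mean_network_size = if (any(sub$is_respondent)) mean(sub$network_size, na.rm = TRUE) else NA_real_,
      prop_married = if (any(sub$is_respondent)) mean(sub$married, na.rm = TRUE) else NA_real_,
      mean_srh = if (any(sub$is_respondent)) mean(sub$srh, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    ), as.data.frame(as.list(shares)))
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  num_cols <- list(
    mean_age = per_node$age, prop_female = per_node$female,
    mean_chronic = per_node$n_chronic,
    mean_years_in_village = per_node$years_in_village,
    mean_network_size = per_node$network_size,
    prop_married = per_node$married, mean_srh = per_node$srh
  )
  anova_rows <- lapply(names(num_cols), function(nm) {
    res <- anova_oneway(num_cols[[nm]], per_node$class)
    data.frame(column = nm, F = res$statistic, p = res$p.value,
               stringsAsFactors = FALSE)
  })
  list(summary = summary, anova = do.call(rbind, anova_rows))
}
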
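#' Complete-network centralities per node
#'
#' In-degree and out-degree (counts of inward and outward discussion ties),
#' normalized closeness and normalized betweenness for every node of the
#' complete network.
#'
#' By default closeness and betweenness are computed on the undirected
#' projection of the discussion network ("all-closeness"), because the
#' surveyed network is far from strongly connected and strict directed
#' reachability would zero out most nodes; a directed variant is available.
#'
#' Closeness is the reciprocal of the summed shortest-path lengths to other
#' nodes, normalized so that a node adjacent to everyone scores 1. Because
#' the network is disconnected, the default `"wf"` variant applies the
#' Wasserman-Faust component correction: with `R` the set of nodes
#' reachable from the focal node (excluding itself) in a network of `N`
#' nodes, the score is `|R|^2 / ((N - 1) * sum of distances to R)`;
#' isolates score 0. `"component"` normalizes within the node's component
#' only (`|R| / sum d`), and `"harmonic"` is the mean of inverse distances,
#' `sum(1/d) / (N - 1)`.
#'
#' Betweenness is shortest-path betweenness with fractional credit over
#' equally short paths, divided by the number of node pairs excluding the
#' focal node: `(N-1)(N-2)/2` unordered pairs on the undirected projection,
#' `(N-1)(N-2)` ordered pairs in directed mode.
#'
#' @param net a `complete_network`.
#' @param projection `"undirected"` (default) or `"directed"`.
#' @param closeness_variant `"wf"` (Wasserman-Faust, default),
#'   `"component"` or `"harmonic"`.
#' @return data frame: `node_id`, `in_degree`, `out_degree`,
#'   `closeness_norm`, `betweenness_norm`.
#' @export
node_centrality <- function(net,
                            projection = c("undirected", "directed"),
                            closeness_variant = c("wf", "component", "harmonic")) {
  projection <- match.arg(projection)
  closeness_variant <- match.arg(closeness_variant)
  gd <- as_igraph(net, "directed")
  n <- igraph::vcount(gd)
  ids <- igraph::V(gd)$name
  indeg <- igraph::degree(gd, mode = "in")
  outdeg <- igraph::degree(gd, mode = "out")

  g <- if (projection == "undirected") igraph::as_undirected(gd, mode = "collapse") else gd
  dist_mode <- if (projection == "undirected") "all" else "out"
  D <- igraph::distances(g, mode = dist_mode)

  clo <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d) & d > 0
    r <- sum(reach)
    if (n < 2 || r == 0) return(0)
    switch(closeness_variant,
           wf = r^2 / ((n - 1) * sum(d[reach])),
           component = r / sum(d[reach]),
           harmonic = sum(1 / d[reach]) / (n - 1))
  }, numeric(1))

  if (n >= 3) {
    btw_raw <- igraph::betweenness(g, directed = (projection == "directed"))
    denom <- if (projection == "undirected") (n - 1) * (n - 2) / 2 else (n - 1) * (n - 2)
    btw <- unname(btw_raw) / denom
  } else {
    btw <- rep(NA_real_, n)
  }

  data.frame(node_id = ids, in_degree = unname(indeg), out_degree = unname(outdeg),
             closeness_norm = unname(clo), betweenness_norm = btw,
             stringsAsFactors = FALSE)
}

.gf_role <- function(gj, gi, gk) {
  ifelse(gj == gi & gi == gk, "coordinator",
  ifelse(gj != gi & gi == gk, "gatekeeper",
  ifelse(gj == gi & gi != gk, "representative",
  ifelse(gj == gk & gj != gi, "itinerant", "liaison"))))
}

#' Gould-Fernandez brokerage roles per node
#'
#' Counts, for every node `i`, the ordered two-paths `j -> i -> k`
#' (`j != k`) and classifies each by the district memberships of the three
#' nodes: *coordinator* (all three in the same district), *gatekeeper*
#' (`j` outside `i`'s district, `k` inside), *representative* (`j` inside,
#' `k` outside), *itinerant* (`j` and `k` share a district that is not
#' `i`'s), and *liaison* (all three districts distinct).
#'
#' In the default `"exclusive"` mode a two-path only counts when the
#' endpoints are disconnected otherwise, i.e. when there is no direct tie
#' `j -> k` or `k -> j`; `"classic"` counts every two-path as in the
#' original Gould-Fernandez index.
#'
#' @param net a `complete_network`.
#' @param groups named character vector mapping node id to group (district);
#'   defaults to the nodes' `district` attribute.
#' @param mode `"exclusive"` (endpoints disconnected otherwise, default)
#'   or `"classic"`.
#' @return data frame keyed by `node_id` with columns `coordinator`,
#'   `gatekeeper`, `representative`, `itinerant`, `liaison` and `total`.
#' @export
brokerage <- function(net, groups = NULL, mode = c("exclusive", "classic")) {
  mode <- match.arg(mode)
  ids <- net$nodes$node_id
  if (is.null(groups)) {
    groups <- stats::setNames(net$nodes$district, ids)
  }
  missing_g <- ids[!(ids %in% names(groups)) | is.na(groups[ids])]
  if (length(missing_g))
    stop("brokerage: missing district/group for node ", missing_g[1])
  groups <- groups[ids]

  roles <- c("coordinator", "gatekeeper", "representative", "itinerant", "liaison")
  counts <- matrix(0L, nrow = length(ids), ncol = length(roles),
                   dimnames = list(ids, roles))
  if (nrow(net$ties)) {
    out_nbr <- split(net$ties$dst, net$ties$src)
    in_nbr <- split(net$ties$src, net$ties$dst)
    edge_key <- paste(net$ties$src, net$ties$dst, sep = "\r")
    for (i in ids) {
      js <- in_nbr[[i]]; ks <- out_nbr[[i]]
      if (is.null(js) || is.null(ks)) next
      pairs <- expand.grid(j = js, k = ks, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$j != pairs$k & pairs$j != i & pairs$k != i, , drop = FALSE]
      if (!nrow(pairs)) next
      if (mode == "exclusive") {
        direct <- paste(pairs$j, pairs$k, sep = "\r") %in% edge_key |
          paste(pairs$k, pairs$j, sep = "\r") %in% edge_key
        pairs <- pairs[!direct, , drop = FALSE]
        if (!nrow(pairs)) next
      }
      role <- .gf_role(groups[pairs$j], groups[i], groups[pairs$k])
      tab <- table(factor(role, levels = roles))
      counts[i, ] <- counts[i, ] + as.integer(tab)
    }
  }
  out <- data.frame(node_id = ids, counts, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$total <- rowSums(counts)
  out
}
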
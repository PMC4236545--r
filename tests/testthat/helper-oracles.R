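# Independent reference routines used to cross-check the package's network
# computations. They work from raw adjacency matrices with their own BFS /
# path-counting / triad enumeration, sharing no code with the implementation.

# BFS distances and shortest-path counts from every source.
# A is a 0/1 adjacency matrix; row -> column interpretation.
oracle_dist_sigma <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- rep(0, n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s; lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      reach <- as.vector(sg[frontier] %*% A[frontier, , drop = FALSE])
      newly <- which(reach > 0 & !is.finite(d))
      sg[newly] <- reach[newly]
      d[newly] <- lev
      frontier <- newly
    }
    D[s, ] <- d; S[s, ] <- sg
  }
  list(D = D, S = S)
}

# Raw betweenness (fractional credit, unordered pairs) from pair-wise
# dependency sums; A must be symmetric.
oracle_betweenness <- function(A) {
  r <- oracle_dist_sigma(A)
  D <- r$D; S <- r$S
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    on_path <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D) & S > 0
    contrib <- outer(S[, v], S[v, ]) / S
    contrib[!on_path] <- 0
    contrib[v, ] <- 0; contrib[, v] <- 0; diag(contrib) <- 0
    sum(contrib) / 2
  }, numeric(1))
}

# Normalized closeness with the reachable-set (Wasserman-Faust) correction,
# from oracle BFS distances on a symmetric adjacency matrix.
oracle_closeness_wf <- function(A) {
  D <- oracle_dist_sigma(A)$D
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (sum(reach) == 0) return(0)
    sum(reach)^2 / ((n - 1) * sum(d[reach]))
  }, numeric(1))
}

# Component membership labels (arbitrary ids, compare with canon_partition).
oracle_weak_membership <- function(A) {
  As <- (A + t(A)) > 0
  D <- oracle_dist_sigma(As * 1)$D
  apply(D, 1, function(r) min(which(is.finite(r))))
}

oracle_strong_membership <- function(A) {
  D <- oracle_dist_sigma(A)$D
  mutual <- is.finite(D) & is.finite(t(D))
  apply(mutual, 1, function(r) min(which(r)))
}

# Canonical form of a partition: components as sorted index sets, ordered by
# their smallest element. Two labelings are the same partition iff equal.
canon_partition <- function(membership) {
  comps <- split(seq_along(membership), membership)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, min, numeric(1)))]
  unname(comps)
}

# Exhaustive ordered-two-path brokerage counts by triad enumeration over a
# tie list (data frame src, dst) with a named group vector.
oracle_brokerage <- function(ties, groups, mode = "exclusive") {
  roles <- c("coordinator", "gatekeeper", "representative", "itinerant", "liaison")
  out <- matrix(0L, length(groups), length(roles),
                dimnames = list(names(groups), roles))
  if (!nrow(ties)) return(out)
  two <- merge(ties, ties, by.x = "dst", by.y = "src")
  names(two) <- c("i", "j", "k")
  two <- two[two$j != two$k & two$j != two$i & two$k != two$i, , drop = FALSE]
  if (mode == "exclusive" && nrow(two)) {
    ek <- paste(ties$src, ties$dst)
    direct <- paste(two$j, two$k) %in% ek | paste(two$k, two$j) %in% ek
    two <- two[!direct, , drop = FALSE]
  }
  for (r in seq_len(nrow(two))) {
    gj <- groups[[two$j[r]]]; gi <- groups[[two$i[r]]]; gk <- groups[[two$k[r]]]
    role <- if (gj == gi && gi == gk) "coordinator"
      else if (gj != gi && gi == gk) "gatekeeper"
      else if (gj == gi && gi != gk) "representative"
      else if (gj == gk) "itinerant" else "liaison"
    out[two$i[r], role] <- out[two$i[r], role] + 1L
  }
  out
}

# Build a complete_network object directly from an integer edge list, for
# tests that need full control over the topology.
make_net <- function(edges, n = NULL, districts = NULL) {
  edges <- as.matrix(edges)
  if (is.null(n)) n <- if (length(edges)) max(edges) else 0
  ids <- sprintf("V%03d", seq_len(n))
  if (is.null(districts)) districts <- rep("R01", n)
  nodes <- data.frame(
    node_id = ids, name_token1 = "a", name_token2 = "b", name_token3 = "c",
    gender = "female", age = 70L, district = districts,
    is_respondent = TRUE, is_spouse_of_respondent = FALSE,
    stringsAsFactors = FALSE
  )
  ties <- if (length(edges)) {
    unique(data.frame(src = ids[edges[, 1]], dst = ids[edges[, 2]],
                      stringsAsFactors = FALSE))
  } else data.frame(src = character(), dst = character(), stringsAsFactors = FALSE)
  ties <- ties[ties$src != ties$dst, , drop = FALSE]
  structure(list(nodes = nodes, ties = ties, provenance = NULL,
                 township_districts = unique(districts),
                 log = list(n_nodes_before = n, n_excluded = 0, n_nodes = n,
                            n_ties_before = nrow(ties), n_ties = nrow(ties))),
            class = "complete_network")
}

# Random directed graph: adjacency matrix + matching complete_network.
rand_net <- function(n, p, n_groups = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  idx <- which(A == 1, arr.ind = TRUE)
  districts <- sample(sprintf("G%02d", seq_len(n_groups)), n, replace = TRUE)
  list(A = A, net = make_net(idx, n = n, districts = districts),
       districts = districts)
}

# Hand-built ego network from compact member specs.
make_ego <- function(..., acq = NULL) {
  specs <- list(...)
  members <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(
      ego_id = "E1", slot = s$slot %||% paste0("d", i),
      name_token1 = "x", name_token2 = "y", name_token3 = "z",
      gender = s$gender %||% "female", age = s$age %||% 70L,
      district = "R01", relationship = s$rel %||% "friend",
      cohabiting = s$cohab %||% FALSE,
      closeness = s$closeness %||% 3L,
      contact_category = s$contact %||% 1L,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(members))
    members <- generate_township(township_config(n_population = 0))$surveys$alters
  if (is.null(acq) && nrow(members) >= 2) {
    acq <- matrix(1, nrow(members), nrow(members),
                  dimnames = list(members$slot, members$slot))
    diag(acq) <- 0
  }
  ego_network("E1", members, acq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
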
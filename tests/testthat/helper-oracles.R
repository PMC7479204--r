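# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (set enumeration, exhaustive search) so they share
# no code with the implementation they check.

# random incidence tibble over herb/ingredient universes
random_incidence <- function(n_rows, n_herbs = 10, n_ings = 10) {
  tibble::tibble(
    herb_id = sprintf("H%02d", sample.int(n_herbs, n_rows, replace = TRUE)),
    ingredient_id = sprintf("I%02d", sample.int(n_ings, n_rows, replace = TRUE))
  )
}

# brute-force projection: pairwise intersection of opposite-side neighbor sets
brute_project <- function(incidence, side = "herb") {
  key <- if (side == "herb") "herb_id" else "ingredient_id"
  other <- if (side == "herb") "ingredient_id" else "herb_id"
  incidence <- unique(incidence[, c(key, other)])
  nbrs <- split(incidence[[other]], incidence[[key]])
  ids <- sort(names(nbrs))
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      shared <- length(intersect(nbrs[[ids[i]]], nbrs[[ids[j]]]))
      if (shared > 0) {
        out[[length(out) + 1L]] <- tibble::tibble(
          from = ids[j], to = ids[i], weight = as.numeric(shared)
        )
      }
    }
  }
  edges <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(from = character(), to = character(), weight = numeric())
  list(nodes = ids, edges = dplyr::arrange(edges, from, to))
}

# canonical sorted edge tibble of a weighted igraph, for exact comparison
graph_edge_table <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  if (!"weight" %in% names(el)) el$weight <- rep(1, nrow(el))
  el$from2 <- pmin(el$from, el$to)
  el$to2 <- pmax(el$from, el$to)
  out <- tibble::tibble(from = el$from2, to = el$to2, weight = el$weight)
  dplyr::arrange(out, from, to)
}

# direct evaluation of Q = sum_c [w_c/W - (s_c/2W)^2] from first principles
direct_modularity <- function(g, memb, weighted = TRUE) {
  el <- igraph::as_data_frame(g, what = "edges")
  w <- if (weighted && "weight" %in% names(el)) el$weight else rep(1, nrow(el))
  W <- sum(w)
  comms <- unique(memb)
  q <- 0
  for (cc in comms) {
    in_c <- names(memb)[memb == cc]
    intra <- sum(w[el$from %in% in_c & el$to %in% in_c])
    strength <- sum(w[el$from %in% in_c]) + sum(w[el$to %in% in_c])
    q <- q + intra / W - (strength / (2 * W))^2
  }
  q
}

# all set partitions of n elements as restricted-growth strings
all_set_partitions <- function(n) {
  parts <- list(integer(0))
  for (i in seq_len(n)) {
    parts <- unlist(lapply(parts, function(p) {
      top <- if (length(p)) max(p) else 0L
      lapply(seq_len(top + 1L), function(b) c(p, b))
    }), recursive = FALSE)
  }
  parts
}

# exhaustive maximum modularity over all partitions (n <= 8)
exhaustive_best_partition <- function(g, weighted = TRUE) {
  nodes <- igraph::V(g)$name
  best_q <- -Inf
  best <- NULL
  for (p in all_set_partitions(length(nodes))) {
    memb <- stats::setNames(p, nodes)
    q <- direct_modularity(g, memb, weighted = weighted)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  list(q = best_q, membership = best)
}

# adjusted Rand index from the contingency-table definition
brute_ari <- function(a, b) {
  common <- intersect(names(a), names(b))
  tab <- table(a[common], b[common])
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# planted herb-side partition of a synthetic dataset as a (node, community) tibble
planted_partition <- function(ds, side = "herb") {
  gt <- ds$ground_truth[ds$ground_truth$side == side, ]
  tibble::tibble(node = gt$entity_id, community = gt$block)
}
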
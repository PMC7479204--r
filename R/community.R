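# Modularity scoring and greedy agglomerative community detection.
#
# Q = sum_c [ w_c / W - (s_c / 2W)^2 ] with W the total edge weight, w_c the
# intra-community weight and s_c the community strength (sum of weighted
# degrees). Unweighted graphs are treated as weight-1 edges.

# membership input: named vector, or data frame (node, community)
as_membership <- function(p, g) {
  if (inherits(p, "tcmnet_partition")) p <- p$assignment
  if (is.data.frame(p)) {
    stopifnot(all(c("node", "community") %in% names(p)))
    p <- stats::setNames(p$community, p$node)
  }
  nodes <- igraph::V(g)$name
  missing <- setdiff(nodes, names(p))
  if (length(missing)) {
    stop_tcmnet(sprintf("partition does not cover node(s): %s",
                        paste(utils::head(missing, 5), collapse = ", ")),
                "tcmnet_coverage_error")
  }
  p[nodes]
}

edge_weights_of <- function(g, weighted) {
  if (weighted && "weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight
  } else {
    rep(1, igraph::gsize(g))
  }
}

#' Newman-Girvan modularity of a partition
#'
#' @param g an undirected graph (typically a projection from [project()]).
#' @param partition a named `node -> community` vector, a data frame with
#'   columns `node` and `community`, or a [fast_greedy()] result.
#' @param weighted use edge weights when present (default `TRUE`).
#' @return the modularity Q, a number in \[-0.5, 1\].
#' @examples
#' tri2 <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
#' score_modularity(tri2, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)) # 0.5
#' @export
score_modularity <- function(g, partition, weighted = TRUE) {
  memb <- as_membership(partition, g)
  w <- edge_weights_of(g, weighted)
  W <- sum(w)
  if (W <= 0) {
    stop_tcmnet("graph has no edges: modularity undefined", "tcmnet_no_edges")
  }
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  c1 <- memb[ends[, 1]]
  c2 <- memb[ends[, 2]]
  intra <- tapply(w[c1 == c2], factor(c1[c1 == c2], levels = unique(memb)),
                  sum, default = 0)
  strength <- tapply(c(w, w), factor(c(c1, c2), levels = unique(memb)),
                     sum, default = 0)
  sum(intra / W - (strength / (2 * W))^2)
}

#' Fast greedy (CNM) modularity optimization
#'
#' Agglomerative community detection: starting from singleton communities,
#' repeatedly merge the connected pair of communities with the largest
#' modularity gain while any gain is positive. Ties on the gain are broken
#' by the lexicographically smallest pair of community labels, a community
#' being labelled by its smallest member id, so the algorithm is
#' deterministic without a seed.
#'
#' @inheritParams score_modularity
#' @return an object of class `tcmnet_partition`: list with `assignment`
#'   (tibble `node`, `community` with labels contiguous from 0),
#'   `membership` (named integer vector), `modularity`, `algorithm`,
#'   `weighted`.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c, c - a, a - d, d - e, e - f, f - d)
#' fast_greedy(g)$modularity
#' @export
fast_greedy <- function(g, weighted = TRUE) {
  n <- igraph::vcount(g)
  if (igraph::gsize(g) == 0L) {
    stop_tcmnet("graph has no edges: cannot cluster", "tcmnet_no_edges")
  }
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  w <- edge_weights_of(g, weighted)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)

  # dense inter-community weight matrix; communities start as singletons
  E <- matrix(0, n, n)
  for (e in seq_along(w)) {
    i <- ends[e, 1]; j <- ends[e, 2]
    if (i != j) {
      E[i, j] <- E[i, j] + w[e]
      E[j, i] <- E[j, i] + w[e]
    }
  }
  W <- sum(w)
  s <- rowSums(E)
  active <- rep(TRUE, n)
  label <- nodes                     # community label = smallest member id
  members <- as.list(seq_len(n))

  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    sub <- E[act, act, drop = FALSE]
    dq <- sub / W - outer(s[act], s[act]) / (2 * W^2)
    dq[sub == 0] <- -Inf             # only connected pairs may merge
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    best <- max(dq)
    if (best <= 1e-12) break
    cand <- which(dq >= best - 1e-15, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      lab_lo <- pmin(label[act[cand[, 1]]], label[act[cand[, 2]]])
      lab_hi <- pmax(label[act[cand[, 1]]], label[act[cand[, 2]]])
      cand <- cand[order(lab_lo, lab_hi), , drop = FALSE]
    }
    i <- act[cand[1, 1]]; j <- act[cand[1, 2]]
    # absorb j into i
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[i, i] <- 0
    E[j, ] <- 0; E[, j] <- 0
    s[i] <- s[i] + s[j]
    members[[i]] <- c(members[[i]], members[[j]])
    label[i] <- min(label[i], label[j])
    active[j] <- FALSE
  }

  memb <- integer(n)
  act <- which(active)
  # contiguous labels 0..k-1, ordered by community label
  for (k in seq_along(act[order(label[act])])) {
    memb[members[[act[order(label[act])][k]]]] <- k - 1L
  }
  assignment <- tibble::tibble(node = nodes, community = memb)
  partition <- structure(
    list(assignment = assignment,
         membership = stats::setNames(memb, nodes),
         modularity = NA_real_,
         algorithm = "fast_greedy",
         weighted = weighted),
    class = "tcmnet_partition"
  )
  partition$modularity <- score_modularity(g, partition, weighted = weighted)
  partition
}

#' @export
print.tcmnet_partition <- function(x, ...) {
  cat(sprintf("<tcmnet_partition> %s: %d nodes in %d communities, Q = %.4f\n",
              x$algorithm, nrow(x$assignment),
              dplyr::n_distinct(x$assignment$community), x$modularity))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fast_greedy
#' @param x a `tcmnet_partition`.
#' @param ... unused.
#' @method tidy tcmnet_partition
#' @export
tidy.tcmnet_partition <- function(x, ...) x$assignment

#' @rdname fast_greedy
#' @method glance tcmnet_partition
#' @export
glance.tcmnet_partition <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_nodes = nrow(x$assignment),
    n_communities = dplyr::n_distinct(x$assignment$community),
    modularity = x$modularity,
    weighted = x$weighted
  )
}

#' Read / write partitions as CSV
#'
#' Two columns `node,community` with a header row — the exchange format for
#' externally produced partitions (e.g. infomap or walktrap runs from other
#' tools), which [compare_partitions()] can rescore.
#'
#' @param path file path.
#' @return `read_partition()`: a tibble (`node`, `community`).
#' @export
read_partition <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "integer"))
  names(df)[1:2] <- c("node", "community")
  tibble::as_tibble(df)
}

#' @rdname read_partition
#' @param partition a `tcmnet_partition` or a (`node`, `community`) data frame.
#' @export
write_partition <- function(partition, path) {
  df <- if (inherits(partition, "tcmnet_partition")) partition$assignment else partition
  utils::write.csv(df[, c("node", "community")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- partitioner registry ---------------------------------------------------

partitioner_registry <- new.env(parent = emptyenv())

#' Register a community-detection algorithm
#'
#' External partitioners (infomap, walktrap, ...) are not reimplemented;
#' they plug in as functions `graph -> partition` (anything
#' [score_modularity()] accepts), and [compare_partitions()] rescores every
#' partition with the same modularity so the comparison is like for like.
#'
#' @param name algorithm name.
#' @param fun function taking an `igraph` and returning a partition.
#' @export
register_partitioner <- function(name, fun) {
  stopifnot(is.character(name), is.function(fun))
  assign(name, fun, envir = partitioner_registry)
  invisible(name)
}

get_partitioner <- function(name) {
  if (identical(name, "fast_greedy")) return(fast_greedy)
  if (!exists(name, envir = partitioner_registry, inherits = FALSE)) {
    stop_tcmnet(sprintf("unknown algorithm '%s'; register it with register_partitioner()",
                        name),
                "tcmnet_registry_error")
  }
  get(name, envir = partitioner_registry, inherits = FALSE)
}

#' Compare community-detection algorithms by mean modularity
#'
#' Runs (or loads) each algorithm's partition on each graph, rescores every
#' partition with [score_modularity()], and ranks algorithms by their mean
#' modularity across graphs — the winner is the argmax of the mean.
#'
#' @param graphs a named list of graphs (e.g. the NSN and ISN projections).
#' @param algos character vector of algorithm names: `"fast_greedy"` is
#'   built in, others must be registered via [register_partitioner()].
#' @param weighted passed to the scorer and to `fast_greedy`.
#' @return an object of class `tcmnet_comparison`: list with `scores`
#'   (tibble `algorithm`, `graph`, `modularity`), `means` (tibble
#'   `algorithm`, `mean_modularity`), and `winner`.
#' @export
compare_partitions <- function(graphs, algos = "fast_greedy", weighted = TRUE) {
  if (is.null(names(graphs))) names(graphs) <- paste0("graph", seq_along(graphs))
  scores <- purrr::map_dfr(algos, function(a) {
    fun <- get_partitioner(a)
    purrr::imap_dfr(graphs, function(g, gname) {
      p <- fun(g)
      tibble::tibble(algorithm = a, graph = gname,
                     modularity = score_modularity(g, p, weighted = weighted))
    })
  })
  means <- scores |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(mean_modularity = mean(.data$modularity), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_modularity))
  structure(list(scores = scores, means = means,
                 winner = means$algorithm[1]),
            class = "tcmnet_comparison")
}

#' @export
print.tcmnet_comparison <- function(x, ...) {
  cat(sprintf("<tcmnet_comparison> winner: %s\n", x$winner))
  print(x$means)
  invisible(x)
}

#' @rdname compare_partitions
#' @param x a `tcmnet_comparison`.
#' @param ... unused.
#' @method tidy tcmnet_comparison
#' @export
tidy.tcmnet_comparison <- function(x, ...) x$scores

#' @rdname compare_partitions
#' @method glance tcmnet_comparison
#' @export
glance.tcmnet_comparison <- function(x, ...) {
  dplyr::mutate(x$means, winner = .data$algorithm == x$winner)
}

#' Reduce a graph to its community-level network
#'
#' Each community becomes one node; an edge between two communities carries
#' the summed weight of the original edges between them, and each node
#' records its intra-community weight and member count. The summed reduced
#' edge weight plus the total intra-community weight equals the original
#' total edge weight.
#'
#' @inheritParams score_modularity
#' @return an object of class `tcmnet_reduced`: list of tibbles `nodes`
#'   (`community`, `n_members`, `intra_weight`) and `edges`
#'   (`from`, `to`, `weight`).
#' @export
reduce_graph <- function(g, partition, weighted = TRUE) {
  memb <- as_membership(partition, g)
  w <- edge_weights_of(g, weighted)
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  c1 <- memb[ends[, 1]]
  c2 <- memb[ends[, 2]]
  lo <- pmin(c1, c2)
  hi <- pmax(c1, c2)
  edges_df <- tibble::tibble(from = lo, to = hi, weight = w) |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  intra <- edges_df |> dplyr::filter(.data$from == .data$to)
  nodes <- tibble::tibble(community = memb) |>
    dplyr::count(.data$community, name = "n_members") |>
    dplyr::left_join(dplyr::select(intra, community = "from",
                                   intra_weight = "weight"),
                     by = "community") |>
    dplyr::mutate(intra_weight = dplyr::coalesce(.data$intra_weight, 0)) |>
    dplyr::arrange(.data$community)
  structure(
    list(nodes = nodes,
         edges = dplyr::filter(edges_df, .data$from != .data$to)),
    class = "tcmnet_reduced"
  )
}

#' @export
print.tcmnet_reduced <- function(x, ...) {
  cat(sprintf("<tcmnet_reduced> %d communities, %d inter-community edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of (a superset of) the
#' same entities; used to compare detected communities with planted blocks.
#' Entities present in only one labeling are ignored.
#'
#' @param a,b named label vectors or (`node`/`entity_id`, `community`/`block`)
#'   data frames.
#' @return the adjusted Rand index, 1 for identical partitions.
#' @export
adjusted_rand <- function(a, b) {
  a <- as_label_vector(a)
  b <- as_label_vector(b)
  common <- intersect(names(a), names(b))
  if (length(common) < 2L) {
    stop_tcmnet("fewer than 2 shared entities between partitions",
                "tcmnet_input_error")
  }
  mclust::adjustedRandIndex(a[common], b[common])
}

as_label_vector <- function(x) {
  if (is.data.frame(x)) {
    idcol <- intersect(c("node", "entity_id"), names(x))[1]
    labcol <- intersect(c("community", "block"), names(x))[1]
    stopifnot(!is.na(idcol), !is.na(labcol))
    return(stats::setNames(x[[labcol]], x[[idcol]]))
  }
  if (inherits(x, "tcmnet_partition")) return(x$membership)
  stopifnot(!is.null(names(x)))
  x
}
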
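# Bipartite herb-ingredient graph model.
#
# Side membership is tracked structurally: vertex names carry an internal
# side tag ("herb:" / "ing:") so the same identifier string may legally occur
# on both sides; user-facing ids live in the `id` vertex attribute.

herb_tag <- function(ids) paste0("herb:", ids)
ing_tag <- function(ids) paste0("ing:", ids)

#' Load an incidence table from a delimited file
#'
#' Expects two columns (herb_id, ingredient_id). Blank lines and lines
#' starting with `#` are skipped. A header row whose first field is
#' `herb_id` is recognized and dropped. Rows are deduplicated; the number of
#' collapsed duplicates is reported.
#'
#' @param path file path.
#' @param delim field delimiter, default tab.
#' @return a tibble with character columns `herb_id` and `ingredient_id`.
#' @export
load_incidence <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    stop_tcmnet(sprintf("incidence file not found: %s", path), "tcmnet_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(lines[idx], delim, fixed = TRUE)
  fields <- lapply(fields, function(f) trimws(f)[nzchar(trimws(f))])
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop_tcmnet(
      sprintf("malformed incidence row at line %d: expected 2 non-empty fields, got %d",
              idx[bad[1]], length(fields[[bad[1]]])),
      "tcmnet_parse_error"
    )
  }
  if (length(fields) && identical(tolower(fields[[1]][1]), "herb_id")) {
    fields <- fields[-1]
  }
  if (!length(fields)) {
    return(tibble::tibble(herb_id = character(), ingredient_id = character()))
  }
  tab <- tibble::tibble(
    herb_id = vapply(fields, `[`, character(1), 1L),
    ingredient_id = vapply(fields, `[`, character(1), 2L)
  )
  out <- dplyr::distinct(tab)
  dup <- nrow(tab) - nrow(out)
  if (dup > 0) message(sprintf("load_incidence: collapsed %d duplicate row(s)", dup))
  out
}

#' Build a bipartite herb-ingredient graph
#'
#' Herbs and ingredients form the two parts; each incidence row becomes one
#' unweighted edge. Entities only enter via incidence rows, so degree-0
#' nodes never exist in the graph.
#'
#' @param incidence a data frame with columns `herb_id`, `ingredient_id`
#'   (e.g. from [load_incidence()] or [generate_dataset()]).
#' @return an undirected `igraph` object with logical vertex attribute
#'   `type` (`FALSE` = herb, `TRUE` = ingredient) and character attribute
#'   `id` holding the user-facing identifier.
#' @examples
#' g <- build_bipartite(data.frame(
#'   herb_id = c("H1", "H2", "H2"), ingredient_id = c("I1", "I1", "I2")
#' ))
#' igraph::gsize(g)
#' @export
build_bipartite <- function(incidence) {
  stopifnot(is.data.frame(incidence),
            all(c("herb_id", "ingredient_id") %in% names(incidence)))
  incidence <- dplyr::distinct(
    tibble::tibble(herb_id = as.character(incidence$herb_id),
                   ingredient_id = as.character(incidence$ingredient_id))
  )
  if (nrow(incidence) == 0L) {
    stop_tcmnet("empty incidence table: nothing to build", "tcmnet_empty_input")
  }
  herbs <- sort(unique(incidence$herb_id))
  ings <- sort(unique(incidence$ingredient_id))
  g <- igraph::graph_from_data_frame(
    data.frame(from = herb_tag(incidence$herb_id),
               to = ing_tag(incidence$ingredient_id)),
    directed = FALSE,
    vertices = data.frame(
      name = c(herb_tag(herbs), ing_tag(ings)),
      type = rep(c(FALSE, TRUE), c(length(herbs), length(ings))),
      id = c(herbs, ings)
    )
  )
  g
}

#' @rdname build_bipartite
#' @param g a bipartite graph from `build_bipartite()`.
#' @export
herb_ids <- function(g) igraph::V(g)$id[!igraph::V(g)$type]

#' @rdname build_bipartite
#' @export
ingredient_ids <- function(g) igraph::V(g)$id[igraph::V(g)$type]

#' Extract the giant component of a bipartite graph
#'
#' Returns the induced subgraph on the largest connected component. If
#' several components tie for the largest size, the one containing the
#' lexicographically smallest entity id wins. The number and sizes of
#' discarded components are reported via `message()`.
#'
#' @param g a bipartite graph from [build_bipartite()].
#' @return the induced subgraph on the giant component, same attributes.
#' @export
giant_component <- function(g) {
  if (igraph::vcount(g) == 0L) {
    stop_tcmnet("empty graph: no components", "tcmnet_empty_input")
  }
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1L) {
    # tie-break: component holding the lexicographically smallest id
    min_id <- vapply(biggest, function(k) min(igraph::V(g)$id[comp$membership == k]),
                     character(1))
    biggest <- biggest[order(min_id)]
  }
  winner <- biggest[1]
  if (comp$no > 1L) {
    message(sprintf("giant_component: discarded %d component(s) of sizes %s",
                    comp$no - 1L,
                    paste(sort(sizes[-winner], decreasing = TRUE), collapse = ", ")))
  }
  igraph::induced_subgraph(g, which(comp$membership == winner))
}

#' Project a bipartite graph onto one node set
#'
#' Two same-side nodes are joined iff they share at least one opposite-side
#' neighbor; the edge weight is the number of shared neighbors. Computed as
#' the incidence matrix composed with its transpose with the diagonal
#' removed. Nodes without any projection edge are retained as isolates.
#'
#' @param g a bipartite graph from [build_bipartite()].
#' @param side `"herb"` (the natural-product similarity network, NSN) or
#'   `"ingredient"` (the ingredient similarity network, ISN).
#' @return an undirected weighted `igraph` whose vertex names are the
#'   user-facing ids of the chosen side; graph attribute `side` records the
#'   projection side.
#' @examples
#' g <- build_bipartite(data.frame(
#'   herb_id = c("H1", "H1", "H2", "H2", "H3"),
#'   ingredient_id = c("I1", "I2", "I2", "I3", "I4")
#' ))
#' p <- project(g, "herb")
#' igraph::as_data_frame(p)
#' @export
project <- function(g, side = c("herb", "ingredient")) {
  side <- match.arg(side)
  if (igraph::vcount(g) == 0L) {
    stop_tcmnet("empty graph: nothing to project", "tcmnet_empty_input")
  }
  keep_type <- side == "ingredient" # type TRUE = ingredient
  edges <- igraph::as_data_frame(g, what = "edges")
  type <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  ids <- stats::setNames(igraph::V(g)$id, igraph::V(g)$name)
  # orient every incidence pair as (kept side, opposite side)
  a <- ifelse(type[edges$from] == keep_type, edges$from, edges$to)
  b <- ifelse(type[edges$from] == keep_type, edges$to, edges$from)
  nodes <- sort(ids[names(type)[type == keep_type]])
  M <- Matrix::sparseMatrix(
    i = match(ids[a], nodes),
    j = match(b, sort(unique(b))),
    x = 1,
    dims = c(length(nodes), length(unique(b)))
  )
  P <- Matrix::tcrossprod(M)
  P <- methods::as(P, "TsparseMatrix")
  keep <- P@i < P@j # strict upper triangle: no self-loops, each pair once
  el <- tibble::tibble(
    from = nodes[P@i[keep] + 1L],
    to = nodes[P@j[keep] + 1L],
    weight = P@x[keep]
  )
  out <- igraph::graph_from_data_frame(el, directed = FALSE,
                                       vertices = data.frame(name = nodes))
  out$side <- side
  out
}

#' Degree statistics and network heterogeneity
#'
#' The degree of a node is the number of links attached to it; network
#' heterogeneity is the square root of the (population) variance of the
#' degrees divided by their mean. Weights are ignored: degrees count edges.
#'
#' @param g an `igraph` (typically a projection from [project()]).
#' @return a list with `degrees` (tibble `node`, `degree`), `mean_degree`,
#'   and `heterogeneity`.
#' @examples
#' star <- igraph::make_star(4, mode = "undirected")
#' degree_stats(star)$heterogeneity # sqrt(0.75) / 1.5
#' @export
degree_stats <- function(g) {
  if (igraph::vcount(g) == 0L) {
    stop_tcmnet("empty graph: no degrees", "tcmnet_empty_input")
  }
  deg <- igraph::degree(g)
  m <- mean(deg)
  if (m == 0) {
    stop_tcmnet("all nodes are isolates: heterogeneity undefined",
                "tcmnet_degenerate_graph")
  }
  nm <- igraph::V(g)$name %||% as.character(seq_along(deg))
  list(
    degrees = tibble::tibble(node = nm, degree = as.integer(deg)),
    mean_degree = m,
    heterogeneity = sqrt(mean((deg - m)^2)) / m
  )
}

#' Write a projected graph as a weighted edge-list TSV
#'
#' Columns `from`, `to`, `weight` with a header row. Isolated nodes are
#' listed in an accompanying comment header line so the node set survives a
#' round trip.
#'
#' @param g a projection from [project()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_projection <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(iso)) {
    writeLines(sprintf("# isolates: %s", paste(iso, collapse = ",")), con)
  }
  utils::write.table(el[, c("from", "to", "weight")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge-list TSV written by [write_projection()]
#' @param path file path.
#' @return an undirected weighted `igraph`.
#' @export
read_projection <- function(path) {
  lines <- readLines(path, warn = FALSE)
  iso <- character()
  iso_line <- grep("^# isolates:", lines)
  if (length(iso_line)) {
    iso <- strsplit(sub("^# isolates:\\s*", "", lines[iso_line[1]]), ",")[[1]]
  }
  el <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          colClasses = c("character", "character", "numeric"))
  verts <- data.frame(name = sort(unique(c(el$from, el$to, iso))))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}
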
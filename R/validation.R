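# Within-community annotation coherence against a random-grouping null.
#
# Set-valued annotations (meridians, properties, protein targets) are
# compared with the overlap coefficient |A n B| / min(|A|, |B|) by default
# (Jaccard selectable); strings are compared with the Dice index over their
# character-bigram sets. All pairwise similarities for one annotation table
# are computed once as a dense matrix via an indicator-matrix cross product,
# so permutation replicates only reindex the matrix.

#' Tokenize a string into its set of character bigrams
#'
#' Default tokenizer for string annotations (SMILES). Length-1 strings
#' tokenize to themselves so similarity stays defined.
#'
#' @param s a character string.
#' @return character vector of distinct bigrams.
#' @examples
#' tokenize_bigrams("CCO") # "CC", "CO"
#' @export
tokenize_bigrams <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(s)
  unique(substring(s, 1:(n - 1L), 2:n))
}

payload_tokens <- function(payload, kind, tokenizer) {
  if (kind == "string") lapply(payload, function(p) tokenizer(p[[1]])) else payload
}

#' Similarity between two annotation payloads
#'
#' Label and id sets are compared with the overlap coefficient
#' \eqn{|A \cap B| / \min(|A|, |B|)} (default) or the Jaccard index
#' \eqn{|A \cap B| / |A \cup B|}; strings are tokenized (by default into
#' character bigrams) and compared with the Dice index
#' \eqn{2 |T_a \cap T_b| / (|T_a| + |T_b|)}.
#'
#' @param a,b payloads: character vectors for set kinds, single strings for
#'   kind `"string"`.
#' @param kind `"label_set"`, `"string"` or `"id_set"`.
#' @param method set similarity for the set kinds: `"overlap"` or `"jaccard"`.
#' @param tokenizer string tokenizer, default [tokenize_bigrams()]; plug in
#'   e.g. a chemical fingerprint generator for real SMILES.
#' @return a similarity in \[0, 1\].
#' @examples
#' pair_similarity(c("a", "b"), c("b", "c", "d"), kind = "label_set") # 0.5
#' pair_similarity("CCO", "CCN", kind = "string") # Dice = 0.5
#' @export
pair_similarity <- function(a, b, kind = c("label_set", "string", "id_set"),
                            method = c("overlap", "jaccard"),
                            tokenizer = tokenize_bigrams) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  if (!length(a) || !length(b) || !any(nzchar(a)) || !any(nzchar(b))) {
    stop_tcmnet("empty annotation payload", "tcmnet_annotation_error")
  }
  if (kind == "string") {
    a <- tokenizer(a[[1]])
    b <- tokenizer(b[[1]])
    return(2 * length(intersect(a, b)) / (length(unique(a)) + length(unique(b))))
  }
  a <- unique(a)
  b <- unique(b)
  inter <- length(intersect(a, b))
  if (method == "overlap") inter / min(length(a), length(b))
  else inter / length(union(a, b))
}

# dense entity-by-entity similarity matrix for one annotation table
similarity_matrix <- function(ann, method = "overlap",
                              tokenizer = tokenize_bigrams) {
  kind <- annotation_kind(ann)
  tokens <- payload_tokens(ann$payload, kind, tokenizer)
  universe <- unique(unlist(tokens))
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(tokens), lengths(tokens)),
    j = match(unlist(tokens), universe),
    x = 1,
    dims = c(length(tokens), length(universe))
  )
  inter <- as.matrix(Matrix::tcrossprod(M))
  sizes <- lengths(tokens)
  S <- if (kind == "string") {
    2 * inter / outer(sizes, sizes, `+`)
  } else if (method == "overlap") {
    inter / outer(sizes, sizes, pmin)
  } else {
    inter / (outer(sizes, sizes, `+`) - inter)
  }
  dimnames(S) <- list(ann$entity_id, ann$entity_id)
  S
}

# per-cluster mean pairwise similarity from a precomputed matrix;
# assignment: named community labels over entities present in S
cluster_means_from_matrix <- function(S, assignment) {
  split_ids <- split(names(assignment), assignment)
  purrr::imap_dfr(split_ids, function(ids, comm) {
    ids <- intersect(ids, rownames(S))
    if (length(ids) < 2L) {
      return(tibble::tibble(community = comm, n_annotated = length(ids),
                            similarity = NA_real_))
    }
    sub <- S[ids, ids]
    tibble::tibble(community = comm, n_annotated = length(ids),
                   similarity = mean(sub[upper.tri(sub)]))
  })
}

#' Mean within-cluster annotation similarity
#'
#' For every cluster with at least two annotated members, the mean of
#' [pair_similarity()] over all unordered annotated pairs. Clusters with
#' fewer than two annotated members are excluded and reported; entities
#' without an annotation are excluded from this computation only.
#'
#' @param partition a [fast_greedy()] result or (`node`, `community`) data
#'   frame.
#' @param ann an [annotation_table()].
#' @inheritParams pair_similarity
#' @param quiet suppress exclusion messages.
#' @return a tibble with one row per evaluable cluster: `community`,
#'   `n_members`, `n_annotated`, `similarity`.
#' @export
cluster_similarity <- function(partition, ann, method = c("overlap", "jaccard"),
                               tokenizer = tokenize_bigrams, quiet = FALSE) {
  method <- match.arg(method)
  assignment <- partition_assignment(partition)
  S <- similarity_matrix(ann, method = method, tokenizer = tokenizer)
  cluster_similarity_impl(S, assignment, quiet = quiet)
}

partition_assignment <- function(partition) {
  if (inherits(partition, "tcmnet_partition")) return(partition$membership)
  if (is.data.frame(partition)) {
    stopifnot(all(c("node", "community") %in% names(partition)))
    return(stats::setNames(partition$community, partition$node))
  }
  stopifnot(!is.null(names(partition)))
  partition
}

cluster_similarity_impl <- function(S, assignment, quiet = FALSE) {
  n_members <- table(assignment)
  unannotated <- sum(!names(assignment) %in% rownames(S))
  res <- cluster_means_from_matrix(S, assignment)
  res$n_members <- as.integer(n_members[as.character(res$community)])
  dropped <- res[is.na(res$similarity), ]
  res <- res[!is.na(res$similarity), c("community", "n_members",
                                       "n_annotated", "similarity")]
  if (!quiet) {
    if (unannotated > 0) {
      message(sprintf("cluster_similarity: %d entities without annotation excluded",
                      unannotated))
    }
    if (nrow(dropped) > 0) {
      message(sprintf("cluster_similarity: %d cluster(s) with < 2 annotated members excluded",
                      nrow(dropped)))
    }
  }
  if (nrow(res) == 0L) {
    stop_tcmnet("no cluster has >= 2 annotated members: nothing to validate",
                "tcmnet_validation_error")
  }
  tibble::as_tibble(res)
}

#' Random-grouping null distribution of within-cluster similarity
#'
#' Each replicate permutes the entity-to-cluster assignment uniformly at
#' random, preserving the multiset of cluster sizes, and recomputes the
#' per-cluster mean similarities; all per-cluster means are pooled across
#' replicates.
#'
#' @inheritParams cluster_similarity
#' @param n_replicates number of random groupings (the reference analysis
#'   uses 100).
#' @param seed optional integer seed for reproducibility; `NULL` uses the
#'   current RNG stream.
#' @return a tibble (`replicate`, `community`, `n_annotated`, `similarity`).
#' @export
random_grouping_null <- function(partition, ann, n_replicates = 100,
                                 seed = NULL,
                                 method = c("overlap", "jaccard"),
                                 tokenizer = tokenize_bigrams) {
  method <- match.arg(method)
  stopifnot(n_replicates >= 1)
  assignment <- partition_assignment(partition)
  S <- similarity_matrix(ann, method = method, tokenizer = tokenizer)
  with_seed_if(seed, random_null_impl(S, assignment, n_replicates))
}

random_null_impl <- function(S, assignment, n_replicates) {
  # entities with an annotation, in a fixed order; replicates only permute
  # the assignment vector and average precomputed similarity entries
  ids <- names(assignment)
  in_S <- match(ids, rownames(S))
  labels <- sort(unique(assignment))
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    shuffled <- assignment[sample.int(length(assignment))]
    sim <- rep(NA_real_, length(labels))
    n_ann <- integer(length(labels))
    for (k in seq_along(labels)) {
      rows <- in_S[shuffled == labels[k]]
      rows <- rows[!is.na(rows)]
      n_ann[k] <- length(rows)
      if (length(rows) >= 2L) {
        sub <- S[rows, rows]
        sim[k] <- mean(sub[upper.tri(sub)])
      }
    }
    keep <- !is.na(sim)
    reps[[r]] <- tibble::tibble(replicate = r,
                                community = as.character(labels[keep]),
                                n_annotated = n_ann[keep],
                                similarity = sim[keep])
  }
  dplyr::bind_rows(reps)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided. The p-value is computed by exact enumeration when the pooled
#' sample has at most 12 values and no ties, otherwise by the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (observed vs null similarities).
#' @return a one-row tibble: `statistic` (Mann-Whitney U for `x`),
#'   `p_value`, `exact`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(10, 11, 12)) # U = 0, exact p = 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop_tcmnet("rank_sum_test needs non-empty samples", "tcmnet_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = min(ht$p.value, 1),
                 exact = exact)
}

#' Validate community coherence against a random-grouping null
#'
#' Composes [cluster_similarity()], [random_grouping_null()] and
#' [rank_sum_test()]: the observed per-cluster mean similarities are
#' compared with the pooled null distribution from `n_replicates` random
#' groupings of the same cluster sizes.
#'
#' @inheritParams random_grouping_null
#' @return an object of class `tcmnet_validation`: list with `observed`
#'   (per-cluster tibble), `null` (pooled tibble), `observed_median`,
#'   `null_median`, `statistic`, `p_value`, `exact`, `n_replicates`,
#'   `seed`, `kind`, `method`.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 3))
#' part <- ds$ground_truth |>
#'   dplyr::filter(side == "herb") |>
#'   dplyr::transmute(node = entity_id, community = block)
#' v <- validate_communities(part, ds$annotations$meridian, seed = 1)
#' glance(v)
#' @export
validate_communities <- function(partition, ann, n_replicates = 100,
                                 seed = NULL,
                                 method = c("overlap", "jaccard"),
                                 tokenizer = tokenize_bigrams) {
  method <- match.arg(method)
  assignment <- partition_assignment(partition)
  S <- similarity_matrix(ann, method = method, tokenizer = tokenizer)
  observed <- cluster_similarity_impl(S, assignment)
  null <- with_seed_if(seed, random_null_impl(S, assignment, n_replicates))
  test <- rank_sum_test(observed$similarity, null$similarity)
  structure(
    list(observed = observed,
         null = null,
         observed_median = stats::median(observed$similarity),
         null_median = stats::median(null$similarity),
         statistic = test$statistic,
         p_value = test$p_value,
         exact = test$exact,
         n_replicates = n_replicates,
         seed = seed,
         kind = annotation_kind(ann),
         method = if (annotation_kind(ann) == "string") "dice_bigram" else method),
    class = "tcmnet_validation"
  )
}

#' @export
print.tcmnet_validation <- function(x, ...) {
  cat(sprintf(
    paste0("<tcmnet_validation> kind = %s (%s): %d clusters vs %d pooled null values\n",
           "  observed median = %.3f, null median = %.3f, p = %.3g (Wilcoxon rank-sum)\n"),
    x$kind, x$method, nrow(x$observed), nrow(x$null),
    x$observed_median, x$null_median, x$p_value
  ))
  invisible(x)
}

#' @rdname validate_communities
#' @param x a `tcmnet_validation`.
#' @param ... unused.
#' @method tidy tcmnet_validation
#' @export
tidy.tcmnet_validation <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$observed, group = "observed", replicate = NA_integer_),
    dplyr::mutate(x$null, group = "null", n_members = NA_integer_)
  ) |>
    dplyr::select("group", "replicate", "community", "n_annotated", "similarity")
}

#' @rdname validate_communities
#' @method glance tcmnet_validation
#' @export
glance.tcmnet_validation <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    method = x$method,
    n_clusters = nrow(x$observed),
    n_replicates = x$n_replicates,
    observed_median = x$observed_median,
    null_median = x$null_median,
    statistic = x$statistic,
    p_value = x$p_value
  )
}

#' Write a validation report
#'
#' `write_validation()` writes the full report as JSON plus a long-format
#' TSV of observed and null similarity values for external plotting.
#'
#' @param v a `tcmnet_validation`.
#' @param json_path output JSON path.
#' @param values_path optional TSV path for the long value table.
#' @return `json_path`, invisibly.
#' @export
write_validation <- function(v, json_path, values_path = NULL) {
  payload <- list(
    kind = v$kind, method = v$method,
    n_replicates = v$n_replicates,
    seed = v$seed,
    observed_median = v$observed_median,
    null_median = v$null_median,
    statistic = v$statistic,
    p_value = v$p_value,
    observed = v$observed,
    null_values = v$null$similarity
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  if (!is.null(values_path)) {
    utils::write.table(tidy(v), values_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
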
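label_ann <- function(payloads, ids = sprintf("E%02d", seq_along(payloads)),
                      kind = "label_set") {
  annotation_table(tibble::tibble(entity_id = ids, payload = payloads),
                   kind = kind)
}

# all non-empty subsets of a small universe
power_set <- function(universe) {
  unlist(lapply(seq_along(universe), function(k) {
    utils::combn(universe, k, simplify = FALSE)
  }), recursive = FALSE)
}

test_that("pair_similarity reproduces hand-enumerated cases", {
  expect_equal(pair_similarity(c("a", "b"), c("a", "b"), "label_set"), 1)
  expect_equal(pair_similarity(c("a", "b"), c("c", "d"), "id_set"), 0)
  expect_equal(pair_similarity(c("a", "b"), c("b", "c", "d"), "label_set"), 0.5)
  expect_equal(pair_similarity(c("a", "b"), c("b", "c", "d"), "label_set",
                               method = "jaccard"), 0.25)
  # Dice on bigrams: T(CCO)={CC,CO}, T(CCN)={CC,CN} -> 2*1/4
  expect_equal(pair_similarity("CCO", "CCN", "string"), 0.5)
  expect_equal(pair_similarity("CCO", "CCO", "string"), 1)
  expect_equal(pair_similarity("ab", "cd", "string"), 0)
  expect_error(pair_similarity(character(0), "a", "label_set"),
               class = "tcmnet_annotation_error")
})

test_that("similarity is symmetric, bounded, with Dice/overlap equality conditions", {
  subsets <- power_set(letters[1:5])
  for (i in seq_along(subsets)) {
    for (j in seq_len(i)) {
      a <- subsets[[i]]
      b <- subsets[[j]]
      for (m in c("overlap", "jaccard")) {
        s_ab <- pair_similarity(a, b, "label_set", method = m)
        expect_equal(s_ab, pair_similarity(b, a, "label_set", method = m))
        expect_gte(s_ab, 0)
        expect_lte(s_ab, 1)
      }
      # overlap == 1 iff one set contains the other
      contained <- all(a %in% b) || all(b %in% a)
      expect_equal(pair_similarity(a, b, "label_set") == 1, contained)
      # jaccard == 1 iff equal
      expect_equal(pair_similarity(a, b, "label_set", method = "jaccard") == 1,
                   setequal(a, b))
    }
  }
  # Dice == 1 iff bigram token sets are equal
  strings <- c("CCO", "CCOC", "OCC", "CC", "COCO", "CCOCC")
  for (a in strings) {
    for (b in strings) {
      d <- pair_similarity(a, b, "string")
      expect_equal(d == 1, setequal(tokenize_bigrams(a), tokenize_bigrams(b)),
                   info = paste(a, b))
      expect_equal(d, pair_similarity(b, a, "string"))
    }
  }
})

test_that("cluster_similarity averages pairs and excludes unevaluable clusters", {
  ann <- label_ann(list(c("x"), c("x"), c("y")), ids = c("e1", "e2", "e3"))
  part <- tibble::tibble(node = c("e1", "e2", "e3"), community = c(1, 1, 1))
  cs <- cluster_similarity(part, ann)
  # pairs: (1, 0, 0) -> mean 1/3
  expect_equal(cs$similarity, 1 / 3)
  expect_equal(cs$n_annotated, 3L)

  two <- label_ann(list(c("a", "b"), c("a", "b")), ids = c("e1", "e2"))
  cs2 <- cluster_similarity(tibble::tibble(node = c("e1", "e2"), community = 0),
                            two)
  expect_equal(cs2$similarity, 1)

  # all singletons -> validation error
  singles <- tibble::tibble(node = c("e1", "e2", "e3"), community = 1:3)
  expect_error(cluster_similarity(singles, ann),
               class = "tcmnet_validation_error")

  # unannotated entities excluded with a message, not an error
  part4 <- tibble::tibble(node = c("e1", "e2", "e3", "e4"),
                          community = c(1, 1, 1, 1))
  expect_message(cs4 <- cluster_similarity(part4, ann), "1 entities without")
  expect_equal(cs4$n_annotated, 3L)
  expect_equal(cs4$n_members, 4L)
})

test_that("random_grouping_null pools k values per replicate and is seed-stable", {
  withr::local_seed(1)
  ds <- generate_dataset(synthetic_config(seed = 5))
  part <- planted_partition(ds)
  ann <- ds$annotations$meridian
  null2 <- random_grouping_null(part, ann, n_replicates = 2, seed = 42)
  expect_equal(nrow(null2), 2 * 3) # 2 replicates x 3 evaluable clusters
  expect_identical(null2,
                   random_grouping_null(part, ann, n_replicates = 2, seed = 42))

  # identical annotations for everyone -> all null values 1
  same <- label_ann(rep(list(c("a", "b")), 10))
  part10 <- tibble::tibble(node = sprintf("E%02d", 1:10),
                           community = rep(1:2, each = 5))
  nl <- random_grouping_null(part10, same, n_replicates = 3, seed = 1)
  expect_true(all(nl$similarity == 1))
})

test_that("rank_sum_test matches exact enumeration and degenerate cases", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1) # 2 of the C(6,3)=20 arrangements as extreme
  expect_true(r$exact)

  r2 <- rank_sum_test(1, 2)
  expect_equal(r2$p_value, 1)

  same <- rank_sum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)

  # large samples switch to the corrected normal approximation
  withr::local_seed(2)
  big <- rank_sum_test(rnorm(30), rnorm(40, mean = 2))
  expect_false(big$exact)
  expect_lt(big$p_value, 1e-4)

  expect_error(rank_sum_test(numeric(0), 1), class = "tcmnet_input_error")
})

test_that("validate_communities composes the stages into a coherent report", {
  ds <- generate_dataset(synthetic_config(annotation_noise = 0, seed = 9))
  part <- planted_partition(ds)
  v <- validate_communities(part, ds$annotations$meridian, n_replicates = 20,
                            seed = 3)
  # noise-free planted blocks: within-block payloads identical
  expect_equal(v$observed_median, 1)
  expect_equal(nrow(v$null), 20 * nrow(v$observed))
  expect_lt(v$null_median, v$observed_median)
  expect_lt(v$p_value, 0.05)

  gl <- glance(v)
  expect_equal(gl$kind, "label_set")
  expect_equal(gl$n_replicates, 20)
  td <- tidy(v)
  expect_setequal(unique(td$group), c("observed", "null"))
  expect_true(all(td$similarity >= 0 & td$similarity <= 1))
})

test_that("block-correlated annotations separate observed from null medians", {
  ds <- generate_dataset(synthetic_config(annotation_noise = 0.1, seed = 23))
  herb_part <- planted_partition(ds, "herb")
  ing_part <- planted_partition(ds, "ingredient")
  combos <- list(
    list(part = herb_part, ann = ds$annotations$meridian),
    list(part = herb_part, ann = ds$annotations$property),
    list(part = ing_part, ann = ds$annotations$smiles),
    list(part = ing_part, ann = ds$annotations$targets)
  )
  for (cb in combos) {
    v <- validate_communities(cb$part, cb$ann, n_replicates = 30, seed = 7)
    expect_gt(v$observed_median, v$null_median)
  }
})

test_that("observed median is invariant to relabeling and entity renaming", {
  ds <- generate_dataset(synthetic_config(seed = 13))
  part <- planted_partition(ds)
  ann <- ds$annotations$meridian
  v1 <- validate_communities(part, ann, n_replicates = 5, seed = 1)

  relabeled <- dplyr::mutate(part, community = 99 - community)
  v2 <- validate_communities(relabeled, ann, n_replicates = 5, seed = 1)
  expect_equal(v2$observed_median, v1$observed_median)

  rename <- stats::setNames(paste0("X", part$node), part$node)
  part3 <- dplyr::mutate(part, node = rename[node])
  ann3 <- annotation_table(
    tibble::tibble(entity_id = rename[ann$entity_id], payload = ann$payload),
    kind = "label_set"
  )
  v3 <- validate_communities(part3, ann3, n_replicates = 5, seed = 1)
  expect_equal(v3$observed_median, v1$observed_median)
})

test_that("validation report JSON and value TSV round trip key fields", {
  ds <- generate_dataset(synthetic_config(seed = 29))
  v <- validate_communities(planted_partition(ds), ds$annotations$meridian,
                            n_replicates = 10, seed = 2)
  json_path <- withr::local_tempfile(fileext = ".json")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_validation(v, json_path, tsv_path)
  back <- jsonlite::read_json(json_path)
  expect_equal(back$observed_median, v$observed_median)
  expect_equal(back$p_value, v$p_value)
  expect_equal(length(back$null_values), nrow(v$null))
  vals <- utils::read.delim(tsv_path)
  expect_equal(nrow(vals), nrow(tidy(v)))
})
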
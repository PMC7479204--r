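# Planted-block synthetic herb-ingredient data.
#
# The generator emulates the shape of a curated TCM database export: a
# bipartite herb-ingredient incidence table plus four annotation tables
# (herb meridians, herb properties, ingredient SMILES-like strings,
# ingredient protein targets), with a planted block structure that plays the
# role of the latent herb classes a community detection should recover.

# fixed 12-symbol alphabet of common SMILES characters; strings need not be
# chemically valid, they only exercise the bigram tokenizer
SMILES_ALPHABET <- c("C", "c", "N", "O", "=", "(", ")", "1", "2", "S", "F", "[")

#' Configuration for the planted-block generator
#'
#' Defaults describe a small benchmark: 3 blocks of 20 herbs and 30
#' ingredients each, 6 ingredient draws per herb, 5% cross-block
#' contamination and 10% annotation noise. Label universes follow the domain:
#' 12 meridian labels (the twelve classical channels), 9 property labels
#' (natures plus flavors), 60 protein targets.
#'
#' @param n_blocks number of planted blocks (communities).
#' @param herbs_per_block,ingredients_per_block entities per block.
#' @param ingredients_per_herb ingredient draws per herb; duplicate draws are
#'   collapsed, so realized herb degree may be lower.
#' @param cross_block_rate probability that a draw comes from a uniformly
#'   chosen foreign block's ingredient pool instead of the herb's own block.
#' @param annotation_noise probability that each inherited signature label is
#'   replaced by a uniform draw from its label universe.
#' @param n_meridian_labels,n_property_labels,n_target_labels universe sizes.
#' @param labels_per_entity size of each block's signature label set.
#' @param string_length length of the synthetic SMILES-like signature string.
#' @param string_mutation_rate per-character probability that a signature
#'   string character is replaced by a uniform alphabet character.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return a validated list of class `tcmnet_config`.
#' @examples
#' cfg <- synthetic_config(n_blocks = 2, seed = 7)
#' @export
synthetic_config <- function(n_blocks = 3L,
                             herbs_per_block = 20L,
                             ingredients_per_block = 30L,
                             ingredients_per_herb = 6L,
                             cross_block_rate = 0.05,
                             annotation_noise = 0.1,
                             n_meridian_labels = 12L,
                             n_property_labels = 9L,
                             n_target_labels = 60L,
                             labels_per_entity = 3L,
                             string_length = 20L,
                             string_mutation_rate = 0.1,
                             seed = 1L) {
  cfg <- list(
    n_blocks = check_count(n_blocks, "n_blocks"),
    herbs_per_block = check_count(herbs_per_block, "herbs_per_block"),
    ingredients_per_block = check_count(ingredients_per_block, "ingredients_per_block"),
    ingredients_per_herb = check_count(ingredients_per_herb, "ingredients_per_herb"),
    cross_block_rate = check_prob(cross_block_rate, "cross_block_rate"),
    annotation_noise = check_prob(annotation_noise, "annotation_noise"),
    n_meridian_labels = check_count(n_meridian_labels, "n_meridian_labels"),
    n_property_labels = check_count(n_property_labels, "n_property_labels"),
    n_target_labels = check_count(n_target_labels, "n_target_labels"),
    labels_per_entity = check_count(labels_per_entity, "labels_per_entity"),
    string_length = check_count(string_length, "string_length"),
    string_mutation_rate = check_prob(string_mutation_rate, "string_mutation_rate"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$labels_per_entity > min(cfg$n_meridian_labels, cfg$n_property_labels,
                                  cfg$n_target_labels)) {
    stop_tcmnet("labels_per_entity exceeds a label universe size",
                "tcmnet_config_error")
  }
  structure(cfg, class = "tcmnet_config")
}

# resample each label with probability `noise` from `universe`, keep as a set
noisy_labels <- function(labels, universe, noise) {
  hit <- stats::runif(length(labels)) < noise
  labels[hit] <- sample(universe, sum(hit), replace = TRUE)
  unique(labels)
}

mutate_string <- function(s, alphabet, rate) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- sample(alphabet, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a planted-block herb-ingredient dataset
#'
#' Each herb of block *b* draws `ingredients_per_herb` ingredients; each draw
#' comes from block *b*'s ingredient pool with probability
#' `1 - cross_block_rate`, otherwise from a uniformly chosen foreign block.
#' Duplicate (herb, ingredient) pairs are collapsed to a single unweighted
#' incidence row. Every block owns a signature meridian/property/target label
#' set and a signature SMILES-like motif; entities inherit the signature of
#' their block, then labels are resampled with probability `annotation_noise`
#' and string characters mutated with probability `string_mutation_rate`.
#'
#' A single RNG stream seeded from `config$seed` drives all draws in a fixed
#' order (block signatures, then incidence draws per herb, then herb
#' annotations, then ingredient annotations), so output is byte-identical
#' across runs for a given configuration.
#'
#' @param config a [synthetic_config()].
#' @return a list of class `tcmnet_dataset` with elements
#'   * `incidence`: tibble (`herb_id`, `ingredient_id`), deduplicated;
#'   * `annotations`: named list of [annotation_table()]s `meridian`,
#'     `property` (herbs) and `smiles`, `targets` (ingredients);
#'   * `ground_truth`: tibble (`entity_id`, `side`, `block`) with 0-based
#'     block indices, every generated entity exactly once.
#' @examples
#' ds <- generate_dataset(synthetic_config(n_blocks = 2, seed = 7))
#' dplyr::count(ds$incidence, herb_id)
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "tcmnet_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  B <- cfg$n_blocks
  herbs <- make_ids("H", B * cfg$herbs_per_block)
  ings <- make_ids("I", B * cfg$ingredients_per_block)
  herb_block <- rep(seq_len(B) - 1L, each = cfg$herbs_per_block)
  ing_block <- rep(seq_len(B) - 1L, each = cfg$ingredients_per_block)

  meridian_universe <- sprintf("M%02d", seq_len(cfg$n_meridian_labels))
  property_universe <- sprintf("P%02d", seq_len(cfg$n_property_labels))
  target_universe <- sprintf("T%03d", seq_len(cfg$n_target_labels))

  # 1. block signatures, in block order
  sig <- lapply(seq_len(B), function(b) {
    list(
      meridian = sample(meridian_universe, cfg$labels_per_entity),
      property = sample(property_universe, cfg$labels_per_entity),
      targets = sample(target_universe, cfg$labels_per_entity),
      motif = paste(sample(SMILES_ALPHABET, cfg$string_length, replace = TRUE),
                    collapse = "")
    )
  })

  # 2. incidence draws, herb by herb
  pools <- split(ings, ing_block)
  rows <- vector("list", length(herbs))
  for (h in seq_along(herbs)) {
    b <- herb_block[h]
    src <- integer(cfg$ingredients_per_herb)
    for (d in seq_len(cfg$ingredients_per_herb)) {
      cross <- B > 1L && stats::runif(1) < cfg$cross_block_rate
      if (cross) {
        foreign <- setdiff(seq_len(B) - 1L, b)
        src[d] <- foreign[sample.int(length(foreign), 1L)]
      } else {
        src[d] <- b
      }
    }
    picked <- vapply(src, function(sb) {
      pool <- pools[[as.character(sb)]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    rows[[h]] <- tibble::tibble(herb_id = herbs[h], ingredient_id = picked)
  }
  incidence <- dplyr::distinct(dplyr::bind_rows(rows))

  # 3. herb annotations (meridian then property per herb), 4. ingredient
  # annotations (smiles then targets per ingredient)
  mer <- vector("list", length(herbs))
  prop <- vector("list", length(herbs))
  for (h in seq_along(herbs)) {
    b <- herb_block[h] + 1L
    mer[[h]] <- noisy_labels(sig[[b]]$meridian, meridian_universe, cfg$annotation_noise)
    prop[[h]] <- noisy_labels(sig[[b]]$property, property_universe, cfg$annotation_noise)
  }
  smi <- character(length(ings))
  tgt <- vector("list", length(ings))
  for (i in seq_along(ings)) {
    b <- ing_block[i] + 1L
    smi[i] <- mutate_string(sig[[b]]$motif, SMILES_ALPHABET, cfg$string_mutation_rate)
    tgt[[i]] <- noisy_labels(sig[[b]]$targets, target_universe, cfg$annotation_noise)
  }

  annotations <- list(
    meridian = annotation_table(tibble::tibble(entity_id = herbs, payload = mer),
                                kind = "label_set"),
    property = annotation_table(tibble::tibble(entity_id = herbs, payload = prop),
                                kind = "label_set"),
    smiles = annotation_table(tibble::tibble(entity_id = ings, payload = as.list(smi)),
                              kind = "string"),
    targets = annotation_table(tibble::tibble(entity_id = ings, payload = tgt),
                               kind = "id_set")
  )
  ground_truth <- tibble::tibble(
    entity_id = c(herbs, ings),
    side = rep(c("herb", "ingredient"),
               c(length(herbs), length(ings))),
    block = c(herb_block, ing_block)
  )
  structure(
    list(incidence = incidence, annotations = annotations,
         ground_truth = ground_truth, config = cfg),
    class = "tcmnet_dataset"
  )
}

#' @export
print.tcmnet_dataset <- function(x, ...) {
  cat(sprintf(
    "<tcmnet_dataset> %d herbs x %d ingredients, %d incidence rows, %d blocks\n",
    dplyr::n_distinct(x$incidence$herb_id),
    dplyr::n_distinct(x$incidence$ingredient_id),
    nrow(x$incidence), x$config$n_blocks
  ))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Writes `incidence.tsv` (herb_id, ingredient_id), one annotation TSV per
#' kind (`annotation_<name>.tsv`, set payloads joined by `"|"`) and
#' `ground_truth.tsv` (entity_id, block).
#'
#' @param dataset a [generate_dataset()] result.
#' @param outdir output directory, created if missing.
#' @return `outdir` invisibly.
#' @export
write_dataset <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "tcmnet_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(dataset$incidence, file.path(outdir, "incidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(dataset$annotations)) {
    write_annotations(dataset$annotations[[nm]],
                      file.path(outdir, sprintf("annotation_%s.tsv", nm)))
  }
  utils::write.table(dataset$ground_truth[, c("entity_id", "block")],
                     file.path(outdir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
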
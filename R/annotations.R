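#' Annotation tables
#'
#' An annotation table maps entity identifiers (herbs or ingredients) to an
#' annotation payload. Three payload kinds are supported:
#'
#' * `"label_set"` — a set of categorical labels, e.g. the meridian (channel
#'   tropism) or property (nature/flavor) classifications of a herb;
#' * `"string"` — a single character string, e.g. a SMILES string of a
#'   chemical ingredient;
#' * `"id_set"` — a set of identifiers, e.g. protein targets of an ingredient.
#'
#' @param data a data frame with columns `entity_id` and `payload`. `payload`
#'   may be a list column of character vectors, or a character column whose
#'   multi-valued cells are joined by `delim`.
#' @param kind one of `"label_set"`, `"string"`, `"id_set"`.
#' @param delim delimiter used to split character payload cells for set kinds.
#' @return a tibble of class `tcmnet_annotation` with columns `entity_id` and
#'   `payload` (list column) and a `kind` attribute.
#' @examples
#' annotation_table(
#'   data.frame(entity_id = c("H1", "H2"), payload = c("liver|lung", "liver")),
#'   kind = "label_set"
#' )
#' @export
annotation_table <- function(data, kind = c("label_set", "string", "id_set"),
                             delim = "|") {
  kind <- match.arg(kind)
  if (!all(c("entity_id", "payload") %in% names(data))) {
    stop_tcmnet("annotation data must have columns `entity_id` and `payload`",
                "tcmnet_annotation_error")
  }
  payload <- data[["payload"]]
  if (!is.list(payload)) {
    payload <- as.character(payload)
    payload <- if (kind == "string") as.list(payload) else
      strsplit(payload, delim, fixed = TRUE)
  }
  payload <- lapply(payload, function(p) unique(as.character(p)))
  empty <- lengths(payload) == 0L | vapply(payload, function(p) all(!nzchar(p)), logical(1))
  if (any(empty)) {
    stop_tcmnet(
      sprintf("empty annotation payload for entities: %s",
              paste(data$entity_id[empty], collapse = ", ")),
      "tcmnet_annotation_error"
    )
  }
  if (anyDuplicated(data$entity_id)) {
    stop_tcmnet("duplicate entity_id in annotation table", "tcmnet_annotation_error")
  }
  out <- tibble::tibble(entity_id = as.character(data$entity_id), payload = payload)
  class(out) <- c("tcmnet_annotation", class(out))
  attr(out, "kind") <- kind
  out
}

#' @export
print.tcmnet_annotation <- function(x, ...) {
  cat(sprintf("<tcmnet_annotation> kind = %s, %d entities\n",
              annotation_kind(x), nrow(x)))
  NextMethod()
}

#' Annotation kind of an annotation table
#' @param ann a [annotation_table()].
#' @return `"label_set"`, `"string"` or `"id_set"`.
#' @export
annotation_kind <- function(ann) attr(ann, "kind")

#' Read / write annotation tables
#'
#' Plain TSV with a header row `entity_id<TAB>payload`; set-valued payload
#' cells are joined by `delim`.
#'
#' @param path file path.
#' @inheritParams annotation_table
#' @return `read_annotations()` returns a `tcmnet_annotation` tibble;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path, kind = c("label_set", "string", "id_set"),
                             delim = "|") {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          comment.char = "#", blank.lines.skip = TRUE)
  names(df)[1:2] <- c("entity_id", "payload")
  annotation_table(df, kind = kind, delim = delim)
}

#' @rdname read_annotations
#' @param ann a `tcmnet_annotation` table.
#' @export
write_annotations <- function(ann, path, delim = "|") {
  flat <- vapply(ann$payload, paste, character(1), collapse = delim)
  utils::write.table(
    data.frame(entity_id = ann$entity_id, payload = flat),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
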
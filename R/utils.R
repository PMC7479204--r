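#' @importFrom rlang abort %||%
#' @importFrom stats median
#' @keywords internal
"_PACKAGE"

# zero-padded entity ids: H0001..., I0001...
make_ids <- function(prefix, n) {
  width <- max(4L, nchar(as.character(n)))
  sprintf("%s%0*d", prefix, width, seq_len(n))
}

stop_tcmnet <- function(msg, class) {
  rlang::abort(msg, class = c(class, "tcmnet_error"))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min || x != as.integer(x)) {
    stop_tcmnet(
      sprintf("`%s` must be a single integer >= %d (got %s)", name, min, deparse(x)),
      "tcmnet_config_error"
    )
  }
  invisible(as.integer(x))
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0 || x > 1) {
    stop_tcmnet(
      sprintf("`%s` must be a single probability in [0, 1] (got %s)", name, deparse(x)),
      "tcmnet_config_error"
    )
  }
  invisible(as.numeric(x))
}

# run expr under a fixed seed when given, otherwise use the current RNG stream
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
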
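#' @importFrom rlang %||% abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n count across pull rename relocate distinct
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_int imap pmap list_rbind
#' @importFrom Matrix colSums rowSums rowMeans t sparseMatrix
#' @importFrom stats rnbinom rlnorm rgamma rhyper runif setNames
#'   wilcox.test p.adjust median quantile
#' @importFrom methods as is
NULL

# Deterministic 31-bit seed for a named substream: polynomial rolling hash
# over the concatenated tokens (exact in double precision), so substreams
# depend on names, not call order.
substream_seed <- function(seed, ...) {
  tokens <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(tokens)) h <- (h * 31 + b) %% 2147483629
  as.integer(h)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

assert_count_matrix <- function(m, arg = "counts") {
  if (!is(m, "sparseMatrix") && !is.matrix(m)) {
    abort(sprintf("`%s` must be a (sparse) matrix, got <%s>", arg, class(m)[1]))
  }
  if ((nrow(m) > 0 && is.null(rownames(m))) ||
      (ncol(m) > 0 && is.null(colnames(m)))) {
    abort(sprintf("`%s` must have gene ids as rownames and barcodes as colnames", arg))
  }
  if (anyDuplicated(rownames(m))) abort(sprintf("`%s` has duplicated gene ids", arg))
  if (anyDuplicated(colnames(m))) abort(sprintf("`%s` has duplicated barcodes", arg))
  x <- if (is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(x) && min(x) < 0) abort(sprintf("`%s` contains negative entries", arg))
  if (length(x) && any(x != floor(x))) abort(sprintf("`%s` contains non-integer entries", arg))
  invisible(m)
}

as_dgc <- function(m) as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")

check_cells_aligned <- function(m, cells) {
  if (!all(c("barcode") %in% names(cells))) abort("`cells` must have a `barcode` column")
  if (!setequal(colnames(m), cells$barcode) || ncol(m) != nrow(cells)) {
    abort("`cells` barcodes do not match matrix columns")
  }
  cells[match(colnames(m), cells$barcode), , drop = FALSE]
}
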
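#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname tidy.scaffold_space
#' @method tidy hilbert_embedding
#' @export
tidy.hilbert_embedding <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' Tidy and summarize package result objects
#'
#' `tidy()` returns the underlying per-record tibble; `glance()` returns a
#' one-row summary.
#'
#' @param x A `scaffold_space`, `hilbert_embedding` or
#'   `distance_correlation`.
#' @param ... Ignored.
#' @return A tibble.
#' @method tidy scaffold_space
#' @export
tidy.scaffold_space <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidy.scaffold_space
#' @method tidy distance_correlation
#' @export
tidy.distance_correlation <- function(x, ...) {
  as_tibble(unclass_keep_tbl(x))
}

#' @rdname tidy.scaffold_space
#' @method glance scaffold_space
#' @export
glance.scaffold_space <- function(x, ...) {
  tibble(n_scaffolds = nrow(x),
         n_dropped = attr(x, "n_dropped") %||% NA_integer_,
         source = attr(x, "source") %||% NA_character_,
         dedup = attr(x, "dedup") %||% NA_character_,
         checksum = attr(x, "checksum") %||% NA_character_)
}

#' @rdname tidy.scaffold_space
#' @method glance hilbert_embedding
#' @export
glance.hilbert_embedding <- function(x, ...) {
  skipped <- attr(x, "skipped")
  tibble(z = attr(x, "z"), n_side = attr(x, "n_side"),
         n_cells = attr(x, "n_cells"), bin_width = attr(x, "bin_width"),
         space_size = attr(x, "space_size"),
         n_embedded = nrow(x),
         n_skipped = if (is.null(skipped)) 0L else nrow(skipped),
         space_checksum = attr(x, "space_checksum"))
}

#' @rdname tidy.scaffold_space
#' @method glance distance_correlation
#' @export
glance.distance_correlation <- function(x, ...) {
  tibble(method = attr(x, "method"), n_subsets = nrow(x),
         mean = attr(x, "mean"), sd = attr(x, "sd"))
}

unclass_keep_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  for (a in c("z", "n_side", "n_cells", "bin_width", "space_size",
              "space_checksum", "skipped", "checksum", "source", "dedup",
              "n_dropped", "mean", "sd", "method", "mean_displacement")) {
    attr(x, a) <- NULL
  }
  x
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
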
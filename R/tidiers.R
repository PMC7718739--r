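#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a per-stain ratio result
#'
#' One row per stain with the fold-change ratio for that staining batch.
#'
#' @param x a `ratio_result` from [ratio_analysis()].
#' @param ... unused.
#' @return Tibble with columns `genotype_num`, `genotype_den`, `stain_id`,
#'   `ratio`.
#' @method tidy ratio_result
#' @export
tidy.ratio_result <- function(x, ...) {
  dplyr::mutate(x$per_stain, genotype_num = x$genotype_num,
                genotype_den = x$genotype_den, .before = 1)
}

#' One-row summary of a ratio result
#'
#' @param x a `ratio_result` from [ratio_analysis()].
#' @param ... unused.
#' @return One-row tibble: `genotype_num`, `genotype_den`, `mean_ratio`,
#'   `t_stat`, `df`, `p_value`, `n_stains`, `alternative`.
#' @method glance ratio_result
#' @export
glance.ratio_result <- function(x, ...) {
  tibble::tibble(genotype_num = x$genotype_num,
                 genotype_den = x$genotype_den,
                 mean_ratio = x$mean_ratio, t_stat = x$t_stat, df = x$df,
                 p_value = x$p_one_sample, n_stains = x$n_stains,
                 alternative = x$alternative)
}

#' Tidy a stripe set
#'
#' @param x a `stripe_set` from [segment_eve_stripes()].
#' @param ... unused.
#' @return Plain tibble of per-stripe metrics.
#' @method tidy stripe_set
#' @export
tidy.stripe_set <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Tidy a lateral trace
#'
#' @param x a `lateral_trace`.
#' @param ... unused.
#' @return Plain tibble with `bin`, `ap`, `value` (and `sem` when present).
#' @method tidy lateral_trace
#' @export
tidy.lateral_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
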
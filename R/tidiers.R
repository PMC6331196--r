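## broom-style tidiers ------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a drive/contingency test result
#'
#' @param x A `zt_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `statistic`, `p.value`,
#'   `alternative`, `null.value` and `branch`.
#' @method tidy zt_test
#' @export
tidy.zt_test <- function(x, ...) {
  tibble::tibble(
    method = x$statistic_name,
    statistic = x$statistic,
    p.value = x$p_value,
    alternative = x$alternative,
    null.value = x$null_probability,
    branch = x$branch
  )
}

#' @rdname tidy.zt_test
#' @method glance zt_test
#' @export
glance.zt_test <- function(x, ...) tidy.zt_test(x, ...)

#' Tidy a loss-rate estimate
#'
#' `tidy()` returns the per-chromosome loss table; `glance()` a one-row
#' summary with the pooled rate and the heterogeneity p-value.
#'
#' @param x A `zt_loss_rate` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy zt_loss_rate
#' @export
tidy.zt_loss_rate <- function(x, ...) x$per_chromosome

#' @rdname tidy.zt_loss_rate
#' @method glance zt_loss_rate
#' @export
glance.zt_loss_rate <- function(x, ...) {
  tibble::tibble(
    rate = x$rate, n_loss = x$n_loss, n_scored = x$n_scored, by = x$by,
    heterogeneity_statistic = x$heterogeneity$statistic,
    heterogeneity_p.value = x$heterogeneity$p_value
  )
}
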
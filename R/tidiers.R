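#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname fit_power_law
#' @param x A `power_law_fit`.
#' @param ... Unused.
tidy.power_law_fit <- function(x, ...) {
  tibble(term = c("log_A", "alpha"),
         estimate = c(log(x$A), x$alpha))
}

#' @export
#' @rdname fit_power_law
glance.power_law_fit <- function(x, ...) {
  tibble(A = x$A, alpha = x$alpha, r_squared = x$r_squared,
         t_min = unname(x$window["t_min"]), t_max = unname(x$window["t_max"]),
         n_points = x$n_points)
}

#' @export
#' @rdname pearson_linear_fit
#' @param x A `linear_fit`.
#' @param ... Unused.
tidy.linear_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope))
}

#' @export
#' @rdname pearson_linear_fit
glance.linear_fit <- function(x, ...) {
  tibble(r_squared = x$r_squared, p_two_tailed = x$p_two_tailed, n = x$n,
         slope = x$slope, intercept = x$intercept)
}
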
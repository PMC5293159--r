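#' Tidy a fitted fraction map
#'
#' @param x A `fraction_map`.
#' @param ... Unused.
#' @return One-row tibble: `replicate`, `a`, `b`, `n_anchors`, `mad`.
#' @method tidy fraction_map
#' @export
tidy.fraction_map <- function(x, ...) {
  tibble(replicate = x$replicate, a = x$a, b = x$b,
         n_anchors = x$n_anchors, mad = x$mad)
}

#' @rdname tidy.fraction_map
#' @method glance fraction_map
#' @export
glance.fraction_map <- function(x, ...) {
  tibble(n_anchors = x$n_anchors, mad = x$mad, rounds = x$rounds)
}

#' Tidy a fitted ratio mixture
#'
#' One row per mixture component, in ascending mean order.
#'
#' @param x A `cofrac_mixture` from [fit_ratio_mixture()].
#' @param ... Unused.
#' @return Tibble: `component`, `mean`, `sd`, `weight`.
#' @method tidy cofrac_mixture
#' @export
tidy.cofrac_mixture <- function(x, ...) {
  tibble(component = seq_len(x$k), mean = x$means, sd = x$sds,
         weight = x$weights)
}

#' @rdname tidy.cofrac_mixture
#' @method glance cofrac_mixture
#' @export
glance.cofrac_mixture <- function(x, ...) {
  tibble(k = x$k, n = x$n, loglik = x$loglik, converged = x$converged,
         n_iter = x$n_iter)
}
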
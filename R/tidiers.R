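#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy fitted model weights
#'
#' One row per model term (bias first), broom style.
#'
#' @param x A `secure_lr_fit`, `clear_lr_fit` or `fixed_lr_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.secure_lr_fit <- function(x, ...) x$weights

#' @rdname tidy.secure_lr_fit
#' @export
tidy.clear_lr_fit <- function(x, ...) x$weights

#' @rdname tidy.secure_lr_fit
#' @export
tidy.fixed_lr_fit <- function(x, ...) x$weights

#' One-row model summaries
#'
#' For a secure fit the summary includes the channel cost of the whole
#' protocol execution (rounds, messages, bytes per direction) alongside the
#' public training parameters.
#'
#' @param x A fitted model.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.secure_lr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, iterations = x$iterations,
                 learning_rate = x$learning_rate, variant = x$variant,
                 ring_bits = x$fmt$lam, frac_bits = x$fmt$a, int_bits = x$fmt$b,
                 rounds = x$session$rounds, messages = x$session$messages,
                 bytes_per_direction = x$session$bytes_a2b)
}

#' @rdname glance.secure_lr_fit
#' @export
glance.clear_lr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, iterations = x$iterations,
                 learning_rate = x$learning_rate)
}

#' @rdname glance.secure_lr_fit
#' @export
glance.fixed_lr_fit <- function(x, ...) {
  tibble::tibble(n = x$n, m = x$m, iterations = x$iterations,
                 learning_rate = x$learning_rate, trunc_model = x$trunc_model,
                 ring_bits = x$fmt$lam, frac_bits = x$fmt$a, int_bits = x$fmt$b)
}

#' Plot secure-model weights against a reference
#'
#' Scatter of the decoded secure weights against the float clear-trained
#' weights for the same job (points on the identity line mean the secure
#' protocol tracked the plaintext trainer).
#'
#' @param object A `secure_lr_fit`.
#' @param reference A `clear_lr_fit` or `fixed_lr_fit` on the same terms.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.secure_lr_fit <- function(object, reference, ...) {
  df <- dplyr::inner_join(
    dplyr::rename(object$weights, secure = "estimate"),
    dplyr::rename(reference$weights, reference = "estimate"),
    by = "term")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$secure)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference weight", y = "secure weight",
                  title = "Secure vs reference clipped-ReLU weights")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
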
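# broom-style accessors for fitted objects.

#' Tidy an EM abundance fit
#'
#' @param x an `iso_em_fit` from [em_abundance()].
#' @param ... unused.
#' @return a tibble with one row per isoform: `isoform_id`, `est_counts`,
#'   `tpm`, `theta`.
#' @method tidy iso_em_fit
#' @export
tidy.iso_em_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("isoform_id", "est_counts", "tpm",
                                 "theta")])
}

#' One-row summary of an EM abundance fit
#'
#' @param x an `iso_em_fit`.
#' @param ... unused.
#' @return a tibble with `n_isoforms`, `n_mapped`, `n_iter`, `converged`,
#'   `loglik` (final).
#' @method glance iso_em_fit
#' @export
glance.iso_em_fit <- function(x, ...) {
  ll <- attr(x, "loglik")
  tibble::tibble(n_isoforms = nrow(x),
                 n_mapped = attr(x, "n_mapped"),
                 n_iter = attr(x, "n_iter"),
                 converged = attr(x, "converged"),
                 loglik = if (length(ll)) ll[length(ll)] else NA_real_)
}

#' Tidy a differential screen
#'
#' @param x an `iso_de` tibble from [de_screen()].
#' @param ... unused.
#' @return the underlying per-isoform tibble.
#' @method tidy iso_de
#' @export
tidy.iso_de <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-row summary of a differential screen
#'
#' @param x an `iso_de`.
#' @param ... unused.
#' @return a tibble with `n_isoforms`, `n_pass`, `n_up`, `n_down`.
#' @method glance iso_de
#' @export
glance.iso_de <- function(x, ...) {
  tibble::tibble(n_isoforms = nrow(x), n_pass = sum(x$pass),
                 n_up = sum(x$pass & x$direction == "up"),
                 n_down = sum(x$pass & x$direction == "down"))
}
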
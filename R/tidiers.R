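#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an association scan
#'
#' @param x a `recmapr_scan`
#' @param ... unused
#' @return plain tibble of per-marker results, sorted by p_raw
#' @export
tidy.recmapr_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  dplyr::arrange(out, .data$p_raw)
}

#' One-row summary of an association scan
#'
#' @param x a `recmapr_scan`
#' @param ... unused
#' @return tibble: m, n_cases, n_controls, lambda, top_marker, min_p_raw,
#'   min_p_bonf
#' @export
glance.recmapr_scan <- function(x, ...) {
  top <- which.min(x$p_raw)
  tibble::tibble(
    m = attr(x, "m"), n_cases = attr(x, "n_cases"),
    n_controls = attr(x, "n_controls"), lambda = attr(x, "lambda"),
    top_marker = x$marker_id[top], min_p_raw = x$p_raw[top],
    min_p_bonf = x$p_bonf[top]
  )
}

#' @rdname tidy.recmapr_scan
#' @export
tidy.ase_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname glance.recmapr_scan
#' @export
glance.ase_result <- function(x, ...) {
  tibble::tibble(
    n_sites = nrow(x), alpha = attr(x, "alpha"),
    fc_threshold = attr(x, "fc_threshold"),
    n_balanced = sum(x$verdict == "balanced"),
    min_p = min(x$p), max_fold_change = max(x$fold_change)
  )
}
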
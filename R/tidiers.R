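#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a driver-model fit
#'
#' One row per coefficient: `term` and `estimate`, plus `class` (the
#' non-reference cluster) for multinomial fits and `std_error`/`p_value`
#' (Wald) for binary fits.
#'
#' @param x A `como_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.como_fit <- function(x, ...) {
  if (x$model == "multinomial") {
    m <- x$coefficients
    tibble::tibble(
      class = rep(rownames(m), times = ncol(m)),
      term = rep(colnames(m), each = nrow(m)),
      estimate = as.vector(m)
    )
  } else {
    dplyr::bind_rows(
      tibble::tibble(term = "(Intercept)",
                     estimate = unname(x$coefficients[1]),
                     std_error = NA_real_, p_value = NA_real_),
      tibble::tibble(term = x$wald$feature, estimate = x$wald$estimate,
                     std_error = x$wald$std_error, p_value = x$wald$p)
    )
  }
}

#' @rdname tidy.como_fit
#' @export
glance.como_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, kind = x$kind, n = x$n, k = x$k,
    loglik_model = x$loglik_model, loglik_null = x$loglik_null,
    mcfadden_r2 = x$mcfadden_r2, lrt_stat = x$lrt_stat, lrt_df = x$lrt_df,
    lrt_p = x$lrt_p, converged = x$converged,
    separation_flag = x$separation_flag
  )
}

#' Tidy a comorbidity clustering
#'
#' `tidy()` returns one row per gene with its cluster id; `glance()` one row
#' summarizing the model.
#'
#' @param x A `como_clusters`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.como_clusters <- function(x, ...) x$labels

#' @rdname tidy.como_clusters
#' @export
glance.como_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, within_ss = x$within_ss,
                 sizes = paste(x$sizes, collapse = "/"))
}
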
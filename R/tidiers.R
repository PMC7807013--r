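#' Tidy a Conway-Maxwell-Poisson regression
#'
#' @param x a `cmp_fit`.
#' @param ... unused.
#' @return one row per coefficient with estimate, SE, Wald z and p-value.
#' @method tidy cmp_fit
#' @export
tidy.cmp_fit <- function(x, ...) {
  z <- x$coefficients / x$se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' @rdname tidy.cmp_fit
#' @method glance cmp_fit
#' @export
glance.cmp_fit <- function(x, ...) {
  tibble::tibble(nu = x$nu, nu_se = x$nu_se, logLik = x$logLik,
                 AICc = aicc(x$logLik, x$k, x$n), k = x$k, n = x$n,
                 converged = x$converged)
}

#' Tidy the wing-growth calibration
#'
#' @param x a `wing_growth_model`.
#' @param ... unused.
#' @method tidy wing_growth_model
#' @export
tidy.wing_growth_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "age"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname tidy.wing_growth_model
#' @method glance wing_growth_model
#' @export
glance.wing_growth_model <- function(x, ...) {
  tibble::tibble(nest_sd = x$nest_sd, resid_sd = x$resid_sd,
                 r2_marginal = x$r2_marginal, n = x$n,
                 n_excluded = x$n_excluded)
}

#' Tidy the seasonal condition smoother
#'
#' `tidy()` reports the smooth terms (edf and approximate tests); `glance()`
#' the variance components; `augment()` returns the per-capture index table
#' (raw condition, z-scored condition and the relative-condition residual).
#'
#' @param x a `condition_smooth`.
#' @param ... unused.
#' @method tidy condition_smooth
#' @export
tidy.condition_smooth <- function(x, ...) {
  st <- summary(x$fit)$s.table
  tibble::tibble(term = rownames(st), edf = st[, "edf"],
                 statistic = st[, 3], p.value = st[, "p-value"])
}

#' @rdname tidy.condition_smooth
#' @method glance condition_smooth
#' @export
glance.condition_smooth <- function(x, ...) {
  tibble::tibble(n = x$n, bird_sd = x$bird_sd, resid_sd = x$resid_sd,
                 edf_total = x$edf)
}

#' @rdname tidy.condition_smooth
#' @method augment condition_smooth
#' @export
augment.condition_smooth <- function(x, ...) x$index

#' Tidy a selection table
#'
#' `tidy()` returns the ranking as a plain tibble; `glance()` one row with
#' the criterion name, number of candidates, \eqn{\hat c} (QAICc only) and
#' the final model.
#'
#' @param x a `selection_table`.
#' @param ... unused.
#' @method tidy selection_table
#' @export
tidy.selection_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.selection_table
#' @method glance selection_table
#' @export
glance.selection_table <- function(x, ...) {
  tibble::tibble(criterion = attr(x, "criterion_name"),
                 n_models = nrow(x),
                 chat = attr(x, "chat") %||% NA_real_,
                 final = x$model[x$final])
}
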
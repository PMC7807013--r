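#' Small-sample information criteria
#'
#' `aicc()` is Akaike's information criterion with the small-sample correction,
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}.}
#' `qaicc()` is the quasi-likelihood analogue used when a variance-inflation
#' factor \eqn{\hat c} has been estimated from an overdispersed (quasi)binomial
#' global model: \eqn{-2\ell} is divided by \eqn{\hat c} and one parameter is
#' added to `k` for \eqn{\hat c} itself.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters (see [rank_subsets()] for the
#'   counting convention used across a candidate set).
#' @param n number of observations; must exceed `k + 1`.
#' @param chat overdispersion estimate \eqn{\hat c \ge 1}.
#' @return the criterion value (scalar).
#' @examples
#' aicc(-47, k = 3, n = 20)   # 101.5
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
qaicc <- function(loglik, chat, k, n) {
  if (chat < 1) stop("`chat` must be >= 1 for QAICc", call. = FALSE)
  kq <- k + 1
  if (n <= kq + 1) {
    stop("QAICc undefined: n must exceed k + 2", call. = FALSE)
  }
  -2 * loglik / chat + 2 * kq + 2 * kq * (kq + 1) / (n - kq - 1)
}

#' Overdispersion estimate from a binomial global model
#'
#' \eqn{\hat c} = Pearson \eqn{\chi^2} / residual degrees of freedom, computed
#' from the most complex (global) model and applied to every sub-model in a
#' QAICc ranking. Values below 1 are floored at 1 (no credit for apparent
#' underdispersion in a quasi-binomial analysis).
#'
#' @param fit a fitted binomial `glm`.
#' @return scalar \eqn{\hat c \ge 1}; attribute `"raw"` carries the unfloored
#'   value.
#' @export
estimate_chat <- function(fit) {
  df <- stats::df.residual(fit)
  if (df <= 0) stop("cannot estimate overdispersion with zero residual df",
                    call. = FALSE)
  raw <- sum(stats::residuals(fit, type = "pearson")^2) / df
  structure(max(1, raw), raw = raw)
}

#' Describe a candidate global model
#'
#' A `model_spec` names the response, the fixed-effect terms of the global
#' model, the error family and (optionally) a random-intercept grouping and a
#' weights column. [rank_subsets()] expands it into all admissible sub-models.
#'
#' @param response response column name.
#' @param terms character vector of fixed-effect terms; interactions are given
#'   as `"a:b"` and are only ever fitted together with both main effects.
#' @param family one of `"gaussian"`, `"poisson"`, `"cmp"`, `"binomial"`,
#'   `"quasibinomial"`.
#' @param random optional grouping column for a random intercept (Gaussian
#'   mixed models only; fitted by maximum likelihood so that AICc comparisons
#'   across fixed structures are valid).
#' @param weights optional weights column ((quasi)binomial proportion models
#'   only, e.g. clutch size for fledging probability).
#' @return a `model_spec` object.
#' @export
model_spec <- function(response, terms, family = c("gaussian", "poisson",
                       "cmp", "binomial", "quasibinomial"),
                       random = NULL, weights = NULL) {
  family <- match.arg(family)
  if (!is.null(weights) && !family %in% c("binomial", "quasibinomial")) {
    stop("weights are only supported for (quasi)binomial models", call. = FALSE)
  }
  structure(list(response = response, terms = terms, family = family,
                 random = random, weights = weights),
            class = "model_spec")
}

# all subsets of `terms` respecting marginality: an interaction a:b is kept
# only when both a and b are present; always includes the null model.
admissible_subsets <- function(terms) {
  n <- length(terms)
  idx <- if (n == 0L) list(integer(0)) else
    unlist(lapply(0:n, function(k) utils::combn(n, k, simplify = FALSE)),
           recursive = FALSE)
  keep <- vapply(idx, function(i) {
    sub <- terms[i]
    ints <- sub[grepl(":", sub, fixed = TRUE)]
    all(vapply(ints, function(tt) {
      all(strsplit(tt, ":", fixed = TRUE)[[1]] %in% sub)
    }, logical(1)))
  }, logical(1))
  lapply(idx[keep], function(i) terms[i])
}

build_formula <- function(response, terms, random = NULL) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (!is.null(random)) rhs <- paste0(rhs, " + (1 | ", random, ")")
  stats::as.formula(paste(response, "~", rhs))
}

# Fit one candidate. Parameter counting convention (held fixed across a
# candidate set): fixed coefficients + 1 per variance component (residual,
# random intercept) + 1 for nu (CMP); QAICc adds 1 for chat internally.
fit_candidate <- function(spec, terms, data) {
  f <- build_formula(spec$response, terms, spec$random)
  w <- if (!is.null(spec$weights)) data[[spec$weights]] else NULL
  out <- switch(spec$family,
    gaussian = {
      if (!is.null(spec$random)) {
        fit <- lme4::lmer(f, data = data, REML = FALSE)
        p <- length(lme4::fixef(fit))
        list(fit = fit, k = p + 2L, logLik = as.numeric(stats::logLik(fit)),
             n = stats::nobs(fit))
      } else {
        fit <- stats::lm(f, data = data)
        list(fit = fit, k = length(stats::coef(fit)) + 1L,
             logLik = as.numeric(stats::logLik(fit)), n = stats::nobs(fit))
      }
    },
    poisson = {
      fit <- stats::glm(f, data = data, family = stats::poisson())
      list(fit = fit, k = length(stats::coef(fit)),
           logLik = as.numeric(stats::logLik(fit)), n = stats::nobs(fit))
    },
    cmp = {
      fit <- fit_cmp_regression(f, data)
      list(fit = fit, k = fit$k, logLik = fit$logLik, n = fit$n,
           converged = fit$converged)
    },
    binomial = ,
    quasibinomial = {
      data$.w <- if (is.null(w)) rep(1, nrow(data)) else w
      fit <- suppressWarnings(
        stats::glm(f, data = data, family = stats::binomial(), weights = .w)
      )
      list(fit = fit, k = length(stats::coef(fit)),
           logLik = as.numeric(stats::logLik(fit)), n = stats::nobs(fit))
    }
  )
  if (is.null(out$converged)) {
    out$converged <- !inherits(out$fit, "glm") || out$fit$converged
  }
  out$terms <- terms
  out
}

#' All-subsets model selection with the delta-2 / fewest-parameters rule
#'
#' Expands a global [model_spec()] into every sub-model that respects
#' marginality (interactions never appear without their main effects), fits
#' each, ranks by AICc -- or QAICc for the quasibinomial family, with
#' \eqn{\hat c} estimated once from the global binomial fit via
#' [estimate_chat()] -- and marks the competitive subset within 2 criterion
#' units of the best model. The final model is the member of that subset with
#' the fewest parameters, ties broken by the better criterion value. Model
#' averaging is deliberately not performed: candidate sets here contain
#' interaction terms, for which averaged coefficients are not interpretable.
#'
#' Non-convergent sub-models are dropped from the ranking with a message.
#'
#' @param spec a [model_spec()] describing the global model.
#' @param data data frame with all referenced columns.
#' @return a `selection_table`: a tibble with one row per fitted sub-model
#'   (`model` label, `k`, `logLik`, criterion, `delta`, `in_delta2`, `final`),
#'   ranked best-first, carrying the fitted objects, the spec, the final-model
#'   fit and (for QAICc) \eqn{\hat c} as attributes.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(60), g = gl(2, 30))
#' d$y <- 0.8 * d$x + rnorm(60)
#' rank_subsets(model_spec("y", c("x", "g"), "gaussian"), d)
#' @export
rank_subsets <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  subsets <- admissible_subsets(spec$terms)

  chat <- NULL
  if (spec$family == "quasibinomial") {
    global <- fit_candidate(spec, spec$terms, data)
    chat <- estimate_chat(global$fit)
  }

  fits <- vector("list", length(subsets))
  ok <- logical(length(subsets))
  for (i in seq_along(subsets)) {
    fits[[i]] <- tryCatch(fit_candidate(spec, subsets[[i]], data),
                          error = function(e) e)
    ok[i] <- !inherits(fits[[i]], "error") && isTRUE(fits[[i]]$converged)
  }
  if (!all(ok)) {
    message(sum(!ok), " sub-model(s) failed or did not converge; dropped")
  }
  fits <- fits[ok]
  if (!length(fits)) stop("no candidate model converged", call. = FALSE)

  crit <- vapply(fits, function(m) {
    if (is.null(chat)) aicc(m$logLik, m$k, m$n)
    else qaicc(m$logLik, chat, m$k, m$n)
  }, numeric(1))

  tab <- tibble::tibble(
    model = vapply(fits, function(m)
      if (length(m$terms)) paste(m$terms, collapse = " + ") else "1",
      character(1)),
    k = vapply(fits, function(m) m$k, numeric(1)) +
      if (is.null(chat)) 0 else 1,
    logLik = vapply(fits, function(m) m$logLik, numeric(1)),
    criterion = crit
  )
  ord <- order(tab$criterion)
  tab <- tab[ord, ]
  fits <- fits[ord]
  sel <- select_delta2(tab$criterion, tab$k)
  tab$delta <- sel$delta
  tab$in_delta2 <- sel$in_delta2
  tab$final <- sel$final
  final_i <- which(sel$final)

  structure(tab, class = c("selection_table", class(tab)),
            fits = fits, spec = spec, chat = chat,
            criterion_name = if (is.null(chat)) "AICc" else "QAICc",
            final_fit = fits[[final_i]]$fit,
            final_terms = fits[[final_i]]$terms)
}

#' Apply the delta-2 / fewest-parameters selection rule
#'
#' Given criterion values and parameter counts for a candidate set, marks the
#' competitive subset (within 2 units of the best) and selects its member
#' with the fewest parameters, ties broken by the better criterion value.
#' Invariant to adding a constant to every criterion value.
#'
#' @param criterion (Q)AICc values.
#' @param k parameter counts.
#' @return list with `delta`, `in_delta2` and the logical `final` selector.
#' @examples
#' select_delta2(c(100, 101.1, 103), k = c(4, 2, 1))$final  # picks the k = 2
#' @export
select_delta2 <- function(criterion, k) {
  stopifnot(length(criterion) == length(k))
  delta <- criterion - min(criterion)
  in_delta2 <- delta <= 2
  cand <- which(in_delta2)
  final_i <- cand[order(k[cand], criterion[cand])][1]
  list(delta = delta, in_delta2 = in_delta2,
       final = seq_along(criterion) == final_i)
}

#' Extract the final model from a selection table
#' @param x a `selection_table` from [rank_subsets()].
#' @return the fitted model object selected by the delta-2 / fewest-parameters
#'   rule.
#' @export
final_model <- function(x) {
  stopifnot(inherits(x, "selection_table"))
  attr(x, "final_fit")
}

#' @export
print.selection_table <- function(x, ...) {
  cat("Model selection (", attr(x, "criterion_name"), ", n models = ",
      nrow(x), ")\n", sep = "")
  if (!is.null(attr(x, "chat"))) {
    cat("  c-hat =", format(attr(x, "chat"), digits = 4), "\n")
  }
  cat("  final:", x$model[x$final], "\n\n")
  NextMethod()
}

#' Post-hoc contrasts for a strategy-by-area interaction
#'
#' Given a final model that retains the strategy-by-area interaction, computes
#' the migrant-minus-resident contrast within each area and the between-area
#' contrast within each strategy, with a single-step adjustment based on the
#' joint distribution of the contrast statistics (multcomp's max-t test).
#' Refuses to run when the final model does not contain the interaction,
#' because within-area strategy contrasts are then not a model quantity.
#'
#' @param fit a fitted `lm` or `lmerMod` whose fixed effects include
#'   `strategy`, `area` and their interaction (treatment contrasts, two levels
#'   each).
#' @param strategy,area names of the factor columns.
#' @return a tibble with contrast labels, estimates, SEs, adjusted p-values
#'   and the adjustment method name.
#' @export
posthoc_contrasts <- function(fit, strategy = "strategy", area = "area") {
  cf <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  nm <- names(cf)
  is_int <- grepl(":", nm, fixed = TRUE)
  s_main <- nm[!is_int & startsWith(nm, strategy)]
  a_main <- nm[!is_int & startsWith(nm, area)]
  inter <- nm[is_int & grepl(strategy, nm, fixed = TRUE) &
                grepl(area, nm, fixed = TRUE)]
  if (length(s_main) != 1L || length(a_main) != 1L || length(inter) != 1L) {
    stop("final model does not contain the ", strategy, " x ", area,
         " interaction (with both main effects); post-hoc contrasts refused",
         call. = FALSE)
  }
  s_lab2 <- sub(strategy, "", s_main)   # non-reference strategy level
  a_lab2 <- sub(area, "", a_main)       # non-reference area level

  K <- matrix(0, nrow = 4, ncol = length(cf), dimnames = list(c(
    paste0(s_lab2, " - ref strategy | ref area"),
    paste0(s_lab2, " - ref strategy | ", a_lab2),
    paste0(a_lab2, " - ref area | ref strategy"),
    paste0(a_lab2, " - ref area | ", s_lab2)
  ), nm))
  K[1, s_main] <- 1
  K[2, c(s_main, inter)] <- 1
  K[3, a_main] <- 1
  K[4, c(a_main, inter)] <- 1

  gh <- multcomp::glht(fit, linfct = K)
  sm <- summary(gh)  # default: single-step max-t adjustment
  tibble::tibble(
    contrast = rownames(K),
    estimate = as.numeric(sm$test$coefficients),
    se = as.numeric(sm$test$sigma),
    statistic = as.numeric(sm$test$tstat),
    p_adjusted = as.numeric(sm$test$pvalues),
    method = "single-step (joint max-t)"
  )
}
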
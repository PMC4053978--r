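#' Multiplicative wild-type carbon-by-nitrogen growth model
#'
#' Fits ordinary least squares to the natural logarithm of the wild-type
#' replicate growth rates with carbon main effects, nitrogen main effects
#' and carbon-by-nitrogen interaction terms under reference-cell coding
#' (glucose and ammonium as baselines). On the raw scale this is a
#' multiplicative model: independent nutrient contributions combine as
#' products, and a significant interaction term flags a condition whose
#' wild-type rate is not predicted by its sources' independent
#' contributions. Zero rates are excluded from the log fit and counted.
#'
#' @param wt_rates Tibble of wild-type replicate rates with columns
#'   `carbon`, `nitrogen`, `rate` (one row per replicate).
#' @param alpha Per-term significance level (default 0.01).
#' @return An object of class `cn_wt_fit`: a list with the underlying `lm`
#'   fit, a tidy `terms` tibble, `alpha` and the number of excluded zero
#'   rates. Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
fit_wt_model <- function(wt_rates, alpha = 0.01) {
  stopifnot(all(c("carbon", "nitrogen", "rate") %in% names(wt_rates)),
            alpha > 0, alpha < 1)
  d <- wt_rates[is.finite(wt_rates$rate), ]
  n_zero <- sum(d$rate <= 0)
  d <- d[d$rate > 0, ]
  counts <- dplyr::count(d, .data$carbon, .data$nitrogen)
  empty <- counts[counts$n < 2, ]
  present <- paste(counts$carbon, counts$nitrogen)
  grid <- tidyr::expand_grid(carbon = unique(d$carbon),
                             nitrogen = unique(d$nitrogen))
  absent <- grid[!paste(grid$carbon, grid$nitrogen) %in% present, ]
  if (nrow(absent) > 0 || nrow(empty) > 0) {
    bad <- dplyr::bind_rows(absent[, c("carbon", "nitrogen")],
                            empty[, c("carbon", "nitrogen")])
    stop("condition(s) without at least 2 positive wild-type rates: ",
         paste(paste0(bad$carbon, ":", bad$nitrogen), collapse = ", "),
         call. = FALSE)
  }
  d$carbon <- stats::relevel(factor(d$carbon), ref = "glucose")
  d$nitrogen <- stats::relevel(factor(d$nitrogen), ref = "ammonium")
  fit <- stats::lm(log(rate) ~ carbon * nitrogen, data = d)
  terms <- wt_term_table(fit, alpha)
  structure(list(fit = fit, terms = terms, alpha = alpha, n_zero = n_zero,
                 n_used = nrow(d)),
            class = "cn_wt_fit")
}

wt_term_table <- function(fit, alpha) {
  cf <- summary(fit)$coefficients
  term <- rownames(cf)
  strip <- function(x) sub("^carbon", "", sub("nitrogen", "", x))
  parts <- strsplit(term, ":", fixed = TRUE)
  type <- dplyr::case_when(
    term == "(Intercept)" ~ "intercept",
    lengths(parts) == 2 ~ "interaction",
    startsWith(term, "carbon") ~ "carbon",
    TRUE ~ "nitrogen"
  )
  carbon <- ifelse(type %in% c("carbon", "interaction"),
                   strip(vapply(parts, `[`, "", 1L)), NA_character_)
  nitrogen <- ifelse(type == "interaction",
                     strip(vapply(parts, `[`, "", 2L)),
                     ifelse(type == "nitrogen", strip(term), NA_character_))
  tibble::tibble(
    term = term, type = type, carbon = carbon, nitrogen = nitrogen,
    estimate = cf[, "Estimate"], std.error = cf[, "Std. Error"],
    statistic = cf[, "t value"], p.value = cf[, "Pr(>|t|)"],
    significant = cf[, "Pr(>|t|)"] < alpha
  )
}

#' @export
print.cn_wt_fit <- function(x, ...) {
  cat("Wild-type carbon x nitrogen log-linear model\n")
  cat("  observations:", x$n_used, "(", x$n_zero, "zero rates excluded )\n")
  ia <- x$terms[x$terms$type == "interaction", ]
  cat("  interaction terms:", nrow(ia), "of which",
      sum(ia$significant), "significant at alpha =", x$alpha, "\n")
  invisible(x)
}

#' @method tidy cn_wt_fit
#' @export
tidy.cn_wt_fit <- function(x, ...) x$terms

#' @method glance cn_wt_fit
#' @export
glance.cn_wt_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma,
                 nobs = x$n_used, n_zero_excluded = x$n_zero,
                 df.residual = x$fit$df.residual)
}

#' Conditions whose wild-type rate shows no carbon-by-nitrogen interaction
#'
#' Returns the non-reference condition cells whose interaction term is not
#' significant at the model's alpha --- the conditions where the wild-type
#' growth rate is predicted by independent carbon and nitrogen
#' contributions.
#'
#' @param model A `cn_wt_fit` from [fit_wt_model()].
#' @return Tibble with columns `carbon`, `nitrogen`, `estimate`, `p.value`.
#' @export
independent_conditions <- function(model) {
  stopifnot(inherits(model, "cn_wt_fit"))
  ia <- model$terms[model$terms$type == "interaction" &
                      !model$terms$significant, ]
  ia[, c("carbon", "nitrogen", "estimate", "p.value")]
}

#' Compare multiplicative and additive wild-type models
#'
#' Fits the carbon-by-nitrogen model both on the log scale (multiplicative
#' contributions) and on the raw rate scale (additive contributions) and
#' reports fit summaries on a common response scale: the log-model
#' likelihood is converted to the raw-rate scale by the log-normal change of
#' variables, so the information criteria are directly comparable.
#'
#' @inheritParams fit_wt_model
#' @return Tibble with one row per model family: `model`, `rss` (on its own
#'   response scale), `logLik` (raw-rate scale), `aic`, and `preferred`
#'   marking the lower-AIC family.
#' @export
compare_model_families <- function(wt_rates) {
  d <- wt_rates[is.finite(wt_rates$rate) & wt_rates$rate > 0, ]
  d$carbon <- factor(d$carbon)
  d$nitrogen <- factor(d$nitrogen)
  fit_mult <- stats::lm(log(rate) ~ carbon * nitrogen, data = d)
  fit_add <- stats::lm(rate ~ carbon * nitrogen, data = d)
  ll_mult <- as.numeric(stats::logLik(fit_mult)) - sum(log(d$rate))
  ll_add <- as.numeric(stats::logLik(fit_add))
  k <- length(stats::coef(fit_mult)) + 1 # same parameter count + sigma
  out <- tibble::tibble(
    model = c("multiplicative", "additive"),
    rss = c(sum(stats::residuals(fit_mult)^2),
            sum(stats::residuals(fit_add)^2)),
    logLik = c(ll_mult, ll_add),
    aic = -2 * c(ll_mult, ll_add) + 2 * k
  )
  out$preferred <- out$aic == min(out$aic)
  out
}

#' @method autoplot cn_wt_fit
#' @export
autoplot.cn_wt_fit <- function(object, ...) {
  d <- object$terms[object$terms$type != "intercept", ]
  d$label <- ifelse(d$type == "interaction",
                    paste0(d$carbon, " x ", d$nitrogen),
                    ifelse(d$type == "carbon", d$carbon, d$nitrogen))
  d$label <- factor(d$label, levels = d$label[order(d$type, -d$estimate)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$estimate,
                                  fill = .data$type,
                                  alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                        ymax = .data$estimate + .data$std.error),
                           width = 0.3, alpha = 1) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.4),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "log-rate term estimate",
                  fill = "term type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
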
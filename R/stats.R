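#' ANCOVA of formulation and droplet size on local oxidation rates
#'
#' Ordinary-least-squares fit of \code{rate ~ formulation + 1/radius}
#' (reference-coded factor, homogeneous slopes). The formulation effect is
#' tested by the extra-sum-of-squares F comparing the full model with the
#' covariate-only model; the size effect by the t-test on the covariate
#' coefficient in the full model. Results are invariant to group ordering.
#'
#' @param rates rate table from \code{\link{buildRateTable}}.
#' @param response \code{"c_lip"} or \code{"c_prot"}.
#' @param alpha significance level (default 0.05).
#' @return list of class \code{"ancovaResult"}: F, df, p for the
#'   formulation factor; beta (day^-1 um), t, p for the inverse-radius
#'   covariate; group-adjusted means (at the overall mean 1/r); n per
#'   group; the full \code{lm} fit.
#' @export
rateAncova <- function(rates, response = c("c_lip", "c_prot"),
                       alpha = 0.05) {
  response <- match.arg(response)
  d <- data.frame(y = rates[[response]], group = factor(rates$group),
                  inv_radius = rates$inv_radius)
  d <- d[complete.cases(d), ]
  d$group <- droplevels(d$group)
  ng <- table(d$group)
  if (length(ng) < 2L)
    stop("ANCOVA needs at least two formulation groups")
  if (any(ng < 3L))
    stop("each group needs at least 3 converged rates")
  if (sd(d$inv_radius) == 0)
    stop("degenerate covariate: all droplet radii equal")
  full <- lm(y ~ group + inv_radius, data = d)
  reduced <- lm(y ~ inv_radius, data = d)
  cmp <- anova(reduced, full)
  co <- summary(full)$coefficients["inv_radius", ]
  adj <- predict(full, newdata = data.frame(
    group = factor(levels(d$group), levels = levels(d$group)),
    inv_radius = mean(d$inv_radius)))
  structure(list(
    response = response,
    F = cmp$F[2], df1 = cmp$Df[2], df2 = cmp$Res.Df[2], p = cmp$`Pr(>F)`[2],
    beta = unname(co["Estimate"]), beta_se = unname(co["Std. Error"]),
    beta_t = unname(co["t value"]), beta_p = unname(co["Pr(>|t|)"]),
    adjusted_means = setNames(as.numeric(adj), levels(d$group)),
    n = as.integer(ng), groups = names(ng), alpha = alpha, fit = full),
    class = "ancovaResult")
}

#' @export
print.ancovaResult <- function(x, ...) {
  cat(sprintf("ANCOVA on %s (alpha = %g)\n", x$response, x$alpha))
  cat(sprintf("  formulation: F(%d, %d) = %.4g, p = %.3g%s\n",
              x$df1, x$df2, x$F, x$p,
              if (x$p < x$alpha) " *" else ""))
  cat(sprintf("  1/radius:    beta = %.4g /day/um, t = %.3g, p = %.3g%s\n",
              x$beta, x$beta_t, x$beta_p,
              if (x$beta_p < x$alpha) " *" else ""))
  invisible(x)
}

#' Within-group regression of rate on inverse radius
#'
#' Simple linear regression of the local oxidation rate on 1/radius inside
#' one formulation group, with a two-sided t-test on the slope.
#'
#' @param rates rate table from \code{\link{buildRateTable}}.
#' @param response \code{"c_lip"} or \code{"c_prot"}.
#' @param group formulation label to subset.
#' @return list of class \code{"slopeResult"}: slope (day^-1 um),
#'   intercept (day^-1), slope standard error, t, p, n.
#' @export
withinGroupRegression <- function(rates, response = c("c_lip", "c_prot"),
                                  group) {
  response <- match.arg(response)
  d <- data.frame(y = rates[[response]], g = rates$group,
                  inv_radius = rates$inv_radius)
  d <- d[complete.cases(d) & d$g == group, ]
  if (nrow(d) < 3L) stop("need at least 3 rates in the group")
  if (sd(d$inv_radius) == 0)
    stop("degenerate covariate: all droplet radii equal")
  fit <- lm(y ~ inv_radius, data = d)
  co <- summary(fit)$coefficients
  structure(list(
    response = response, group = group,
    slope = co["inv_radius", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    slope_se = co["inv_radius", "Std. Error"],
    t = co["inv_radius", "t value"], p = co["inv_radius", "Pr(>|t|)"],
    n = nrow(d), fit = fit), class = "slopeResult")
}

#' @export
print.slopeResult <- function(x, ...) {
  cat(sprintf(
    "Group %s, %s ~ 1/r: slope = %.4g /day/um (se %.3g), t = %.3g, p = %.3g, n = %d\n",
    x$group, x$response, x$slope, x$slope_se, x$t, x$p, x$n))
  invisible(x)
}

#' Tidy summary of oxidation-rate tests
#'
#' @param ... any mix of \code{ancovaResult} and \code{slopeResult}
#'   objects (or a single list of them).
#' @param alpha significance flag level.
#' @return data.frame with one row per test: test, response, group,
#'   statistic, estimate, p, n, significant.
#' @export
summarizeTests <- function(..., alpha = 0.05) {
  objs <- list(...)
  if (length(objs) == 1L && !inherits(objs[[1]], c("ancovaResult",
                                                   "slopeResult")))
    objs <- objs[[1]]
  rows <- lapply(objs, function(o) {
    if (inherits(o, "ancovaResult"))
      data.frame(test = "ancova_formulation", response = o$response,
                 group = "all", statistic = o$F, estimate = NA_real_,
                 p = o$p, n = sum(o$n))
    else if (inherits(o, "slopeResult"))
      data.frame(test = "slope_vs_inv_radius", response = o$response,
                 group = o$group, statistic = o$t, estimate = o$slope,
                 p = o$p, n = o$n)
    else stop("unsupported result object")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(test = character(0), response = character(0),
                      group = character(0), statistic = numeric(0),
                      estimate = numeric(0), p = numeric(0), n = integer(0))
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}
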
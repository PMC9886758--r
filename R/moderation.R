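# Moderated regression of behaviour on an FC marker x genotype interaction,
# with the interaction's incremental variance share and Johnson-Neyman
# region of significance for the conditional genotype effect across FC.

#' Moderated multiple regression of behaviour on FC x genotype
#'
#' Ordinary least squares of `y ~ x + w + x:w + covariates`, where `x` is
#' the (uncentered) FC marker and `w` the 0/1 carrier indicator, plus the
#' fit of the same model without the interaction; the increase in variance
#' explained `delta_R2 = R2_full - R2_reduced` quantifies the moderation.
#' `x` is deliberately left on its raw scale so that Johnson-Neyman
#' thresholds are reported in PLV units.
#'
#' @param y outcome (e.g. delayed recall).
#' @param x continuous focal predictor (FC marker).
#' @param w moderator: 0/1 vector or a two-level factor (second level = 1);
#'   must have both levels present.
#' @param covariates optional covariates (e.g. age, education).
#' @param data optional data frame to look up `y`, `x`, `w`, covariates by
#'   name.
#' @return An object of class `moderation_fit`: coefficients `b0`, `b1`
#'   (x), `b2` (w), `b3` (x:w) and covariate terms, their covariance
#'   matrix, `R2_full`, `R2_reduced`, `delta_R2`, `n`, `df`, and the
#'   underlying `lm` fit.
#' @export
fit_moderation <- function(y, x, w, covariates = NULL, data = NULL) {
  if (!is.null(data)) {
    get1 <- function(v) if (is.character(v) && length(v) == 1L) data[[v]] else v
    y <- get1(y)
    x <- get1(x)
    w <- get1(w)
    if (is.character(covariates)) covariates <- data[covariates]
  }
  if (is.factor(w) || is.character(w)) {
    w <- as.factor(w)
    if (nlevels(droplevels(w)) != 2L)
      stop("moderator must have exactly two levels")
    w <- as.integer(w == levels(w)[2L])
  }
  w <- as.numeric(w)
  if (length(unique(w)) != 2L)
    stop("moderator must take both values")
  n <- length(y)
  if (n < 10L) stop("need at least 10 observations")
  C <- prepare_covariates(covariates, n)
  dat <- data.frame(y = y, x = x, w = w, xw = x * w)
  if (ncol(C)) dat <- cbind(dat, as.data.frame(C))
  if (anyNA(dat)) stop("NA in moderation inputs")
  full <- stats::lm(y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) stop("collinear design")
  red <- stats::lm(y ~ ., data = dat[, setdiff(names(dat), "xw")])
  R2f <- summary(full)$r.squared
  R2r <- summary(red)$r.squared
  cf <- stats::coef(full)
  names(cf)[1:4] <- c("b0", "b1", "b2", "b3")
  V <- stats::vcov(full)
  dimnames(V) <- list(names(cf), names(cf))
  sm <- summary(full)$coefficients
  rownames(sm) <- names(cf)
  structure(
    list(coefficients = cf, vcov = V, table = sm,
         R2_full = R2f, R2_reduced = R2r, delta_R2 = max(0, R2f - R2r),
         n = n, df = full$df.residual, fit = full),
    class = "moderation_fit"
  )
}

#' @export
coef.moderation_fit <- function(object, ...) object$coefficients

#' @export
vcov.moderation_fit <- function(object, ...) object$vcov

#' @export
residuals.moderation_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.moderation_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  if (!"xw" %in% names(newdata)) newdata$xw <- newdata$x * newdata$w
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat(sprintf(
    "moderation_fit: n = %d, R2 = %.4f (delta_R2 for x:w = %.4f)\n",
    x$n, x$R2_full, x$delta_R2
  ))
  stats::printCoefmat(x$table, ...)
  invisible(x)
}

#' @export
summary.moderation_fit <- function(object, ...) {
  out <- list(table = object$table, R2_full = object$R2_full,
              R2_reduced = object$R2_reduced, delta_R2 = object$delta_R2,
              n = object$n, df = object$df)
  class(out) <- "summary.moderation_fit"
  out
}

#' @export
print.summary.moderation_fit <- function(x, ...) {
  stats::printCoefmat(x$table, ...)
  cat(sprintf("R2 full %.4f, reduced %.4f, delta_R2 %.4f (n = %d, df = %d)\n",
              x$R2_full, x$R2_reduced, x$delta_R2, x$n, x$df))
  invisible(x)
}

#' Johnson-Neyman region of significance
#'
#' For the default probe — the conditional effect of the moderator `w`
#' across values of the focal FC variable `x` — solves
#' `theta(x) = b2 + b3 x`, `Var(theta) = V22 + x^2 V33 + 2 x V23`, for the
#' values of `x` at which `|theta| / SE(theta)` equals the two-sided
#' critical t on the model's residual degrees of freedom: the real roots of
#' the quadratic `theta(x)^2 = t_crit^2 Var(theta(x))`. The region is then
#' classified by probing `t(x)` between and beyond the thresholds. With
#' `probe = "x_across_w"` the conditional effect of `x` is simply reported
#' at `w = 0` and `w = 1` (a binary moderator has no continuum to solve
#' over).
#'
#' @param fit a `moderation_fit`.
#' @param probe which conditional effect to probe.
#' @param alpha significance level.
#' @return For the default probe, an object of class `jn_region`: list with
#'   `thresholds` (0-2 sorted values of `x`), `direction` (textual region
#'   classification), `alpha`, `t_crit`, `df`, and the conditional-effect
#'   function `theta_t(x)` returning the t statistic.
#' @export
johnson_neyman <- function(fit, probe = c("w_across_x", "x_across_w"),
                           alpha = 0.05) {
  stopifnot(inherits(fit, "moderation_fit"))
  probe <- match.arg(probe)
  V <- fit$vcov
  cf <- fit$coefficients
  tcrit <- stats::qt(1 - alpha / 2, fit$df)
  if (probe == "x_across_w") {
    eff <- function(wv) {
      th <- cf[["b1"]] + cf[["b3"]] * wv
      se <- sqrt(V["b1", "b1"] + wv^2 * V["b3", "b3"] +
                   2 * wv * V["b1", "b3"])
      c(effect = th, se = se, t = th / se,
        p = 2 * stats::pt(-abs(th / se), fit$df))
    }
    return(structure(
      list(probe = probe, at = list(`w=0` = eff(0), `w=1` = eff(1)),
           alpha = alpha, t_crit = tcrit, df = fit$df),
      class = "jn_region"
    ))
  }
  v22 <- V["b2", "b2"]
  v33 <- V["b3", "b3"]
  v23 <- V["b2", "b3"]
  if (v22 <= 0 || v33 < 0) stop("non-positive variance estimates")
  b2 <- cf[["b2"]]
  b3 <- cf[["b3"]]
  theta_t <- function(x) {
    (b2 + b3 * x) / sqrt(v22 + x^2 * v33 + 2 * x * v23)
  }
  A <- b3^2 - tcrit^2 * v33
  B <- 2 * (b2 * b3 - tcrit^2 * v23)
  Cc <- b2^2 - tcrit^2 * v22
  disc <- B^2 - 4 * A * Cc
  thresholds <- numeric(0)
  if (abs(A) < .Machine$double.eps^0.75) {
    if (abs(B) > .Machine$double.eps^0.5) thresholds <- -Cc / B
  } else if (disc >= 0) {
    thresholds <- sort(c((-B - sqrt(disc)) / (2 * A),
                         (-B + sqrt(disc)) / (2 * A)))
  }
  # polish roots of t(x)^2 = tcrit^2 and classify the region
  thresholds <- vapply(thresholds, function(r) {
    g <- function(x) theta_t(x)^2 - tcrit^2
    h <- max(1e-6, abs(r) * 1e-6)
    out <- tryCatch(
      stats::uniroot(g, c(r - h, r + h), extendInt = "yes",
                     tol = .Machine$double.eps^0.75)$root,
      error = function(e) r
    )
    out
  }, numeric(1))
  probes <- if (length(thresholds) == 0L) 0 else
    c(min(thresholds) - 1, if (length(thresholds) == 2L)
      mean(thresholds), max(thresholds) + 1)
  sig <- abs(theta_t(probes)) > tcrit
  direction <- if (length(thresholds) == 0L) {
    if (all(sig)) "significant everywhere" else "significant nowhere"
  } else if (length(thresholds) == 1L) {
    if (sig[1]) "significant below the threshold"
    else "significant above the threshold"
  } else {
    if (sig[2]) "significant between the thresholds"
    else "significant outside the thresholds"
  }
  structure(
    list(probe = probe, thresholds = thresholds, direction = direction,
         alpha = alpha, t_crit = tcrit, df = fit$df, theta_t = theta_t),
    class = "jn_region"
  )
}

#' @export
print.jn_region <- function(x, ...) {
  if (x$probe == "x_across_w") {
    cat("conditional effect of x at the two moderator levels:\n")
    for (nm in names(x$at)) {
      e <- x$at[[nm]]
      cat(sprintf("  %s: effect %.4g (t = %.3f, p = %.4g)\n",
                  nm, e[["effect"]], e[["t"]], e[["p"]]))
    }
  } else if (length(x$thresholds) == 0L) {
    cat(sprintf("Johnson-Neyman: no finite threshold; %s (alpha = %g)\n",
                x$direction, x$alpha))
  } else {
    cat(sprintf("Johnson-Neyman thresholds at x = %s; %s (alpha = %g)\n",
                paste(signif(x$thresholds, 6), collapse = ", "),
                x$direction, x$alpha))
  }
  invisible(x)
}

#' Stratified moderation profile by diagnostic group
#'
#' Reruns the moderated regression and Johnson-Neyman probe separately in
#' each diagnostic group (after excluding rare APOE genotypes), and
#' tabulates the age-adjusted Spearman correlation between marker and
#' outcome within every group x carrier cell — the stratified descriptive
#' profile of how the FC-memory association varies with genotype.
#'
#' @param cohort cohort data frame (columns `group`, `apoe_e4`,
#'   `delayed_recall`, `age`, `education`, plus the marker).
#' @param marker per-subject marker vector, or the name of a cohort column.
#' @param y,covariates outcome column and covariate columns for the fits.
#' @param min_stratum strata smaller than this are skipped with a warning.
#' @return An object of class `moderation_profile`: per-group list of
#'   `moderation_fit` + `jn_region`, and `rho_table` with one row per
#'   group x carrier cell.
#' @export
subgroup_moderation_profile <- function(cohort, marker,
                                        y = "delayed_recall",
                                        covariates = c("age", "education"),
                                        min_stratum = 10L) {
  if (is.character(marker) && length(marker) == 1L)
    marker <- cohort[[marker]]
  cohort$...marker <- marker
  cohort <- drop_rare_genotypes(cohort)
  groups <- levels(as.factor(cohort$group))
  fits <- list()
  rho_rows <- list()
  for (g in groups) {
    sub <- cohort[cohort$group == g, , drop = FALSE]
    res <- tryCatch({
      f <- fit_moderation(sub[[y]], sub$...marker, sub$apoe_e4 == "carrier",
                          covariates = sub[, covariates, drop = FALSE])
      list(fit = f, jn = johnson_neyman(f))
    }, error = function(e) {
      warning(sprintf("group %s skipped: %s", g, conditionMessage(e)))
      NULL
    })
    fits[[g]] <- res
    for (cr in c("noncarrier", "carrier")) {
      cell <- sub[sub$apoe_e4 == cr, , drop = FALSE]
      if (nrow(cell) < min_stratum) {
        warning(sprintf("stratum %s/%s skipped (n = %d)", g, cr, nrow(cell)))
        next
      }
      ps <- partial_spearman(cell$...marker, cell[[y]],
                             covariates = cell$age)
      rho_rows[[length(rho_rows) + 1L]] <- data.frame(
        group = g, apoe_e4 = cr, n = nrow(cell),
        rho = ps$rho, p = ps$p, stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(fits = fits, rho_table = do.call(rbind, rho_rows)),
    class = "moderation_profile"
  )
}

#' @export
print.moderation_profile <- function(x, ...) {
  for (g in names(x$fits)) {
    cat(sprintf("== group %s ==\n", g))
    if (is.null(x$fits[[g]])) {
      cat("  (skipped)\n")
      next
    }
    b3 <- x$fits[[g]]$fit$table["b3", ]
    cat(sprintf("  interaction b3 = %.4g (t = %.3f, p = %.4g), delta_R2 = %.4f\n",
                b3[["Estimate"]], b3[["t value"]], b3[["Pr(>|t|)"]],
                x$fits[[g]]$fit$delta_R2))
    print(x$fits[[g]]$jn)
  }
  cat("stratified age-adjusted Spearman rho:\n")
  print(x$rho_table, row.names = FALSE)
  invisible(x)
}
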
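# Structure-function association tables with FDR control, and
# covariate-adjusted group contrasts of cluster markers.

#' Correlate FC markers with cohort measures under FDR control
#'
#' Spearman correlations between each marker and each measure, computed for
#' the whole sample and within each group, with Benjamini-Hochberg
#' correction applied within each (marker, group) family across measures
#' (the family definition is recorded in the output and configurable in
#' spirit: correct a different slice by filtering the table and re-running
#' `p.adjust` yourself).
#'
#' @param markers named list of per-subject marker vectors (a single vector
#'   is accepted and named `"marker"`).
#' @param measures data frame of per-subject measures (numeric columns).
#' @param group optional factor splitting subjects into groups; rows for
#'   each level are produced in addition to the whole-sample rows.
#' @param min_n minimum subjects per (group, measure) cell.
#' @return A data frame of class `association_table` with columns `marker`,
#'   `measure`, `group`, `n`, `rho`, `p_raw`, `p_fdr`, `flagged`. Constant
#'   measures are flagged and excluded from their correction family.
#' @export
marker_associations <- function(markers, measures, group = NULL,
                                min_n = 5L) {
  if (!is.list(markers)) markers <- list(marker = markers)
  if (is.null(names(markers)))
    names(markers) <- paste0("marker", seq_along(markers))
  measures <- as.data.frame(measures)
  n <- nrow(measures)
  splits <- list(all = rep(TRUE, n))
  if (!is.null(group)) {
    group <- as.factor(group)
    for (g in levels(group)) splits[[g]] <- group == g
  }
  rows <- list()
  for (mk in names(markers)) {
    x <- markers[[mk]]
    if (length(x) != n) stop("marker length must match measures rows")
    for (g in names(splits)) {
      sel <- splits[[g]]
      for (ms in names(measures)) {
        y <- measures[[ms]][sel]
        xs <- x[sel]
        ok <- stats::complete.cases(xs, y)
        flagged <- sum(ok) < min_n || stats::sd(y[ok]) == 0 ||
          stats::sd(xs[ok]) == 0
        if (flagged) {
          rho <- NA_real_
          p <- NA_real_
        } else {
          ct <- suppressWarnings(
            stats::cor.test(xs[ok], y[ok], method = "spearman",
                            exact = FALSE)
          )
          rho <- unname(ct$estimate)
          p <- ct$p.value
        }
        rows[[length(rows) + 1L]] <- data.frame(
          marker = mk, measure = ms, group = g, n = sum(ok),
          rho = rho, p_raw = p, flagged = flagged,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$p_fdr <- NA_real_
  for (key in unique(paste(tab$marker, tab$group))) {
    fam <- paste(tab$marker, tab$group) == key & !tab$flagged
    tab$p_fdr[fam] <- stats::p.adjust(tab$p_raw[fam], method = "BH")
  }
  attr(tab, "family") <- "within marker x group, across measures"
  class(tab) <- c("association_table", class(tab))
  tab
}

#' Covariate-adjusted group comparison of a marker (ANCOVA)
#'
#' Fits `marker ~ group + covariates` by least squares and reports the
#' F statistic of the group term on `(1, n - p)` degrees of freedom (the
#' square of the group coefficient's t), its p-value, and the adjusted
#' group means evaluated at the covariate means.
#'
#' @param marker per-subject marker values.
#' @param group two-level factor.
#' @param covariates data frame / matrix of covariates (e.g. age and
#'   education).
#' @return An object of class `group_compare`: list with `F`, `p`,
#'   `adjusted_means`, `df`, `fit`.
#' @export
group_compare <- function(marker, group, covariates = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L)
    stop("group must have exactly two non-empty levels")
  C <- prepare_covariates(covariates, length(marker))
  ncov <- ncol(C)
  if (any(table(group) < ncov + 2L))
    stop("each group needs at least ncov + 2 subjects")
  dat <- data.frame(marker = marker, group = group)
  if (ncov) dat <- cbind(dat, as.data.frame(C))
  fit <- stats::lm(marker ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: a covariate is confounded with the group")
  sm <- summary(fit)
  gcoef <- grep("^group", rownames(sm$coefficients))
  tval <- sm$coefficients[gcoef, "t value"]
  Fval <- tval^2
  df2 <- fit$df.residual
  p <- stats::pf(Fval, 1, df2, lower.tail = FALSE)
  newdat <- dat[rep(1L, 2L), , drop = FALSE]
  newdat$group <- factor(levels(group), levels = levels(group))
  if (ncov) newdat[, colnames(C)] <- rep(colMeans(C), each = 2L)
  adj <- stats::predict(fit, newdata = newdat)
  names(adj) <- levels(group)
  structure(
    list(F = unname(Fval), p = unname(p), df = c(1L, df2),
         adjusted_means = adj, fit = fit),
    class = "group_compare"
  )
}

#' @export
print.group_compare <- function(x, ...) {
  cat(sprintf(
    "ANCOVA group contrast: F(%d, %d) = %.3f, p = %.4g\n  adjusted means: %s\n",
    x$df[1], x$df[2], x$F, x$p,
    paste(sprintf("%s = %.4g", names(x$adjusted_means), x$adjusted_means),
          collapse = ", ")
  ))
  invisible(x)
}
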
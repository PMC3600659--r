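# Repeated-measures mixed ANOVA / ANCOVA via the classical univariate
# approach: per-subject cell means are projected onto orthonormal
# within-subject contrasts; each within stratum is a multivariate linear
# model on the between-subject design whose averaged univariate F equals
# the standard mixed-model F in the balanced case. Type III (sum-to-zero)
# hypotheses are used between subjects. Greenhouse-Geisser epsilon and
# Mauchly's sphericity test are computed from the stratum residual
# covariance; by convention the GG correction is applied only when
# Mauchly's test rejects at alpha = 0.05.

#' Greenhouse-Geisser epsilon from a within-factor covariance matrix
#'
#' Box's epsilon computed from the double-centered covariance of the k
#' repeated measures, clamped to `[1/(k-1), 1]`. Equals 1 under compound
#' symmetry (sphericity).
#'
#' @param within_covariance Symmetric positive semi-definite `k x k`
#'   covariance matrix of the repeated measures.
#' @return Epsilon in `[1/(k-1), 1]`.
#' @export
#' @examples
#' gg_epsilon(diag(4) * 2 + 1) # compound symmetric -> 1
gg_epsilon <- function(within_covariance) {
  S <- as.matrix(within_covariance)
  k <- nrow(S)
  if (ncol(S) != k || k < 2L) stop("need a square matrix, k >= 2")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("covariance matrix must be symmetric")
  }
  H <- diag(k) - matrix(1 / k, k, k)
  Sc <- H %*% S %*% H
  num <- sum(diag(Sc))^2
  den <- (k - 1) * sum(Sc^2)
  if (den <= 0) return(1) # degenerate (rank-0 centered covariance)
  min(1, max(1 / (k - 1), num / den))
}

# Epsilon from a d x d residual covariance in the orthonormal-contrast
# space (d = k - 1): eps = tr(E)^2 / (d * sum(E^2)).
eps_from_contrast_cov <- function(E) {
  d <- nrow(E)
  den <- d * sum(E^2)
  if (den <= 0) return(1)
  min(1, max(1 / d, sum(diag(E))^2 / den))
}

# Mauchly's sphericity test from the contrast-space residual covariance E
# (d x d, already divided by the error df) and the error df.
mauchly_p <- function(E, df_error) {
  d <- nrow(E)
  if (d < 2L || df_error <= d) return(NA_real_)
  ev <- eigen(E, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(0) # singular covariance: maximal violation
  W <- prod(ev) / (mean(ev))^d
  rho <- 1 - (2 * d^2 + d + 2) / (6 * d * df_error)
  stat <- -rho * df_error * log(W)
  df <- d * (d + 1) / 2 - 1
  pchisq(stat, df, lower.tail = FALSE)
}

# Orthonormal contrasts for a k-level factor: k x (k-1), columns
# orthonormal and orthogonal to the unit vector.
onorm_contrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), stats::contr.helmert(k))))[, -1, drop = FALSE]
}

# Type III general-linear-hypothesis SS for the columns `idx` of the
# design, summed over the columns of the multivariate response.
glh_ss <- function(B, XtXi, idx) {
  Bj <- B[idx, , drop = FALSE]
  M <- solve(XtXi[idx, idx, drop = FALSE])
  sum(vapply(seq_len(ncol(B)), function(j)
    drop(t(Bj[, j]) %*% M %*% Bj[, j]), numeric(1)))
}

# Fit one stratum: multivariate response Z (n x d) on between design X
# (with term assignment `assign` and labels `labels`). Returns per-term
# SS/df plus the residual SS/df and contrast-space residual covariance.
fit_stratum <- function(Z, X, assign, labels) {
  n <- nrow(Z); d <- ncol(Z)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient ",
                               "(collinear predictors)")
  B <- qr.coef(qrx, Z)
  res <- Z - X %*% B
  df_err <- n - ncol(X)
  if (df_err <= 0) stop("no residual degrees of freedom in stratum")
  ss_err <- sum(res^2)
  E <- crossprod(res) / df_err
  XtXi <- chol2inv(chol(crossprod(X)))
  all_labels <- c("(Intercept)", labels)
  terms <- lapply(sort(unique(assign)), function(i) {
    idx <- which(assign == i)
    list(label = all_labels[i + 1L], ss = glh_ss(B, XtXi, idx),
         df = length(idx) * d)
  })
  list(terms = terms, ss_err = ss_err, df_err = df_err * d,
       df_err_units = df_err, E = E, d = d)
}

# Assemble result rows for one stratum. For within strata (d > 1) the
# intercept carries the within main effect and is relabelled.
stratum_rows <- function(fit, rename_intercept = NULL,
                         drop_intercept = FALSE, gg_alpha = 0.05) {
  d <- fit$d
  eps <- if (d > 1L) eps_from_contrast_cov(fit$E) else NA_real_
  mau <- if (d > 1L) mauchly_p(fit$E, fit$df_err_units) else NA_real_
  gg_applied <- d > 1L && !is.na(mau) && mau < gg_alpha
  ms_err <- fit$ss_err / fit$df_err
  rows <- lapply(fit$terms, function(tm) {
    lab <- tm$label
    if (identical(lab, "(Intercept)")) {
      if (drop_intercept) return(NULL)
      if (!is.null(rename_intercept)) lab <- rename_intercept
    } else if (!is.null(rename_intercept)) {
      lab <- paste(rename_intercept, lab, sep = ":")
    }
    Fv <- (tm$ss / tm$df) / ms_err
    p_unc <- pf(Fv, tm$df, fit$df_err, lower.tail = FALSE)
    df1a <- if (gg_applied) tm$df * eps else tm$df
    df2a <- if (gg_applied) fit$df_err * eps else fit$df_err
    p_adj <- pf(Fv, df1a, df2a, lower.tail = FALSE)
    data.frame(effect = lab, df_num = tm$df, df_den = fit$df_err,
               F = Fv, p_uncorrected = p_unc,
               epsilon = eps, mauchly_p = mau, gg_applied = gg_applied,
               df_num_adj = df1a, df_den_adj = df2a, p = p_adj,
               pes = tm$ss / (tm$ss + fit$ss_err),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Pivot a long design into a per-subject cell matrix. Cells are ordered
# with the first within factor varying slowest.
pivot_design <- function(data, dv, within, id) {
  for (w in within) data[[w]] <- factor(data[[w]])
  ids <- unique(data[[id]])
  levs <- lapply(within, function(w) levels(data[[w]]))
  cells <- do.call(expand.grid,
                   c(rev(levs), list(stringsAsFactors = FALSE)))
  cells <- cells[, rev(seq_along(within)), drop = FALSE]
  names(cells) <- within
  key <- function(df) do.call(paste, c(df[within], list(sep = "\r")))
  cell_keys <- key(cells)
  data_keys <- key(data)
  Y <- matrix(NA_real_, length(ids), nrow(cells))
  for (i in seq_along(ids)) {
    sub <- data[data[[id]] == ids[i], ]
    m <- match(cell_keys, key(sub))
    if (anyNA(m) || nrow(sub) != nrow(cells)) {
      stop(sprintf(
        "unbalanced design: subject %s has %d rows, expected %d (one per %s cell)",
        ids[i], nrow(sub), nrow(cells),
        paste(within, collapse = " x ")))
    }
    Y[i, ] <- sub[[dv]][m]
  }
  list(Y = Y, ids = ids, levels = levs, n_levels = lengths(levs))
}

# Kronecker contrast matrix for a subset of within factors: orthonormal
# contrasts for factors in `effect`, normalised unit averaging otherwise.
effect_contrast <- function(n_levels, in_effect) {
  mats <- lapply(seq_along(n_levels), function(i) {
    k <- n_levels[i]
    if (in_effect[i]) onorm_contrasts(k) else
      matrix(rep(1 / sqrt(k), k), k, 1)
  })
  Reduce(kronecker, mats)
}

#' Mixed repeated-measures ANOVA
#'
#' Balanced mixed ANOVA with one or more within-subject factors and one
#' between-subject grouping factor, with Type III hypotheses,
#' Greenhouse-Geisser epsilon per within effect, and Mauchly-gated GG
#' correction (applied when Mauchly's test rejects at `gg_alpha`).
#'
#' @param data Long-format data frame.
#' @param dv Name of the response column.
#' @param within Character vector of within-subject factor columns (e.g.
#'   `c("phase", "block")` or `"channel"`).
#' @param between Name of the grouping factor column.
#' @param id Name of the subject identifier column.
#' @param gg_alpha Mauchly alpha gating the GG correction (default 0.05).
#' @return A data frame of class `prlt_anova`, one row per effect:
#'   `effect`, `df_num`, `df_den`, `F`, `p_uncorrected`, `epsilon`,
#'   `mauchly_p`, `gg_applied`, adjusted dfs, final `p`, and partial eta
#'   squared (`pes`).
#' @export
mixed_anova <- function(data, dv, within, between, id,
                        gg_alpha = 0.05) {
  stopifnot(all(c(dv, within, between, id) %in% names(data)))
  pv <- pivot_design(data, dv, within, id)
  g <- factor(data[[between]][match(pv$ids, data[[id]])])
  if (nlevels(g) < 2L) stop("need at least two groups")
  X <- stats::model.matrix(~g, data = data.frame(g = g),
                           contrasts.arg = list(g = "contr.sum"))
  assign <- attr(X, "assign")
  labels <- between
  ncells <- ncol(pv$Y)

  # between stratum: subject means (scaled so SS are on the cell scale)
  Zb <- matrix(rowMeans(pv$Y) * sqrt(ncells), ncol = 1)
  fb <- fit_stratum(Zb, X, assign, labels)
  rows <- stratum_rows(fb, drop_intercept = TRUE)

  # within strata: one per non-empty subset of within factors
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(within)))
  for (s in seq_len(nrow(subsets))) {
    in_effect <- unlist(subsets[s, ])
    if (!any(in_effect)) next
    C <- effect_contrast(pv$n_levels, in_effect)
    Zw <- pv$Y %*% C
    fw <- fit_stratum(Zw, X, assign, labels)
    lab <- paste(within[in_effect], collapse = ":")
    rows <- rbind(rows, stratum_rows(fw, rename_intercept = lab,
                                     gg_alpha = gg_alpha))
  }
  rownames(rows) <- NULL
  class(rows) <- c("prlt_anova", "data.frame")
  rows
}

#' Repeated-measures ANCOVA with continuous covariates
#'
#' Single-group repeated-measures analysis with within-subject factors
#' and (typically two) continuous covariates. Covariates are centered
#' before entering the design. Covariate main effects are tested in the
#' between-subject stratum; covariate-by-within interactions are modelled
#' in the within strata when `within_interactions = TRUE` and pooled into
#' error otherwise. GG handling as in [mixed_anova()].
#'
#' @param data Long-format data frame for one group.
#' @param dv Response column name.
#' @param within Character vector of within-subject factor columns.
#' @param covariates Character vector of covariate columns (constant
#'   within subject).
#' @param id Subject identifier column.
#' @param within_interactions Model covariate-by-within-factor
#'   interactions (default `TRUE`).
#' @param gg_alpha Mauchly alpha gating the GG correction.
#' @return A `prlt_anova` data frame (see [mixed_anova()]).
#' @export
ancova_rm <- function(data, dv, within, covariates, id,
                      within_interactions = TRUE, gg_alpha = 0.05) {
  stopifnot(all(c(dv, within, covariates, id) %in% names(data)))
  pv <- pivot_design(data, dv, within, id)
  cv <- sapply(covariates, function(v)
    data[[v]][match(pv$ids, data[[id]])])
  cv <- as.matrix(cv)
  if (any(apply(cv, 2, sd) < 1e-12)) {
    stop("covariates must be non-constant")
  }
  cv <- scale(cv, center = TRUE, scale = FALSE)
  if (qr(cbind(1, cv))$rank < ncol(cv) + 1L) {
    stop("collinear covariates: design matrix is rank deficient")
  }
  X <- cbind("(Intercept)" = 1, cv)
  assign <- c(0L, seq_along(covariates))
  labels <- covariates
  ncells <- ncol(pv$Y)

  Zb <- matrix(rowMeans(pv$Y) * sqrt(ncells), ncol = 1)
  fb <- fit_stratum(Zb, X, assign, labels)
  rows <- stratum_rows(fb, drop_intercept = TRUE)

  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(within)))
  Xw <- if (within_interactions) X else X[, 1, drop = FALSE]
  assign_w <- if (within_interactions) assign else 0L
  for (s in seq_len(nrow(subsets))) {
    in_effect <- unlist(subsets[s, ])
    if (!any(in_effect)) next
    C <- effect_contrast(pv$n_levels, in_effect)
    Zw <- pv$Y %*% C
    fw <- fit_stratum(Zw, Xw, assign_w, labels)
    lab <- paste(within[in_effect], collapse = ":")
    rows <- rbind(rows, stratum_rows(fw, rename_intercept = lab,
                                     gg_alpha = gg_alpha))
  }
  rownames(rows) <- NULL
  class(rows) <- c("prlt_anova", "data.frame")
  rows
}

#' @export
print.prlt_anova <- function(x, ...) {
  y <- as.data.frame(x)
  y$F <- round(y$F, 3); y$p <- signif(y$p, 3)
  y$pes <- round(y$pes, 3)
  print(y[, c("effect", "df_num", "df_den", "F", "p", "gg_applied",
              "pes")], row.names = FALSE)
  invisible(x)
}

#' Pairwise group comparisons (LSD / Bonferroni)
#'
#' Pairwise pooled-variance two-sample t tests between groups on a
#' per-subject response (subjects collapsed over within cells if `id`
#' given). `"lsd"` leaves the raw p values; `"bonferroni"` multiplies
#' them by the number of comparisons (capped at 1).
#'
#' @param data Data frame.
#' @param dv Response column.
#' @param between Grouping column.
#' @param id Optional subject column: responses are averaged per subject
#'   first.
#' @param method `"lsd"` or `"bonferroni"`.
#' @return A data frame with one row per pair: `group1`, `group2`, `t`,
#'   `df`, `p_raw`, `p_adjusted`.
#' @export
posthoc <- function(data, dv, between, id = NULL,
                    method = c("lsd", "bonferroni")) {
  method <- match.arg(method)
  if (!is.null(id)) {
    agg <- aggregate(data[[dv]],
                     by = list(id = data[[id]], g = data[[between]]),
                     FUN = mean)
    y <- agg$x; g <- factor(agg$g)
  } else {
    y <- data[[dv]]; g <- factor(data[[between]])
  }
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(i) {
    a <- y[g == pairs[1, i]]; b <- y[g == pairs[2, i]]
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tval), n1 + n2 - 2)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i], t = tval,
               df = n1 + n2 - 2, p_raw = p,
               p_adjusted = if (method == "bonferroni") min(1, p * m)
               else p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
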
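#' ROI-level age regression for one metric
#'
#' Ordinary least squares of a metric on age with optional quadratic age and
#' sex terms, following the model ladder M1: Age; M2: Age + Age^2;
#' M3: Age + Sex; M4: Age + Age^2 + Sex. The reported t-statistic tests the
#' linear age coefficient (H0: beta1 = 0, two-sided, dof = n - p); the
#' Pearson correlation r is reported from the age-only relationship, for
#' which t = r * sqrt(n - 2) / sqrt(1 - r^2).
#'
#' @param y numeric response vector (one metric).
#' @param age ages in years.
#' @param sex binary indicator (0/1); required for M3/M4.
#' @param model one of "M1", "M2", "M3", "M4".
#' @return One-row tibble: beta0, beta1, beta2 (NA when sex is not in the
#'   model), t, p, r, n, dof.
#' @export
ols_age_model <- function(y, age, sex = NULL, model = c("M3", "M1", "M2", "M4")) {
  model <- match.arg(model)
  n <- length(y)
  stopifnot(length(age) == n)
  if (model %in% c("M3", "M4") && is.null(sex))
    stop("models M3 and M4 require the sex covariate")
  df <- data.frame(y = y, age = age)
  form <- switch(model,
                 M1 = y ~ age,
                 M2 = y ~ age + I(age^2),
                 M3 = y ~ age + sex,
                 M4 = y ~ age + I(age^2) + sex)
  if (!is.null(sex)) df$sex <- as.numeric(sex)
  p <- switch(model, M1 = 2, M2 = 3, M3 = 3, M4 = 4)
  if (n <= p + 1) stop("too few observations for model ", model)
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  sm <- summary(fit)$coefficients
  r <- stats::cor(y, age)
  tibble::tibble(
    beta0 = sm["(Intercept)", 1],
    beta1 = sm["age", 1],
    beta2 = if ("sex" %in% rownames(sm)) sm["sex", 1] else NA_real_,
    t = sm["age", 3],
    p = sm["age", 4],
    r = r, n = n, dof = fit$df.residual)
}

#' Age regression across the metrics of a cohort table
#'
#' Data-frame-first wrapper: runs [ols_age_model()] for every metric column
#' and applies Benjamini-Hochberg FDR within each metric family (one family
#' per metric across its ROIs when a `roi` column is present, otherwise one
#' family across the supplied metrics).
#'
#' @param data tibble with columns `age`, `sex`, optionally `roi`, and the
#'   metric columns.
#' @param metrics character vector of metric column names; default every
#'   numeric column other than age/sex/subject identifiers.
#' @param model model code, see [ols_age_model()].
#' @return Tibble of class `hippo_age_fit`, one row per metric (x ROI) with
#'   r, t, p and FDR-adjusted p.
#' @export
age_regression <- function(data, metrics = NULL, model = "M3") {
  stopifnot(all(c("age", "sex") %in% names(data)))
  if (is.null(metrics)) {
    drop <- c("age", "sex", "subject", "roi")
    metrics <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                       drop)
  }
  has_roi <- "roi" %in% names(data)
  groups <- if (has_roi) split(data, data$roi) else list(all = data)
  rows <- purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(names(groups), function(g) {
      d <- groups[[g]]
      res <- ols_age_model(d[[m]], d$age, d$sex, model = model)
      dplyr::mutate(res, metric = m, roi = if (has_roi) g else NA_character_,
                    .before = 1)
    })
  })
  rows <- dplyr::group_by(rows, .data$metric)
  rows <- dplyr::mutate(rows, p_fdr = bh_fdr(.data$p))
  rows <- dplyr::ungroup(rows)
  class(rows) <- c("hippo_age_fit", class(rows))
  rows
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: monotone, capped at 1 and never below the raw
#' p-value.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Welch two-sample t from group summaries
#'
#' Unequal-variance two-sample t-statistic
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)` with the
#' Welch-Satterthwaite degrees of freedom, as used to check the
#' age balance between the male and female halves of a cohort.
#'
#' @param n1,mean1,sd1 first group size, mean, sd.
#' @param n2,mean2,sd2 second group size, mean, sd.
#' @return One-row tibble: t, dof, p (two-sided).
#' @export
welch_t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 <= 0 || sd2 <= 0) stop("group standard deviations must be > 0")
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  dof <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  tibble::tibble(t = t, dof = dof,
                 p = 2 * stats::pt(-abs(t), dof))
}

#' Likelihood-ratio test between nested OLS age models
#'
#' Gaussian-likelihood LRT `n * ln(RSS0 / RSS1)` compared to a chi-square
#' with degrees of freedom equal to the number of added columns; used to
#' compare the age-only model against richer specifications (quadratic age,
#' sex).
#'
#' @param y response vector.
#' @param design_simple,design_complex model matrices; the simple design's
#'   columns must all appear in the complex design.
#' @return One-row tibble: statistic, df, p.
#' @export
lrt_nested <- function(y, design_simple, design_complex) {
  design_simple <- as.matrix(design_simple)
  design_complex <- as.matrix(design_complex)
  nested <- all(apply(design_simple, 2, function(col)
    any(apply(design_complex, 2, function(cc) isTRUE(all.equal(cc, col))))))
  if (!nested) stop("designs are not nested")
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  n <- length(y)
  stat <- n * log(rss(design_simple) / rss(design_complex))
  df <- ncol(design_complex) - ncol(design_simple)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = max(stat, 0), df = df, p = p)
}

#' Design matrices for the M1-M4 age-model ladder
#'
#' @param age,sex cohort covariates.
#' @param model model code.
#' @return Model matrix including the intercept.
#' @export
age_model_design <- function(age, sex = NULL, model = "M1") {
  switch(model,
         M1 = cbind(1, age),
         M2 = cbind(1, age, age^2),
         M3 = cbind(1, age, as.numeric(sex)),
         M4 = cbind(1, age, age^2, as.numeric(sex)),
         stop("unknown model ", model))
}

#' Vertexwise age regression
#'
#' Fits Metric = b0 + b1 Age + b2 Sex at every vertex of a cohort's common
#' template (closed-form OLS, vectorised across vertices), reports the
#' age-only Pearson r per vertex, and applies BH-FDR across the vertices of
#' the map.
#'
#' @param maps n_subject x n_vertex matrix of per-vertex metric values.
#' @param age,sex cohort covariates.
#' @param alpha FDR level for the significance mask.
#' @return Tibble with one row per vertex: vertex, r, t, p, p_fdr,
#'   significant.
#' @export
vertexwise_regression <- function(maps, age, sex, alpha = 0.05) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (length(age) != n || length(sex) != n)
    stop("covariate length does not match the subject count")
  X <- cbind(1, age, as.numeric(sex))
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  B <- XtXinv %*% crossprod(X, maps)          # p x V
  res <- maps - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  se_age <- sqrt(sigma2 * XtXinv[2, 2])
  tt <- B[2, ] / se_age
  pv <- 2 * stats::pt(-abs(tt), n - p)
  sdm <- apply(maps, 2, stats::sd)
  r <- rep(0, ncol(maps))
  nz <- sdm > 0
  r[nz] <- as.vector(stats::cor(age, maps[, nz, drop = FALSE]))
  pf <- bh_fdr(pv)
  tibble::tibble(vertex = seq_len(ncol(maps)), r = r, t = tt, p = pv,
                 p_fdr = pf, significant = pf < alpha)
}

#' Spatial Pearson correlation matrix between metric maps
#'
#' Pairwise Pearson correlation of k per-vertex maps across all vertices
#' (missing vertices excluded pairwise), with BH-FDR flags on the
#' off-diagonal tests.
#'
#' @param maps n_vertex x k matrix or data frame, one column per metric.
#' @param alpha FDR level.
#' @return List with `r` (symmetric k x k matrix, unit diagonal), `p`,
#'   `p_fdr` (off-diagonal, FDR within the upper triangle), `significant`
#'   and `n` (pairwise vertex counts).
#' @export
spatial_correlation_matrix <- function(maps, alpha = 0.05) {
  maps <- as.matrix(maps)
  k <- ncol(maps)
  r <- diag(1, k); pm <- matrix(NA_real_, k, k); nm <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    ok <- stats::complete.cases(maps[, c(i, j)])
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 common vertices for metrics ", i, ", ", j)
    rij <- stats::cor(maps[ok, i], maps[ok, j])
    tij <- rij * sqrt(n - 2) / sqrt(max(1 - rij^2, 1e-300))
    r[i, j] <- r[j, i] <- rij
    pm[i, j] <- pm[j, i] <- 2 * stats::pt(-abs(tij), n - 2)
    nm[i, j] <- nm[j, i] <- n
  }
  up <- upper.tri(pm)
  pf <- matrix(NA_real_, k, k)
  pf[up] <- bh_fdr(pm[up])
  pf[lower.tri(pf)] <- t(pf)[lower.tri(pf)]
  dimnames(r) <- dimnames(pm) <- dimnames(pf) <- dimnames(nm) <-
    list(colnames(maps), colnames(maps))
  list(r = r, p = pm, p_fdr = pf, significant = pf < alpha, n = nm)
}

#' Per-ROI per-subject means of vertex maps
#'
#' Unweighted mean over each subfield's vertices; thickness is excluded for
#' the dentate gyrus by passing NA at those vertices (NAs are dropped, and
#' an all-NA ROI errors).
#'
#' @param maps n_subject x n_vertex matrix.
#' @param labels per-vertex ROI labels.
#' @param subjects optional subject identifiers (default row index).
#' @return Tibble: subject, roi, value.
#' @export
roi_summary <- function(maps, labels, subjects = NULL) {
  maps <- as.matrix(maps)
  stopifnot(length(labels) == ncol(maps))
  if (is.null(subjects)) subjects <- seq_len(nrow(maps))
  labs <- as.character(labels)
  purrr::map_dfr(unique(labs), function(l) {
    cols <- which(labs == l)
    vals <- unname(rowMeans(maps[, cols, drop = FALSE], na.rm = TRUE))
    if (all(!is.finite(vals))) stop("ROI ", l, " has no defined vertices")
    tibble::tibble(subject = subjects, roi = l, value = vals)
  })
}

#' @export
autoplot.hippo_age_fit <- function(object, ...) {
  d <- dplyr::mutate(object,
                     label = ifelse(is.na(.data$roi), .data$metric,
                                    paste(.data$metric, .data$roi)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$label,
                                  fill = .data$p_fdr < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "grey60"),
                               name = "FDR p < 0.05") +
    ggplot2::labs(x = "Pearson r with age", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
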
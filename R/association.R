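# Association layer: Bonferroni-corrected univariate mode correlations,
# group comparisons with a normality gate, covariate-adjusted multivariate
# regression, and the morphometric shape mode assembled from the predictor's
# per-mode coefficients.

#' Univariate associations between mode scores and a variable
#'
#' Pearson correlation of each atlas mode score with the variable, with a
#' two-sided t-based p-value (for standardized variables this is the slope
#' test of the equivalent univariate regression). Both sides are
#' standardized first. A mode is significant iff \code{p < alpha / m} with
#' the Bonferroni family size m equal to the number of modes tested (one
#' family per variable); the family size is reported in the output.
#'
#' @param scores n x K matrix of mode scores.
#' @param variable length-n numeric vector.
#' @param alpha family-wise level (default 0.05).
#' @return A list of class \code{"AssociationResult"}: data.frame
#'   \code{table} (mode, r, p, significant), \code{threshold},
#'   \code{significant_modes}, \code{family_size}, \code{alpha}.
#' @export
univariateModeAssociations <- function(scores, variable, alpha = 0.05) {
  scores <- as.matrix(scores)
  n <- nrow(scores); K <- ncol(scores)
  if (n < 3) .stopf("need at least 3 subjects")
  if (length(variable) != n) .stopf("variable length must match score rows")
  if (anyNA(scores) || anyNA(variable)) .stopf("missing values not supported; use complete cases")
  if (stats::sd(variable) == 0) .stopf("variable has zero variance")
  v <- as.numeric(scale(variable))
  r <- numeric(K); p <- numeric(K)
  for (k in seq_len(K)) {
    if (stats::sd(scores[, k]) == 0) .stopf("mode %d scores have zero variance", k)
    ct <- stats::cor.test(as.numeric(scale(scores[, k])), v)
    r[k] <- unname(ct$estimate); p[k] <- ct$p.value
  }
  thr <- alpha / K
  tab <- data.frame(mode = seq_len(K), r = r, p = p, significant = p < thr)
  structure(list(table = tab, threshold = thr,
                 significant_modes = which(tab$significant),
                 family_size = K, alpha = alpha),
            class = "AssociationResult")
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("Univariate mode associations (Bonferroni family m = %d, threshold %.3g)\n",
              x$family_size, x$threshold))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Compare a variable across groups
#'
#' Two groups: Welch t-test. More than two: Shapiro-Wilk normality per group
#' at level 0.05; one-way ANOVA when every group passes, Kruskal-Wallis
#' otherwise. The test actually run is recorded.
#'
#' @param values numeric vector.
#' @param labels group labels (coerced to factor), each group n >= 3.
#' @return A list of class \code{"GroupComparison"}: \code{test_used},
#'   \code{statistic}, \code{p}, and per-group \code{summaries}
#'   (mean, sd, n).
#' @export
compareGroups <- function(values, labels) {
  labels <- as.factor(labels)
  if (length(values) != length(labels)) .stopf("values and labels must match")
  tab <- table(labels)
  if (length(tab) < 2) .stopf("need at least 2 groups")
  if (any(tab < 3)) .stopf("every group needs at least 3 observations")
  summaries <- do.call(rbind, lapply(levels(labels), function(g) {
    v <- values[labels == g]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  if (length(tab) == 2) {
    tt <- stats::t.test(values ~ labels)  # Welch
    res <- list(test_used = "t_test", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    normal <- vapply(levels(labels), function(g) {
      v <- values[labels == g]
      stats::shapiro.test(v)$p.value >= 0.05
    }, logical(1))
    if (all(normal)) {
      fit <- stats::aov(values ~ labels)
      sm <- summary(fit)[[1]]
      res <- list(test_used = "anova", statistic = sm[["F value"]][1],
                  p = sm[["Pr(>F)"]][1])
    } else {
      kw <- stats::kruskal.test(values, labels)
      res <- list(test_used = "kruskal_wallis", statistic = unname(kw$statistic),
                  p = kw$p.value)
    }
  }
  structure(c(res, list(summaries = summaries)), class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_used, x$statistic, x$p))
  print(x$summaries, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fit the morphometric shape mode by covariate-adjusted regression
#'
#' Per retained mode k, ordinary least squares of the mode score on the
#' standardized predictor and standardized covariates (plus intercept):
#' \deqn{z_k = \beta_k\, p + c^\top \gamma_k + \varepsilon.}
#' The predictor's coefficients are assembled into the morphometric
#' displacement
#' \deqn{\Delta = \sum_k \beta_k \sqrt{\lambda_k}\, \phi_k,}
#' the shape-space change per +1 SD of the predictor, independent of the
#' covariates. A rank-deficient design is an error naming the collinear
#' columns.
#'
#' @param scores n x K matrix of normalized mode scores.
#' @param predictor length-n numeric vector (e.g. average indexed vorticity).
#' @param covariates data.frame with columns \code{sex}, \code{height},
#'   \code{weight}, \code{age} (sex coded 0/1; all standardized internally).
#' @param atlas a [ShapeAtlas-class]; its first K modes and variances build
#'   the displacement. \code{NULL} fits the regressions only (empty
#'   displacement), for calibration work with no shape model at hand.
#' @param conf confidence level for the per-mode intervals (default 0.95).
#' @param predictor_name label stored in the result.
#' @return A [MorphometricMode-class].
#' @export
fitMorphometricMode <- function(scores, predictor, covariates, atlas = NULL,
                                conf = 0.95, predictor_name = "predictor") {
  scores <- as.matrix(scores)
  n <- nrow(scores); K <- ncol(scores)
  if (length(predictor) != n || nrow(covariates) != n)
    .stopf("predictor/covariates must match score rows")
  if (anyNA(scores) || anyNA(predictor) || anyNA(covariates))
    .stopf("missing values not supported; use complete cases")
  covNames <- c("sex", "height", "weight", "age")
  if (!all(covNames %in% names(covariates)))
    .stopf("covariates must contain: %s", paste(covNames, collapse = ", "))
  X <- cbind(predictor = as.numeric(predictor),
             as.matrix(covariates[, covNames]))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) .stopf("zero-variance column(s): %s",
                            paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X)
  design <- cbind(`(Intercept)` = 1, Xs)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    .stopf("rank-deficient design; collinear column(s): %s",
           paste(dropped, collapse = ", "))
  }
  if (n <= ncol(design)) .stopf("need more subjects than predictors")
  df <- n - ncol(design)
  XtXinv <- chol2inv(qr.R(qrd))
  tcrit <- stats::qt(1 - (1 - conf) / 2, df)
  beta <- numeric(K); se <- numeric(K)
  ci <- matrix(NA_real_, K, 2, dimnames = list(NULL, c("lower", "upper")))
  covBetas <- matrix(NA_real_, K, length(covNames),
                     dimnames = list(NULL, covNames))
  pcol <- 2L  # predictor column in the design
  for (k in seq_len(K)) {
    coefs <- qr.coef(qrd, scores[, k])
    resid <- scores[, k] - design %*% coefs
    s2 <- sum(resid^2) / df
    beta[k] <- coefs[pcol]
    se[k] <- sqrt(s2 * XtXinv[pcol, pcol])
    ci[k, ] <- beta[k] + c(-1, 1) * tcrit * se[k]
    covBetas[k, ] <- coefs[-(1:2)]
  }
  disp <- if (is.null(atlas)) numeric(0) else {
    lam <- atlasVariances(atlas)[seq_len(K)]
    as.numeric(atlasModes(atlas)[, seq_len(K), drop = FALSE] %*% (beta * sqrt(lam)))
  }
  new("MorphometricMode", betaPerMode = beta, betaSE = se, betaCI = ci,
      covariateBetas = covBetas, displacement = disp,
      predictorName = predictor_name)
}

#' Render shapes along an atlas mode or a morphometric mode
#'
#' Produces the spectrum of shapes \code{mean + alpha * direction} for each
#' requested SD multiple alpha, where the direction is either
#' \code{sqrt(lambda_k) * phi_k} for an atlas mode index, or the
#' morphometric displacement. Shapes can optionally be written as PLY
#' meshes for external viewing.
#'
#' @param atlas a [ShapeAtlas-class].
#' @param mode an integer atlas mode index or a [MorphometricMode-class].
#' @param alphas numeric SD multiples (non-empty), e.g. \code{c(-2, 0, 2)}.
#' @param out_dir optional directory; when given, each shape is written via
#'   [writeShape()] as \code{mode_<alpha>}.
#' @return Named list of [BiventricularShape-class], one per alpha.
#' @export
renderModeShapes <- function(atlas, mode, alphas, out_dir = NULL) {
  stopifnot(is(atlas, "ShapeAtlas"))
  if (!length(alphas)) .stopf("alphas must be non-empty")
  if (is(mode, "MorphometricMode")) {
    dirvec <- mode@displacement
  } else {
    mode <- as.integer(mode)
    if (mode < 1 || mode > ncol(atlas@modes)) .stopf("mode index out of range")
    dirvec <- atlas@modes[, mode] * sqrt(atlas@variances[mode])
  }
  out <- lapply(alphas, function(a) vectorToShape(atlas@meanShape + a * dirvec, atlas))
  names(out) <- sprintf("alpha_%+g", alphas)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) writeShape(out[[nm]], out_dir, nm)
  }
  out
}
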
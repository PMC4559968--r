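# Univariate and multivariate symptom-domain analysis: pooled two-sample
# t-tests per ADI-R domain, 2x2 demographic ANOVA, and a sparse
# (L1-penalized logistic) classifier of sex from domain scores with
# leave-one-out cross-validation.

#' Domain-wise pooled two-sample t-tests
#'
#' One two-sided pooled-variance (Student) t-test per symptom domain,
#' comparing the two levels of `grouping`. The pooled test is used (rather
#' than Welch) so that `df = n1 + n2 - 2`. Sign convention: the statistic
#' and mean difference are first level minus second level of the grouping
#' factor (with the default sex factor, female minus male). Subjects with
#' a missing score are dropped per domain and the per-test df reflects the
#' subjects actually used.
#'
#' @param table a `symptom_table` data frame.
#' @param grouping name of the two-level factor column (default `"sex"`).
#' @param domains character vector of score columns to test.
#' @return a `data.frame` with one row per domain: `domain, t, df, p,
#'   mean_diff, n1, n2`.
#' @examples
#' tab <- generate_symptom_cohort(ndar_cohort_spec(seed = 1))
#' domain_ttests(tab[tab$group == "ASD", ])
#' @export
domain_ttests <- function(table, grouping = "sex",
                          domains = c("adi_social", "adi_comm", "adi_rrb",
                                      "adi_total")) {
  g <- droplevels(factor(table[[grouping]]))
  if (nlevels(g) != 2) stop("grouping must have exactly two levels, got ",
                            nlevels(g))
  out <- lapply(domains, function(dom) {
    x <- table[[dom]]
    if (is.null(x)) stop("no such domain column: ", dom)
    ok <- !is.na(x)
    x1 <- x[ok & g == levels(g)[1]]
    x2 <- x[ok & g == levels(g)[2]]
    if (length(x1) < 2 || length(x2) < 2)
      stop("group with fewer than 2 subjects for domain ", dom)
    if (sd(x1) == 0 && sd(x2) == 0)
      stop("scores constant in both groups for domain ", dom,
           ": t statistic undefined")
    tt <- t.test(x1, x2, var.equal = TRUE)
    data.frame(domain = dom, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = mean(x1) - mean(x2),
               n1 = length(x1), n2 = length(x2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "groups") <- levels(g)
  out
}

#' Group-by-sex ANOVA of a demographic variable
#'
#' Two-way factorial ANOVA (type-II sums of squares) of a demographic
#' variable on the 2x2 group-by-sex design, reporting F and p for the two
#' main effects and their interaction. With the balanced cells the
#' sums-of-squares type is immaterial.
#'
#' @param table a `symptom_table`.
#' @param dv dependent variable column, `"age"` or `"iq"`.
#' @param factors length-2 character vector naming the two crossed factors.
#' @return `data.frame` with columns `effect, F, df1, df2, p`.
#' @export
demographic_anova <- function(table, dv = "age", factors = c("group", "sex")) {
  f1 <- droplevels(factor(table[[factors[1]]]))
  f2 <- droplevels(factor(table[[factors[2]]]))
  if (nlevels(f1) != 2 || nlevels(f2) != 2)
    stop("both factors must have two levels")
  if (any(table(f1, f2) < 2)) stop("each design cell needs >= 2 subjects")
  y <- table[[dv]]
  dat <- data.frame(y = y, f1 = f1, f2 = f2)
  fit <- lm(y ~ f1 * f2, data = dat)
  if (sum(stats::residuals(fit)^2) < 1e-12 * max(1, sum(y^2)))
    stop("zero residual variance: ", dv, " is constant within cells")
  a <- car::Anova(fit, type = 2)
  eff <- c("f1", "f2", "f1:f2")
  lab <- c(factors[1], factors[2], paste(factors, collapse = ":"))
  data.frame(effect = lab,
             F = a[eff, "F value"],
             df1 = a[eff, "Df"],
             df2 = a["Residuals", "Df"],
             p = a[eff, "Pr(>F)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sparse linear classification of a label from symptom domains
#'
#' L1-penalized (lasso) logistic regression classifying the two levels of
#' `label` from the given domain scores, evaluated by leave-one-out
#' cross-validation. Inside every LOOCV fold the penalty is selected by
#' internal 10-fold cross-validation on the training subjects only
#' (1-SE rule) and features are standardized with training-fold
#' statistics, so the held-out subject never influences model selection.
#' The reported coefficients come from a final fit on all subjects at the
#' penalty selected the same way; the selected feature set is the set of
#' nonzero coefficients. A held-out predicted probability of exactly 0.5
#' is resolved to the majority class of the training fold.
#'
#' @param table a `symptom_table`.
#' @param features character vector of feature columns.
#' @param label two-level factor column to classify (default `"sex"`).
#' @param seed integer seed controlling the internal CV fold assignment.
#' @param lambda_rule `"1se"` (default) or `"min"`.
#' @return a list of class `classifier_report`: `loocv_accuracy`,
#'   `balanced_accuracy`, `confusion` (2x2 table), `coefficients` (named,
#'   including intercept), `selected_features`, `lambda`, `n`.
#' @export
sparse_classifier_loocv <- function(table,
                                    features = c("adi_social", "adi_comm",
                                                 "adi_rrb"),
                                    label = "sex", seed = 1L,
                                    lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  y <- droplevels(factor(table[[label]]))
  if (nlevels(y) != 2) stop("label must have exactly two levels")
  if (min(table(y)) < 2) stop("each class needs >= 2 subjects")
  X <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(X)) stop("missing feature values; subset to complete cases first")
  if (all(apply(X, 2, sd) == 0)) stop("all features are constant")
  n <- nrow(X)
  sel <- function(cvfit) if (lambda_rule == "1se") cvfit$lambda.1se else cvfit$lambda.min

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # internal-CV fold assignments are drawn once per fit from the seed
  cv_lasso <- function(Xtr, ytr, fold_seed) {
    set.seed(fold_seed)
    foldid <- .stratified_fold_ids(ytr, nfolds = 10)
    # grouped = FALSE: per-observation CV errors (the grouped SE needs
    # >= 3 observations per fold, which LOOCV training sets rarely give)
    glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                      type.measure = "class", foldid = foldid,
                      standardize = FALSE, grouped = FALSE)
  }

  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    mu <- colMeans(Xtr)
    sig <- apply(Xtr, 2, sd)
    sig[sig < 1e-12] <- 1
    Xs <- scale(Xtr, mu, sig)
    cvfit <- cv_lasso(Xs, ytr, fold_seed = seed + i)
    ph <- predict(cvfit, matrix((X[i, ] - mu) / sig, 1), s = sel(cvfit),
                  type = "response")[1]
    pred[i] <- if (ph > 0.5) levels(y)[2]
    else if (ph < 0.5) levels(y)[1]
    else names(which.max(table(ytr)))
  }
  confusion <- table(truth = y, predicted = pred)
  acc <- mean(pred == y)
  bal <- mean(diag(confusion) / rowSums(confusion))

  mu <- colMeans(X); sig <- apply(X, 2, sd); sig[sig < 1e-12] <- 1
  cvfit <- cv_lasso(scale(X, mu, sig), y, fold_seed = seed)
  cf <- as.matrix(coef(cvfit, s = sel(cvfit)))[, 1]
  selected <- names(cf)[-1][cf[-1] != 0]
  structure(list(loocv_accuracy = acc, balanced_accuracy = bal,
                 confusion = confusion, coefficients = cf,
                 selected_features = selected, lambda = sel(cvfit),
                 n = n, label_levels = levels(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("sparse classifier:", x$n, "subjects, LOOCV accuracy",
      sprintf("%.1f%%", 100 * x$loocv_accuracy),
      sprintf("(balanced %.1f%%)", 100 * x$balanced_accuracy), "\n")
  cat("selected features:",
      if (length(x$selected_features)) paste(x$selected_features, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# deals class-stratified fold ids 1..nfolds (used for glmnet internal CV
# and for the searchlight M-fold assignment)
.stratified_fold_ids <- function(y, nfolds, strata = NULL) {
  n <- length(y)
  key <- if (is.null(strata)) factor(y) else interaction(y, strata, drop = TRUE)
  fold <- integer(n)
  offset <- 0L
  for (lev in levels(key)) {
    idx <- which(key == lev)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- (seq_along(idx) - 1L + offset) %% nfolds + 1L
    offset <- offset + length(idx)
  }
  fold
}
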
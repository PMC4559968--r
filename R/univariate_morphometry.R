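# Mass-univariate voxelwise statistics on gray-matter cohorts: two-sample
# t maps (GM ~ group + covariates) and 2x2 group-by-sex factorial ANOVA
# with type-II F maps, all computed by shared-design linear algebra.

#' Voxelwise two-sample t map
#'
#' Fits `GM ~ group + covariates` at every in-mask voxel and maps the t
#' statistic of the group effect. Sign convention: first level of `labels`
#' minus second level. Voxels with zero residual variance yield `NaN`
#' statistics and are counted in a warning rather than silently set to
#' p = 1.
#'
#' @param cohort a [gm_cohort()].
#' @param labels two-level factor, one entry per subject.
#' @param covs optional covariate data frame (e.g. `age`, `site`).
#' @return a `stat_map` list: `stat` and `p` 3-D arrays (NA outside the
#'   mask), `df`, `contrast`, `type = "t"`, `mask`.
#' @export
voxelwise_ttest <- function(cohort, labels, covs = NULL) {
  labels <- droplevels(factor(labels))
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  n <- ncol(cohort$data)
  if (length(labels) != n) stop("labels length does not match cohort")
  Xn <- .nuisance_design(covs, n)
  # dummy: +1/2 first level, -1/2 second -> coefficient = mean1 - mean2
  g <- ifelse(labels == levels(labels)[1], 0.5, -0.5)
  X <- cbind(Xn, group = g)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design rank-deficient (group aliased with covariates?)")
  Y <- t(cohort$data[cohort$mask, , drop = FALSE])
  cf <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  df <- n - qx$rank
  if (df < 1) stop("no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  cgg <- XtXinv[ncol(X), ncol(X)]
  se <- sqrt(sigma2 * cgg)
  tt <- cf[ncol(X), ] / se
  bad <- sigma2 < 1e-24
  if (any(bad)) {
    tt[bad] <- NaN
    warning(sum(bad), " voxel(s) with zero residual variance set to NaN")
  }
  p <- 2 * pt(-abs(tt), df)
  .as_stat_map(cohort, stat = tt, p = p, df = df, type = "t",
               contrast = paste(levels(labels)[1], "-", levels(labels)[2]))
}

.as_stat_map <- function(cohort, stat, p, df, type, contrast) {
  sa <- array(NA_real_, cohort$dim); pa <- array(NA_real_, cohort$dim)
  sa[cohort$mask] <- stat
  pa[cohort$mask] <- p
  structure(list(stat = sa, p = pa, df = df, type = type,
                 contrast = contrast, mask = cohort$mask,
                 affine = cohort$affine),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("stat_map (", x$type, "): ", x$contrast, ", df = ",
      paste(x$df, collapse = ", "), ", ", sum(x$mask), " in-mask voxels\n",
      sep = "")
  invisible(x)
}

# residual sum of squares per voxel under a given design
.rss <- function(X, Y) {
  qx <- qr(X)
  colSums(qr.resid(qx, Y)^2)
}

#' Voxelwise 2x2 group-by-sex ANOVA maps
#'
#' Fits `GM ~ group * sex + covariates` at every in-mask voxel and returns
#' type-II F maps for the group and sex main effects and their
#' interaction (each effect's sum of squares is taken adjusting for the
#' other main effect and the covariates, the interaction adjusting for
#' both mains; the error term is the full-model residual).
#'
#' @param cohort a [gm_cohort()].
#' @param group,sex two-level factors per subject.
#' @param covs optional covariate data frame.
#' @return named list of three `stat_map`s: `group`, `sex`, `interaction`.
#' @export
voxelwise_anova_2x2 <- function(cohort, group, sex, covs = NULL) {
  group <- droplevels(factor(group)); sex <- droplevels(factor(sex))
  if (nlevels(group) != 2 || nlevels(sex) != 2)
    stop("group and sex must each have two levels")
  if (any(table(group, sex) < 2)) stop("each of the four cells needs >= 2 subjects")
  n <- ncol(cohort$data)
  Xn <- .nuisance_design(covs, n)
  G <- ifelse(group == levels(group)[1], 0.5, -0.5)
  S <- ifelse(sex == levels(sex)[1], 0.5, -0.5)
  Y <- t(cohort$data[cohort$mask, , drop = FALSE])

  X_full <- cbind(Xn, G = G, S = S, GS = G * S)
  qf <- qr(X_full)
  if (qf$rank < ncol(X_full)) stop("full 2x2 design is rank-deficient")
  res_full <- qr.resid(qf, Y)
  df_err <- n - qf$rank
  rss_full <- colSums(res_full^2)
  ms_err <- rss_full / df_err
  degenerate <- ms_err < 1e-24
  if (any(degenerate))
    warning(sum(degenerate),
            " voxel(s) with zero full-model residual variance: F set to NaN")

  f_of <- function(rss_reduced, rss_base) {
    f <- (rss_reduced - rss_base) / ms_err
    f[degenerate] <- NaN
    f
  }
  # type II: each main adjusted for the other main + covs (no interaction)
  rss_GS <- .rss(cbind(Xn, G = G, S = S), Y)
  rss_S  <- .rss(cbind(Xn, S = S), Y)
  rss_G  <- .rss(cbind(Xn, G = G), Y)
  F_group <- f_of(rss_S, rss_GS)
  F_sex   <- f_of(rss_G, rss_GS)
  F_int   <- f_of(rss_GS, rss_full)

  mk <- function(f, label) {
    p <- pf(f, 1, df_err, lower.tail = FALSE)
    .as_stat_map(cohort, stat = f, p = p, df = c(1, df_err), type = "F",
                 contrast = label)
  }
  list(group = mk(F_group, "main effect of group"),
       sex = mk(F_sex, "main effect of sex"),
       interaction = mk(F_int, "group x sex interaction"))
}

#' Summarize suprathreshold voxels of a stat map
#'
#' @param map a `stat_map`.
#' @param p_threshold uncorrected p threshold.
#' @return `data.frame` of voxel indices, world coordinates, statistic and
#'   p for voxels below the threshold.
#' @export
stat_map_table <- function(map, p_threshold = 0.001) {
  idx <- which(map$p <= p_threshold & map$mask)
  if (!length(idx))
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stat = numeric(), p = numeric()))
  ijk <- arrayInd(idx, dim(map$mask))
  w <- voxel_to_world(map$affine, ijk)
  data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
             x = w[, 1], y = w[, 2], z = w[, 3],
             stat = map$stat[idx], p = map$p[idx])
}
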
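#' Statistics configuration
#'
#' Defaults follow the conventional analysis settings: significance level
#' 0.05 (uncorrected and FDR-corrected), Benjamini-Hochberg FDR, and the
#' expression filter "more than 10 expected read counts in more than 50% of
#' samples" (both inequalities strict).
#'
#' @param alpha significance level in (0, 1).
#' @param erc_min minimum count, strict `>`.
#' @param erc_sample_frac fraction of samples, strict `>`.
#' @return list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, erc_min = 10, erc_sample_frac = 0.5) {
  stopifnot(alpha > 0, alpha < 1, erc_min >= 0,
            erc_sample_frac >= 0, erc_sample_frac <= 1)
  structure(list(alpha = alpha, fdr_method = "BH", erc_min = erc_min,
                 erc_sample_frac = erc_sample_frac),
            class = "stats_config")
}

#' Filter genes on expected read counts
#'
#' A gene is kept iff its count exceeds `erc_min` in strictly more than
#' `erc_sample_frac` of the samples. A gene at exactly the count threshold in
#' every sample, or above it in exactly half the samples, is removed.
#'
#' @param counts numeric matrix, genes x samples, raw expected read counts.
#' @param cfg a [stats_config()].
#' @return the row-subset matrix of kept genes.
#' @export
filter_genes <- function(counts, cfg = stats_config()) {
  stopifnot(is.matrix(counts), nrow(counts) > 0, ncol(counts) > 0)
  keep <- rowSums(counts > cfg$erc_min) > cfg$erc_sample_frac * ncol(counts)
  counts[keep, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} ( m * p_(j) / j )`, capped at 1, mapped back to the
#' input order. Monotone in rank; a single p-value is unchanged.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA passed through).
#' @return adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- q
  out
}

#' Pearson correlation with two-sided p-value
#'
#' Textbook Pearson r with `t = r * sqrt((n - 2) / (1 - r^2))`,
#' `df = n - 2`. Zero variance in either vector yields `NA` with a warning
#' flag rather than a spurious value.
#'
#' @param x,y numeric vectors, `n >= 3`, finite.
#' @return list `(r, p, n, df, flag)`; `flag` is `"zero_variance"` or `NA`.
#' @export
corr_unadjusted <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - 2L,
                flag = "zero_variance"))
  }
  r <- stats::cor(x, y)
  df <- n - 2L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  list(r = r, p = min(p, 1), n = n, df = df, flag = NA_character_)
}

#' Age-adjusted (multilevel) Pearson correlation
#'
#' The "multilevel" correlation treats the grouping variable (age group) as a
#' random offset: both variables are mean-centered within each group and
#' Pearson's r is computed on the pooled centered values, with
#' `df = n - g - 1` (g = number of groups) feeding the t-transform p-value.
#' This is the standard construction behind partial/multilevel correlation
#' calls, and removes any association carried purely by group-level shifts.
#' Groups with fewer than 2 observations are dropped with a warning.
#'
#' @param x,y numeric vectors.
#' @param group grouping factor (e.g. age group), >= 1 level after dropping.
#' @return list `(r, p, n, df, g, flag)`.
#' @export
corr_age_adjusted <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  group <- as.factor(group)
  sizes <- table(group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("dropping group(s) with n < 2: %s",
                    paste(small, collapse = ", ")))
    keep <- !(group %in% small)
    x <- x[keep]; y <- y[keep]; group <- droplevels(group[keep])
  }
  n <- length(x)
  g <- nlevels(group)
  if (n < g + 3L) stop("too few observations after dropping small groups",
                       call. = FALSE)
  xc <- x - stats::ave(x, group)
  yc <- y - stats::ave(y, group)
  if (stats::sd(xc) == 0 || stats::sd(yc) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, df = n - g - 1L, g = g,
                flag = "zero_variance"))
  }
  r <- stats::cor(xc, yc)
  df <- n - g - 1L
  tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df)
  list(r = r, p = min(p, 1), n = n, df = df, g = g, flag = NA_character_)
}

#' Classify genes by when their load correlation is significant
#'
#' Categories are determined solely by the two uncorrected p-values at level
#' `alpha`: significant only before age adjustment = `age_dependent`
#' (association carried by the shared age shift); only after =
#' `age_independent` (association within age groups, unmasked by removing
#' age-driven variance); both = `both`; neither = `ns`.
#'
#' @param p_unadjusted,p_adjusted numeric vectors of uncorrected p-values.
#' @param cfg a [stats_config()].
#' @return factor with levels `age_dependent`, `age_independent`, `both`,
#'   `ns`.
#' @export
classify_genes <- function(p_unadjusted, p_adjusted, cfg = stats_config()) {
  stopifnot(length(p_unadjusted) == length(p_adjusted))
  a <- cfg$alpha
  su <- p_unadjusted < a
  sa <- p_adjusted < a
  out <- rep("ns", length(su))
  out[su & !sa] <- "age_dependent"
  out[!su & sa] <- "age_independent"
  out[su & sa] <- "both"
  factor(out, levels = c("age_dependent", "age_independent", "both", "ns"))
}

#' Correlate gene expression with regional load, with and without age
#' adjustment
#'
#' Runs [corr_unadjusted()] and [corr_age_adjusted()] for every gene against
#' one load vector, FDR-adjusts each p-value family, and classifies genes.
#'
#' @param expr numeric matrix, genes x samples (normalized expression).
#' @param load numeric vector of per-sample regional loads.
#' @param age_group grouping factor per sample.
#' @param cfg a [stats_config()].
#' @return data.table per gene: `r_unadjusted, p_unadjusted, q_unadjusted,
#'   r_adjusted, p_adjusted, q_adjusted, category`.
#' @export
correlate_load_expression <- function(expr, load, age_group,
                                      cfg = stats_config()) {
  stopifnot(is.matrix(expr), ncol(expr) == length(load),
            length(load) == length(age_group))
  res <- lapply(seq_len(nrow(expr)), function(i) {
    un <- corr_unadjusted(expr[i, ], load)
    ad <- corr_age_adjusted(expr[i, ], load, age_group)
    data.table::data.table(
      gene = if (is.null(rownames(expr))) as.character(i) else rownames(expr)[i],
      r_unadjusted = un$r, p_unadjusted = un$p,
      r_adjusted = ad$r, p_adjusted = ad$p)
  })
  dt <- data.table::rbindlist(res)
  dt[, q_unadjusted := bh_fdr(p_unadjusted)]
  dt[, q_adjusted := bh_fdr(p_adjusted)]
  dt[, category := classify_genes(p_unadjusted, p_adjusted, cfg)]
  dt[]
}

#' Two-factor ANOVA for an age effect on regional load
#'
#' Fixed-effects ANOVA with age and strain as additive factors, Type-II sums
#' of squares (appropriate for the unbalanced strain cells):
#' `SS(age | strain) = RSS(load ~ strain) - RSS(load ~ age + strain)`.
#' Designs where age is confounded with strain (no residual df, or the age
#' term aliased) are flagged rather than reported.
#'
#' @param load numeric response vector.
#' @param age,strain factors per observation.
#' @return list `(F, p, df1, df2, flag)`.
#' @export
age_effect_test <- function(load, age, strain) {
  age <- droplevels(as.factor(age)); strain <- droplevels(as.factor(strain))
  stopifnot(length(load) == length(age), length(load) == length(strain))
  if (nlevels(age) < 2L) {
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                flag = "single_age_group"))
  }
  d <- data.frame(load = load, age = age, strain = strain)
  # a single-strain design degrades to one-way ANOVA on age
  has_strain <- nlevels(strain) >= 2L
  full <- if (has_strain) stats::lm(load ~ age + strain, data = d)
          else stats::lm(load ~ age, data = d)
  if (anyNA(stats::coef(full)[grep("^age", names(stats::coef(full)))])) {
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                flag = "age_aliased"))
  }
  reduced <- if (has_strain) stats::lm(load ~ strain, data = d)
             else stats::lm(load ~ 1, data = d)
  df2 <- stats::df.residual(full)
  if (df2 < 1L) {
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                flag = "no_residual_df"))
  }
  rss_full <- sum(stats::residuals(full)^2)
  rss_red <- sum(stats::residuals(reduced)^2)
  df1 <- stats::df.residual(reduced) - df2
  if (df1 < 1L) {
    # age adds no estimable df beyond strain: perfectly confounded
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                flag = "age_aliased"))
  }
  Fv <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(F = Fv, p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, flag = NA_character_)
}

#' Age-effect ANOVA across regions with FDR
#'
#' @param loads data.frame with columns `region_id`, `load_pct`, `age_group`,
#'   `strain` (and optionally `stain`, analyzed separately).
#' @return data.table per region (x stain): `F`, `p`, `q`, `flag`.
#' @export
age_effect_by_region <- function(loads) {
  dt <- data.table::as.data.table(loads)
  stopifnot(all(c("region_id", "load_pct", "age_group", "strain")
                %in% names(dt)))
  by_cols <- intersect(c("stain", "region_id"), names(dt))
  out <- dt[, {
    r <- age_effect_test(load_pct, age_group, strain)
    .(F = r$F, p = r$p, flag = r$flag)
  }, keyby = by_cols]
  if ("stain" %in% by_cols) {
    out[, q := bh_fdr(p), by = stain]
  } else {
    out[, q := bh_fdr(p)]
  }
  out[]
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares paired per-animal loads between two registration methods.
#' Zero differences are dropped (flagged `all_zero` with `p = 1` if nothing
#' remains). For `n <= 25` untied |differences| the two-sided p-value is
#' exact from the signed-rank null distribution; otherwise a normal
#' approximation with tie-corrected variance is used.
#'
#' @param x,y paired numeric vectors (e.g. linear and nonlinear loads).
#' @return list `(statistic, p, n, method, flag)`; `statistic` is V, the sum
#'   of ranks of positive differences.
#' @export
method_difference_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  if (!n) {
    return(list(statistic = NA_real_, p = 1, n = 0L, method = "degenerate",
                flag = "all_zero"))
  }
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  list(statistic = V, p = p, n = n, method = method, flag = NA_character_)
}

#' Method-difference tests across regions with FDR
#'
#' @param linear,nonlinear data.frames with `brain_id`, `region_id`,
#'   `load_pct` (and optionally `stain`); rows paired by brain within
#'   region (x stain).
#' @return data.table per region (x stain): `statistic`, `p`, `q`, `n`.
#' @export
method_difference_by_region <- function(linear, nonlinear) {
  lin <- data.table::as.data.table(linear)
  non <- data.table::as.data.table(nonlinear)
  keys <- intersect(c("brain_id", "stain", "region_id"), names(lin))
  merged <- merge(lin[, c(keys, "load_pct"), with = FALSE],
                  non[, c(keys, "load_pct"), with = FALSE],
                  by = keys, suffixes = c("_linear", "_nonlinear"))
  by_cols <- setdiff(keys, "brain_id")
  out <- merged[, {
    r <- method_difference_test(load_pct_linear, load_pct_nonlinear)
    .(statistic = r$statistic, p = r$p, n = r$n, flag = r$flag)
  }, keyby = by_cols]
  if ("stain" %in% by_cols) out[, q := bh_fdr(p), by = stain]
  else out[, q := bh_fdr(p)]
  out[]
}
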
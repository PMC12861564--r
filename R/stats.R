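#' Chi-square test on a subtype-by-category contingency table
#'
#' Pearson chi-square with `df = (r-1)(c-1)`; for 2x2 tables the Yates
#' continuity correction is applied by default (the convention used for
#' the cohort contingency comparisons). All-zero rows or columns are
#' dropped with a warning before testing.
#'
#' @param table matrix of nonnegative counts (rows = subtype).
#' @param yates_2x2 apply continuity correction when the table is 2x2.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(table, yates_2x2 = TRUE) {
  tab <- as.matrix(table)
  if (any(tab < 0) || sum(tab) == 0) stop("invalid contingency table")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero rows/columns")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  correct <- yates_2x2 && all(dim(tab) == c(2L, 2L))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Returns the U statistic for `x` (number of (x, y) pairs with x > y,
#' ties counting 1/2), the tie-corrected Z statistic (signed, with an
#' optional continuity correction toward zero), and the two-sided
#' normal-approximation p-value.
#'
#' @param x,y numeric samples.
#' @param continuity apply the 0.5 continuity correction.
#' @return List with `U`, `Z`, `p`.
#' @export
mann_whitney <- function(x, y, continuity = TRUE) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  n1 <- length(x); n2 <- length(y); nn <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  if (sigma2 <= 0) return(list(U = u, Z = 0, p = 1))
  cc <- if (continuity) sign(u - mu) * 0.5 else 0
  z <- (u - mu - cc) / sqrt(sigma2)
  list(U = u, Z = z, p = 2 * pnorm(-abs(z)))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' @param os_days survival/censoring times.
#' @param event 1 = death observed, 0 = censored.
#' @param group two-level grouping.
#' @return List with `fit` (a `survival::survfit` object), `chisq`
#'   (log-rank statistic), `p`.
#' @export
km_logrank <- function(os_days, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2L) stop("need two groups")
  if (any(tapply(event, group, sum) == 0))
    warning("a group has no events; log-rank may be unstable")
  sf <- survival::survfit(survival::Surv(os_days, event) ~ group)
  sd_ <- survival::survdiff(survival::Surv(os_days, event) ~ group)
  df <- length(sd_$n) - 1
  list(fit = sf, chisq = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit for the subtype survival model
#'
#' Fits a Cox model (Breslow tie handling, Newton-Raphson partial
#' likelihood) of overall survival on a covariate data.frame and
#' returns the per-covariate coefficient table with Wald statistics and
#' hazard ratios. The canonical covariate coding for the cohort
#' analysis is subtype (high- vs low-risk), dichotomized age (>= 52
#' years), gender, WHO grade (3 and 4 vs 2), and dichotomized tumor
#' volume (>= 91 cm^3); [cox_subtype_table()] builds exactly that.
#'
#' @param os_days,event survival outcome.
#' @param covariates data.frame of covariates (factors or numerics).
#' @return data.frame with columns `term`, `b`, `se`, `z`, `p`, `hr`,
#'   `hr_lo`, `hr_hi` (Wald 95% CI).
#' @export
cox_fit <- function(os_days, event, covariates) {
  covariates <- as.data.frame(covariates)
  if (any(vapply(covariates, function(v) length(unique(v)) < 2L, TRUE)))
    stop("constant covariate")
  dat <- cbind(data.frame(.time = os_days, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "breslow")
  if (!is.null(fit$fail)) stop("cox fit failed: ", fit$fail)
  sm <- summary(fit)
  co <- sm$coefficients
  data.frame(term = rownames(co), b = co[, "coef"], se = co[, "se(coef)"],
             z = co[, "z"], p = co[, "Pr(>|z|)"], hr = exp(co[, "coef"]),
             hr_lo = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
             hr_hi = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
             row.names = NULL)
}

#' Cox model with the canonical cohort covariate coding
#'
#' @param clinical a [clinical_table()].
#' @param labels subtype label per sample; `high_level` names the
#'   high-risk subtype (non-reference).
#' @param high_level value of `labels` treated as high-risk.
#' @param age_cut,volume_cut dichotomization cutpoints (52 years,
#'   91 cm^3).
#' @return Coefficient table as in [cox_fit()].
#' @export
cox_subtype_table <- function(clinical, labels, high_level = 1,
                              age_cut = 52, volume_cut = 91) {
  cov <- data.frame(
    subtype_high = as.integer(labels == high_level),
    age_ge = as.integer(clinical$age_years >= age_cut),
    gender_male = as.integer(clinical$gender == "male"),
    grade = factor(clinical$grade, levels = c(2, 3, 4)),
    volume_ge = as.integer(clinical$tumor_volume_cm3 >= volume_cut))
  cox_fit(clinical$os_days, clinical$event, cov)
}

#' Point-biserial correlation between subtype and tumor volume
#'
#' Pearson correlation of a binary subtype coding with volume, with a
#' Fisher-z 95% confidence interval.
#'
#' @param labels binary subtype labels (coerced to 0/1 numerically).
#' @param volumes tumor volumes.
#' @return List with `r`, `ci` (length-2).
#' @export
subtype_volume_correlation <- function(labels, volumes) {
  x <- as.numeric(as.factor(labels))
  if (length(unique(x)) != 2L) stop("labels must be binary")
  if (sd(volumes) == 0 || sd(x) == 0) stop("zero variance")
  ct <- stats::cor.test(x, volumes)
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int))
}

#' Pathway activity scores by per-sample multivariate linear model
#'
#' For each sample, ordinary least squares regresses the sample's gene
#' expression vector jointly on all pathway weight columns (plus
#' intercept); the score of a pathway is the t-value of its slope. A
#' positive t indicates pathway activation, negative inhibition.
#'
#' @param expression samples x genes matrix.
#' @param weights genes x pathways (sparse, signed) weight matrix; gene
#'   names are matched against expression columns.
#' @return Matrix samples x pathways of t-values (class
#'   `pathway_scores`).
#' @export
pathway_scores_mlm <- function(expression, weights) {
  expression <- as.matrix(expression); weights <- as.matrix(weights)
  genes <- intersect(colnames(expression), rownames(weights))
  if (length(genes) < ncol(weights) + 2L)
    stop("need at least pathways + 2 shared genes")
  e <- expression[, genes, drop = FALSE]
  w <- weights[genes, , drop = FALSE]
  x <- cbind(`(Intercept)` = 1, w)
  qx <- qr(x)
  if (qx$rank < ncol(x)) stop("rank-deficient pathway weight matrix")
  xtx_inv <- chol2inv(qr.R(qx))
  coefs <- xtx_inv %*% crossprod(x, t(e))       # (p+1) x n
  fitted <- x %*% coefs
  dfree <- length(genes) - ncol(x)
  rss <- colSums((t(e) - fitted)^2)
  sigma <- pmax(sqrt(rss / dfree), .Machine$double.eps)  # exact fits stay finite
  se <- sqrt(diag(xtx_inv))                      # per-coefficient unit SE
  tval <- coefs / (outer(se, sigma))
  scores <- t(tval[-1L, , drop = FALSE])         # drop intercept
  dimnames(scores) <- list(rownames(expression), colnames(w))
  class(scores) <- c("pathway_scores", class(scores))
  scores
}

#' Between-group comparison of pathway scores
#'
#' Welch two-sided t-test per pathway on per-sample scores. The sign
#' convention is `mean(high group) - mean(low group)`: positive t means
#' the pathway is more active in the high-risk group.
#'
#' @param scores matrix from [pathway_scores_mlm()].
#' @param groups two-level grouping per sample.
#' @param high value of `groups` treated as the high-risk group
#'   (default: first sorted level).
#' @return data.frame with `pathway`, `t`, `p`.
#' @export
pathway_group_compare <- function(scores, groups, high = NULL) {
  groups <- as.vector(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("need exactly two groups")
  high <- high %||% lv[1L]
  hi <- groups == high
  if (min(sum(hi), sum(!hi)) < 2L) stop("each group needs >= 2 samples")
  res <- t(vapply(seq_len(ncol(scores)), function(j) {
    tt <- t.test(scores[hi, j], scores[!hi, j])
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2)))
  data.frame(pathway = colnames(scores), t = res[, 1L], p = res[, 2L],
             row.names = NULL)
}

#' Hypergeometric enrichment of altered radiomic features in clusters
#'
#' Features are z-scored; a sample's value is called over-expressed if
#' it exceeds the cohort 75th percentile of that feature and
#' under-expressed below the 25th percentile (linear-interpolation
#' quantiles, pooled across the cohort). For every (feature, cluster,
#' direction) the upper-tail hypergeometric probability of the altered
#' count inside the cluster is computed, Benjamini-Hochberg adjusted in
#' one family, and a record is flagged significant when `q <
#' fdr_level`, at least `frac_in` of the cluster is altered, and fewer
#' than `frac_out` of the samples in at least one other cluster are.
#'
#' @param features a [feature_table()] or numeric matrix.
#' @param labels cluster assignment (>= 2 clusters).
#' @param fdr_level BH threshold (default 0.05).
#' @param upper_q,lower_q percentile thresholds (0.75 / 0.25).
#' @param frac_in,frac_out alteration-fraction filters (2/3, 1/3).
#' @return data.frame of enrichment records: `feature`, `cluster`,
#'   `direction`, `k_in`, `cluster_size`, `k_total`, `n`, `p`, `q`,
#'   `passes_fraction_filter`, `significant`.
#' @export
radiomic_enrichment <- function(features, labels, fdr_level = 0.05,
                                upper_q = 0.75, lower_q = 0.25,
                                frac_in = 2 / 3, frac_out = 1 / 3) {
  x <- zscore(as.matrix(features))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop("need at least 2 clusters")
  n <- nrow(x)
  hi <- apply(x, 2, quantile, probs = upper_q)
  lo <- apply(x, 2, quantile, probs = lower_q)
  over <- sweep(x, 2, hi, ">")
  under <- sweep(x, 2, lo, "<")
  rec <- list()
  for (dir in c("over", "under")) {
    alt <- if (dir == "over") over else under
    k_tot <- colSums(alt)
    for (g in cl) {
      in_g <- labels == g
      m <- sum(in_g)
      k_in <- colSums(alt[in_g, , drop = FALSE])
      fr_in <- k_in / m
      fr_out_min <- vapply(seq_len(ncol(x)), function(j) {
        min(vapply(setdiff(cl, g), function(h)
          mean(alt[labels == h, j]), 0))
      }, 0)
      p <- phyper(k_in - 1, k_tot, n - k_tot, m, lower.tail = FALSE)
      rec[[length(rec) + 1L]] <- data.frame(
        feature = colnames(x), cluster = g, direction = dir,
        k_in = k_in, cluster_size = m, k_total = k_tot, n = n, p = p,
        passes_fraction_filter = fr_in >= frac_in & fr_out_min < frac_out,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rec)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr_level & out$passes_fraction_filter
  out[, c("feature", "cluster", "direction", "k_in", "cluster_size",
          "k_total", "n", "p", "q", "passes_fraction_filter",
          "significant")]
}
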
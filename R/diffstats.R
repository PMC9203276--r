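#' Benjamini-Hochberg adjustment with NA propagation
#'
#' Step-up false discovery rate control over the non-missing p values;
#' missing entries stay missing and do not count towards the number of
#' tests.
#'
#' @param p Numeric vector of p values in `[0, 1]` (NA allowed).
#' @return Adjusted p values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    abort_data("p values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Median-of-ratios size factors
#'
#' Standard library-size normalization for count matrices: per sample, the
#' median ratio to the per-feature geometric mean, computed over features
#' that are positive in every sample.
#'
#' @param counts Numeric matrix (features x samples).
#' @return Named numeric vector of size factors (one per column).
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_gm <- rowMeans(log(counts))
  use <- is.finite(log_gm)
  if (!any(use)) {
    return(setNames(rep(1, ncol(counts)), colnames(counts)))
  }
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnts) {
    exp(median(log(cnts) - log_gm[use]))
  })
  setNames(sf, colnames(counts))
}

#' Convert RPGC region means to integer pseudo-counts
#'
#' Scaled coverage tracks are continuous; the negative-binomial test needs
#' count support. A region at mean RPGC `m` and width `w` corresponds to
#' about `m * w / fragment_length` fragments, which is rounded to the
#' nearest integer.
#'
#' @param mean_rpgc Numeric vector of region mean RPGC values.
#' @param width Region widths (bp).
#' @param fragment_length Fragment length used for the tracks (bp).
#' @return Integer vector of pseudo-counts.
#' @export
rpgc_to_counts <- function(mean_rpgc, width, fragment_length = 150L) {
  as.integer(round(mean_rpgc * width / fragment_length))
}

# method-of-moments NB dispersion from normalized counts of one group;
# Var(K/s) = mu * mean(1/s) + alpha * mu^2
mom_dispersion_group <- function(y, s) {
  n <- ncol(y)
  m <- rowMeans(y)
  v <- rowSums((y - m)^2) / (n - 1)
  a <- (v - m * mean(1 / s)) / m^2
  a[!is.finite(a)] <- NA_real_
  a
}

# mean dispersion in 10 log-mean quantile bins, linearly interpolated; the
# bin mean (not median) is used because the method-of-moments estimator at
# few replicates is right-skewed and its median underestimates the typical
# dispersion, which makes the Wald test anticonservative
dispersion_trend <- function(alpha, base_mean, n_bins = 10) {
  ok <- is.finite(alpha) & alpha > 0 & base_mean > 0
  if (sum(ok) < n_bins) {
    return(rep(mean(alpha[ok]) %||% 1e-2, length(alpha)))
  }
  lm_ <- log(base_mean[ok])
  br <- quantile(lm_, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- br[1] - 1e-9
  bin <- cut(lm_, breaks = unique(br), include.lowest = TRUE)
  med <- tapply(alpha[ok], bin, mean)
  mid <- tapply(lm_, bin, median)
  fit <- approx(mid, med, xout = log(pmax(base_mean, min(base_mean[ok]))), rule = 2)$y
  fit[!is.finite(fit)] <- mean(alpha[ok])
  fit
}

# Newton iterations for the NB group mean on the log scale with known
# dispersion and fixed size factors; returns list(q, info)
nb_group_mean <- function(K, s, alpha, iter = 25) {
  m <- sweep(K, 2, s, "/")
  q <- rowMeans(m)
  pos <- q > 0
  beta <- rep(-Inf, nrow(K))
  beta[pos] <- log(q[pos])
  for (it in seq_len(iter)) {
    mu <- exp(beta[pos]) %o% s
    w <- 1 + alpha[pos] * mu
    score <- rowSums((K[pos, , drop = FALSE] - mu) / w)
    info <- rowSums(mu / w)
    step <- score / pmax(info, 1e-12)
    step <- pmax(pmin(step, 5), -5)
    beta[pos] <- beta[pos] + step
    if (max(abs(step)) < 1e-10) break
  }
  q_hat <- exp(beta)
  q_hat[!pos] <- 0
  # Fisher information at the estimate (zero groups evaluated at the
  # fold-change pseudocount so the Wald SE stays finite)
  q_se <- ifelse(q_hat > 0, q_hat, 0.1)
  mu <- q_se %o% s
  info <- rowSums(mu / (1 + alpha * mu))
  list(q = q_hat, info = info)
}

#' Negative-binomial Wald test with fixed size factors
#'
#' A DESeq2-like two-group differential test operating on integer counts
#' with user-supplied (fixed) size factors, as needed when the inputs are
#' already quantitatively scaled: per feature, dispersion is estimated by
#' method of moments (floored at 1e-4) and shrunk towards a 10-bin mean
#' trend over the mean (weight 1/4 on the feature estimate, chosen so the
#' test holds its nominal size at three replicates); group means are fitted by
#' maximum likelihood under the NB model with a log link; the Wald statistic
#' `log2fc / se` is referred to a standard normal, two-sided. A pseudocount
#' of 0.1 is added to both group means before the ratio when one of them is
#' zero. Features with zero counts in both conditions get `log2fc = 0` and a
#' missing p value (excluded from the BH adjustment). This is a documented
#' approximation of DESeq2 (no Cox-Reid adjustment, no empirical-Bayes
#' posterior); aggregate ratios are robust to the difference.
#'
#' @param counts Tibble whose first column is the feature id and remaining
#'   columns are integer sample counts, or a matrix with feature rownames.
#' @param design Tibble with columns `sample` and `condition` covering the
#'   count columns.
#' @param condition_a,condition_b Conditions to compare; `log2fc` is B over
#'   A.
#' @param size_factors Named numeric vector (default all 1, i.e. counts are
#'   already on a common scale).
#' @return Tibble of class `nb_diff`: `feature`, `base_mean`, `log2fc`,
#'   `lfc_se`, `stat`, `pvalue`, `padj`, with the comparison recorded in
#'   attributes `condition_a`/`condition_b`.
#' @export
nb_wald_test <- function(counts, design, condition_a, condition_b,
                         size_factors = NULL) {
  if (is.matrix(counts)) {
    features <- rownames(counts)
    K_all <- counts
  } else {
    counts <- as_tibble(counts)
    features <- as.character(counts[[1]])
    K_all <- as.matrix(counts[, -1])
    rownames(K_all) <- features
  }
  design <- as_tibble(design)
  for (cond in c(condition_a, condition_b)) {
    smp <- design$sample[design$condition == cond]
    if (length(smp) < 2) {
      abort_config(sprintf("condition '%s' needs >= 2 replicates", cond))
    }
    if (!all(smp %in% colnames(K_all))) {
      abort_data(sprintf("count columns missing for condition '%s'", cond))
    }
  }
  sA <- design$sample[design$condition == condition_a]
  sB <- design$sample[design$condition == condition_b]
  if (is.null(size_factors)) {
    size_factors <- setNames(rep(1, ncol(K_all)), colnames(K_all))
  }
  if (any(size_factors[c(sA, sB)] <= 0)) {
    abort_config("size factors must be > 0")
  }
  KA <- K_all[, sA, drop = FALSE]
  KB <- K_all[, sB, drop = FALSE]
  fA <- unname(size_factors[sA])
  fB <- unname(size_factors[sB])
  yA <- sweep(KA, 2, fA, "/")
  yB <- sweep(KB, 2, fB, "/")
  base_mean <- rowMeans(cbind(yA, yB))

  # per-feature method-of-moments dispersion, pooled over the two groups
  aA <- mom_dispersion_group(yA, fA)
  aB <- mom_dispersion_group(yB, fB)
  dfA <- length(sA) - 1
  dfB <- length(sB) - 1
  alpha_raw <- purrr::map2_dbl(aA, aB, function(x, y) {
    if (is.na(x) && is.na(y)) {
      return(NA_real_)
    }
    stats::weighted.mean(c(x, y), c(dfA, dfB), na.rm = TRUE)
  })
  alpha_mom <- pmax(alpha_raw, 1e-4)
  alpha_mom[is.na(alpha_mom)] <- 1e-4
  trend <- pmax(dispersion_trend(alpha_mom, base_mean), 1e-4)
  # shrink strongly towards the trend: at 2-3 replicates the per-feature
  # moment estimate carries little information, and weighting it above ~1/4
  # leaves the Wald test visibly anticonservative
  alpha <- pmax(0.25 * alpha_mom + 0.75 * trend, 1e-4)

  fitA <- nb_group_mean(KA, fA, alpha)
  fitB <- nb_group_mean(KB, fB, alpha)
  qA <- fitA$q
  qB <- fitB$q

  zero_any <- qA == 0 | qB == 0
  log2fc <- ifelse(
    zero_any,
    log2((qB + 0.1) / (qA + 0.1)),
    (log(qB) - log(qA)) / log(2)
  )
  se <- sqrt(1 / fitA$info + 1 / fitB$info) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * pnorm(-abs(stat))

  both_zero <- qA == 0 & qB == 0
  log2fc[both_zero] <- 0
  stat[both_zero] <- NA_real_
  pvalue[both_zero] <- NA_real_

  out <- tibble(
    feature = features, base_mean = base_mean, log2fc = log2fc,
    lfc_se = se, stat = stat, pvalue = pvalue,
    padj = bh_adjust(pvalue)
  )
  class(out) <- c("nb_diff", class(out))
  attr(out, "condition_a") <- condition_a
  attr(out, "condition_b") <- condition_b
  out
}

#' Flag significant features by FDR and fold-change thresholds
#'
#' @param diff A differential-result tibble (`log2fc`, `padj`).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fc_threshold Linear fold-change cutoff (default 1.5; use 2 for the
#'   RNA-seq rule FDR < 5 percent and |log2FC| > 1).
#' @return The table with logical `significant_up` / `significant_down`
#'   columns (`up` means `padj < alpha` and `log2fc > log2(fc_threshold)`),
#'   thresholds recorded as attributes.
#' @export
call_significant <- function(diff, alpha = 0.05, fc_threshold = 1.5) {
  lfc_cut <- log2(fc_threshold)
  out <- as_tibble(diff) |>
    mutate(
      significant_up = !is.na(.data$padj) & .data$padj < alpha & .data$log2fc > lfc_cut,
      significant_down = !is.na(.data$padj) & .data$padj < alpha & .data$log2fc < -lfc_cut
    )
  class(out) <- unique(c(class(diff)[1], class(out)))
  attr(out, "condition_a") <- attr(diff, "condition_a")
  attr(out, "condition_b") <- attr(diff, "condition_b")
  attr(out, "alpha") <- alpha
  attr(out, "fc_threshold") <- fc_threshold
  out
}

# exact two-sided rank-sum p by complete enumeration (midranks for ties):
# doubles the smaller tail probability of the rank-sum statistic
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(length(ranks), n1)
  w_all <- colSums(matrix(ranks[combos], nrow = n1))
  eps <- 1e-9
  p_lo <- mean(w_all <= w_obs + eps)
  p_hi <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_lo, p_hi))
}

#' Class-versus-all response statistics
#'
#' Compares the log2 fold changes of a gene class against those of all genes
#' (class included, matching the convention of comparing a class with the
#' full distribution): a two-sided unpaired Wilcoxon rank-sum test (exact
#' enumeration when both groups have at most `exact_limit` members, normal
#' approximation with tie correction otherwise) and Cohen's d on pooled
#' standard deviation.
#'
#' @param lfc Named numeric vector of log2 fold changes for all genes, or a
#'   tibble with `feature` and `log2fc` columns.
#' @param class_members Character vector of gene ids in the class.
#' @param label Class label recorded in the output.
#' @param exact_limit Group-size bound for the exact Wilcoxon path
#'   (default 10).
#' @return One-row tibble: `class`, `n_class`, `n_all`, `median_class_lfc`,
#'   `median_all_lfc`, `wilcoxon_p`, `cohens_d`.
#' @export
class_response <- function(lfc, class_members, label = "class",
                           exact_limit = 10L) {
  if (is.data.frame(lfc)) {
    lfc <- setNames(lfc$log2fc, lfc$feature)
  }
  lfc <- lfc[is.finite(lfc)]
  cls <- lfc[names(lfc) %in% class_members]
  if (length(cls) == 0) {
    abort_data(sprintf("class '%s' has no members with finite values", label))
  }
  all_v <- unname(lfc)
  cls_v <- unname(cls)
  if (length(cls_v) <= exact_limit && length(all_v) <= exact_limit) {
    p <- exact_ranksum_p(cls_v, all_v)
  } else {
    p <- suppressWarnings(
      wilcox.test(cls_v, all_v, exact = FALSE, correct = FALSE)$p.value
    )
  }
  n1 <- length(cls_v)
  n2 <- length(all_v)
  pooled_var <- ((n1 - 1) * var(cls_v) + (n2 - 1) * var(all_v)) / (n1 + n2 - 2)
  if (n1 == 1) pooled_var <- var(all_v) # single-gene class: background SD
  d <- if (is.na(pooled_var) || pooled_var <= 0) {
    NA_real_
  } else {
    (mean(cls_v) - mean(all_v)) / sqrt(pooled_var)
  }
  tibble(
    class = label, n_class = n1, n_all = n2,
    median_class_lfc = median(cls_v), median_all_lfc = median(all_v),
    wilcoxon_p = p, cohens_d = d
  )
}
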
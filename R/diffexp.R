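#' Unpaired two-sample Student's t-test
#'
#' Pooled-variance two-tailed t-test, `df = n_x + n_y - 2`. Degenerate
#' variance is resolved deterministically: zero pooled variance with
#' equal means gives `t = 0, p = 1`; with unequal means `p = 0` and the
#' `degenerate` flag is set.
#'
#' @param x,y Numeric vectors of at least 2 values each.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `degenerate`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
unpaired_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop_pq("each group needs at least 2 values")
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  delta <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (delta == 0) {
      return(tibble::tibble(t_stat = 0, df = df, p_value = 1,
                            degenerate = FALSE))
    }
    return(tibble::tibble(t_stat = sign(delta) * Inf, df = df,
                          p_value = 0, degenerate = TRUE))
  }
  t_stat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  tibble::tibble(t_stat = t_stat, df = df,
                 p_value = 2 * pt(-abs(t_stat), df), degenerate = FALSE)
}

# Vectorised pooled t over the rows of two matrices (one protein per
# row). Same degenerate-variance conventions as unpaired_t_test().
row_t_test <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  df <- na + nb - 2
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  sp2 <- (ssa + ssb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  delta <- mb - ma
  t_stat <- delta / se
  p <- 2 * pt(-abs(t_stat), df)
  degen <- sp2 <= 0
  t_stat[degen & delta == 0] <- 0
  p[degen & delta == 0] <- 1
  t_stat[degen & delta != 0] <- sign(delta[degen & delta != 0]) * Inf
  p[degen & delta != 0] <- 0
  tibble::tibble(mean_a = ma, mean_b = mb, log2fc = delta,
                 t_stat = t_stat, df = df, p_value = p,
                 degenerate = degen & delta != 0)
}

# Number of step-up rejections at level `alpha` under the two-stage
# adaptive (Benjamini-Krieger-Yekutieli) procedure, given the sorted
# BH-adjusted p-values. Both stages are linear step-ups over the same
# statistic: a step-up at level t rejects #{adjusted p <= t} hypotheses.
bky_n_reject <- function(sorted_padj, alpha) {
  m <- length(sorted_padj)
  q1 <- alpha / (1 + alpha)
  r1 <- findInterval(q1, sorted_padj)
  if (r1 == 0) return(0L)
  if (r1 == m) return(m)
  findInterval(q1 * m / (m - r1), sorted_padj)
}

#' Benjamini-Krieger two-stage adaptive FDR adjustment
#'
#' The two-stage linear step-up procedure: stage one is a
#' Benjamini-Hochberg step-up at level `q' = fdr_level / (1 + fdr_level)`
#' yielding `r1` rejections; with `r1 = 0` nothing is rejected, with
#' `r1 = m` everything is; otherwise the number of true nulls is
#' estimated as `m0_hat = m - r1` and stage two is a BH step-up at level
#' `q' * m / m0_hat`. The per-hypothesis q-value is the smallest nominal
#' FDR level at which that hypothesis is rejected, found by bisection to
#' 1e-6; the `rejected` flags come from the exact decision at
#' `fdr_level` (they agree with `q_value < fdr_level` to the bisection
#' tolerance).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param fdr_level Target FDR in (0, 1).
#' @return A list: `q_values` (same order as input), `rejected` (logical),
#'   `m0_hat` (estimated number of true nulls at `fdr_level`).
#' @examples
#' bky_adjust(c(0.001, 0.008, 0.04, 0.2, 0.9), fdr_level = 0.05)
#' @export
bky_adjust <- function(p_values, fdr_level = 0.01) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop_pq("p-values must lie in [0, 1]")
  if (fdr_level <= 0 || fdr_level >= 1)
    stop_pq("fdr_level must lie in (0, 1)")
  m <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  # BH-adjusted p: monotone min over m * p_(k) / k from the top
  padj <- rev(cummin(rev(p_sorted * m / seq_len(m))))
  padj <- pmin(padj, 1)

  n_rej <- bky_n_reject(padj, fdr_level)
  rejected_sorted <- seq_len(m) <= n_rej
  r1 <- findInterval(fdr_level / (1 + fdr_level), padj)
  m0_hat <- m - r1

  # q-value of the hypothesis of sorted rank k: smallest alpha with
  # n_reject(alpha) >= k. n_reject is non-decreasing in alpha.
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    if (k > 1 && padj[k] == padj[k - 1]) {
      q_sorted[k] <- q_sorted[k - 1]
      next
    }
    if (bky_n_reject(padj, 1 - 1e-9) < k) {
      q_sorted[k] <- 1
      next
    }
    lo <- 0; hi <- 1
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (bky_n_reject(padj, mid) >= k) hi <- mid else lo <- mid
    }
    q_sorted[k] <- hi
  }
  # enforce monotonicity in rank (bisection noise could break ties)
  q_sorted <- cummax(q_sorted)

  q_values <- numeric(m); q_values[ord] <- q_sorted
  rejected <- logical(m); rejected[ord] <- rejected_sorted
  list(q_values = q_values, rejected = rejected, m0_hat = as.integer(m0_hat))
}

#' Per-protein differential expression between two groups
#'
#' For every protein: group means on the log2 scale,
#' `log2fc = mean_b - mean_a`, a pooled-variance unpaired two-tailed
#' t-test, then a joint Benjamini-Krieger FDR adjustment over all
#' proteins, and DEP calling against the q-value and fold-change
#' thresholds. Records are sorted by q then p.
#'
#' @param data Log2-scale wide abundance tibble (after
#'   [preprocess_lfq()] or [log2_view()]); must have no missing cells.
#' @param metadata Sample metadata with `sample_id` and `group`.
#' @param group_a,group_b Group labels to compare; `log2fc > 0` means
#'   higher in `group_b`.
#' @param q_threshold DEP q-value cutoff (default 0.01).
#' @param log2fc_threshold DEP absolute log2 fold-change cutoff
#'   (default 1).
#' @param fdr_level Nominal FDR of the adjustment (default 0.01).
#' @return Tibble with one row per protein: `protein_id`, `mean_a`,
#'   `mean_b`, `log2fc`, `t_stat`, `df`, `p_value`, `q_value`, `is_dep`.
#'   Comparison parameters are attached as attribute `comparison`.
#' @export
run_comparison <- function(data, metadata, group_a, group_b,
                           q_threshold = 0.01, log2fc_threshold = 1,
                           fdr_level = 0.01) {
  if (identical(group_a, group_b)) stop_pq("group_a and group_b must differ")
  if (nrow(data) == 0) stop_pq("no proteins to test")
  check_metadata(data, metadata)
  samples <- sample_cols(data)
  grp <- setNames(metadata$group, metadata$sample_id)[samples]
  sa <- samples[grp == group_a]
  sb <- samples[grp == group_b]
  if (length(sa) < 2 || length(sb) < 2)
    stop_pq("both groups need >= 2 samples (got %d in %s, %d in %s)",
            length(sa), group_a, length(sb), group_b)
  xa <- as.matrix(data[sa]); xb <- as.matrix(data[sb])
  if (anyNA(xa) || anyNA(xb))
    stop_pq("data contains missing cells; impute before testing")

  res <- row_t_test(xa, xb)
  adj <- bky_adjust(res$p_value, fdr_level)
  out <- dplyr::bind_cols(tibble::tibble(protein_id = data$protein_id), res)
  out$q_value <- adj$q_values
  out <- call_deps(out, q_threshold = q_threshold,
                   log2fc_threshold = log2fc_threshold)
  out <- dplyr::arrange(out, .data$q_value, .data$p_value)
  attr(out, "comparison") <- list(
    group_a = group_a, group_b = group_b, q_threshold = q_threshold,
    log2fc_threshold = log2fc_threshold, fdr_level = fdr_level,
    m0_hat = adj$m0_hat)
  out
}

#' Flag differentially expressed proteins
#'
#' A record is a DEP iff `q_value < q_threshold` and
#' `|log2fc| > log2fc_threshold` (both strict, as published:
#' q < 0.01 and absolute log2 FC > 1).
#'
#' @param records Tibble with `q_value` and `log2fc` columns.
#' @param q_threshold,log2fc_threshold DEP thresholds.
#' @return `records` with the `is_dep` logical column set.
#' @export
call_deps <- function(records, q_threshold = 0.01, log2fc_threshold = 1) {
  dplyr::mutate(records,
                is_dep = .data$q_value < q_threshold &
                  abs(.data$log2fc) > log2fc_threshold)
}

#' Build a signed ranked list for enrichment tools
#'
#' Rank score is `sign(log2fc) * (-log10 p)`, descending; p-values are
#' clipped below at 1e-300. Ties break lexicographically on protein id.
#'
#' @param records Differential records with `protein_id`, `log2fc`,
#'   `p_value`.
#' @return Tibble `protein_id`, `rank_score`, ordered by descending
#'   score.
#' @export
build_ranked_list <- function(records) {
  records |>
    dplyr::mutate(rank_score = sign(.data$log2fc) *
                    -log10(pmax(.data$p_value, 1e-300))) |>
    dplyr::arrange(dplyr::desc(.data$rank_score), .data$protein_id) |>
    dplyr::select("protein_id", "rank_score")
}
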
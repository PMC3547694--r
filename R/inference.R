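# Randomized-complete-block two-way ANOVA (one observation per cell),
# Tukey HSD pairwise comparisons, and the compact line-grouping display.

#' Randomized-complete-block ANOVA, one observation per cell
#'
#' Two-way additive analysis of variance for a complete blocks-by-treatments
#' matrix with a single observation per cell: here incidents are blocks
#' (rows) and indicators are treatments (columns). The total sum of squares
#' decomposes exactly into treatment, block and error components around the
#' grand, column and row means; there is no interaction term.
#'
#' @param matrix Numeric matrix, blocks in rows (b >= 2), treatments in
#'   columns (a >= 2), no missing cells.
#' @param treatment Label for the treatment factor in the output table.
#' @param block Label for the block factor.
#' @return An `anova_rcb` object: the ANOVA table as a data frame (`term`,
#'   `df`, `sum_sq`, `mean_sq`, `F`, `p`) plus `a`, `b`, `df_error`,
#'   `ms_error` and the treatment means.
#' @export
rcb_anova <- function(matrix, treatment = "indicator", block = "incident") {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix)) stop("matrix has missing cells", call. = FALSE)
  a <- ncol(matrix)
  b <- nrow(matrix)
  if (a < 2L || b < 2L) {
    stop("need at least 2 treatments and 2 blocks", call. = FALSE)
  }
  grand <- mean(matrix)
  col_means <- colMeans(matrix)
  row_means <- rowMeans(matrix)
  ss_treat <- b * sum((col_means - grand)^2)
  ss_block <- a * sum((row_means - grand)^2)
  ss_total <- sum((matrix - grand)^2)
  ss_error <- ss_total - ss_treat - ss_block
  # clamp float cancellation: a perfectly additive matrix has SS_error 0
  if (ss_error <= 1e-10 * max(ss_total, .Machine$double.eps)) ss_error <- 0

  df_treat <- a - 1L
  df_block <- b - 1L
  df_error <- df_treat * df_block
  ms_treat <- ss_treat / df_treat
  ms_block <- ss_block / df_block
  ms_error <- ss_error / df_error

  if (ms_error <= 0) {
    warning("zero error variance; F and p reported as exact limits",
            call. = FALSE)
    f_treat <- if (ms_treat > 0) Inf else 0
    f_block <- if (ms_block > 0) Inf else 0
    p_treat <- if (ms_treat > 0) 0 else 1
    p_block <- if (ms_block > 0) 0 else 1
  } else {
    f_treat <- ms_treat / ms_error
    f_block <- ms_block / ms_error
    p_treat <- stats::pf(f_treat, df_treat, df_error, lower.tail = FALSE)
    p_block <- stats::pf(f_block, df_block, df_error, lower.tail = FALSE)
  }

  tab <- data.frame(
    term = c(treatment, block, "error", "total"),
    df = c(df_treat, df_block, df_error, a * b - 1L),
    sum_sq = c(ss_treat, ss_block, ss_error, ss_total),
    mean_sq = c(ms_treat, ms_block, ms_error, NA_real_),
    F = c(f_treat, f_block, NA_real_, NA_real_),
    p = c(p_treat, p_block, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, a = a, b = b, df_error = df_error,
         ms_error = ms_error, treatment_means = col_means),
    class = "anova_rcb"
  )
}

#' Studentized range quantile
#'
#' Quantile of the studentized range distribution with `k` means and `df`
#' error degrees of freedom, as used by the Tukey HSD procedure. Delegates to
#' the vetted routine in \pkg{stats}.
#'
#' @param p Probability in (0, 1).
#' @param k Number of means (>= 2).
#' @param df Error degrees of freedom (>= 1).
#' @return The quantile `q` such that P(Q <= q) = p.
#' @export
studentized_range_quantile <- function(p, k, df) {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0,1)",
                                              call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stats::qtukey(p, nmeans = k, df = df)
}

#' Tukey HSD pairwise comparisons for an RCB design
#'
#' With equal replication (every treatment observed once in each of the `b`
#' blocks) the honestly-significant difference is a single constant,
#' `hsd = q * sqrt(MS_error / b)` with `q` the studentized-range quantile at
#' `(1 - alpha, a, (a-1)(b-1))`. A pair differs significantly iff its
#' absolute mean difference exceeds `hsd`; adjusted p-values come from the
#' studentized range CDF of `|diff| / sqrt(MS_error / b)`.
#'
#' @param matrix Blocks-by-treatments score matrix (see [rcb_anova()]).
#' @param alpha Familywise significance level, default 0.05.
#' @return A `tukey_result`: `alpha`, `q_critical`, `hsd`, `pairs` (data
#'   frame of all a(a-1)/2 comparisons: `i`, `j`, `diff`, `p_adj`,
#'   `significant`), `groups` (the compact line groups, see
#'   [line_grouping()]), `means`, and the underlying `anova` fit.
#' @export
tukey_hsd <- function(matrix, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  fit <- rcb_anova(matrix)
  a <- fit$a
  b <- fit$b
  means <- fit$treatment_means
  labels <- if (is.null(colnames(matrix))) {
    as.character(seq_len(a))
  } else {
    colnames(matrix)
  }

  if (fit$ms_error <= 0) {
    warning("zero error variance; every nonzero difference is significant",
            call. = FALSE)
    se <- 0
    q_crit <- NA_real_
    hsd <- 0
  } else {
    se <- sqrt(fit$ms_error / b)
    q_crit <- studentized_range_quantile(1 - alpha, a, fit$df_error)
    hsd <- q_crit * se
  }

  idx <- utils::combn(a, 2)
  diffs <- means[idx[2, ]] - means[idx[1, ]]
  p_adj <- if (se > 0) {
    stats::ptukey(abs(diffs) / se, nmeans = a, df = fit$df_error,
                  lower.tail = FALSE)
  } else {
    ifelse(abs(diffs) > 0, 0, 1)
  }
  pairs <- data.frame(
    i = labels[idx[1, ]], j = labels[idx[2, ]],
    diff = unname(diffs), p_adj = unname(p_adj),
    significant = unname(abs(diffs) > hsd),
    stringsAsFactors = FALSE
  )
  structure(
    list(alpha = alpha, q_critical = q_crit, hsd = hsd, pairs = pairs,
         groups = line_grouping(means, hsd, labels = labels),
         means = means, anova = fit),
    class = "tukey_result"
  )
}

#' Compact line grouping of treatment means
#'
#' Reproduces the underlining display in which treatments joined by a common
#' horizontal line do not differ significantly. Means are sorted ascending
#' and every maximal contiguous run whose range (max - min) is at most `hsd`
#' becomes one group. Valid under equal replication, where the significance
#' threshold is the single constant `hsd`, so i and j share a group iff
#' `|m_i - m_j| <= hsd`.
#'
#' @param means Numeric vector of treatment means.
#' @param hsd Non-negative honestly-significant difference.
#' @param labels Treatment labels reported in the groups; defaults to names
#'   of `means` or indices.
#' @return List of character vectors, one per line, ordered by ascending
#'   mean; every treatment appears in at least one group.
#' @export
line_grouping <- function(means, hsd, labels = NULL) {
  if (hsd < 0) stop("hsd must be non-negative", call. = FALSE)
  k <- length(means)
  if (is.null(labels)) {
    labels <- if (!is.null(names(means))) names(means) else
      as.character(seq_len(k))
  }
  ord <- order(means)
  m <- means[ord]
  lab <- labels[ord]
  groups <- list()
  last_end <- 0L
  for (start in seq_len(k)) {
    end <- start
    while (end < k && m[end + 1L] - m[start] <= hsd) end <- end + 1L
    if (end > last_end || start == 1L) {
      groups[[length(groups) + 1L]] <- lab[start:end]
      last_end <- end
    }
  }
  # drop non-maximal runs that can arise when start advances without
  # extending the end (subset of the previous group)
  keep <- rep(TRUE, length(groups))
  if (length(groups) > 1L) {
    for (g in 2:length(groups)) {
      if (all(groups[[g]] %in% groups[[g - 1L]])) keep[g] <- FALSE
    }
  }
  groups[keep]
}

#' Text underlining display of line groups
#'
#' Renders treatments on a baseline ordered by ascending mean, with one row
#' of dashes per group joining treatments that do not differ significantly.
#'
#' @param tukey A `tukey_result` from [tukey_hsd()].
#' @return Character vector of display lines.
#' @export
underline_display <- function(tukey) {
  ord <- order(tukey$means)
  lab <- names(tukey$means)[ord]
  if (is.null(lab)) lab <- as.character(seq_along(tukey$means))[ord]
  widths <- nchar(lab)
  starts <- cumsum(c(1, utils::head(widths + 2, -1)))
  header <- paste(lab, collapse = "  ")
  lines <- vapply(tukey$groups, function(g) {
    pos <- match(g, lab)
    from <- min(starts[pos])
    to <- max(starts[pos] + widths[pos] - 1)
    paste0(strrep(" ", from - 1), strrep("-", to - from + 1))
  }, character(1))
  c(header, lines)
}
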
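#' Summarise a classified cohort
#'
#' Aggregates unique-junction classifications into the microhomology (MH)
#' spectrum (per-length 0-9, then >=10 grouped), insertion classes, the
#' three-way partition used for pathway comparison (MH 0-3 / MH >=4 /
#' insertion), and the ECS size list.
#'
#' @param classifications Data frame from [classify_cohort()], after
#'   [unique_junctions()].
#' @param condition Label for the cohort.
#' @return Object of class `cohort_summary`: a list with `condition`,
#'   `n_unique`, `counts` (named integer vector over `blunt`, `mh_1` ...
#'   `mh_9`, `mh_ge10`, `ins_small`, `ins_long`), `pct`, `partition3`
#'   (data frame over `mh_0_3`, `mh_ge4`, `insertion`), `pathway_counts`
#'   and `ecs_sizes`.
#' @export
summarize_cohort <- function(classifications, condition = "cohort") {
  n <- nrow(classifications)
  if (n == 0L) stop("empty cohort: nothing to summarise", call. = FALSE)
  lev <- c("blunt", paste0("mh_", 1:9), "mh_ge10", "ins_small", "ins_long")
  lab <- with(classifications, ifelse(
    insertion_len > 0, ifelse(category == "ins_long", "ins_long", "ins_small"),
    ifelse(mh_length == 0, "blunt",
           ifelse(mh_length >= 10, "mh_ge10", paste0("mh_", mh_length)))))
  counts <- table(factor(lab, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  pct <- 100 * counts / n
  p3c <- c(
    mh_0_3 = sum(counts[c("blunt", "mh_1", "mh_2", "mh_3")]),
    mh_ge4 = sum(counts[c(paste0("mh_", 4:9), "mh_ge10")]),
    insertion = sum(counts[c("ins_small", "ins_long")])
  )
  partition3 <- data.frame(class = names(p3c), count = as.integer(p3c),
                           pct = 100 * as.numeric(p3c) / n,
                           stringsAsFactors = FALSE)
  pw <- table(factor(classifications$pathway, levels = c("C-NHEJ", "A-EJ")))
  structure(
    list(condition = condition, n_unique = n, counts = counts, pct = pct,
         partition3 = partition3,
         pathway_counts = stats::setNames(as.integer(pw), names(pw)),
         ecs_sizes = sort(classifications$insertion_len[classifications$ecs])),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %s: %d unique junctions\n",
              x$condition, x$n_unique))
  cat(sprintf("  C-NHEJ %d (%.1f%%) / A-EJ %d (%.1f%%); %d ECS\n",
              x$pathway_counts[["C-NHEJ"]],
              100 * x$pathway_counts[["C-NHEJ"]] / x$n_unique,
              x$pathway_counts[["A-EJ"]],
              100 * x$pathway_counts[["A-EJ"]] / x$n_unique,
              length(x$ecs_sizes)))
  invisible(x)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of the hypergeometric probabilities of
#' all tables with the observed margins whose point probability does not
#' exceed that of the observed table (within a relative tolerance of
#' 1e-12) - the point-probability convention of standard exact-test
#' implementations.
#'
#' @param a,b,c,d Cell counts, row-wise: `a b / c d`.
#' @return Object of class `exact_test_result`: `table`, `p_two_tailed`,
#'   `odds_ratio` (the cross-product ratio `ad/bc`; `Inf` when only `bc`
#'   is zero, `NaN` when both products are zero).
#' @examples
#' fisher_two_tailed(3, 1, 1, 3)$p_two_tailed  # 34/70
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(x) == 0) stop("the grand total must be positive", call. = FALSE)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  kk <- lo:hi
  dh <- stats::dhyper(kk, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  p <- sum(dh[dh <= pobs * (1 + 1e-12)])
  p <- min(1, p)
  ad <- a * d; bc <- b * c
  or <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  structure(
    list(table = matrix(as.integer(x), 2, 2, byrow = TRUE),
         p_two_tailed = p, odds_ratio = or),
    class = "exact_test_result"
  )
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat("<exact_test_result> 2x2:", x$table[1, ], "/", x$table[2, ], "\n")
  cat(sprintf("  p (two-tailed) = %.4g, odds ratio = %.4g\n",
              x$p_two_tailed, x$odds_ratio))
  invisible(x)
}

#' Compare two cohort summaries with exact tests
#'
#' In the `pathway` contrast the 2x2 table is condition x pathway
#' (C-NHEJ vs A-EJ) built from unique-junction counts. In `per_category`
#' mode each spectrum category is tested against the rest, with
#' Bonferroni-adjusted p-values reported alongside the raw ones.
#'
#' @param summary_a,summary_b [summarize_cohort()] objects.
#' @param contrast `"pathway"` or `"per_category"`.
#' @return Data frame with one row per test: `contrast`, cells `a`-`d`,
#'   `p`, `odds_ratio`, and `p_bonferroni` (per-category mode only).
#' @export
compare_conditions <- function(summary_a, summary_b,
                               contrast = c("pathway", "per_category")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(summary_a, "cohort_summary"),
            inherits(summary_b, "cohort_summary"))
  if (contrast == "pathway") {
    a <- summary_a$pathway_counts[["C-NHEJ"]]
    b <- summary_a$pathway_counts[["A-EJ"]]
    c <- summary_b$pathway_counts[["C-NHEJ"]]
    d <- summary_b$pathway_counts[["A-EJ"]]
    ft <- fisher_two_tailed(a, b, c, d)
    return(data.frame(contrast = "C-NHEJ vs A-EJ", a = a, b = b, c = c, d = d,
                      p = ft$p_two_tailed, odds_ratio = ft$odds_ratio,
                      p_bonferroni = NA_real_, stringsAsFactors = FALSE))
  }
  cats <- names(summary_a$counts)
  rows <- lapply(cats, function(cat) {
    a <- summary_a$counts[[cat]]; b <- summary_a$n_unique - a
    c <- summary_b$counts[[cat]]; d <- summary_b$n_unique - c
    ft <- fisher_two_tailed(a, b, c, d)
    data.frame(contrast = cat, a = a, b = b, c = c, d = d,
               p = ft$p_two_tailed, odds_ratio = ft$odds_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * length(cats))
  out
}

#' ECS frequency and size distribution per condition
#'
#' @param classifications Named list of classification data frames (one per
#'   condition), or a single data frame.
#' @return List with `summary` (data frame: `condition`, `n_unique`,
#'   `n_ecs`, `frequency_pct`) and `sizes` (named list of integer vectors).
#' @export
ecs_size_distribution <- function(classifications) {
  if (is.data.frame(classifications)) {
    classifications <- list(cohort = classifications)
  }
  conds <- names(classifications)
  sizes <- lapply(classifications, function(df) {
    sort(df$insertion_len[df$ecs])
  })
  summary <- data.frame(
    condition = conds,
    n_unique = vapply(classifications, nrow, integer(1)),
    n_ecs = vapply(sizes, length, integer(1)),
    stringsAsFactors = FALSE
  )
  summary$frequency_pct <- 100 * summary$n_ecs / summary$n_unique
  rownames(summary) <- NULL
  list(summary = summary, sizes = sizes)
}

#' Two-sample t-test on replicate values
#'
#' Convenience wrapper around [stats::t.test()] for replicate-level
#' summaries (CSR percentages, qPCR fold changes). Pooled-variance by
#' default; `welch = TRUE` drops the equal-variance assumption.
#'
#' @param x,y Numeric vectors, at least two values each.
#' @param welch Use the Welch approximation.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
t_test_two_sample <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least two values", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
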
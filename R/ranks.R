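# Friedman two-way analysis of ranks for related samples: reviews are
# blocks, feature sets are treatments.

#' Friedman rank analysis of a reviews-by-feature-sets metric table
#'
#' Ranks each review's row (average ranks on ties), sums ranks per
#' feature set and computes the tie-corrected Friedman chi-square:
#' `chi2 = [12 / (n k (k+1)) * sum_j R_j^2 - 3 n (k+1)] / C`, with
#' `C = 1 - sum(t^3 - t) / (n (k^3 - k))` summed over tie groups, and
#' `df = k - 1`. Ranks ascend with the metric value; `direction` says
#' whether a high rank is good (F3, recall, precision) or bad
#' (classification error).
#'
#' @param x A numeric matrix or data frame, rows = reviews (blocks),
#'   columns = feature sets (treatments), no missing cells.
#' @param direction `"higher_better"` or `"lower_better"`.
#' @return A `rank_table`: list with `ranks` (tibble), `mean_ranks`,
#'   `chi2`, `df`, `p_value`, `direction`, `best`.
#' @export
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 1, 3))
#' friedman_ranks(m)$chi2
friedman_ranks <- function(x, direction = c("higher_better",
                                            "lower_better")) {
  direction <- match.arg(direction)
  m <- as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    abort("need at least 2 reviews and 2 feature sets")
  }
  if (anyNA(m)) abort("metric table has missing cells")
  n <- nrow(m)
  k <- ncol(m)
  ranks <- t(apply(m, 1L, rank))
  mean_ranks <- colMeans(ranks)
  R <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  # tie correction over the tie groups of each row
  tie_sum <- sum(apply(m, 1L, function(row) {
    t_sizes <- table(row)
    sum(t_sizes^3 - t_sizes)
  }))
  C <- 1 - tie_sum / (n * (k^3 - k))
  if (C > 0) chi2 <- chi2 / C
  df <- k - 1L
  cols <- colnames(m) %||% paste0("set", seq_len(k))
  best <- if (direction == "higher_better") cols[which.max(mean_ranks)]
          else cols[which.min(mean_ranks)]
  structure(list(
    ranks = tibble::as_tibble(ranks, .name_repair = "minimal"),
    mean_ranks = setNames(as.numeric(mean_ranks), cols),
    chi2 = chi2,
    df = df,
    p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
    direction = direction,
    best = best
  ), class = "rank_table")
}

#' @exportS3Method base::print
print.rank_table <- function(x, ...) {
  cat(sprintf("<rank_table> Friedman chi2(%d df) = %.3f, p = %.3f (%s)\n",
              x$df, x$chi2, x$p_value, x$direction))
  cat("mean ranks:\n")
  print(round(x$mean_ranks, 2))
  invisible(x)
}

#' @export
tidy.rank_table <- function(x, ...) {
  tibble::tibble(
    feature_set = names(x$mean_ranks),
    mean_rank = as.numeric(x$mean_ranks)
  )
}

#' @export
glance.rank_table <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value,
                 direction = x$direction, best = x$best)
}
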
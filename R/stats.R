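#' Paired two-sided t-test
#'
#' Closed-form paired t on the within-pair differences, as used to compare
#' free-running periods between matched light treatments.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2).
#' @param alpha Significance level recorded in the result.
#' @return A `test_result` list: `test_name`, `statistic`, `df`,
#'   `p_value`, `alpha`, `groups`.
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) abort_validation("x and y must be paired (equal length)")
  if (length(x) < 2) abort_validation("paired t-test needs at least 2 pairs")
  d <- x - y
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      # All differences identically zero: no evidence of any difference.
      return(structure(list(test_name = "paired t-test", statistic = 0,
                            df = length(d) - 1, p_value = 1, alpha = alpha,
                            groups = c("x", "y")), class = "test_result"))
    }
    abort_validation("differences have zero variance; paired t-test undefined")
  }
  n <- length(d)
  t_stat <- mean(d) / (sdd / sqrt(n))
  structure(
    list(test_name = "paired t-test", statistic = t_stat, df = n - 1,
         p_value = 2 * stats::pt(-abs(t_stat), n - 1), alpha = alpha,
         groups = c("x", "y")),
    class = "test_result"
  )
}

# Shared sums-of-squares decomposition.
anova_decompose <- function(groups) {
  if (length(groups) < 2) abort_validation("one-way ANOVA needs at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) abort_validation("every group needs at least 2 values")
  all_vals <- unlist(groups, use.names = FALSE)
  grand <- mean(all_vals)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  k <- length(groups)
  n <- length(all_vals)
  list(means = means, sizes = sizes, ssb = ssb, ssw = ssw,
       df1 = k - 1, df2 = n - k, msw = ssw / (n - k))
}

#' One-way analysis of variance
#'
#' F-ratio of between-group to within-group mean squares.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @param alpha Significance level recorded in the result.
#' @return A `test_result` with `df = c(df_between, df_within)`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  a <- anova_decompose(groups)
  if (a$msw == 0) {
    abort_validation("within-group variance is zero; the F ratio is undefined")
  }
  f_stat <- (a$ssb / a$df1) / a$msw
  structure(
    list(test_name = "one-way ANOVA", statistic = f_stat,
         df = c(a$df1, a$df2),
         p_value = stats::pf(f_stat, a$df1, a$df2, lower.tail = FALSE),
         alpha = alpha,
         groups = names(groups) %||% paste0("g", seq_along(groups))),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4f, df = %s, p = %.4g\n", x$test_name,
              x$statistic, paste(x$df, collapse = ", "), x$p_value))
  invisible(x)
}

#' Tukey HSD pairwise comparisons with compact letter display
#'
#' All pairwise group comparisons using the studentized-range
#' distribution, with the Tukey-Kramer standard error so unequal group
#' sizes are handled correctly. Significance groups are summarised by the
#' insert-and-absorb compact-letter-display algorithm: two groups share a
#' letter exactly when their pairwise comparison is non-significant at
#' `alpha`. Letters are assigned in order of descending group mean
#' (presentation only).
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @param alpha Familywise significance level (default 0.05).
#' @return A `tukey_result`: `comparisons` (tibble with `group1`,
#'   `group2`, `diff`, `se`, `q`, `p_value`, `significant`), `letters`
#'   (named character), `alpha`, `msw`, `df_within`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  a <- anova_decompose(groups)
  if (a$msw == 0) {
    abort_validation("within-group variance is zero; Tukey HSD is undefined")
  }
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  if (anyDuplicated(labels)) abort_validation("group labels must be unique")
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  comp <- tibble::tibble(
    group1 = labels[pairs[1, ]],
    group2 = labels[pairs[2, ]],
    diff = unname(a$means[pairs[1, ]] - a$means[pairs[2, ]]),
    se = unname(sqrt(a$msw / 2 * (1 / a$sizes[pairs[1, ]] + 1 / a$sizes[pairs[2, ]])))
  )
  comp$q <- abs(comp$diff) / comp$se
  comp$p_value <- stats::ptukey(comp$q, nmeans = k, df = a$df2,
                                lower.tail = FALSE)
  comp$significant <- comp$p_value < alpha
  sig <- matrix(FALSE, k, k, dimnames = list(labels, labels))
  for (i in seq_len(ncol(pairs))) {
    s <- comp$significant[i]
    sig[pairs[1, i], pairs[2, i]] <- s
    sig[pairs[2, i], pairs[1, i]] <- s
  }
  structure(
    list(comparisons = comp,
         letters = compact_letters(sig, order(a$means, decreasing = TRUE)),
         alpha = alpha, msw = a$msw, df_within = a$df2,
         means = stats::setNames(a$means, labels)),
    class = "tukey_result"
  )
}

# Insert-and-absorb compact letter display. `sig` is a symmetric logical
# matrix (TRUE = significantly different); `ord` gives the group order in
# which letters are assigned (descending mean). Invariant: two groups
# share a letter iff sig[i, j] is FALSE.
compact_letters <- function(sig, ord = seq_len(nrow(sig))) {
  k <- nrow(sig)
  labels <- rownames(sig)
  # Columns are logical membership vectors over groups.
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # Absorb: drop any column that is a subset of another.
      keep <- rep(TRUE, length(new_cols))
      for (a_i in seq_along(new_cols)) {
        for (b_i in seq_along(new_cols)) {
          if (a_i != b_i && keep[b_i] &&
              all(new_cols[[a_i]] <= new_cols[[b_i]]) &&
              (any(new_cols[[a_i]] < new_cols[[b_i]]) || a_i > b_i)) {
            keep[a_i] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  # Order columns by the highest-ranked group they contain, so the letter
  # 'a' goes to the largest mean.
  rank_of <- integer(length(cols))
  pos <- match(seq_len(k), ord)
  for (ci in seq_along(cols)) rank_of[ci] <- min(pos[cols[[ci]]])
  cols <- cols[order(rank_of)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, `[`, logical(1), g))], collapse = "")
  }, character(1))
  stats::setNames(out, labels)
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("<tukey_result> alpha = %g\n", x$alpha))
  print(x$comparisons)
  cat("letters: ", paste(names(x$letters), x$letters, sep = "=", collapse = " "), "\n")
  invisible(x)
}
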
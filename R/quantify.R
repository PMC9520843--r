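#' Summarize one field's vesicle table into counts and fractions
#'
#' Produces the per-field record that condition comparisons run on: total
#' vesicle count plus, for every positivity (`pos_<m>`) and co-positivity
#' (`copos_<m>`) column, the positive count and fraction. Fractions are
#' `NA` (absent), not 0/0, when the field has no vesicles.
#'
#' @param table a classified `VesicleTable`.
#' @param condition_label condition tag for the field (default: taken from
#'   `attr(table, "condition_label")` if present).
#' @return one-row data.frame: `condition`, `n_vesicles`, then `n_<flag>` /
#'   `frac_<flag>` pairs.
#' @export
summarize_field <- function(table, condition_label = NULL) {
  condition_label <- condition_label %||%
    attr(table, "condition_label") %||% ""
  n <- nrow(table)
  out <- data.frame(condition = condition_label, n_vesicles = n,
                    stringsAsFactors = FALSE)
  flag_cols <- grep("^(pos|copos)_", names(table), value = TRUE)
  for (fc in flag_cols) {
    k <- sum(table[[fc]], na.rm = TRUE)
    out[[paste0("n_", fc)]] <- k
    out[[paste0("frac_", fc)]] <- if (n > 0) k / n else NA_real_
  }
  out
}

#' Combine per-field summaries
#'
#' Row-binds [summarize_field()] records, filling flag columns absent from
#' some fields with zero counts.
#'
#' @param summaries list of one-row summary data.frames.
#' @return data.frame, one row per field.
#' @export
summarize_fields <- function(summaries) {
  cols <- unique(unlist(lapply(summaries, names)))
  rows <- lapply(summaries, function(s) {
    for (cc in setdiff(cols, names(s)))
      s[[cc]] <- if (grepl("^frac_", cc)) NA_real_ else 0
    s[cols]
  })
  do.call(rbind, rows)
}

#' Compare per-field counts between two conditions
#'
#' Unpaired two-sided two-sample test on a per-field metric (a count or
#' fraction column of the summary table). Default: Welch's t-test;
#' `"student"` gives the classical pooled-variance Student's t-test;
#' `"permutation"` gives an exact-style permutation test on the difference
#' of group means.
#'
#' @param summaries data.frame from [summarize_fields()] with a `condition`
#'   column and exactly two condition levels, each with >= 2 fields.
#' @param metric name of the column to compare (e.g. `"n_vesicles"`,
#'   `"n_copos_smad1"`).
#' @param test `"welch"`, `"student"`, or `"permutation"`.
#' @param n_perm number of permutations for the permutation test.
#' @return list of class `ConditionComparison`: `test`, `metric`,
#'   `statistic`, `p_value`, `group_means` (named), `n` (named).
#' @export
compare_conditions <- function(summaries, metric = "n_vesicles",
                               test = c("welch", "student", "permutation"),
                               n_perm = 2000L) {
  test <- match.arg(test)
  .assert(metric %in% names(summaries), "metric '%s' not in summaries", metric)
  groups <- split(summaries[[metric]], summaries$condition)
  .assert(length(groups) == 2L,
          "exactly two conditions required, found %d", length(groups))
  for (g in names(groups))
    .assert(sum(is.finite(groups[[g]])) >= 2L,
            "condition '%s' has fewer than 2 fields", g)
  x <- groups[[1]]; y <- groups[[2]]
  means <- vapply(groups, mean, numeric(1))
  ns <- vapply(groups, length, numeric(1))

  if (test %in% c("welch", "student")) {
    if (sd(x) == 0 && sd(y) == 0) {
      # degenerate: both groups constant
      stat <- if (means[1] == means[2]) 0 else Inf * sign(means[1] - means[2])
      p <- if (means[1] == means[2]) 1 else 0
    } else {
      ht <- t.test(x, y, var.equal = (test == "student"))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
  } else {
    obs <- mean(x) - mean(y)
    pooled <- c(x, y); nx <- length(x)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      pi <- sample.int(length(pooled), nx)
      d <- mean(pooled[pi]) - mean(pooled[-pi])
      if (abs(d) >= abs(obs) - 1e-12) exceed <- exceed + 1L
    }
    stat <- obs
    p <- (1 + exceed) / (1 + n_perm)
  }
  structure(list(test = test, metric = metric, statistic = stat,
                 p_value = p, group_means = means, n = ns),
            class = "ConditionComparison")
}

#' @export
print.ConditionComparison <- function(x, ...) {
  cat(sprintf("%s: %s test, %s = %.3f vs %.3f (n = %d, %d), stat = %.3f, p = %.4g\n",
              x$metric, x$test,
              names(x$group_means)[1], x$group_means[1], x$group_means[2],
              x$n[1], x$n[2], x$statistic, x$p_value))
  invisible(x)
}

#' Match detections to simulator ground truth
#'
#' Greedy nearest-neighbor matching: candidate (detection, truth) pairs are
#' taken in ascending centroid-distance order, each side used at most once,
#' pairs accepted only within `max_dist`. Precision is matched/detected
#' (absent when nothing was detected), recall matched/truth (absent when
#' the truth is empty).
#'
#' @param table a `VesicleTable` with `row`/`col` centroids.
#' @param truth a `GroundTruth` data.frame with `row`/`col` centers.
#' @param max_dist maximum matching distance in px (> 0).
#' @return list of class `MatchResult`: `pairs` (data.frame `label`, `id`,
#'   `dist`), `false_positives` (labels), `false_negatives` (ids),
#'   `precision`, `recall`, `rmse` (centroid RMSE over matched pairs).
#' @export
match_to_ground_truth <- function(table, truth, max_dist = 3) {
  .assert(.is_number(max_dist) && max_dist > 0, "max_dist must be > 0")
  nd <- nrow(table); nt <- nrow(truth)
  pairs <- data.frame(label = integer(0), id = integer(0), dist = numeric(0))
  if (nd > 0 && nt > 0) {
    d <- sqrt(outer(table$row, truth$row, "-")^2 +
                outer(table$col, truth$col, "-")^2)
    ord <- order(d)
    used_d <- logical(nd); used_t <- logical(nt)
    for (k in ord) {
      if (d[k] > max_dist) break
      i <- (k - 1) %% nd + 1
      j <- (k - 1) %/% nd + 1
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- used_t[j] <- TRUE
        pairs <- rbind(pairs, data.frame(label = table$label[i],
                                         id = truth$id[j], dist = d[k]))
      }
    }
  } else {
    used_d <- logical(nd); used_t <- logical(nt)
  }
  m <- nrow(pairs)
  structure(list(
    pairs = pairs,
    false_positives = table$label[!used_d],
    false_negatives = truth$id[!used_t],
    precision = if (nd > 0) m / nd else NA_real_,
    recall = if (nt > 0) m / nt else NA_real_,
    rmse = if (m > 0) sqrt(mean(pairs$dist^2)) else NA_real_
  ), class = "MatchResult")
}
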
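#' Modified mean coefficient of variation
#'
#' Compares the paired measurement variability of an endpoint over N subjects
#' to its absolute magnitude:
#' \deqn{CoV = \frac{\sum_i SD(x_{1i}, x_{2i})}{\sum_i |(x_{1i}+x_{2i})/2|} \times 100}
#' where the two-value standard deviation is `|x1 - x2| / sqrt(2)` (N-1
#' convention) and the denominator uses the absolute value of each subject's
#' paired mean (so endpoints of either sign are handled).  The statistic is
#' scale-invariant but not translation-invariant: endpoints with means near
#' zero (such as mid-ventricular twist) inflate it without bound.
#'
#' @param x1,x2 Paired measurements, one element per subject (N >= 1).
#' @return CoV in percent.
#' @export
modified_cov <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 1)
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 1) stop("no complete pairs")
  num <- sum(abs(x1 - x2) / sqrt(2))
  den <- sum(abs((x1 + x2) / 2))
  if (den == 0) stop("undefined CoV: sum of absolute paired means is zero")
  100 * num / den
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = x2 - x1`; limits of agreement are `mean(d) +/- 2 sd(d)`
#' (sample standard deviation, the +/- 2 SD convention used for inter-test
#' agreement plots).
#'
#' @param x1,x2 Paired measurements (N >= 2).
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(x1, x2) {
  stopifnot(length(x1) == length(x2))
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  if (length(x1) < 2) stop("Bland-Altman requires at least 2 pairs")
  d <- x2 - x1
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s, loa_low = m - 2 * s, loa_high = m + 2 * s)
}

#' Reproducibility report over a cohort endpoint table
#'
#' Computes the modified mean CoV, the reproducibility flag (CoV <= 20%) and
#' Bland-Altman statistics for every endpoint and comparison.  The inter-test
#' comparison pairs observer 1's day-1 and day-2 analyses; the inter-observer
#' comparison pairs observer 2's and observer 1's day-1 analyses.
#'
#' @param table Data frame with columns `mouse`, `condition`
#'   (`"obs1_day1"`, `"obs1_day2"`, `"obs2_day1"`), `endpoint`, `value`, and
#'   optionally `group`.
#' @param comparisons Character vector among `"inter_test"`,
#'   `"inter_observer"`.
#' @param subgroups Optional character vector of group labels: the report is
#'   additionally computed restricted to each group.
#' @param cov_threshold Reproducibility threshold in percent (inclusive).
#' @return Data frame with one row per endpoint x comparison (x subgroup):
#'   `cov`, `n`, `reproducible`, `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`.  Comparisons with fewer than 2 contributing subjects are
#'   reported with `NA` statistics, not dropped.
#' @export
reproducibility_report <- function(table,
                                   comparisons = c("inter_test", "inter_observer"),
                                   subgroups = NULL,
                                   cov_threshold = 20) {
  stopifnot(all(c("mouse", "condition", "endpoint", "value") %in% names(table)))
  cond_pairs <- list(inter_test = c("obs1_day1", "obs1_day2"),
                     inter_observer = c("obs2_day1", "obs1_day1"))
  comparisons <- match.arg(comparisons, names(cond_pairs), several.ok = TRUE)
  scopes <- list(list(label = "all", rows = rep(TRUE, nrow(table))))
  for (g in subgroups) {
    scopes[[length(scopes) + 1]] <- list(label = g, rows = table$group == g)
  }
  out <- list()
  for (sc in scopes) {
    tab <- table[sc$rows, , drop = FALSE]
    for (cmp in comparisons) {
      conds <- cond_pairs[[cmp]]
      for (ep in unique(tab$endpoint)) {
        a <- tab[tab$endpoint == ep & tab$condition == conds[1], c("mouse", "value")]
        b <- tab[tab$endpoint == ep & tab$condition == conds[2], c("mouse", "value")]
        merged <- merge(a, b, by = "mouse", suffixes = c("_1", "_2"))
        merged <- merged[!is.na(merged$value_1) & !is.na(merged$value_2), ]
        n_dropped <- length(union(a$mouse, b$mouse)) - nrow(merged)
        if (n_dropped > 0) {
          message(sprintf("%s/%s/%s: dropped %d mice with missing values",
                          sc$label, cmp, ep, n_dropped))
        }
        row <- data.frame(scope = sc$label, comparison = cmp, endpoint = ep,
                          n = nrow(merged), cov = NA_real_,
                          reproducible = NA, mean_diff = NA_real_,
                          sd_diff = NA_real_, loa_low = NA_real_,
                          loa_high = NA_real_, stringsAsFactors = FALSE)
        if (nrow(merged) >= 2) {
          cv <- tryCatch(modified_cov(merged$value_1, merged$value_2),
                         error = function(e) NA_real_)
          ba <- bland_altman(merged$value_1, merged$value_2)
          row$cov <- cv
          row$reproducible <- if (is.na(cv)) NA else cv <= cov_threshold
          row$mean_diff <- ba$mean_diff
          row$sd_diff <- ba$sd_diff
          row$loa_low <- ba$loa_low
          row$loa_high <- ba$loa_high
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  do.call(rbind, out)
}
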
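#' Mann-Whitney U test for two independent samples
#'
#' Two-sided rank-sum comparison. For small samples (`min(n) <= 8`) without
#' ties the p-value is exact (full permutation distribution); otherwise the
#' normal approximation with tie correction and no continuity correction is
#' used. The statistic reported is U for the first sample.
#'
#' @param a,b numeric samples.
#' @return object of class `test_result`: `statistic`, `p_value`, `test`,
#'   `n` (group sizes).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1)
    stop("degenerate test: pooled data are constant")
  ties <- any(duplicated(pooled))
  exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = FALSE))
  new_test_result(statistic = unname(wt$statistic),
                  p_value = wt$p.value,
                  test = if (exact) "mann-whitney-u (exact)"
                         else "mann-whitney-u (normal approximation)",
                  n = c(length(a), length(b)))
}

#' Chi-square comparison of criterion satisfaction rates
#'
#' Pearson chi-square (no continuity correction) on the 2 x 2 pass/fail
#' table of two groups.
#'
#' @param pass_counts length-2 vector of bones satisfying the criterion.
#' @param group_sizes length-2 vector of group sizes.
#' @return a `test_result`.
#' @export
chi_square_fit_rates <- function(pass_counts, group_sizes) {
  if (length(pass_counts) != 2 || length(group_sizes) != 2)
    stop("pass_counts and group_sizes must each have length 2")
  if (any(pass_counts > group_sizes) || any(pass_counts < 0))
    stop("pass counts must be between 0 and the group sizes")
  tab <- cbind(pass = pass_counts, fail = group_sizes - pass_counts)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("degenerate table: an expected cell count is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result(statistic = unname(ct$statistic),
                  p_value = ct$p.value,
                  test = "chi-square (Pearson, uncorrected)",
                  n = group_sizes)
}

#' Spearman rank correlation
#'
#' Nonparametric correlation with average ranks for ties; two-sided
#' p-value via the t approximation.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return a `test_result` (the statistic is rho).
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("undefined correlation: a variable is constant")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  new_test_result(statistic = unname(ct$estimate),
                  p_value = ct$p.value,
                  test = "spearman (t approximation)",
                  n = length(x))
}

new_test_result <- function(statistic, p_value, test, n) {
  structure(list(statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), test = test, n = n),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Age-group classification
#'
#' @param age age in years.
#' @param cut cut point (default 65: young < 65, old >= 65).
#' @return `"young"` or `"old"`.
#' @export
age_group <- function(age, cut = 65) {
  ifelse(age < cut, "young", "old")
}

med_sd_range <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0)
    return(c(median = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_))
  c(median = median(x), sd = if (length(x) > 1) sd(x) else NA_real_,
    min = min(x), max = max(x))
}

strata_rows <- function() {
  expand.grid(age_group = c("both", "young", "old"),
              sex = c("all", "male", "female"),
              stringsAsFactors = FALSE)[, 2:1]
}

select_stratum <- function(df, eth, grp, sx) {
  sel <- df$ethnicity == eth
  if (grp != "both") sel <- sel & df$age_group == grp
  if (sx != "all") sel <- sel & df$sex == sx
  df[sel, , drop = FALSE]
}

# the pairwise comparisons reported by the descriptive and fit tables
comparison_list <- function(eths) {
  cmp <- list()
  for (e in eths) {
    for (g in c("both", "young", "old"))
      cmp[[length(cmp) + 1]] <- list(
        label = sprintf("%s males vs. females (%s)", e,
                        if (g == "both") "all" else g),
        a = list(eth = e, grp = g, sex = "male"),
        b = list(eth = e, grp = g, sex = "female"))
    for (sx in c("all", "male", "female"))
      cmp[[length(cmp) + 1]] <- list(
        label = sprintf("%s young vs. old (%s)", e, sx),
        a = list(eth = e, grp = "young", sex = sx),
        b = list(eth = e, grp = "old", sex = sx))
  }
  if (length(eths) == 2) {
    pairs <- list(c("both", "all"), c("both", "male"), c("both", "female"),
                  c("young", "all"), c("old", "all"),
                  c("young", "male"), c("young", "female"),
                  c("old", "male"), c("old", "female"))
    for (p in pairs)
      cmp[[length(cmp) + 1]] <- list(
        label = sprintf("%s vs. %s (%s %s)", eths[1], eths[2], p[1], p[2]),
        a = list(eth = eths[1], grp = p[1], sex = p[2]),
        b = list(eth = eths[2], grp = p[1], sex = p[2]))
  }
  cmp
}

safe_p <- function(expr) {
  r <- tryCatch(expr, error = function(e) NULL)
  if (is.null(r)) c(statistic = NA_real_, p = NA_real_)
  else c(statistic = r$statistic, p = r$p_value)
}

#' Build cohort summary and comparison tables
#'
#' Produces four analogues of the protocol's reporting tables from a
#' cohort metadata frame and the per-bone fit summary of
#' [cohort_fit_run()]:
#' \describe{
#'   \item{descriptive}{per-stratum median, SD and range of age, height and
#'     bow radius (the median-with-SD pairing follows the reporting
#'     convention of the protocol).}
#'   \item{descriptive_tests}{Mann-Whitney U p-values for age, height and
#'     bow radius across the standard group comparisons.}
#'   \item{fit}{per-stratum median, SD and range of the per-bone mean
#'     plate-bone distance for each criterion, with satisfied counts and
#'     percentages, and the overall-fit column.}
#'   \item{fit_tests}{per-comparison Mann-Whitney U p-values on the mean
#'     distances and chi-square p-values on the satisfaction rates.}
#' }
#'
#' @param metadata cohort metadata (columns `id`, `ethnicity`, `age`,
#'   `sex`, `height_cm`, and `roc_mm` or `true_R_bow_mm`).
#' @param fit_summary per-bone summary from [cohort_fit_run()]; may be
#'   `NULL` to produce only the descriptive tables.
#' @return named list of data frames.
#' @export
make_tables <- function(metadata, fit_summary = NULL) {
  md <- as.data.frame(metadata)
  if (!"roc_mm" %in% names(md)) md$roc_mm <- md$true_R_bow_mm
  if (!"age_group" %in% names(md)) md$age_group <- age_group(md$age)
  eths <- unique(md$ethnicity)

  rows <- list()
  for (e in eths) {
    grid <- strata_rows()
    for (k in seq_len(nrow(grid))) {
      sub <- select_stratum(md, e, grid$age_group[k], grid$sex[k])
      ar <- med_sd_range(sub$age)
      hr <- med_sd_range(sub$height_cm)
      rr <- med_sd_range(sub$roc_mm)
      rows[[length(rows) + 1]] <- data.frame(
        ethnicity = e, age_group = grid$age_group[k], sex = grid$sex[k],
        n = nrow(sub),
        age_median = ar[1], age_sd = ar[2], age_min = ar[3], age_max = ar[4],
        height_median = hr[1], height_sd = hr[2],
        height_min = hr[3], height_max = hr[4],
        roc_median = rr[1], roc_sd = rr[2], roc_min = rr[3], roc_max = rr[4],
        stringsAsFactors = FALSE)
    }
  }
  descriptive <- do.call(rbind, rows)
  rownames(descriptive) <- NULL

  cmp <- comparison_list(eths)
  trows <- lapply(cmp, function(cm) {
    a <- select_stratum(md, cm$a$eth, cm$a$grp, cm$a$sex)
    b <- select_stratum(md, cm$b$eth, cm$b$grp, cm$b$sex)
    data.frame(comparison = cm$label, n_a = nrow(a), n_b = nrow(b),
               age_p = safe_p(mann_whitney_u(a$age, b$age))[2],
               height_p = safe_p(mann_whitney_u(a$height_cm, b$height_cm))[2],
               roc_p = safe_p(mann_whitney_u(a$roc_mm, b$roc_mm))[2],
               stringsAsFactors = FALSE)
  })
  descriptive_tests <- do.call(rbind, trows)
  rownames(descriptive_tests) <- NULL

  out <- list(descriptive = descriptive, descriptive_tests = descriptive_tests)
  if (is.null(fit_summary)) return(out)

  fs <- merge(fit_summary, md[, c("id", "age_group")], by = "id")
  rows <- list()
  for (e in eths) {
    grid <- strata_rows()
    for (k in seq_len(nrow(grid))) {
      sub <- select_stratum(fs, e, grid$age_group[k], grid$sex[k])
      row <- data.frame(ethnicity = e, age_group = grid$age_group[k],
                        sex = grid$sex[k], n = nrow(sub),
                        stringsAsFactors = FALSE)
      for (cr in c("c1", "c2", "c3")) {
        m <- med_sd_range(sub[[paste0(cr, "_mean")]])
        npass <- sum(sub[[paste0(cr, "_pass")]])
        row[[paste0(cr, "_median")]] <- m[1]
        row[[paste0(cr, "_sd")]] <- m[2]
        row[[paste0(cr, "_min")]] <- m[3]
        row[[paste0(cr, "_max")]] <- m[4]
        row[[paste0(cr, "_satisfied_n")]] <- npass
        row[[paste0(cr, "_satisfied_pct")]] <-
          if (nrow(sub) > 0) 100 * npass / nrow(sub) else NA_real_
      }
      row$overall_n <- sum(sub$overall_fit)
      row$overall_pct <-
        if (nrow(sub) > 0) 100 * sum(sub$overall_fit) / nrow(sub) else NA_real_
      rows[[length(rows) + 1]] <- row
    }
  }
  fit <- do.call(rbind, rows)
  rownames(fit) <- NULL

  trows <- lapply(cmp, function(cm) {
    a <- select_stratum(fs, cm$a$eth, cm$a$grp, cm$a$sex)
    b <- select_stratum(fs, cm$b$eth, cm$b$grp, cm$b$sex)
    row <- data.frame(comparison = cm$label, n_a = nrow(a), n_b = nrow(b),
                      stringsAsFactors = FALSE)
    for (cr in c("c1", "c2", "c3")) {
      row[[paste0(cr, "_dist_p")]] <-
        safe_p(mann_whitney_u(a[[paste0(cr, "_mean")]],
                              b[[paste0(cr, "_mean")]]))[2]
      row[[paste0(cr, "_rate_p")]] <-
        safe_p(chi_square_fit_rates(
          c(sum(a[[paste0(cr, "_pass")]]), sum(b[[paste0(cr, "_pass")]])),
          c(nrow(a), nrow(b))))[2]
    }
    row
  })
  fit_tests <- do.call(rbind, trows)
  rownames(fit_tests) <- NULL

  c(out, list(fit = fit, fit_tests = fit_tests))
}
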
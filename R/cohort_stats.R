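check_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(tab != round(tab))) stop("counts must be integers")
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by hypergeometric enumeration over all tables with
#' the observed margins; the p-value sums the probabilities of tables whose
#' point probability does not exceed that of the observed table. Wraps
#' [stats::fisher.test()] with shape/count validation.
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- check_contingency(tab)
  if (nrow(tab) != 2 || ncol(tab) != 2) stop("table must be exactly 2x2")
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-square test for an r x c table
#'
#' `chi2 = sum (O - E)^2 / E` with expected counts from the margins,
#' `(r-1)(c-1)` degrees of freedom and no continuity correction.
#'
#' @param tab An r x c matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chisq_rxc <- function(tab) {
  tab <- check_contingency(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Rank test of a continuous variable across groups
#'
#' Two groups are compared with the Mann-Whitney U test of [mw_test()];
#' three or more with the Kruskal-Wallis test (tie-corrected H, chi-square
#' p with k - 1 degrees of freedom).
#'
#' @param values Numeric vector (missing values dropped per group).
#' @param groups Factor of group memberships.
#' @return Two-sided p-value.
#' @export
continuous_group_test <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups with data")
  if (any(table(groups) < 2))
    stop("each group needs at least 2 non-missing values")
  if (nlevels(groups) == 2) {
    mw_test(values[groups == levels(groups)[1]],
            values[groups == levels(groups)[2]])$p
  } else {
    if (stats::var(values) == 0) return(1)
    stats::kruskal.test(values, groups)$p.value
  }
}

#' Build a cohort characteristics table
#'
#' Summarizes a sample sheet the way clinical baseline tables are reported:
#' continuous variables as mean +/- SD per group with a rank-test p-value
#' ([continuous_group_test()]); categorical variables as per-group counts
#' with Fisher's exact test (two groups, 2 categories) or the Pearson
#' chi-square test otherwise. Missing values are excluded per row and
#' counted.
#'
#' @param samples Sample sheet data.frame including a `group` column.
#' @param variables Named character vector mapping column names to
#'   `"continuous"` or `"categorical"`.
#' @return Data.frame with one row per variable: per-group summary columns,
#'   `p` and `n_missing`.
#' @export
build_characteristics_table <- function(samples, variables) {
  if (is.null(names(variables)) || any(names(variables) == ""))
    stop("variables must be a named vector of types")
  grp <- droplevels(as.factor(samples$group))
  rows <- list()
  for (v in names(variables)) {
    type <- variables[[v]]
    x <- samples[[v]]
    if (is.null(x)) stop("unknown variable: ", v)
    miss <- is.na(x)
    xs <- x[!miss]; gs <- droplevels(grp[!miss])
    if (type == "continuous") {
      summ <- tapply(xs, gs, function(z)
        sprintf("%.1f ± %.1f", mean(z), stats::sd(z)))
      p <- if (nlevels(gs) >= 2 && stats::var(xs) > 0)
        continuous_group_test(xs, gs) else 1
    } else if (type == "categorical") {
      tab <- table(gs, xs)
      summ <- apply(tab, 1, function(r)
        paste(sprintf("%d %s", r, colnames(tab)), collapse = ", "))
      p <- if (ncol(tab) < 2 || nrow(tab) < 2) 1
      else if (nrow(tab) == 2 && ncol(tab) == 2) fisher_exact_2x2(tab)
      else pearson_chisq_rxc(tab)$p
    } else stop("unknown variable type '", type, "' for ", v)
    row <- c(list(variable = v),
             as.list(stats::setNames(as.character(summ),
                                     paste0("group_", make.names(names(summ))))),
             list(p = p, n_missing = sum(miss)))
    rows[[v]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
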
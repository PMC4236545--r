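#' Reporting categories for each roster member
#'
#' Derives the five grouping variables used in the descriptive tables:
#' age band (<=64, 65-74, >=75), gender, marital status dichotomized to
#' living-with-spouse versus not (never-married respondents join the
#' separated/divorced/widowed group), education (3 levels), and the 3-group
#' recode of self-rated health.
#'
#' @param roster roster data frame.
#' @param codebook a [default_codebook()]; supplies the age breaks and the
#'   health recode.
#' @return data frame: `person_id`, `age_group`, `gender`,
#'   `marital_group`, `education`, `srh_group`.
#' @export
group_categories <- function(roster, codebook = default_codebook()) {
  br <- codebook$age_breaks
  age_labels <- c(paste0("<=", br[1]), paste0(br[1] + 1, "-", br[2]), paste0(">=", br[2] + 1))
  age_group <- age_labels[findInterval(roster$age, c(br[1] + 1, br[2] + 1)) + 1]
  marital_group <- ifelse(roster$marital_status == "living_with_spouse",
                          "living_with_spouse", "separated_divorced_widowed")
  data.frame(
    person_id = roster$person_id,
    age_group = age_group,
    gender = roster$gender,
    marital_group = marital_group,
    education = roster$education,
    srh_group = unname(codebook$srh_3group[as.character(roster$srh)]),
    stringsAsFactors = FALSE
  )
}

#' One-way analysis of variance
#'
#' Classical one-way ANOVA computed from the sum-of-squares decomposition:
#' `F = (SSB / (k - 1)) / (SSW / (n - k))` with the p-value from the upper
#' tail of the F distribution. Missing values are dropped pairwise.
#' Undefined situations (fewer than two non-empty groups, no residual
#' degrees of freedom, or zero variance both between and within) return
#' `NA` rather than an error.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return list with `statistic` (F), `p.value`, `df` (between, within)
#'   and `ss` (between, within sums of squares).
#' @export
anova_oneway <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.character(groups[ok])
  undefined <- list(statistic = NA_real_, p.value = NA_real_,
                    df = c(NA_integer_, NA_integer_), ss = c(NA_real_, NA_real_))
  k <- length(unique(groups))
  n <- length(values)
  if (k < 2 || n - k < 1) return(undefined)
  grand <- mean(values)
  gmeans <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gmeans - grand)^2)
  ssw <- sum((values - gmeans[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0 && ssb == 0) return(undefined)
  if (ssw == 0) {
    return(list(statistic = Inf, p.value = 0, df = c(df1, df2), ss = c(ssb, ssw)))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2), ss = c(ssb, ssw))
}

#' Sample skewness
#'
#' Adjusted Fisher-Pearson standardized third moment,
#' `G1 = g1 * sqrt(n(n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)` (central
#' moments with denominator `n`). The unadjusted `g1` is available via
#' `adjusted = FALSE`. `NA` for fewer than three values or zero variance.
#'
#' @param x numeric vector (NAs dropped).
#' @param adjusted return `G1` (default) or the plain moment ratio `g1`.
#' @return skewness estimate, or `NA`.
#' @export
skewness <- function(x, adjusted = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Overall mean, SD and skewness of a measure
#'
#' Footer statistics for a reporting table: mean over non-missing values,
#' sample (n-1) standard deviation, and adjusted Fisher-Pearson skewness.
#' Each statistic is `NA` when its minimum sample size (1, 2, 3
#' respectively) is not met, or for the skewness when the variance is zero.
#'
#' @param values numeric vector.
#' @return named list `mean`, `sd`, `skewness`.
#' @export
overall_stats <- function(values) {
  x <- values[!is.na(values)]
  list(
    mean = if (length(x) >= 1) mean(x) else NA_real_,
    sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
    skewness = skewness(x)
  )
}

#' Grouped-means tables with ANOVA significance
#'
#' Builds, for every measure-by-grouping combination, the descriptive table
#' used to report network measures: per-category sample size, population
#' share and mean of the measure, the one-way ANOVA p-value across
#' categories, and the overall mean / SD / skewness footer. Means are taken
#' over respondents with a non-missing value of the measure.
#'
#' @param measures data frame of per-respondent measures keyed by a
#'   `person_id` or `ego_id`/`node_id` column.
#' @param groupings character vector of grouping-variable names (columns of
#'   [group_categories()] output), e.g. `c("age_group", "gender")`.
#' @param roster roster data frame (categories are derived from it).
#' @param measure_cols which measure columns to tabulate; defaults to all
#'   numeric columns of `measures`.
#' @param codebook a [default_codebook()].
#' @return list of objects of class `grouped_table`.
#' @export
build_table <- function(measures, groupings, roster,
                        measure_cols = NULL, codebook = default_codebook()) {
  idcol <- intersect(c("person_id", "ego_id", "node_id"), names(measures))[1]
  if (is.na(idcol)) stop("build_table: measures must carry an id column")
  if (is.null(measure_cols))
    measure_cols <- setdiff(names(measures)[vapply(measures, is.numeric, logical(1))], idcol)
  cats <- group_categories(roster, codebook)
  cats <- cats[cats$person_id %in% measures[[idcol]], , drop = FALSE]
  m <- match(cats$person_id, measures[[idcol]])

  out <- list()
  for (meas in measure_cols) {
    vals <- measures[[meas]][m]
    for (gv in groupings) {
      g <- cats[[gv]]
      levels_g <- sort(unique(g[!is.na(g)]))
      per_cat <- lapply(levels_g, function(lv) {
        in_cat <- !is.na(g) & g == lv
        data.frame(category = lv, n = sum(in_cat),
                   proportion = sum(in_cat) / sum(!is.na(g)),
                   mean = if (any(in_cat & !is.na(vals))) mean(vals[in_cat], na.rm = TRUE) else NA_real_,
                   stringsAsFactors = FALSE)
      })
      res <- anova_oneway(vals, g)
      tb <- structure(list(
        measure = meas, grouping = gv,
        table = do.call(rbind, per_cat),
        anova_p = res$p.value, anova_F = res$statistic,
        overall = overall_stats(vals)
      ), class = "grouped_table")
      out[[paste(meas, gv, sep = ".")]] <- tb
    }
  }
  out
}

#' @export
print.grouped_table <- function(x, digits = 3, ...) {
  cat(sprintf("%s by %s\n", x$measure, x$grouping))
  tb <- x$table
  tb$proportion <- round(tb$proportion, digits)
  tb$mean <- round(tb$mean, digits)
  print(tb, row.names = FALSE)
  cat(sprintf("  ANOVA p = %s | overall mean %.3f, SD %s, skewness %s\n",
              format.pval(x$anova_p, digits = digits),
              x$overall$mean,
              formatC(x$overall$sd, digits = digits, format = "fg"),
              formatC(x$overall$skewness, digits = digits, format = "fg")))
  invisible(x)
}

#' @export
as.data.frame.grouped_table <- function(x, ...) {
  tb <- x$table
  tb$measure <- x$measure
  tb$grouping <- x$grouping
  tb$anova_p <- x$anova_p
  tb$overall_mean <- x$overall$mean
  tb$overall_sd <- x$overall$sd
  tb$overall_skewness <- x$overall$skewness
  tb[, c("measure", "grouping", "category", "n", "proportion", "mean",
         "anova_p", "overall_mean", "overall_sd", "overall_skewness")]
}
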
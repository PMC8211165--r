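#' Per-unit records for the group analysis
#'
#' Builds the analysis table: one row per unit with its performance (count of
#' rewarded trials), fitted parameters from the supplied MAP fit tables, and
#' — for dyads and triads — the max/min/mean aggregates of the members'
#' *individual-session* values of each variable (performance, `alpha`,
#' `beta` from the simple model; `bias`, `beta_asym`, `phi` from the
#' asymmetric model). Aggregates are `NA` for individuals and for members
#' without an individual session.
#'
#' @param x A `bandit_dataset` or list of [session()]s.
#' @param fits_simple,fits_asym Optional [fit_sessions()] tables.
#' @return Data frame, one row per unit.
#' @export
unit_records <- function(x, fits_simple = NULL, fits_asym = NULL) {
  sess <- sessions_of(x)
  df <- data.frame(
    unit_id = vapply(sess, `[[`, character(1), "unit_id"),
    size = vapply(sess, `[[`, integer(1), "size"),
    performance = vapply(sess, performance, integer(1)),
    stringsAsFactors = FALSE
  )
  member_lists <- lapply(sess, `[[`, "member_ids")

  merge_fit <- function(df, fits, cols, rename = cols) {
    if (is.null(fits)) return(df)
    idx <- match(df$unit_id, fits$unit_id)
    for (j in seq_along(cols)) df[[rename[j]]] <- fits[[cols[j]]][idx]
    df
  }
  df <- merge_fit(df, fits_simple, c("alpha", "beta"))
  df <- merge_fit(df, fits_asym, c("bias", "beta", "phi"),
                  c("bias", "beta_asym", "phi"))

  # map member -> their individual session's row
  ind_rows <- which(df$size == 1L)
  member_of_ind <- vapply(sess[ind_rows], function(s) s$member_ids[1L],
                          character(1))
  vars <- intersect(c("performance", "alpha", "beta", "bias", "beta_asym"),
                    names(df))
  for (v in vars) {
    member_val <- df[[v]][ind_rows][match(
      unlist(member_lists), member_of_ind
    )]
    member_val <- split(member_val, rep(seq_along(sess),
                                        lengths(member_lists)))
    agg <- function(f) vapply(seq_along(sess), function(i) {
      if (df$size[i] == 1L) return(NA_real_)
      vals <- member_val[[i]]
      if (anyNA(vals)) return(NA_real_)
      f(vals)
    }, numeric(1))
    df[[paste0(v, "_member_max")]] <- agg(max)
    df[[paste0(v, "_member_min")]] <- agg(min)
    df[[paste0(v, "_member_mean")]] <- agg(mean)
  }
  df
}

test_summary <- function(method, statistic, df, p_raw, p_adjusted = NA_real_,
                         comparison = NA_character_,
                         direction = NA_character_) {
  data.frame(method = method, statistic = statistic, df = df, p_raw = p_raw,
             p_adjusted = p_adjusted, comparison = comparison,
             direction = direction, stringsAsFactors = FALSE)
}

as_group_list <- function(samples) {
  if (is.data.frame(samples)) {
    samples <- split(samples[[1L]], samples[[2L]])
  }
  if (!is.list(samples)) stop_config("samples must be a (named) list of vectors")
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  if (any(!lengths(samples))) stop_config("every group must be non-empty")
  samples
}

#' Kruskal-Wallis omnibus test across conditions
#'
#' Rank-based omnibus test with midrank tie correction; the statistic is
#' chi-square distributed on k - 1 degrees of freedom.
#'
#' @param samples Named list of numeric vectors, one per condition.
#' @return A one-row test-summary data frame.
#' @export
kruskal_wallis <- function(samples) {
  samples <- as_group_list(samples)
  if (length(samples) < 2L) stop_config("need at least 2 groups")
  x <- unlist(samples, use.names = FALSE)
  if (stats::var(x) == 0) {
    return(test_summary("kruskal_wallis", 0, length(samples) - 1L, 1,
                        comparison = paste(names(samples), collapse = " vs ")))
  }
  kt <- stats::kruskal.test(samples)
  test_summary("kruskal_wallis", unname(kt$statistic), unname(kt$parameter),
               kt$p.value,
               comparison = paste(names(samples), collapse = " vs "))
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment
#'
#' Rank-sum (Mann-Whitney) test for every pair of conditions, normal
#' approximation with midrank tie correction;
#' `p_adjusted = min(1, m * p_raw)` where m is the number of pairs.
#'
#' @param samples Named list of numeric vectors, one per condition.
#' @return Test-summary data frame, one row per pair; `direction` names the
#'   condition with the higher mean rank.
#' @export
pairwise_wilcoxon_bonferroni <- function(samples) {
  samples <- as_group_list(samples)
  if (length(samples) < 2L) stop_config("need at least 2 groups")
  pairs <- utils::combn(names(samples), 2L, simplify = FALSE)
  m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- samples[[pr[1L]]]
    y <- samples[[pr[2L]]]
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    rk <- rank(c(x, y))
    mr_x <- mean(rk[seq_along(x)])
    mr_y <- mean(rk[-seq_along(x)])
    dir <- if (mr_x > mr_y) pr[1L] else if (mr_y > mr_x) pr[2L] else "none"
    test_summary("wilcoxon_rank_sum", unname(wt$statistic), NA_real_,
                 wt$p.value, min(1, m * wt$p.value),
                 comparison = paste(pr, collapse = " vs "), direction = dir)
  })
  do.call(rbind, rows)
}

#' Within-group contrast: group value vs member aggregate
#'
#' Compares the vector of per-unit group values against the vector of
#' per-unit member aggregates (max, min or mean of members' individual
#' values). The default is a two-sample rank test in chi-square form on 1
#' degree of freedom; `paired = TRUE` instead runs the Wilcoxon signed-rank
#' test on the per-unit differences, which respects the natural pairing.
#'
#' @param group_values,member_aggregate Equal-length numeric vectors (units
#'   with `NA` in either are dropped).
#' @param paired Use the paired signed-rank variant.
#' @param labels Length-2 labels for the two vectors.
#' @return A one-row test-summary data frame; `direction` says which vector
#'   ranks higher.
#' @export
within_group_contrast <- function(group_values, member_aggregate,
                                  paired = FALSE,
                                  labels = c("group", "aggregate")) {
  if (length(group_values) != length(member_aggregate)) {
    stop_config("group and aggregate vectors differ in length")
  }
  keep <- stats::complete.cases(group_values, member_aggregate)
  g <- group_values[keep]
  a <- member_aggregate[keep]
  if (!length(g)) stop_config("no complete pairs to compare")
  dir_of <- function() {
    rk <- rank(c(g, a))
    mg <- mean(rk[seq_along(g)])
    ma <- mean(rk[-seq_along(g)])
    if (mg > ma) paste0(labels[1L], "_higher")
    else if (ma > mg) paste0(labels[2L], "_higher")
    else "none"
  }
  if (paired) {
    if (all(g == a)) {
      return(test_summary("wilcoxon_signed_rank", 0, NA_real_, 1,
                          comparison = paste(labels, collapse = " vs "),
                          direction = "none"))
    }
    wt <- suppressWarnings(stats::wilcox.test(g, a, paired = TRUE,
                                              exact = FALSE))
    test_summary("wilcoxon_signed_rank", unname(wt$statistic), NA_real_,
                 wt$p.value, comparison = paste(labels, collapse = " vs "),
                 direction = dir_of())
  } else {
    kt <- if (stats::var(c(g, a)) == 0) {
      list(statistic = c(chi = 0), parameter = c(df = 1), p.value = 1)
    } else {
      stats::kruskal.test(list(g, a))
    }
    test_summary("rank_chisq_1df", unname(kt$statistic),
                 unname(kt$parameter), kt$p.value,
                 comparison = paste(labels, collapse = " vs "),
                 direction = if (kt$p.value > 0.999) "none" else dir_of())
  }
}

#' One-sample test of the positivity bias
#'
#' Wilcoxon signed-rank test that the median of the per-unit
#' `alpha_plus - alpha_minus` values is zero.
#'
#' @param deltas Numeric vector of positivity biases.
#' @return One-row test-summary data frame; `direction` is `"positive"`,
#'   `"negative"` or `"none"`. An all-zero vector is degenerate and reported
#'   with p = 1.
#' @export
positivity_bias_test <- function(deltas) {
  if (!length(deltas)) stop_config("deltas must be non-empty")
  if (all(deltas == 0)) {
    return(test_summary("wilcoxon_signed_rank", 0, NA_real_, 1,
                        comparison = "bias vs 0", direction = "none"))
  }
  wt <- suppressWarnings(stats::wilcox.test(deltas, mu = 0))
  med <- stats::median(deltas)
  test_summary("wilcoxon_signed_rank", unname(wt$statistic), NA_real_,
               wt$p.value, comparison = "bias vs 0",
               direction = if (med > 0) "positive"
                           else if (med < 0) "negative" else "none")
}

#' Poisson regression of performance
#'
#' Fits a Poisson GLM of the rewarded-trial count. The default link is the
#' *identity* (coefficients on the count scale), fitted by iteratively
#' reweighted least squares with step-halving so fitted means stay positive;
#' a log link is available. Size enters either as condition dummies (with
#' the dyad or the individual condition as baseline) or as `size + size^2`
#' (the quadratic U-shape specification); additional covariate columns (e.g.
#' fitted learning parameters) are added by name.
#'
#' @param data Data frame with a `performance` count column, a `size` column
#'   and any covariate columns.
#' @param spec `"dummies1"` (individual + triad terms, dyad baseline),
#'   `"dummies2"` (dyad + triad terms, individual baseline), `"quadratic"`
#'   (size + size squared) or `"intercept"` (no size terms).
#' @param covariates Character vector of covariate column names.
#' @param link `"identity"` (default) or `"log"`.
#' @param response Name of the count column.
#' @return A `regression_table` data frame (`term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`) with attributes `aic`, `log_likelihood`,
#'   `spec`, `link`, `n` and the underlying `glm` fit.
#' @export
poisson_regression <- function(data,
                               spec = c("dummies1", "dummies2", "quadratic",
                                        "intercept"),
                               covariates = character(),
                               link = c("identity", "log"),
                               response = "performance") {
  spec <- match.arg(spec)
  link <- match.arg(link)
  y <- data[[response]]
  if (is.null(y)) stop_config("column '%s' not found", response)
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y))) {
    stop_config("%s must be non-negative integer counts", response)
  }
  mf <- data.frame(.y = y)
  for (v in covariates) {
    if (is.null(data[[v]])) stop_config("covariate '%s' not found", v)
    mf[[v]] <- data[[v]]
  }
  size_terms <- switch(
    spec,
    dummies1 = {
      mf$individual <- as.numeric(data$size == 1L)
      mf$triad <- as.numeric(data$size == 3L)
      c("individual", "triad")
    },
    dummies2 = {
      mf$dyad <- as.numeric(data$size == 2L)
      mf$triad <- as.numeric(data$size == 3L)
      c("dyad", "triad")
    },
    quadratic = {
      mf$size <- as.numeric(data$size)
      mf$size_squared <- as.numeric(data$size)^2
      c("size", "size_squared")
    },
    intercept = character()
  )
  rhs <- c(covariates, size_terms)
  fml <- stats::as.formula(
    paste(".y ~", if (length(rhs)) paste(rhs, collapse = " + ") else "1")
  )
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  X <- stats::model.matrix(fml, mf)
  if (qr(X)$rank < ncol(X)) stop_config("design matrix is rank-deficient")
  fit <- stats::glm(
    fml, data = mf, family = stats::poisson(link = link),
    start = c(if (link == "identity") mean(mf$.y) else log(mean(mf$.y)),
              rep(0, ncol(X) - 1L))
  )
  sm <- summary(fit)$coefficients
  out <- data.frame(
    term = rownames(sm), estimate = sm[, 1L], std_error = sm[, 2L],
    statistic = sm[, 3L], p_value = sm[, 4L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out,
            class = c("regression_table", "data.frame"),
            aic = stats::AIC(fit),
            log_likelihood = as.numeric(stats::logLik(fit)),
            spec = spec, link = link, n = nrow(mf), fit = fit)
}

#' @export
print.regression_table <- function(x, ...) {
  cat(sprintf("Poisson regression (%s link, spec '%s', n = %d), AIC = %.1f\n",
              attr(x, "link"), attr(x, "spec"), attr(x, "n"), attr(x, "aic")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Descriptive statistics by group size
#'
#' @param records A [unit_records()] table.
#' @param vars Columns to summarise.
#' @return Data frame of mean/sd per variable and size, with unit counts.
#' @export
describe_by_size <- function(records,
                             vars = intersect(
                               c("performance", "alpha", "beta", "bias",
                                 "beta_asym", "phi"), names(records))) {
  rows <- list()
  for (v in vars) {
    for (s in sort(unique(records$size))) {
      x <- records[[v]][records$size == s]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, size = s, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Full group-size analysis report
#'
#' Runs the statistical pipeline on a [unit_records()] table: descriptives by
#' size; Kruskal-Wallis omnibus and Bonferroni-adjusted pairwise rank-sum
#' tests of performance and each fitted parameter across sizes; one-sample
#' positivity-bias tests per size (when asymmetric fits are present);
#' within-group contrasts of each group variable against the members'
#' max/min/mean individual values; and the three Poisson regression
#' specifications per fitted model.
#'
#' @param records A [unit_records()] table.
#' @param regression_covariates If `TRUE` (default), include the fitted
#'   learning parameters of each model as regression covariates.
#' @param paired_contrasts Use the paired signed-rank within-group variant.
#' @return An `analysis_report`: named list of data frames
#'   (`descriptives`, `omnibus`, `pairwise`, `positivity_bias`,
#'   `within_group`, `regressions`).
#' @export
analysis_report <- function(records, regression_covariates = TRUE,
                            paired_contrasts = FALSE) {
  size_labels <- c("individual", "dyad", "triad")
  by_size <- function(v) {
    out <- lapply(1:3, function(s) {
      x <- records[[v]][records$size == s]
      x[!is.na(x)]
    })
    names(out) <- size_labels
    out[lengths(out) > 0L]
  }
  test_vars <- intersect(c("performance", "alpha", "beta", "bias",
                           "beta_asym"), names(records))
  omnibus <- list()
  pairwise <- list()
  for (v in test_vars) {
    g <- by_size(v)
    if (length(g) >= 2L) {
      om <- kruskal_wallis(g)
      om$variable <- v
      omnibus[[v]] <- om
      pw <- pairwise_wilcoxon_bonferroni(g)
      pw$variable <- v
      pairwise[[v]] <- pw
    }
  }

  positivity <- NULL
  if ("bias" %in% names(records)) {
    rows <- lapply(seq_along(size_labels), function(s) {
      x <- records$bias[records$size == s]
      x <- x[!is.na(x)]
      if (!length(x)) return(NULL)
      r <- positivity_bias_test(x)
      r$variable <- "bias"
      r$condition <- size_labels[s]
      r
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) positivity <- do.call(rbind, rows)
  }

  within <- list()
  for (v in test_vars) {
    for (s in 2:3) {
      sel <- records$size == s
      for (agg in c("max", "min", "mean")) {
        acol <- paste0(v, "_member_", agg)
        if (!acol %in% names(records)) next
        g <- records[[v]][sel]
        a <- records[[acol]][sel]
        if (!any(stats::complete.cases(g, a))) next
        r <- within_group_contrast(g, a, paired = paired_contrasts,
                                   labels = c("group", paste0("member_", agg)))
        r$variable <- v
        r$condition <- size_labels[s]
        within[[paste(v, s, agg)]] <- r
      }
    }
  }

  regressions <- list()
  reg_models <- list()
  if (all(c("alpha", "beta") %in% names(records))) {
    reg_models$simple <- c("alpha", "beta")
  }
  if (all(c("bias", "beta_asym", "phi") %in% names(records))) {
    reg_models$asymmetric <- c("bias", "beta_asym", "phi")
  }
  if (!length(reg_models)) reg_models <- list(size_only = character())
  for (mn in names(reg_models)) {
    covs <- if (regression_covariates) reg_models[[mn]] else character()
    for (sp in c("dummies1", "dummies2", "quadratic")) {
      rt <- poisson_regression(records, spec = sp, covariates = covs)
      tab <- as.data.frame(rt)
      tab$model <- mn
      tab$spec <- sp
      tab$aic <- attr(rt, "aic")
      regressions[[paste(mn, sp)]] <- tab
    }
  }

  structure(
    list(
      descriptives = describe_by_size(records),
      omnibus = if (length(omnibus)) do.call(rbind, omnibus) else NULL,
      pairwise = if (length(pairwise)) do.call(rbind, pairwise) else NULL,
      positivity_bias = positivity,
      within_group = if (length(within)) do.call(rbind, within) else NULL,
      regressions = if (length(regressions)) do.call(rbind, regressions)
                    else NULL
    ),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Group-size analysis report\n==========================\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat("\n--", nm, "--\n")
    print.data.frame(utils::head(as.data.frame(x[[nm]]), 12), digits = 4)
    if (nrow(x[[nm]]) > 12) cat(sprintf("... (%d rows)\n", nrow(x[[nm]])))
  }
  invisible(x)
}
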
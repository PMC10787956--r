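# Per-feature two-group screening: Shapiro-Wilk normality gate, then a
# Welch t-test (both groups normal) or Mann-Whitney rank-sum test.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over `stats::shapiro.test()` returning the W statistic and
#' p-value; sample size must be between 3 and 5000.
#'
#' @param x Numeric sample.
#' @return List with `W` and `p_value`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3 || length(x) > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000 (got ", length(x), ")",
         call. = FALSE)
  }
  res <- stats::shapiro.test(x)
  list(W = unname(res$statistic), p_value = res$p.value)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U via `stats::wilcox.test()` with midranks for
#' ties. The exact null distribution is used for tie-free samples with
#' `n_x + n_y <= 16`; otherwise the normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric samples (both non-empty).
#' @return List with `U` (statistic for `x`), `p_value` and `exact`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 16) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p_value = res$p.value, exact = exact)
}

stars_for <- function(p) {
  ifelse(is.na(p), "ns",
         ifelse(p <= 0.001, "**", ifelse(p <= 0.05, "*", "ns")))
}

#' Two-group significance screening of a feature table
#'
#' For every channel x feature: a Shapiro-Wilk test on each group decides
#' (under `policy = "auto"`) between a Welch two-sample t-test (both
#' groups normal at alpha = 0.05) and the Mann-Whitney rank-sum test. The
#' default policy `"force-mw"` applies the rank-sum test throughout,
#' matching the mixed-normality behaviour typical of these features.
#' Degenerate features (all values identical in both groups) are flagged
#' rather than tested.
#'
#' @param features Feature tibble from [extract_features()] (columns
#'   `group`, `channel` and the 28 feature columns).
#' @param policy `"force-mw"` (default) or `"auto"`.
#' @param alpha Significance level for the stars and the normality gate
#'   (default 0.05).
#' @param groups Length-2 character: reference group first, case group
#'   second (default `c("healthy", "bruxism")`).
#' @return Tibble of class `significance_table`: one row per channel x
#'   feature with group means and SDs, `test_used`, `p_value` and `stars`
#'   (`ns`, `*` for p <= 0.05, `**` for p <= 0.001).
#' @export
compare_groups <- function(features, policy = c("force-mw", "auto"),
                           alpha = 0.05,
                           groups = c("healthy", "bruxism")) {
  policy <- match.arg(policy)
  feat_cols <- intersect(feature_names(), names(features))
  if (length(feat_cols) == 0) stop("no feature columns found", call. = FALSE)
  stopifnot(all(c("group", "channel") %in% names(features)),
            length(groups) == 2L)
  if (!all(groups %in% features$group)) {
    stop("feature table must contain both groups: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  long <- tidyr::pivot_longer(
    dplyr::select(features, "channel", "group",
                  dplyr::all_of(feat_cols)),
    cols = dplyr::all_of(feat_cols), names_to = "feature",
    values_to = "value")
  out <- dplyr::reframe(
    dplyr::group_by(long, .data$channel, .data$feature),
    {
      g1 <- .data$value[.data$group == groups[1]]
      g2 <- .data$value[.data$group == groups[2]]
      if (length(g1) < 2 || length(g2) < 2) {
        stop("need >= 2 epochs per group per feature", call. = FALSE)
      }
      degenerate <- (stats::var(g1) == 0 && stats::var(g2) == 0 &&
                       length(unique(c(g1, g2))) == 1L)
      if (degenerate) {
        test_used <- "degenerate"; p <- NA_real_
      } else if (policy == "auto" &&
                 max(length(g1), length(g2)) <= 5000 &&
                 stats::var(g1) > 0 && stats::var(g2) > 0 &&
                 shapiro_wilk(g1)$p_value > alpha &&
                 shapiro_wilk(g2)$p_value > alpha) {
        test_used <- "t"
        p <- stats::t.test(g1, g2)$p.value
      } else {
        test_used <- "mann-whitney"
        p <- mann_whitney(g1, g2)$p_value
      }
      tibble::tibble(
        healthy_mean = mean(g1), healthy_sd = stats::sd(g1),
        brux_mean = mean(g2), brux_sd = stats::sd(g2),
        test_used = test_used, p_value = p, stars = stars_for(p))
    })
  out <- dplyr::arrange(
    out, .data$channel, match(.data$feature, feature_names()))
  structure(out, class = c("significance_table", class(out)))
}

#' Relative-power summary by band, channel and group
#'
#' Group mean and standard error of each band's relative power, the data
#' behind the classic grouped-bar band-power figure.
#'
#' @param features Feature tibble from [extract_features()].
#' @return Tibble with `channel`, `band`, `group`, `mean`, `se`, `n`.
#' @export
rpsd_summary <- function(features) {
  rp_cols <- paste0("rpsd_", c("delta", "theta", "alpha", "beta"))
  long <- tidyr::pivot_longer(
    dplyr::select(features, "channel", "group", dplyr::all_of(rp_cols)),
    cols = dplyr::all_of(rp_cols), names_to = "band", values_to = "value")
  long$band <- sub("^rpsd_", "", long$band)
  dplyr::summarise(
    dplyr::group_by(long, .data$channel, .data$band, .data$group),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    n = dplyr::n(), .groups = "drop")
}
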
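#' Significance stars for an (adjusted) p-value
#'
#' The star notation used throughout the figures: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `****` p < 0.0001; `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}

#' Screen distributional assumptions before ANOVA
#'
#' Shapiro-Wilk normality per group and Levene's test (median-centred,
#' via `car::leveneTest`) for homogeneity of variance between groups.
#' Shapiro-Wilk requires at least 3 observations per group.
#'
#' @param values Numeric vector of observations.
#' @param group Factor/character of group membership, same length.
#' @return List with `shapiro_p` (named per group) and `levene_p`.
#' @export
screen_assumptions <- function(values, group) {
  group <- as.factor(group)
  stopifnot(length(values) == length(group))
  ns <- table(group)
  if (any(ns < 3))
    stop("screen_assumptions: need >= 3 observations per group for ",
         "Shapiro-Wilk")
  shapiro_p <- vapply(levels(group), function(g) {
    v <- values[group == g]
    if (stats::sd(v) == 0) return(NA_real_)  # degenerate, no test possible
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  lev <- car::leveneTest(values ~ group)
  list(shapiro_p = shapiro_p, levene_p = lev$`Pr(>F)`[1])
}

#' Two-way ANOVA of group x stratum
#'
#' Fits `value ~ group * stratum` and returns Type II F tests (robust to
#' the mild imbalance left by excluded fields; Type I/III selectable) for
#' both main effects and the interaction, together with the cell means.
#' By protocol, observations should already be averaged to the
#' experimental unit (one value per animal per stratum); Levene screening
#' is applied and a failed homogeneity gate raises a warning unless
#' overridden.
#'
#' @param data Data frame with columns `value`, `group`, `stratum` (the
#'   stratum column name can be given via `stratum_col`, e.g. `"area"` or
#'   `"zone"`).
#' @param stratum_col Name of the stratum column.
#' @param ss_type Sum-of-squares type: 2 (default), 1 or 3.
#' @param check_levene Screen variance homogeneity across group x stratum
#'   cells and warn when p < 0.05.
#' @return An `anova_result`: list with `table` (tibble: effect, df, F,
#'   p), `cell_means`, `model` (the `lm` fit), `levene_p`, `mode`.
#' @export
two_way_anova <- function(data, stratum_col = "area", ss_type = 2,
                          check_levene = TRUE) {
  stopifnot(all(c("value", "group", stratum_col) %in% names(data)))
  df <- data.frame(value = data$value,
                   group = as.factor(data$group),
                   stratum = as.factor(data[[stratum_col]]))
  if (any(table(df$group, df$stratum) == 0))
    stop("two_way_anova: empty cells in the group x stratum design")
  levene_p <- NA_real_
  if (check_levene) {
    cell <- interaction(df$group, df$stratum)
    levene_p <- tryCatch(
      car::leveneTest(df$value ~ cell)$`Pr(>F)`[1],
      error = function(e) NA_real_)
    if (!is.na(levene_p) && levene_p < 0.05)
      warning("variance homogeneity violated (Levene p = ",
              signif(levene_p, 3), "); ANOVA interpretation is suspect")
  }
  fit <- stats::lm(value ~ group * stratum, data = df)
  degenerate <- stats::sigma(fit) < 1e-12
  if (degenerate) {
    warning("zero within-cell variance: degenerate design, p-values ",
            "collapse to 0 for any non-null effect")
    ss_type <- 1   # Type II needs a positive residual SS
  }
  tab <- if (ss_type == 1) {
    a <- stats::anova(fit)
    tibble::tibble(effect = rownames(a)[-nrow(a)],
                   df = a$Df[-nrow(a)], F = a$`F value`[-nrow(a)],
                   p = a$`Pr(>F)`[-nrow(a)])
  } else {
    a <- car::Anova(fit, type = ss_type)
    keep <- !rownames(a) %in% c("Residuals", "(Intercept)")
    tibble::tibble(effect = rownames(a)[keep], df = a$Df[keep],
                   F = a$`F value`[keep], p = a$`Pr(>F)`[keep])
  }
  tab$effect <- sub("stratum", stratum_col, tab$effect)
  cm <- stats::aggregate(value ~ group + stratum, df, mean)
  names(cm)[2] <- stratum_col
  structure(list(table = tab, cell_means = tibble::as_tibble(cm),
                 model = fit, levene_p = levene_p,
                 stratum_col = stratum_col, data = df),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> two-way ANOVA (group x", x$stratum_col, ")\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' Tukey post hoc comparisons after a significant omnibus F
#'
#' All pairwise Tukey HSD comparisons of the group x stratum cells, plus
#' the group contrast within each stratum, each with the Tukey-adjusted
#' p-value and its star label. Refuses to run when no omnibus effect
#' reached p < 0.05 (the protocol runs post hoc tests only then).
#'
#' @param anova An `anova_result` from [two_way_anova()].
#' @param which `"within_stratum"` (default: WT vs DS within each
#'   stratum) or `"all"` (every cell pair).
#' @return Tibble: `stratum`, `pair`, `diff`, `p_adj`, `stars`.
#' @export
tukey_posthoc <- function(anova, which = c("within_stratum", "all")) {
  which <- match.arg(which)
  stopifnot(inherits(anova, "anova_result"))
  if (all(anova$table$p >= 0.05, na.rm = TRUE))
    stop("tukey_posthoc: omnibus F not significant (all p >= 0.05); ",
         "post hoc tests are gated")
  fit2 <- stats::aov(value ~ cell,
                     data = transform(anova$data,
                                      cell = interaction(group, stratum,
                                                         sep = "|")))
  tk <- stats::TukeyHSD(fit2, "cell")$cell
  pairs <- rownames(tk)
  parts <- strsplit(pairs, "-", fixed = TRUE)
  a <- vapply(parts, `[`, character(1), 1)
  b <- vapply(parts, `[`, character(1), 2)
  sa <- sub("^[^|]*\\|", "", a); sb <- sub("^[^|]*\\|", "", b)
  ga <- sub("\\|.*$", "", a); gb <- sub("\\|.*$", "", b)
  out <- tibble::tibble(stratum = ifelse(sa == sb, sa, NA_character_),
                        pair = pairs, diff = tk[, "diff"],
                        p_adj = tk[, "p adj"])
  if (which == "within_stratum")
    out <- out[!is.na(out$stratum) & ga != gb, ]
  out$stars <- p_stars(out$p_adj)
  out
}

#' Compare groups on one metric, start to finish
#'
#' The statistics battery applied to one metric's field measurements:
#' average to the animal level within each stratum, screen assumptions,
#' run the two-way ANOVA (group x stratum), and — when the omnibus F is
#' significant — the Tukey post hoc comparisons of WT vs DS within each
#' stratum. A `per_stratum` mode instead runs one ANOVA per stratum
#' (group as the only factor); the mode used is recorded in the result.
#'
#' @param measurements Tidy measurements of one metric (columns
#'   `animal_id`, `group`, `value`, plus `area`/`zone`).
#' @param stratification `"by_area"` or `"by_zone"`.
#' @param mode `"pooled"` (one ANOVA with stratum as a factor, default)
#'   or `"per_stratum"`.
#' @param unit Passed to the animal-level averaging (`"animal"` default).
#' @return List of class `group_comparison`: `anova`, `posthoc` (or NULL
#'   when gated), `screen`, `stratification`, `mode`.
#' @export
compare_groups <- function(measurements,
                           stratification = c("by_area", "by_zone"),
                           mode = c("pooled", "per_stratum"),
                           unit = "animal") {
  stratification <- match.arg(stratification)
  mode <- match.arg(mode)
  stratum_col <- if (stratification == "by_area") "area" else "zone"
  obs <- measurements |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("group", "animal_id", stratum_col)))) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  screen <- tryCatch(screen_assumptions(obs$value, obs$group),
                     error = function(e) NULL)
  if (mode == "pooled") {
    an <- two_way_anova(obs, stratum_col = stratum_col)
    ph <- tryCatch(tukey_posthoc(an), error = function(e) NULL)
    res <- list(anova = an, posthoc = ph)
  } else {
    strata <- unique(obs[[stratum_col]])
    res <- list(anova = lapply(stats::setNames(strata, strata), function(s) {
      d <- obs[obs[[stratum_col]] == s, ]
      fit <- stats::lm(value ~ group, data = d)
      a <- stats::anova(fit)
      tibble::tibble(stratum = s, df = a$Df[1], F = a$`F value`[1],
                     p = a$`Pr(>F)`[1], stars = p_stars(a$`Pr(>F)`[1]))
    }), posthoc = NULL)
  }
  structure(c(res, list(screen = screen, stratification = stratification,
                        mode = mode)),
            class = "group_comparison")
}
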
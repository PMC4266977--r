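#' Log day transform used for decay trajectories
#'
#' `log(day + offset)` with natural log and offset 1 by default, so the
#' post-mortem baseline (day 0) is representable.
#'
#' @param day non-negative day value(s).
#' @param base logarithm base.
#' @param offset added before taking the log.
#' @return Transformed values.
#' @export
log_day <- function(day, base = exp(1), offset = 1) {
  log(day + offset, base = base)
}

#' Pool character trajectories into body-region decay trajectories
#'
#' Joins each character's aggregated ordinal state series to its body
#' region, drops characters that remain pristine throughout (e.g.
#' sclerotized jaws and claws, which carry no trajectory information),
#' pools the (log day, state) points within each region, and fits one
#' ordinary least-squares line per region. Regions contributing fewer than
#' 3 points are dropped with a warning.
#'
#' @param series an [aggregate_states()] data.frame.
#' @param characters a [character_table()].
#' @param base,offset see [log_day()].
#' @return list of class `"region_trajectories"` with `points` (columns
#'   `body_region`, `character_id`, `day`, `log_day`, `state`) and `fits`
#'   (per-region `slope`, `intercept`, `n_points`).
#' @export
build_region_trajectories <- function(series, characters,
                                      base = exp(1), offset = 1) {
  .assert_cols(series, c("character_id", "day", "state"), "state series")
  characters <- character_table(as.data.frame(characters))
  miss <- setdiff(unique(series$character_id), characters$character_id)
  if (length(miss)) {
    .stopf("character(s) without a body region: %s",
           paste(miss, collapse = ", "))
  }
  # all-pristine characters are excluded from the pools
  max_state <- tapply(series$state, series$character_id, max)
  pristine <- names(max_state)[max_state == 0L]
  pts <- series[!(series$character_id %in% pristine), , drop = FALSE]
  if (!nrow(pts)) .stopf("every character is pristine throughout")
  pts$body_region <- characters$body_region[match(pts$character_id,
                                                  characters$character_id)]
  pts$log_day <- log_day(pts$day, base = base, offset = offset)
  pts <- pts[, c("body_region", "character_id", "day", "log_day", "state")]
  counts <- table(pts$body_region)
  small <- names(counts)[counts < 3L]
  if (length(small)) {
    warning("dropping region(s) with fewer than 3 points: ",
            paste(small, collapse = ", "), call. = FALSE)
    pts <- pts[!(pts$body_region %in% small), , drop = FALSE]
  }
  if (!nrow(pts)) .stopf("no region has enough points")
  fits <- do.call(rbind, lapply(split(pts, pts$body_region), function(d) {
    cf <- stats::coef(stats::lm(state ~ log_day, data = d))
    data.frame(body_region = d$body_region[1L],
               slope = unname(cf[2L]), intercept = unname(cf[1L]),
               n_points = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(fits) <- NULL
  rownames(pts) <- NULL
  structure(list(points = pts, fits = fits, base = base, offset = offset),
            class = "region_trajectories")
}

#' Test heterogeneity of decay-trajectory slopes across body regions
#'
#' ANCOVA-style model comparison: the separate-slopes model
#' `state ~ region + log_day + region:log_day` against the common-slope
#' model `state ~ region + log_day`. The F statistic has numerator degrees
#' of freedom `k - 1` (k regions) and denominator `N - 2k`; a significant
#' result means the regions decay at different rates.
#'
#' @param trajectories a [build_region_trajectories()] result, or a
#'   data.frame with columns `body_region`, `log_day`, `state`.
#' @return list `F`, `df1`, `df2`, `p_value`, `k_regions`, `n_points`;
#'   class `"slope_heterogeneity"`.
#' @export
slope_heterogeneity_test <- function(trajectories) {
  pts <- if (inherits(trajectories, "region_trajectories")) {
    trajectories$points
  } else {
    as.data.frame(trajectories)
  }
  .assert_cols(pts, c("body_region", "log_day", "state"), "trajectory points")
  pts$body_region <- factor(pts$body_region)
  k <- nlevels(pts$body_region)
  if (k < 2L) .stopf("need at least 2 regions")
  m0 <- stats::lm(state ~ body_region + log_day, data = pts)
  m1 <- stats::lm(state ~ body_region * log_day, data = pts)
  df1 <- stats::df.residual(m0) - stats::df.residual(m1)
  df2 <- stats::df.residual(m1)
  if (df1 < 1L || df2 < 1L) .stopf("singular design: interaction not estimable")
  rss0 <- stats::deviance(m0)
  rss1 <- stats::deviance(m1)
  tss <- sum((pts$state - mean(pts$state))^2)
  tol <- 1e-12 * max(tss, 1)
  if (rss0 <= tol) {
    # the common-slope model already fits perfectly: no heterogeneity
    Fstat <- 0; p <- 1
  } else if (rss1 <= tol) {
    # separate slopes fit perfectly while the common slope does not
    Fstat <- Inf; p <- 0
  } else {
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = Fstat, df1 = df1, df2 = df2, p_value = p,
                 k_regions = k, n_points = nrow(pts)),
            class = "slope_heterogeneity")
}

#' @export
print.slope_heterogeneity <- function(x, ...) {
  cat(sprintf("Slope heterogeneity across %d regions: F = %.3f, df = %d,%d, p = %.4g\n",
              x$k_regions, x$F, x$df1, x$df2, x$p_value))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD on onset-of-loss times by body region
#'
#' Log-transforms each character's onset-of-loss day (censored characters
#' that never reach onset of loss are excluded; regions left entirely
#' censored are dropped with a warning), then fits a one-way ANOVA of
#' `log(day + offset)` on body region and runs Tukey's HSD over all region
#' pairs.
#'
#' @param milestones a [milestone_times()] data.frame.
#' @param characters a [character_table()].
#' @param base,offset see [log_day()].
#' @param conf_level family-wise confidence level for Tukey intervals.
#' @return list `F`, `df1`, `df2`, `p_value`, `k_regions`, `n`, and
#'   `tukey`: data.frame `pair`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`; class `"onset_anova"`.
#' @export
onset_anova_tukey <- function(milestones, characters,
                              base = exp(1), offset = 1,
                              conf_level = 0.95) {
  .assert_cols(milestones, c("character_id", "t_onset_loss"),
               "milestone table")
  characters <- character_table(as.data.frame(characters))
  d <- data.frame(
    character_id = milestones$character_id,
    t_onset_loss = milestones$t_onset_loss,
    body_region = characters$body_region[match(milestones$character_id,
                                               characters$character_id)],
    stringsAsFactors = FALSE)
  if (anyNA(d$body_region)) {
    .stopf("character(s) without a body region: %s",
           paste(d$character_id[is.na(d$body_region)], collapse = ", "))
  }
  censored_regions <- setdiff(
    unique(d$body_region),
    unique(d$body_region[!is.na(d$t_onset_loss)]))
  if (length(censored_regions)) {
    warning("region(s) entirely censored for onset of loss, excluded: ",
            paste(censored_regions, collapse = ", "), call. = FALSE)
  }
  d <- d[!is.na(d$t_onset_loss), , drop = FALSE]
  d$body_region <- factor(d$body_region)
  k <- nlevels(d$body_region)
  if (k < 2L) .stopf("need at least 2 regions with observed onset of loss")
  d$log_t <- log_day(d$t_onset_loss, base = base, offset = offset)
  fit <- stats::aov(log_t ~ body_region, data = d)
  tab <- summary(fit)[[1L]]
  Fstat <- tab[1L, "F value"]
  p <- tab[1L, "Pr(>F)"]
  if (is.nan(Fstat)) {
    # zero variance everywhere: no detectable group effect
    Fstat <- 0; p <- 1
  }
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$body_region
  p_adj <- tk[, "p adj"]
  p_adj[is.nan(p_adj) & abs(tk[, "diff"]) < 1e-12] <- 1
  tukey <- data.frame(pair = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = p_adj,
                      significant = !is.na(p_adj) &
                        p_adj < (1 - conf_level),
                      stringsAsFactors = FALSE)
  rownames(tukey) <- NULL
  structure(list(F = Fstat, df1 = tab[1L, "Df"],
                 df2 = tab[2L, "Df"], p_value = p,
                 k_regions = k, n = nrow(d), tukey = tukey),
            class = "onset_anova")
}

#' @export
print.onset_anova <- function(x, ...) {
  cat(sprintf("Onset-of-loss ANOVA (%d regions, n = %d): F = %.3f, df = %d,%d, p = %.4g\n",
              x$k_regions, x$n, x$F, x$df1, x$df2, x$p_value))
  sig <- x$tukey$pair[x$tukey$significant]
  if (length(sig)) {
    cat("Tukey HSD significant pairs:", paste(sig, collapse = "; "), "\n")
  } else {
    cat("Tukey HSD: no significant pairs\n")
  }
  invisible(x)
}
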
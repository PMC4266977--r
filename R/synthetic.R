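#' Default logarithmic sampling schedule
#'
#' Fourteen sampling days, roughly geometrically spaced from the
#' post-mortem baseline (day 0) to day 273, mirroring the high initial
#' sampling frequency needed to capture early rapid decay.
#'
#' @return Numeric vector of days.
#' @export
default_schedule <- function() {
  c(0, 1, 2, 3, 5, 8, 12, 19, 30, 47, 73, 113, 176, 273)
}

#' Default synthetic character roster
#'
#' Nineteen anatomical characters of a velvet-worm-like organism spread
#' over the five body regions, including two decay-immune sclerotized
#' characters (jaws, claws) that stay pristine throughout.
#'
#' @return A [character_table()].
#' @export
default_characters <- function() {
  character_table(data.frame(
    character_id = c("gut", "slime_glands", "nervous_system", "musculature",
                     "reproductive_organs",
                     "antennae", "eyes", "mouth", "slime_papillae", "jaws",
                     "body_outline", "trunk_cuticle", "epidermis", "pigment",
                     "limb_outline", "foot_pads", "claws",
                     "anal_region", "posterior_papillae"),
    body_region = c(rep("internal", 5),
                    rep("anterior", 5),
                    rep("trunk", 4),
                    rep("limbs", 3),
                    rep("posterior", 2)),
    immune = c(rep(FALSE, 9), TRUE,
               rep(FALSE, 6), TRUE,
               rep(FALSE, 2)),
    stringsAsFactors = FALSE))
}

#' Default per-region decay timing parameters
#'
#' Lognormal parameters (meanlog = log of the median day) for the onset of
#' decay and for the decay-to-loss duration, chosen to reproduce a staged
#' decay sequence: internal organs decay within days and are completely
#' lost early (by roughly days 8-12), while cuticular and external
#' characters decay over weeks and are lost only after one to several
#' months, with the four non-internal regions following closely similar
#' trajectories (anterior ~ trunk, limbs ~ posterior), so that the
#' internal region is the clear outlier.
#'
#' @return data.frame with one row per region: `body_region`,
#'   `onset_meanlog`, `onset_sdlog`, `loss_meanlog`, `loss_sdlog`.
#' @export
default_region_params <- function() {
  data.frame(
    body_region = c("internal", "anterior", "trunk", "limbs", "posterior"),
    onset_meanlog = log(c(1.5, 6, 6, 7, 7)),
    onset_sdlog = rep(0.35, 5),
    loss_meanlog = log(c(6, 66, 64, 70, 68)),
    loss_sdlog = rep(0.45, 5),
    stringsAsFactors = FALSE)
}

#' Configuration for a synthetic decay experiment
#'
#' @param seed RNG seed.
#' @param n_specimens total specimens, spread round-robin over the
#'   schedule (destructive sampling: one day each).
#' @param schedule sampling days (strictly increasing, starting at or near
#'   day 0).
#' @param characters a [character_table()] with an `immune` column.
#' @param region_params per-region lognormal timing parameters, see
#'   [default_region_params()].
#' @param frailty_sdlog sd (log scale) of the specimen-level multiplicative
#'   frailty on decay times; models between-specimen variation that makes
#'   aggregated series non-monotone under destructive sampling.
#' @return list of class `"decay_sim_config"`.
#' @export
decay_sim_config <- function(seed = 1L, n_specimens = 54L,
                             schedule = default_schedule(),
                             characters = default_characters(),
                             region_params = default_region_params(),
                             frailty_sdlog = 0.25) {
  if (any(diff(schedule) <= 0)) .stopf("schedule must be strictly increasing")
  if (any(schedule < 0)) .stopf("schedule days must be non-negative")
  characters <- character_table(as.data.frame(characters))
  .assert_cols(region_params,
               c("body_region", "onset_meanlog", "onset_sdlog",
                 "loss_meanlog", "loss_sdlog"), "region parameters")
  if (any(region_params$onset_sdlog < 0) || any(region_params$loss_sdlog < 0) ||
      frailty_sdlog < 0) {
    .stopf("scale parameters must be non-negative")
  }
  miss <- setdiff(unique(characters$body_region), region_params$body_region)
  if (length(miss)) {
    .stopf("no timing parameters for region(s): %s",
           paste(miss, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), n_specimens = as.integer(n_specimens),
                 schedule = schedule, characters = characters,
                 region_params = region_params,
                 frailty_sdlog = frailty_sdlog),
            class = "decay_sim_config")
}

#' Simulate a destructive-sampling decay experiment
#'
#' Each specimen is assigned a single sampling day (round-robin over the
#' schedule). For every specimen x non-immune character the latent onset of
#' decay is `T1 = frailty * LogNormal(onset_meanlog, onset_sdlog)` of the
#' character's region, and loss occurs at `T2 = T1 +
#' LogNormal(loss_meanlog, loss_sdlog)` (the duration scaled by the same
#' specimen frailty). The observed condition at the specimen's day `d` is
#' pristine if `d < T1`, decaying if `T1 <= d < T2`, lost if `d >= T2`.
#' Immune characters are always pristine.
#'
#' @param config a [decay_sim_config()].
#' @return list with `scores` (a [decay_scores()] object) and `truth`
#'   (data.frame of latent `t_onset`, `t_loss`, `frailty` per specimen x
#'   character; `NA` for immune characters).
#' @export
simulate_experiment <- function(config = decay_sim_config()) {
  stopifnot(inherits(config, "decay_sim_config"))
  set.seed(config$seed)
  chars <- config$characters
  days <- rep(config$schedule, length.out = config$n_specimens)
  days <- sort(days)
  specimen_id <- sprintf("S%03d", seq_len(config$n_specimens))
  frailty <- stats::rlnorm(config$n_specimens, 0, config$frailty_sdlog)
  rp <- config$region_params
  ridx <- match(chars$body_region, rp$body_region)
  nc <- nrow(chars)
  rows <- vector("list", config$n_specimens)
  for (i in seq_len(config$n_specimens)) {
    t1 <- frailty[i] * stats::rlnorm(nc, rp$onset_meanlog[ridx],
                                     rp$onset_sdlog[ridx])
    dur <- frailty[i] * stats::rlnorm(nc, rp$loss_meanlog[ridx],
                                      rp$loss_sdlog[ridx])
    t2 <- t1 + dur
    t1[chars$immune] <- NA_real_
    t2[chars$immune] <- NA_real_
    d <- days[i]
    cond <- ifelse(chars$immune, 0L,
                   ifelse(d < t1, 0L, ifelse(d < t2, 1L, 2L)))
    rows[[i]] <- data.frame(specimen_id = specimen_id[i],
                            character_id = chars$character_id,
                            day = d, condition = as.integer(cond),
                            t_onset = t1, t_loss = t2,
                            frailty = frailty[i],
                            stringsAsFactors = FALSE)
  }
  full <- do.call(rbind, rows)
  scores <- decay_scores(full[, c("specimen_id", "character_id", "day",
                                  "condition")], chars)
  truth <- full[, c("specimen_id", "character_id", "day", "condition",
                    "t_onset", "t_loss", "frailty")]
  rownames(truth) <- NULL
  list(scores = scores, truth = truth)
}

#' Default per-metric morphometric drift parameters
#'
#' Linear drift rates (% per day) saturating at an asymptote, emulating
#' trunk elongation and bloating of 10-30% and limb expansion of 10-25%,
#' with the inner (epidermis) widths shrinking as the cuticle detaches.
#'
#' @return data.frame `metric`, `slope`, `asymptote`, `baseline`.
#' @export
default_metric_params <- function() {
  data.frame(
    metric = morpho_metrics(),
    slope = c(0.35, 0.5, -0.2, 0.3, 0.4, -0.25),
    asymptote = c(20, 20, -12, 17, 16, -14),
    baseline = c(45, 6, 5, 2.5, 1.2, 1.0),
    stringsAsFactors = FALSE)
}

#' Configuration for synthetic morphometric measurements
#'
#' @param seed RNG seed.
#' @param metric_params per-metric true drift (% per day), saturation
#'   asymptote (%; use `Inf`/`-Inf` for no saturation) and baseline
#'   dimension (mm), see [default_metric_params()].
#' @param noise_sd Gaussian measurement noise sd on the percent-change
#'   scale.
#' @param n_per_day specimens measured per sampling day.
#' @return list of class `"morpho_sim_config"`.
#' @export
morpho_sim_config <- function(seed = 1L,
                              metric_params = default_metric_params(),
                              noise_sd = 4, n_per_day = 3L) {
  .assert_cols(metric_params, c("metric", "slope", "asymptote", "baseline"),
               "metric parameters")
  bad <- setdiff(metric_params$metric, morpho_metrics())
  if (length(bad)) .stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), metric_params = metric_params,
                 noise_sd = noise_sd, n_per_day = as.integer(n_per_day)),
            class = "morpho_sim_config")
}

#' Simulate morphometric measurements through decay
#'
#' For each metric, sampling day and specimen:
#' `value_at_day = value_at_death * (1 + (drift + noise) / 100)` where
#' `drift = slope * day` saturating at the metric's asymptote and `noise ~
#' N(0, noise_sd)`. Values are floored just above zero so records stay
#' valid.
#'
#' @param config a [morpho_sim_config()].
#' @param schedule sampling days.
#' @return list with `measurements` (a [measurement_table()]) and `truth`
#'   (per-record latent drift).
#' @export
simulate_measurements <- function(config = morpho_sim_config(),
                                  schedule = default_schedule()) {
  stopifnot(inherits(config, "morpho_sim_config"))
  set.seed(config$seed)
  mp <- config$metric_params
  grid <- expand.grid(day = schedule, rep = seq_len(config$n_per_day),
                      metric_i = seq_len(nrow(mp)))
  slope <- mp$slope[grid$metric_i]
  asym <- mp$asymptote[grid$metric_i]
  drift <- ifelse(asym >= 0, pmin(slope * grid$day, asym),
                  pmax(slope * grid$day, asym))
  noise <- stats::rnorm(nrow(grid), 0, config$noise_sd)
  base <- mp$baseline[grid$metric_i]
  val <- base * (1 + (drift + noise) / 100)
  val <- pmax(val, base * 0.01)
  meas <- measurement_table(data.frame(
    specimen_id = sprintf("M%04d", seq_len(nrow(grid))),
    day = grid$day,
    metric = mp$metric[grid$metric_i],
    value_at_death = base,
    value_at_day = val,
    stringsAsFactors = FALSE))
  truth <- data.frame(specimen_id = meas$specimen_id,
                      metric = meas$metric, day = meas$day,
                      true_drift = drift, noise = noise,
                      stringsAsFactors = FALSE)
  list(measurements = meas, truth = truth)
}

#' Simulate correlated decay/synapomorphic rank pairs
#'
#' Ranks of a bivariate Gaussian sample with correlation `rho`; used for
#' null calibration (type-I error) and power analysis of the slippage
#' test.
#'
#' @param n number of characters.
#' @param rho latent correlation in `[-1, 1]`.
#' @param seed optional RNG seed.
#' @return list `decay_rank`, `syn_rank` (midrank vectors of length `n`).
#' @export
simulate_rank_pairs <- function(n, rho, seed = NULL) {
  if (n < 3L) .stopf("n must be >= 3")
  if (abs(rho) > 1) .stopf("rho must be in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(decay_rank = rank(z1, ties.method = "average"),
       syn_rank = rank(z2, ties.method = "average"))
}

#' Generate a battery of synthetic phylogenetic hypotheses
#'
#' Builds `n_hypotheses` ladder trees whose root-to-focal path has five
#' labelled internal nodes and assigns every non-immune-or-not character a
#' node: decay-immune and uniquely derived characters (jaws, claws, slime
#' papillae) go to the focal clade (depth 1), internal organs to the
#' deepest nodes (symplesiomorphies), cuticular and external characters to
#' intermediate depths. Hypotheses differ by seeded jitter of the
#' intermediate assignments, and each marks two anterior characters
#' (antennae, eyes, when present) as contested with a depth-1 alternative,
#' so the battery runs both homology and homoplasy treatments.
#'
#' @param characters a [character_table()].
#' @param n_hypotheses number of alternative hypotheses.
#' @param seed RNG seed for the jitter.
#' @return list of [phylo_hypothesis()] objects.
#' @export
example_hypotheses <- function(characters = default_characters(),
                               n_hypotheses = 4L, seed = 1L) {
  characters <- character_table(as.data.frame(characters))
  set.seed(seed)
  newick <- "(((((Focal,T1)n1,T2)n2,T3)n3,T4)n4,T5)n5;"
  tree <- ape::read.tree(text = newick)
  base_depth <- c(internal = 4L, anterior = 2L, trunk = 3L,
                  limbs = 2L, posterior = 3L)
  focal_chars <- intersect(c("jaws", "claws", "slime_papillae"),
                           characters$character_id)
  out <- vector("list", n_hypotheses)
  for (h in seq_len(n_hypotheses)) {
    depth <- base_depth[characters$body_region]
    depth[characters$character_id %in% focal_chars] <- 1L
    # internal organs split between deep nodes; jitter intermediates
    is_internal <- characters$body_region == "internal" &
      !(characters$character_id %in% focal_chars)
    depth[is_internal] <- sample(c(4L, 5L), sum(is_internal), replace = TRUE)
    mid <- depth %in% 2:3
    depth[mid] <- pmin(4L, pmax(2L, depth[mid] +
                                  sample(c(-1L, 0L, 1L), sum(mid),
                                         replace = TRUE,
                                         prob = c(0.2, 0.6, 0.2))))
    assignments <- stats::setNames(paste0("n", depth),
                                   characters$character_id)
    contested_chars <- intersect(c("antennae", "eyes"),
                                 characters$character_id)
    contested <- if (length(contested_chars)) {
      stats::setNames(rep("n1", length(contested_chars)), contested_chars)
    } else NULL
    out[[h]] <- phylo_hypothesis(tree, "Focal", assignments, contested,
                                 hypothesis_id = sprintf("H%d", h))
  }
  out
}
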
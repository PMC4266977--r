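#' Aggregate specimen-level conditions into an ordinal decay state
#'
#' Bridges the three-state specimen coding (pristine/decaying/lost) to the
#' five-state ordinal trajectory coding: 0 = pristine, 1 = onset of decay,
#' 2 = complete decay, 3 = onset of loss, 4 = complete loss. For the set of
#' specimens scored for one character on one day:
#' \itemize{
#'   \item 0 if all specimens are pristine;
#'   \item 4 if all are lost;
#'   \item 3 if at least one (but not all) is lost;
#'   \item 2 if all are decaying (decaying-or-worse, none lost);
#'   \item 1 otherwise (at least one decaying, the rest pristine).
#' }
#' Not-scored (`NA`) conditions are excluded; a day with no scored specimen
#' for the character yields `NA` ("no data") and is omitted from series.
#'
#' @param scores a [decay_scores()] object.
#' @param character_id,day which cell to aggregate.
#' @return Integer state 0-4, or `NA` if no specimen was scored.
#' @export
aggregate_character_state <- function(scores, character_id, day) {
  stopifnot(inherits(scores, "decay_scores"))
  rec <- scores$records
  cond <- rec$condition[rec$character_id == character_id & rec$day == day]
  .aggregate_conditions(cond[!is.na(cond)])
}

.aggregate_conditions <- function(cond) {
  if (!length(cond)) return(NA_integer_)
  n_lost <- sum(cond == 2L)
  if (n_lost == length(cond)) return(4L)
  if (n_lost > 0L) return(3L)
  if (all(cond >= 1L)) return(2L)
  if (any(cond == 1L)) return(1L)
  0L
}

#' Aggregate a whole score matrix into per-character state series
#'
#' Applies [aggregate_character_state()] to every character x sampling day
#' cell with at least one scored specimen.
#'
#' @param scores a [decay_scores()] object.
#' @return data.frame with columns `character_id`, `day`, `state` (0-4) and
#'   `n` (specimens scored), ordered by character then day; class
#'   `"aggregated_states"`.
#' @export
aggregate_states <- function(scores) {
  stopifnot(inherits(scores, "decay_scores"))
  rec <- scores$records[!is.na(scores$records$condition), , drop = FALSE]
  if (!nrow(rec)) .stopf("no scored records")
  key <- interaction(rec$character_id, rec$day, drop = TRUE, sep = "\r")
  states <- tapply(rec$condition, key, .aggregate_conditions)
  counts <- tapply(rec$condition, key, length)
  parts <- strsplit(names(states), "\r", fixed = TRUE)
  out <- data.frame(
    character_id = vapply(parts, `[[`, "", 1L),
    day = as.numeric(vapply(parts, `[[`, "", 2L)),
    state = as.integer(states),
    n = as.integer(counts),
    stringsAsFactors = FALSE)
  out <- out[order(out$character_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("aggregated_states", "data.frame")
  out
}

#' Extract decay milestone times from aggregated state series
#'
#' For each character, the first sampled day at which the series reaches
#' (>=) each ordinal threshold: onset of decay (state 1), complete decay
#' (2), onset of loss (3), complete loss (4). A milestone never reached
#' within the experiment is censored and reported as `NA`. Because sampling
#' is destructive, series need not be monotone across days (each day is a
#' different set of specimens); milestones deliberately use first
#' attainment, and a `monotone` flag reports whether the series ever steps
#' down.
#'
#' @param series an [aggregate_states()] data.frame (columns
#'   `character_id`, `day`, `state`).
#' @return data.frame with one row per character: `t_onset_decay`,
#'   `t_complete_decay`, `t_onset_loss`, `t_complete_loss` (day or `NA` =
#'   censored) and `monotone`; class `"milestone_times"`.
#' @export
milestone_times <- function(series) {
  .assert_cols(series, c("character_id", "day", "state"), "state series")
  if (!nrow(series)) .stopf("empty state series")
  split_idx <- split(seq_len(nrow(series)), series$character_id)
  rows <- lapply(split_idx, function(idx) {
    d <- series$day[idx]
    s <- series$state[idx]
    o <- order(d)
    d <- d[o]; s <- s[o]
    first_at <- function(th) {
      hit <- which(s >= th)
      if (length(hit)) d[hit[1L]] else NA_real_
    }
    data.frame(character_id = series$character_id[idx[1L]],
               t_onset_decay = first_at(1L),
               t_complete_decay = first_at(2L),
               t_onset_loss = first_at(3L),
               t_complete_loss = first_at(4L),
               monotone = all(diff(s) >= 0L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("milestone_times", "data.frame")
  out
}

#' Rank characters from most decay-prone to most decay-resistant
#'
#' Characters are ranked primarily by the timing of complete loss; ties are
#' broken by the time of onset of loss, then the time at which all samples
#' exhibit decay (complete decay), then the time of onset of decay.
#' Censored milestones sort after every finite day at every level;
#' censored-vs-censored at one level falls through to the next. Characters
#' tied on the full key tuple receive midranks (rank 1 = most decay-prone).
#'
#' @param milestones a [milestone_times()] data.frame (>= 2 characters).
#' @return data.frame `character_id`, `decay_rank`, `tie_group` plus the
#'   four milestone columns, sorted by rank; class `"decay_rank_table"`.
#' @export
decay_rank_table <- function(milestones) {
  .assert_cols(milestones,
               c("character_id", "t_onset_decay", "t_complete_decay",
                 "t_onset_loss", "t_complete_loss"), "milestone table")
  if (nrow(milestones) < 2L) .stopf("need at least 2 characters to rank")
  keys <- milestones[, c("t_complete_loss", "t_onset_loss",
                         "t_complete_decay", "t_onset_decay")]
  r <- .lex_midrank(keys)
  out <- data.frame(character_id = milestones$character_id,
                    decay_rank = r$rank,
                    tie_group = r$tie_group,
                    stringsAsFactors = FALSE)
  out <- cbind(out, milestones[, c("t_onset_decay", "t_complete_decay",
                                   "t_onset_loss", "t_complete_loss")])
  out <- out[order(out$decay_rank, out$character_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decay_rank_table", "data.frame")
  out
}

#' Classify a sampling day into a decay stage
#'
#' Stages are half-open intervals `[start, end)` over the scheme's
#' boundaries; the last stage is open-ended.
#'
#' @param day non-negative day value (vectorized).
#' @param scheme a [decay_stage_scheme()].
#' @return Stage label(s).
#' @export
assign_decay_stage <- function(day, scheme = decay_stage_scheme()) {
  stopifnot(inherits(scheme, "decay_stage_scheme"))
  if (any(day < 0)) .stopf("day must be non-negative")
  b <- scheme$boundaries
  if (any(day < b[1L])) .stopf("day below the first stage boundary (%g)", b[1L])
  # last boundary is the nominal end of observation; the final stage is open
  starts <- b[-length(b)]
  idx <- findInterval(day, starts)
  scheme$stage_labels[idx]
}
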
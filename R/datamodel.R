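#' Closed vocabularies of the decay data model
#'
#' `body_regions()` returns the five anatomical regions characters are
#' assigned to; `morpho_metrics()` the six linear measurements tracked
#' through decay; `condition_levels()` the three specimen-level condition
#' codes (named integer vector).
#'
#' @return A character vector (or named integer vector for
#'   `condition_levels()`).
#' @export
body_regions <- function() {
  c("anterior", "trunk", "limbs", "posterior", "internal")
}

#' @rdname body_regions
#' @export
morpho_metrics <- function() {
  c("body_length", "body_width_outer", "body_width_inner",
    "limb_length", "limb_width_outer", "limb_width_inner")
}

#' @rdname body_regions
#' @export
condition_levels <- function() {
  c(pristine = 0L, decaying = 1L, lost = 2L)
}

#' Build and validate a character definition table
#'
#' Characters are the anatomical features scored through decay. Each has a
#' unique id, a free-text label and a body region from the closed five-value
#' set (anterior, trunk, limbs, posterior, internal). An optional logical
#' `immune` column marks features that never decay within experimental
#' time-scales (e.g. sclerotized jaws and claws).
#'
#' @param df data.frame with columns `character_id`, `body_region` and
#'   optionally `label`, `immune`.
#' @return The validated data.frame with class `"character_table"`.
#' @export
character_table <- function(df) {
  .assert_cols(df, c("character_id", "body_region"), "character table")
  df$character_id <- as.character(df$character_id)
  if (anyDuplicated(df$character_id)) {
    .stopf("duplicated character_id: %s",
           paste(unique(df$character_id[duplicated(df$character_id)]),
                 collapse = ", "))
  }
  bad <- setdiff(unique(df$body_region), body_regions())
  if (length(bad)) {
    .stopf("unknown body_region value(s): %s (must be one of %s)",
           paste(bad, collapse = ", "), paste(body_regions(), collapse = ", "))
  }
  if (is.null(df$label)) df$label <- df$character_id
  if (is.null(df$immune)) df$immune <- FALSE
  df$immune <- as.logical(df$immune)
  class(df) <- c("character_table", "data.frame")
  df
}

# Parse a condition column given either as integers {0,1,2} or as
# (case-insensitive) tokens pristine/decaying/lost; "not_scored" and NA map
# to NA and are excluded from aggregation.
.parse_condition <- function(x) {
  lev <- condition_levels()
  out <- rep(NA_integer_, length(x))
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & !(x %in% lev))
    if (length(bad)) {
      .stopf("condition outside {0,1,2} at row(s): %s",
             paste(utils::head(bad, 10L), collapse = ", "))
    }
    out <- as.integer(x)
  } else {
    tok <- tolower(trimws(as.character(x)))
    known <- c(names(lev), "not_scored", "na", "0", "1", "2")
    bad <- which(!is.na(tok) & !(tok %in% known))
    if (length(bad)) {
      .stopf("unknown condition token(s) %s at row(s): %s",
             paste(unique(tok[bad]), collapse = ", "),
             paste(utils::head(bad, 10L), collapse = ", "))
    }
    num <- suppressWarnings(as.integer(tok))
    out <- ifelse(!is.na(num), num, unname(lev[tok]))
    out[tok %in% c("not_scored", "na")] <- NA_integer_
    out <- as.integer(out)
  }
  out
}

#' Build and validate a decay score matrix
#'
#' The central container for a destructive-sampling decay experiment: one
#' record per specimen x character x sampling day, with a three-state
#' condition code (0 pristine, 1 decaying, 2 lost; `NA` = not scored).
#' Because sampling is destructive, each specimen may appear at exactly one
#' sampling day. The sampling schedule is inferred from the distinct days.
#'
#' @param records data.frame with columns `specimen_id`, `character_id`,
#'   `day`, `condition` (integer codes or text tokens).
#' @param characters a [character_table()] (or coercible data.frame).
#' @return An object of class `"decay_scores"`: a list with elements
#'   `records`, `characters`, `schedule`.
#' @export
decay_scores <- function(records, characters) {
  characters <- character_table(as.data.frame(characters))
  .assert_cols(records, c("specimen_id", "character_id", "day", "condition"),
               "score table")
  records <- data.frame(specimen_id = as.character(records$specimen_id),
                        character_id = as.character(records$character_id),
                        day = as.numeric(records$day),
                        condition = records$condition,
                        stringsAsFactors = FALSE)
  if (any(is.na(records$day)) || any(records$day < 0)) {
    .stopf("sampling days must be non-negative numbers")
  }
  unknown <- which(!(records$character_id %in% characters$character_id))
  if (length(unknown)) {
    .stopf("unknown character_id %s at row(s): %s",
           paste(unique(records$character_id[unknown]), collapse = ", "),
           paste(utils::head(unknown, 10L), collapse = ", "))
  }
  records$condition <- .parse_condition(records$condition)
  # destructive sampling: one day per specimen
  day_per_spec <- tapply(records$day, records$specimen_id,
                         function(d) length(unique(d)))
  multi <- names(day_per_spec)[day_per_spec > 1L]
  if (length(multi)) {
    .stopf("specimen(s) scored at more than one day (destructive sampling): %s",
           paste(multi, collapse = ", "))
  }
  dup <- duplicated(records[, c("specimen_id", "character_id")])
  if (any(dup)) {
    .stopf("duplicated (specimen, character) record(s) at row(s): %s",
           paste(utils::head(which(dup), 10L), collapse = ", "))
  }
  schedule <- sort(unique(records$day))
  structure(list(records = records, characters = characters,
                 schedule = schedule),
            class = "decay_scores")
}

#' @export
print.decay_scores <- function(x, ...) {
  cat("Decay score matrix:",
      length(unique(x$records$specimen_id)), "specimens,",
      nrow(x$characters), "characters,",
      length(x$schedule), "sampling days",
      sprintf("(day %g-%g)\n", min(x$schedule), max(x$schedule)))
  invisible(x)
}

#' Build and validate a morphometric measurement table
#'
#' Per specimen and metric: the linear dimension immediately after death
#' (`value_at_death`) and at the specimen's sampling day (`value_at_day`).
#' Metrics come from the closed six-value set of [morpho_metrics()].
#'
#' @param df data.frame with columns `specimen_id`, `day`, `metric`,
#'   `value_at_death`, `value_at_day`.
#' @return Validated data.frame with class `"measurement_table"`.
#' @export
measurement_table <- function(df) {
  .assert_cols(df, c("specimen_id", "day", "metric",
                     "value_at_death", "value_at_day"), "measurement table")
  df <- as.data.frame(df)
  df$specimen_id <- as.character(df$specimen_id)
  df$day <- as.numeric(df$day)
  bad <- setdiff(unique(df$metric), morpho_metrics())
  if (length(bad)) {
    .stopf("unknown metric(s): %s", paste(bad, collapse = ", "))
  }
  if (any(df$day < 0)) .stopf("days must be non-negative")
  if (any(df$value_at_death <= 0) || any(df$value_at_day <= 0)) {
    .stopf("measurement values must be positive")
  }
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Decay stage scheme
#'
#' Day boundaries delimiting named decay stages. The default five-stage
#' scheme uses boundaries 0, 2, 8, 34, 109, 220 days; stages are half-open
#' intervals `[start, end)` and the last stage is open-ended (the nominal
#' end of the experiment, day 220, is retained for reference only).
#'
#' @param boundaries strictly increasing day values; `length(boundaries) - 1`
#'   stages.
#' @param labels stage labels, default `1:(length(boundaries) - 1)`.
#' @return Object of class `"decay_stage_scheme"`.
#' @export
decay_stage_scheme <- function(boundaries = c(0, 2, 8, 34, 109, 220),
                               labels = NULL) {
  if (length(boundaries) < 2 || any(diff(boundaries) <= 0)) {
    .stopf("stage boundaries must be strictly increasing, length >= 2")
  }
  n <- length(boundaries) - 1L
  labels <- labels %||% as.character(seq_len(n))
  if (length(labels) != n) .stopf("need %d stage labels", n)
  structure(list(boundaries = boundaries, stage_labels = labels),
            class = "decay_stage_scheme")
}

#' Build and validate a phylogenetic hypothesis
#'
#' A rooted tree with labelled internal nodes, a designated focal terminal
#' (the taxon whose decay experiment is analysed), and an assignment of each
#' anatomical character to the internal node (clade) it is a synapomorphy
#' of. Assigned nodes must lie on the path from the root to the focal
#' terminal. Characters whose homology is contested carry an alternative
#' node assignment used under the homoplasy treatment.
#'
#' @param tree an [ape::read.tree()] `phylo` object, rooted, with internal
#'   node labels.
#' @param focal tip label of the focal terminal.
#' @param assignments named character vector: `character_id -> node label`.
#' @param contested named character vector of alternative node labels for
#'   contested characters; names must be a subset of `names(assignments)`.
#' @param hypothesis_id short identifier.
#' @return Object of class `"phylo_hypothesis"` with the root-to-focal path
#'   (node label and depth, 1 = tip-most) precomputed.
#' @export
phylo_hypothesis <- function(tree, focal, assignments, contested = NULL,
                             hypothesis_id = "H1") {
  if (!inherits(tree, "phylo")) .stopf("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) .stopf("tree must be rooted")
  if (!(focal %in% tree$tip.label)) {
    .stopf("focal terminal '%s' not found in tree", focal)
  }
  path <- .focal_path(tree, focal)
  assignments <- .as_named_chr(assignments, "assignments")
  if (anyDuplicated(names(assignments))) {
    .stopf("duplicated character in assignments")
  }
  off <- setdiff(unname(assignments), path$node)
  if (length(off)) {
    .stopf(paste0("node(s) %s are not labelled nodes on the root-to-'%s' ",
                  "path (characters: %s)"),
           paste(unique(off), collapse = ", "), focal,
           paste(names(assignments)[assignments %in% off], collapse = ", "))
  }
  if (!is.null(contested) && length(contested)) {
    contested <- .as_named_chr(contested, "contested")
    extra <- setdiff(names(contested), names(assignments))
    if (length(extra)) {
      .stopf("contested character(s) not in assignments: %s",
             paste(extra, collapse = ", "))
    }
    offc <- setdiff(unname(contested), path$node)
    if (length(offc)) {
      .stopf("alternative node(s) off the focal path: %s",
             paste(unique(offc), collapse = ", "))
    }
  } else {
    contested <- stats::setNames(character(0), character(0))
  }
  structure(list(hypothesis_id = hypothesis_id, tree = tree, focal = focal,
                 path = path, assignments = assignments,
                 contested = contested),
            class = "phylo_hypothesis")
}

.as_named_chr <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    .stopf("%s must be a named character vector (names = character ids)", what)
  }
  stats::setNames(as.character(x), names(x))
}

# Internal nodes on the path root -> focal tip, tip-ward first.
# depth 1 = parent of the focal terminal (least-inclusive clade containing
# it); max depth = root (most-inclusive).
.focal_path <- function(tree, focal) {
  ntip <- length(tree$tip.label)
  tipidx <- match(focal, tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  nodes <- integer(0)
  node <- tipidx
  repeat {
    p <- parent[node]
    if (p == 0L) break
    nodes <- c(nodes, p)
    node <- p
  }
  if (is.null(tree$node.label)) {
    .stopf("tree has no internal node labels; they are required")
  }
  labels <- tree$node.label[nodes - ntip]
  if (any(is.na(labels) | !nzchar(labels))) {
    .stopf("unlabelled internal node on the root-to-focal path")
  }
  data.frame(node = labels, depth = seq_along(nodes),
             stringsAsFactors = FALSE)
}

#' @export
print.phylo_hypothesis <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic hypothesis '%s': focal terminal '%s', %d on-path nodes, %d characters (%d contested)\n",
    x$hypothesis_id, x$focal, nrow(x$path), length(x$assignments),
    length(x$contested)))
  invisible(x)
}
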
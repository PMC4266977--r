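#' Read and write decay score tables
#'
#' Delimited tables (comma for `.csv`, tab for `.tsv`/`.txt`) with a header
#' row. The score table has columns `specimen_id`, `character_id`, `day`,
#' `condition` (integers 0/1/2 or tokens pristine/decaying/lost,
#' case-insensitive; `not_scored`/`NA` for characters not assessable); the
#' character table has `character_id`, `body_region` and optionally
#' `label`, `immune`.
#'
#' @param path path of the score table.
#' @param characters_path path of the character definition table.
#' @return `read_decay_scores()`: a validated [decay_scores()] object.
#' @export
read_decay_scores <- function(path, characters_path) {
  decay_scores(.read_table(path), .read_table(characters_path))
}

#' @rdname read_decay_scores
#' @param x a [decay_scores()] object.
#' @return `write_decay_scores()`: the score-table path, invisibly.
#' @export
write_decay_scores <- function(x, path, characters_path = NULL) {
  stopifnot(inherits(x, "decay_scores"))
  rec <- x$records
  lev <- condition_levels()
  tok <- names(lev)[match(rec$condition, lev)]
  tok[is.na(tok)] <- "not_scored"
  rec$condition <- tok
  .write_table(rec, path)
  if (!is.null(characters_path)) {
    .write_table(as.data.frame(x$characters), characters_path)
  }
  invisible(path)
}

#' Read and write morphometric measurement tables
#'
#' Columns: `specimen_id`, `day`, `metric` (one of [morpho_metrics()]),
#' `value_at_death`, `value_at_day`.
#'
#' @param path file path (.csv or .tsv).
#' @return `read_measurements()`: a validated [measurement_table()].
#' @export
read_measurements <- function(path) {
  measurement_table(.read_table(path))
}

#' @rdname read_measurements
#' @param x a [measurement_table()].
#' @export
write_measurements <- function(x, path) {
  .write_table(as.data.frame(x), path)
}

#' Read and write phylogenetic hypothesis files
#'
#' The tree is Newick (one rooted tree per file) with labelled internal
#' nodes; branch lengths, if present, are ignored (only topology matters
#' for ranking). The assignment table has columns `character_id`, `node`
#' and optionally `alt_node` (non-empty values mark contested characters
#' and give the node used under the homoplasy treatment).
#'
#' @param tree_path Newick file.
#' @param assignment_path delimited assignment table.
#' @param focal tip label of the focal terminal.
#' @param hypothesis_id identifier; defaults to the tree file name.
#' @return `read_hypothesis()`: a validated [phylo_hypothesis()].
#' @export
read_hypothesis <- function(tree_path, assignment_path, focal,
                            hypothesis_id = NULL) {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) .stopf("could not parse Newick tree in %s", tree_path)
  tab <- .read_table(assignment_path)
  .assert_cols(tab, c("character_id", "node"), "assignment table")
  assignments <- stats::setNames(as.character(tab$node),
                                 as.character(tab$character_id))
  contested <- NULL
  if ("alt_node" %in% names(tab)) {
    keep <- !is.na(tab$alt_node) & nzchar(trimws(as.character(tab$alt_node)))
    if (any(keep)) {
      contested <- stats::setNames(as.character(tab$alt_node[keep]),
                                   as.character(tab$character_id[keep]))
    }
  }
  phylo_hypothesis(tree, focal, assignments, contested,
                   hypothesis_id = hypothesis_id %||%
                     sub("\\.[^.]*$", "", basename(tree_path)))
}

#' @rdname read_hypothesis
#' @param x a [phylo_hypothesis()].
#' @export
write_hypothesis <- function(x, tree_path, assignment_path) {
  stopifnot(inherits(x, "phylo_hypothesis"))
  ape::write.tree(x$tree, tree_path)
  tab <- data.frame(character_id = names(x$assignments),
                    node = unname(x$assignments),
                    alt_node = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(x$contested)) {
    tab$alt_node[match(names(x$contested), tab$character_id)] <-
      unname(x$contested)
  }
  .write_table(tab, assignment_path)
  invisible(tree_path)
}

#' Write an analysis result as TSV and/or JSON
#'
#' Generic report writer used by the pipeline: data.frames go to TSV,
#' arbitrary result lists to JSON (via jsonlite, numbers at full precision).
#'
#' @param x data.frame or list.
#' @param path output path; `.json` selects JSON, anything else delimited
#'   text.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
  } else {
    .write_table(as.data.frame(x), path)
  }
  invisible(path)
}
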
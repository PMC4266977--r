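#' Synapomorphic ranks of characters on a phylogenetic hypothesis
#'
#' Each character is assigned to an internal node on the root-to-focal
#' path; its depth is the number of edges from that node down to the focal
#' terminal. Depth 1 is the least-inclusive clade containing the focal
#' terminal (its apomorphies), the maximum depth is the root
#' (symplesiomorphies shared by the most-inclusive group). Synapomorphic
#' ranks are midranks of depth: rank 1 = most apomorphic, increasing toward
#' the root; characters sharing a node share a midrank. Under the
#' `homoplasy` treatment, contested characters use their alternative node;
#' under `homology`, their primary node.
#'
#' @param hypothesis a [phylo_hypothesis()].
#' @param treatment `"homology"` or `"homoplasy"`.
#' @return data.frame `character_id`, `node`, `depth`, `syn_rank`, with
#'   attributes `hypothesis_id`, `treatment`, `path`; class
#'   `"synapomorphic_ranking"`.
#' @export
synapomorphic_ranks <- function(hypothesis,
                                treatment = c("homology", "homoplasy")) {
  stopifnot(inherits(hypothesis, "phylo_hypothesis"))
  treatment <- match.arg(treatment)
  assign <- hypothesis$assignments
  if (treatment == "homoplasy") {
    contested <- hypothesis$contested
    if (!length(contested)) {
      .stopf("homoplasy treatment requested but hypothesis '%s' has no contested characters with alternative assignments",
             hypothesis$hypothesis_id)
    }
    bad <- names(contested)[is.na(contested) | !nzchar(contested)]
    if (length(bad)) {
      .stopf("contested character(s) lacking an alternative assignment: %s",
             paste(bad, collapse = ", "))
    }
    assign[names(contested)] <- unname(contested)
  }
  depth <- hypothesis$path$depth[match(unname(assign), hypothesis$path$node)]
  out <- data.frame(character_id = names(assign),
                    node = unname(assign),
                    depth = depth,
                    syn_rank = rank(depth, ties.method = "average"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$character_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "hypothesis_id") <- hypothesis$hypothesis_id
  attr(out, "treatment") <- treatment
  attr(out, "path") <- hypothesis$path
  class(out) <- c("synapomorphic_ranking", "data.frame")
  out
}

#' Remove phylogenetically uninformative characters
#'
#' Characters assigned to the least-inclusive on-path node (depth 1:
#' apomorphies of the focal clade itself) and to the most-inclusive,
#' root-adjacent node tell nothing about where a fossil falls *within* the
#' group of interest; their inclusion can bias the slippage test. This
#' removes both extremes, keeps every character at an intermediate depth,
#' and re-ranks both the synapomorphic and the decay ranks over the
#' survivors.
#'
#' @param ranking a [synapomorphic_ranks()] data.frame.
#' @param decay_ranks a [decay_rank_table()].
#' @return list with elements `ranking` and `decay_ranks`, both restricted
#'   to informative characters shared by the two tables and re-ranked.
#' @export
filter_informative <- function(ranking, decay_ranks) {
  path <- attr(ranking, "path")
  if (is.null(path)) .stopf("ranking lacks its path attribute")
  max_depth <- max(path$depth)
  keep <- ranking$depth > 1 & ranking$depth < max_depth
  ranking2 <- ranking[keep, , drop = FALSE]
  shared <- intersect(ranking2$character_id, decay_ranks$character_id)
  if (length(shared) < 3L) {
    .stopf("fewer than 3 informative characters remain after filtering (%d)",
           length(shared))
  }
  ranking2 <- ranking2[ranking2$character_id %in% shared, , drop = FALSE]
  ranking2$syn_rank <- rank(ranking2$depth, ties.method = "average")
  dr <- decay_ranks[decay_ranks$character_id %in% shared, , drop = FALSE]
  dr$decay_rank <- rank(dr$decay_rank, ties.method = "average")
  rownames(ranking2) <- rownames(dr) <- NULL
  for (a in c("hypothesis_id", "treatment", "path")) {
    attr(ranking2, a) <- attr(ranking, a)
  }
  list(ranking = ranking2, decay_ranks = dr)
}

#' Spearman rank correlation with permutation p-values
#'
#' Computes the Spearman coefficient as the Pearson correlation of
#' midranked vectors (ties allowed) and a two-sided p-value for the null of
#' no association, by one of: full enumeration of all `n!` permutations
#' (`"exact"`), seeded Monte Carlo permutation (`"monte_carlo"`), or the
#' t approximation `t = r_s * sqrt((n - 2) / (1 - r_s^2))` on `n - 2`
#' degrees of freedom (`"t_approx"`). The default `"auto"` uses exact
#' enumeration for `n <= 8` and the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length `n >= 3`; midranks are
#'   applied internally, so raw values or ranks may be supplied.
#' @param p_method `"auto"`, `"exact"`, `"monte_carlo"` or `"t_approx"`.
#' @param n_perm Monte Carlo permutation count (default 100000).
#' @param seed optional integer seed for the Monte Carlo draw (local RNG
#'   state; the caller's RNG is untouched).
#' @return list with `r_s`, `p_value`, `p_method`, `n`.
#' @export
spearman_test <- function(x, y,
                          p_method = c("auto", "exact", "monte_carlo",
                                       "t_approx"),
                          n_perm = 1e5, seed = NULL) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) .stopf("x and y must have equal length")
  if (n < 3L) .stopf("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) .stopf("missing values not allowed")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    .stopf("constant ranks: correlation undefined")
  }
  r_obs <- stats::cor(rx, ry)
  if (p_method == "auto") p_method <- if (n <= 8L) "exact" else "t_approx"
  eps <- 1e-12
  p <- switch(p_method,
    exact = {
      perms <- .all_perms(n)
      r_all <- .perm_corrs(rx, ry, perms)
      mean(abs(r_all) >= abs(r_obs) - eps)
    },
    monte_carlo = {
      draw <- function() {
        idx <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
        r_all <- .perm_corrs(rx, ry, t(idx))
        (1 + sum(abs(r_all) >= abs(r_obs) - eps)) / (n_perm + 1)
      }
      if (!is.null(seed)) {
        withr_seed <- function(code) {
          old <- if (exists(".Random.seed", globalenv())) {
            get(".Random.seed", globalenv())
          } else NULL
          on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
                  else rm(".Random.seed", envir = globalenv()))
          set.seed(seed)
          code()
        }
        withr_seed(draw)
      } else draw()
    },
    t_approx = {
      if (abs(r_obs) >= 1 - eps) {
        0
      } else {
        tval <- r_obs * sqrt((n - 2) / (1 - r_obs^2))
        min(1, 2 * stats::pt(-abs(tval), df = n - 2))
      }
    })
  list(r_s = r_obs, p_value = p, p_method = p_method, n = n)
}

# All permutations of 1..n as an (n! x n) integer matrix.
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, m * n, n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * m + 1L):(k * m)
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], m, n - 1L)
  }
  out
}

# Pearson correlations of rx with ry permuted row-wise by `perms`.
.perm_corrs <- function(rx, ry, perms) {
  n <- length(rx)
  rxs <- (rx - mean(rx)) / stats::sd(rx)
  rys <- (ry - mean(ry)) / stats::sd(ry)
  as.vector(matrix(rys[t(perms)], ncol = n, byrow = TRUE) %*% rxs) / (n - 1)
}

#' Run the stemward-slippage correlation test battery
#'
#' For each phylogenetic hypothesis, correlates the decay ranks with the
#' synapomorphic ranks under the homology treatment and — when the
#' hypothesis has contested characters — the homoplasy treatment, yielding
#' one Spearman test per hypothesis x treatment (e.g. 4 hypotheses with
#' contested characters give 8 tests). With `filtered = TRUE`,
#' [filter_informative()] is applied before each test. Under the default
#' rank directions (decay rank 1 = most decay-prone, synapomorphic rank 1 =
#' most apomorphic), preferential decay of symplesiomorphies shows up as a
#' negative correlation.
#'
#' @param decay_ranks a [decay_rank_table()].
#' @param hypotheses list of [phylo_hypothesis()] objects.
#' @param filtered remove uninformative (extreme-depth) characters first?
#' @param p_method,n_perm,seed passed to [spearman_test()].
#' @param holm also report Holm-adjusted p-values across the battery?
#'   Off by default (raw p-values are reported either way).
#' @return data.frame, one row per test: `hypothesis_id`, `treatment`,
#'   `filtered`, `n_characters`, `r_s`, `p_value`, `p_method` (and
#'   `p_holm` if requested); class `"slippage_battery"`.
#' @export
run_test_battery <- function(decay_ranks, hypotheses, filtered = FALSE,
                             p_method = "auto", n_perm = 1e5, seed = NULL,
                             holm = FALSE) {
  if (inherits(hypotheses, "phylo_hypothesis")) hypotheses <- list(hypotheses)
  if (!length(hypotheses)) .stopf("need at least one hypothesis")
  rows <- list()
  for (hyp in hypotheses) {
    treatments <- c("homology", if (length(hyp$contested)) "homoplasy")
    for (tr in treatments) {
      ranking <- synapomorphic_ranks(hyp, tr)
      if (filtered) {
        flt <- filter_informative(ranking, decay_ranks)
        ranking <- flt$ranking
        dr <- flt$decay_ranks
      } else {
        dr <- decay_ranks
      }
      m <- merge(ranking[, c("character_id", "syn_rank")],
                 dr[, c("character_id", "decay_rank")],
                 by = "character_id")
      if (nrow(m) < 3L) {
        .stopf("hypothesis '%s': fewer than 3 shared characters",
               hyp$hypothesis_id)
      }
      m <- m[order(m$character_id), , drop = FALSE]
      st <- spearman_test(m$decay_rank, m$syn_rank, p_method = p_method,
                          n_perm = n_perm, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        hypothesis_id = hyp$hypothesis_id, treatment = tr,
        filtered = filtered, n_characters = st$n, r_s = st$r_s,
        p_value = st$p_value, p_method = st$p_method,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$hypothesis_id, out$treatment), , drop = FALSE]
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  rownames(out) <- NULL
  class(out) <- c("slippage_battery", "data.frame")
  out
}

#' Compare decay ranks between two taxa
#'
#' Restricts two decay-rank tables to their shared character set, re-ranks
#' within the intersection, and runs [spearman_test()]. Used to ask whether
#' the *sequence* of character decay is conserved across taxa even when the
#' overall rate differs.
#'
#' @param ranks_a,ranks_b [decay_rank_table()] objects.
#' @param ... passed to [spearman_test()].
#' @return list `n_characters`, `r_s`, `p_value`, `p_method`,
#'   `characters` (the shared ids).
#' @export
compare_taxa_ranks <- function(ranks_a, ranks_b, ...) {
  shared <- intersect(ranks_a$character_id, ranks_b$character_id)
  if (!length(shared)) .stopf("the two rank tables share no characters")
  if (length(shared) < 3L) {
    .stopf("only %d shared characters; need at least 3", length(shared))
  }
  a <- ranks_a$decay_rank[match(shared, ranks_a$character_id)]
  b <- ranks_b$decay_rank[match(shared, ranks_b$character_id)]
  st <- spearman_test(rank(a, ties.method = "average"),
                      rank(b, ties.method = "average"), ...)
  list(n_characters = st$n, r_s = st$r_s, p_value = st$p_value,
       p_method = st$p_method, characters = shared)
}
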
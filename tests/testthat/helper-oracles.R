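# Independent oracles and fixture builders, kept deliberately separate from
# the package's code paths.

# Midranks computed from first principles: rank of x_i = (# strictly below)
# + (ties including self + 1) / 2.
oracle_midrank <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

# Pearson correlation from the definitional sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_midrank(x), oracle_midrank(y))
}

# All permutations of 1..n by insertion (different construction from the
# package's internal enumerator).
oracle_perms <- function(n) {
  acc <- list(1L)
  for (k in 2:n) {
    acc <- unlist(lapply(acc, function(p) {
      lapply(0:(k - 1L), function(pos) append(p, k, after = pos))
    }), recursive = FALSE)
  }
  do.call(rbind, acc)
}

# Exhaustive two-sided permutation p-value for Spearman's r_s.
oracle_exact_p <- function(x, y) {
  P <- oracle_perms(length(x))
  r_obs <- oracle_spearman(x, y)
  r_all <- apply(P, 1L, function(p) oracle_spearman(x, y[p]))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Tiny fixed score-matrix fixture: 2 characters, 2 specimens per day.
toy_characters <- function() {
  character_table(data.frame(
    character_id = c("gut", "cuticle", "claws"),
    body_region = c("internal", "trunk", "limbs"),
    immune = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

toy_scores <- function() {
  chars <- toy_characters()
  days <- c(1, 1, 4, 4, 16, 16)
  specs <- paste0("sp", seq_along(days))
  rec <- expand.grid(specimen_id = specs,
                     character_id = chars$character_id,
                     stringsAsFactors = FALSE)
  rec$day <- days[match(rec$specimen_id, specs)]
  # gut: decays then is lost; cuticle decays late; claws always pristine
  cond <- function(ch, d, sp) {
    if (ch == "claws") return(0L)
    if (ch == "gut") return(if (d >= 16) 2L else if (d >= 4) 2L - (sp == "sp3") else 1L)
    if (d >= 16) 1L else 0L
  }
  rec$condition <- mapply(cond, rec$character_id, rec$day, rec$specimen_id)
  decay_scores(rec, chars)
}

# Ladder hypothesis over 4 on-path nodes with one character per depth.
ladder_hypothesis <- function(assignments = NULL, contested = NULL,
                              id = "toy") {
  tree <- ape::read.tree(text = "((((Focal,A)n1,B)n2,C)n3,D)n4;")
  assignments <- assignments %||% c(w = "n1", x = "n2", y = "n3", z = "n4")
  phylo_hypothesis(tree, "Focal", assignments, contested, hypothesis_id = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

# Milestone table built directly from a matrix of (t_cl, t_ol, t_cd, t_od).
make_milestones <- function(ids, t_od, t_cd, t_ol, t_cl) {
  data.frame(character_id = ids,
             t_onset_decay = t_od, t_complete_decay = t_cd,
             t_onset_loss = t_ol, t_complete_loss = t_cl,
             stringsAsFactors = FALSE)
}
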
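# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (loops over pairs, grid search,
# exhaustive enumeration) rather than calling the implementation under test.

# Weighted-mean pathway score straight from the printed definition:
# sum of role * log10(ratio) over measured non-zero-role members, divided by
# the sum of absolute roles.
oracle_pal <- function(cnr_values, arr) {
  num <- 0; den <- 0
  for (g in names(arr)) {
    if (arr[[g]] == 0) next
    if (!g %in% names(cnr_values)) next
    num <- num + arr[[g]] * log10(cnr_values[[g]])
    den <- den + abs(arr[[g]])
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Pairwise AUC: count responder/non-responder pairs, ties credited one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Cox partial log-likelihood for a single binary covariate without ties,
# maximized by grid search.
oracle_cox_coef <- function(time, event, x, grid = seq(-5, 5, by = 1e-4)) {
  stopifnot(!anyDuplicated(time[event == 1]))
  loglik <- function(beta) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  grid[which.max(vapply(grid, loglik, numeric(1)))]
}

# Exact distribution of the k-way overlap when drawing fixed-size subsets
# uniformly from small universes: full enumeration over all combinations.
oracle_overlap_p <- function(sizes, universes, observed) {
  choices <- lapply(seq_along(universes), function(i)
    utils::combn(universes[[i]], sizes[i], simplify = FALSE))
  idx <- expand.grid(lapply(choices, seq_along))
  hits <- 0L
  for (r in seq_len(nrow(idx))) {
    sets <- lapply(seq_along(choices), function(i) choices[[i]][[idx[r, i]]])
    if (length(Reduce(intersect, sets)) >= observed) hits <- hits + 1L
  }
  hits / nrow(idx)
}

# Small builders ------------------------------------------------------------

make_profile <- function(id, ..., role = NA_character_, qc = NULL) {
  expression_profile(id, c(...), role = role, qc = qc)
}

random_pathway <- function(id, genes, n_members) {
  members <- sample(genes, n_members)
  pathway(id, stats::setNames(
    sample(c(-1, -0.5, 0, 0.5, 1), n_members, replace = TRUE), members))
}

write_star_fixture <- function(path, genes, counts, n_unmapped = 1000,
                               n_multi = 500, n_nofeat = 200, n_ambig = 100) {
  lines <- c(sprintf("N_unmapped\t%d\t%d\t%d", n_unmapped, n_unmapped, n_unmapped),
             sprintf("N_multimapping\t%d\t%d\t%d", n_multi, n_multi, n_multi),
             sprintf("N_noFeature\t%d\t%d\t%d", n_nofeat, n_nofeat, n_nofeat),
             sprintf("N_ambiguous\t%d\t%d\t%d", n_ambig, n_ambig, n_ambig),
             sprintf("%s\t%d\t%d\t%d", genes, counts, counts * 2L, counts * 3L))
  writeLines(lines, path)
  path
}
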
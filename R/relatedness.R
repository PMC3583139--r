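# Fitch's relatedness test for two ancestral set-sequences. A site pair is
# an unavoidable mutation when its two nucleotide sets are disjoint. The
# observed mutation distance O counts such sites; the null re-pairs sites at
# random, giving expectation E = L * p_disjoint over all L^2 ordered cross
# pairs and binomial spread S = sqrt(E * (1 - p_disjoint)). Relatedness shows
# up as O below E; z = (E - O)/S is referred to the upper normal tail.

# 15x15 lookup: disjoint[i, j] is TRUE when bitmasks i and j share no base
.DISJOINT <- outer(1:15, 1:15, bitwAnd) == 0L

.check_comparable <- function(a, b) {
  stopifnot(inherits(a, "ancestral_state"), inherits(b, "ancestral_state"))
  if (length(a$sites) != length(b$sites) || !identical(a$mask, b$mask))
    stop("states have different site counts or masks", call. = FALSE)
}

#' Observed mutation distance between two ancestral states
#'
#' Counts masked positions at which the two nucleotide sets are disjoint,
#' i.e. where a substitution is unavoidable under any resolution of the
#' ambiguity sets.
#'
#' @param a,b `ancestral_state` objects with equal site counts and
#'   identical masks.
#' @return Integer count in `[0, L]` where `L` is the mask size.
#' @export
observed_distance <- function(a, b) {
  .check_comparable(a, b)
  sum(bitwAnd(a$sites[a$mask], b$sites[b$mask]) == 0L)
}

#' Null probability that randomly paired sites are disjoint
#'
#' Fraction of all `L^2` ordered cross pairs (site of `a`, site of `b`)
#' over the mask whose nucleotide sets are disjoint. This is exactly the
#' mean of [observed_distance()]`/L` under uniform column permutation of
#' `b`.
#'
#' @inheritParams observed_distance
#' @return Probability in `[0, 1]`.
#' @export
null_disjoint_probability <- function(a, b) {
  .check_comparable(a, b)
  ta <- tabulate(a$sites[a$mask], nbins = 15L)
  tb <- tabulate(b$sites[b$mask], nbins = 15L)
  L <- length(a$mask)
  as.numeric(ta %*% .DISJOINT %*% tb) / (L * L)
}

#' One-tailed normal probability for an observed-vs-expected distance
#'
#' The building block of the relatedness test, exposed for recomputing
#' published tables: `z = (expected - observed)/sd` referred to the upper
#' standard normal tail. Vectorised.
#'
#' @param observed,expected Observed and expected mutation distances.
#' @param sd Standard deviation of the null distance.
#' @return Upper-tail probability `P(Z > z)`.
#' @export
relatedness_probability <- function(observed, expected, sd) {
  stats::pnorm((expected - observed) / sd, lower.tail = FALSE)
}

#' Binomial standard deviation of the null mutation distance
#'
#' `sqrt(E * (1 - E/L))`: the spread implied by an expected distance `E`
#' over `L` independently re-paired sites. Vectorised.
#'
#' @param expected Expected mutation distance E.
#' @param n_sites Number of compared sites L.
#' @return Standard deviation.
#' @export
null_sd <- function(expected, n_sites) {
  sqrt(expected * (1 - expected / n_sites))
}

#' Test two ancestral states for relatedness
#'
#' Computes the observed mutation distance O, the random-pairing null
#' expectation `E = L * p_disjoint` and spread `S = sqrt(E(1 - p_disjoint))`,
#' and the one-tailed probability that a distance as small as O arises by
#' chance: `p = P(Z > (E - O)/S)`. Small p means the two set-sequences are
#' more compatible than random pairing allows -- evidence of common
#' ancestry.
#'
#' @param a,b `ancestral_state` objects (see [fitch_downpass()],
#'   [as_ancestral_state()]) with equal site counts and identical masks.
#' @param alpha Significance level used for the `significant` flag.
#' @return Object of classes `relatedness` and `htest` with components
#'   `statistic` (z), `p.value`, `estimate` (O, E, S), `parameter` (L),
#'   and fields `observed`, `expected`, `sd`, `p_disjoint`, `L`, `alpha`,
#'   `significant`.
#' @export
relatedness_test <- function(a, b, alpha = 0.05) {
  .check_comparable(a, b)
  L <- length(a$mask)
  if (L < 2L) stop("need at least 2 masked sites", call. = FALSE)
  O <- observed_distance(a, b)
  p_dis <- null_disjoint_probability(a, b)
  if (p_dis <= 0 || p_dis >= 1)
    stop("degenerate null: disjoint probability is ", p_dis, call. = FALSE)
  E <- L * p_dis
  S <- sqrt(E * (1 - p_dis))
  z <- (E - O) / S
  p <- stats::pnorm(z, lower.tail = FALSE)
  structure(list(
    statistic = c(z = z), p.value = p,
    parameter = c(L = L),
    estimate = c("observed distance" = O, "expected distance" = E,
                 "null sd" = S),
    method = "Fitch relatedness test of ancestral states (one-tailed)",
    data.name = sprintf("%s vs %s",
                        ifelse(is.na(a$node), "a", a$node),
                        ifelse(is.na(b$node), "b", b$node)),
    observed = O, expected = E, sd = S, p_disjoint = p_dis,
    L = L, alpha = alpha, significant = p < alpha
  ), class = c("relatedness", "htest"))
}

#' @export
print.relatedness <- function(x, digits = 4, ...) {
  cat("\n\t", x$method, "\n\n", sep = "")
  cat("states: ", x$data.name, "\n", sep = "")
  cat(sprintf("L = %d masked sites, O = %d, E = %.1f (+/- %.1f)\n",
              x$L, x$observed, x$expected, x$sd))
  cat(sprintf("z = %.4g, one-tailed p = %.4g %s\n",
              unname(x$statistic), x$p.value,
              if (x$significant) sprintf("(< alpha = %g)", x$alpha) else ""))
  invisible(x)
}

#' Select rows whose significant-hit counts exceed an empirical quantile
#'
#' Given per-row counts of significant tests, computes the empirical
#' `q`-quantile with linear interpolation (R's default, type 7) and
#' returns the rows whose count strictly exceeds it.
#'
#' @param counts Named integer vector of per-row significant counts.
#' @param q Quantile level (default 0.95).
#' @return Character vector of selected row names, with attribute
#'   `threshold` carrying the quantile value.
#' @export
screen_by_quantile <- function(counts, q = 0.95) {
  if (length(counts) == 0L) stop("empty count vector", call. = FALSE)
  thr <- unname(stats::quantile(counts, probs = q, type = 7))
  sel <- names(counts)[counts > thr]
  if (is.null(sel)) sel <- which(counts > thr)
  structure(sel, threshold = thr)
}

#' Screen query sequences against a panel of reference ancestral states
#'
#' Runs [relatedness_test()] for every (query, reference) pair, counts per
#' query how many references it is significantly related to, and flags the
#' queries whose count exceeds the empirical `q`-quantile of all counts --
#' the rule used to locate the subtree most likely to retain deep-homology
#' signal.
#'
#' @param queries Named list of `ancestral_state`, or a named character
#'   vector of extant nucleotide sequences (converted to singleton-set
#'   states with the same codon-position mask as the references).
#' @param references Named list of `ancestral_state`.
#' @param alpha Per-test significance level.
#' @param q Quantile level for the selection rule.
#' @return Object of class `relatedness_screen`: list with `p` (matrix of
#'   p-values, queries x references), `counts`, `threshold`, `selected`,
#'   `alpha`, `q`.
#' @export
relatedness_screen <- function(queries, references, alpha = 0.05, q = 0.95) {
  if (is.character(queries)) {
    ref_mask <- references[[1]]$mask
    queries <- lapply(seq_along(queries), function(i)
      as_ancestral_state(queries[[i]], mask = ref_mask,
                         node = names(queries)[i]))
    names(queries) <- vapply(queries, `[[`, character(1), "node")
  }
  if (is.null(names(queries)) || is.null(names(references)))
    stop("queries and references must be named", call. = FALSE)
  p <- matrix(NA_real_, nrow = length(queries), ncol = length(references),
              dimnames = list(names(queries), names(references)))
  for (i in names(queries))
    for (j in names(references))
      p[i, j] <- relatedness_test(queries[[i]], references[[j]],
                                  alpha = alpha)$p.value
  counts <- rowSums(p < alpha)
  sel <- screen_by_quantile(counts, q)
  structure(list(p = p, counts = counts,
                 threshold = attr(sel, "threshold"),
                 selected = as.character(sel), alpha = alpha, q = q),
            class = "relatedness_screen")
}

#' @export
print.relatedness_screen <- function(x, ...) {
  cat(sprintf(
    "Relatedness screen: %d queries x %d references, alpha = %g\n",
    nrow(x$p), ncol(x$p), x$alpha))
  cat(sprintf("%g-quantile of significant counts = %.4g\n", x$q, x$threshold))
  if (length(x$selected))
    cat("selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  else cat("selected: none\n")
  invisible(x)
}
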
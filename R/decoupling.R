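# Spearman rank correlation without the cor.test machinery; average ranks
# for ties, NA-free inputs assumed.
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Does the ancestral state predict the contemporary response?
#'
#' Spearman rank correlation between the ancestral state probabilities at
#' a population's parent node and its relative responses, over the tested
#' note variants. A score of 1 means the ranking of ancestral support
#' (e.g. four > three > two notes) exactly matches the ranking of
#' present-day recognition; -1 the reverse. States never tested in
#' playback are dropped and the ancestral vector renormalized over the
#' tested variants. A constant vector (e.g. a uniform ancestral
#' distribution) makes the rank correlation undefined: the score is 0
#' with `degenerate = TRUE`.
#'
#' @param ancestral named probability vector over states at the
#'   population's ancestor node (names = note counts, e.g.
#'   `c("2" = .1, "3" = .2, "4" = .7)`), or an unnamed vector over
#'   `1..S`.
#' @param rel_table a `"relative_response"` table for the population.
#' @return list with `score` in `[-1, 1]`, `degenerate` flag, and the
#'   aligned `ancestral` / `relative` vectors used.
#' @export
ancestor_prediction_score <- function(ancestral, rel_table) {
  notes <- rel_table$note
  if (is.null(names(ancestral))) names(ancestral) <- seq_along(ancestral)
  if (!all(as.character(notes) %in% names(ancestral)))
    stop("ancestral vector lacks tested variant(s): ",
         paste(setdiff(as.character(notes), names(ancestral)), collapse = ", "))
  a <- ancestral[as.character(notes)]
  if (sum(a) <= 0) {
    return(list(score = 0, degenerate = TRUE, ancestral = a,
                relative = rel_table$relative))
  }
  a <- a / sum(a)
  rho <- spearman_rho(a, rel_table$relative)
  if (is.na(rho))
    return(list(score = 0, degenerate = TRUE, ancestral = a,
                relative = rel_table$relative))
  list(score = rho, degenerate = FALSE, ancestral = a,
       relative = rel_table$relative)
}

#' Coupled/decoupled verdict across populations
#'
#' Senders and receivers are coupled only under the matched-spaces
#' scenario in every population; any population that still recognizes
#' non-own variants implies the signal and its recognition evolve at
#' different rates. The verdict is therefore `"coupled"` iff every
#' population is classified `"matched"`, and `"decoupled"` otherwise.
#' The mean ancestor-prediction score is accompanied by a permutation
#' p-value (relative responses permuted across variants within each
#' population) because the number of populations is small.
#'
#' @param scenarios list of `"scenario_call"` objects.
#' @param scores list of scores from [ancestor_prediction_score()]
#'   (may be `NULL` to skip the permutation test).
#' @param rel_tables list of `"relative_response"` tables matching
#'   `scores` (needed for the permutation null).
#' @param ancestral list of ancestral vectors matching `scores`.
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutation test.
#' @return an object of class `"decoupling_report"`: list with `verdict`,
#'   `scenarios`, `mean_score`, `perm_p`, `n_populations`, `note` (set
#'   when inference is limited, e.g. a single population).
#' @export
decoupling_verdict <- function(scenarios, scores = NULL, rel_tables = NULL,
                               ancestral = NULL, n_perm = 10000L,
                               seed = 1L) {
  if (!length(scenarios)) stop("need at least one population")
  labs <- vapply(scenarios, function(s) s$scenario, "")
  verdict <- if (all(labs == "matched")) "coupled" else "decoupled"
  mean_score <- NA_real_
  perm_p <- NA_real_
  if (!is.null(scores)) {
    sc <- vapply(scores, function(s) s$score, 0)
    mean_score <- mean(sc)
    if (!is.null(rel_tables) && !is.null(ancestral) && n_perm > 0L) {
      set.seed(seed)
      perm_means <- vapply(seq_len(n_perm), function(b) {
        mean(vapply(seq_along(rel_tables), function(i) {
          rt <- rel_tables[[i]]
          rt$relative <- sample(rt$relative)
          ancestor_prediction_score(ancestral[[i]], rt)$score
        }, 0))
      }, 0)
      perm_p <- (1 + sum(perm_means >= mean_score)) / (n_perm + 1)
    }
  }
  out <- list(verdict = verdict,
              scenarios = scenarios,
              scenario_labels = setNames(labs, vapply(
                scenarios, function(s) as.character(s$population %||% ""), "")),
              mean_score = mean_score,
              perm_p = perm_p,
              n_populations = length(scenarios),
              note = if (length(scenarios) == 1L)
                "single population: verdict has no replication" else NULL)
  class(out) <- "decoupling_report"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.decoupling_report <- function(x, ...) {
  cat("Sender-receiver evolution verdict:", toupper(x$verdict), "\n")
  cat("Populations (", x$n_populations, "):\n", sep = "")
  for (s in x$scenarios) {
    cat("  "); print(s)
  }
  if (!is.na(x$mean_score))
    cat(sprintf("Mean ancestor-prediction score: %.3f (permutation p = %.4g)\n",
                x$mean_score, x$perm_p))
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}
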
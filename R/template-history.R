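# Best-template identification against a dated candidate pool and
# era-comparison statistics on improvement over template.

#' Identify the best template for a target
#'
#' Candidates released on or after the target deadline are excluded; the
#' remainder are scored by the sequence-independent structural alignment
#' score ([tm_align()], normalised by the target length) and the best is
#' returned, ties broken by candidate id.
#'
#' @param target an `na_structure`.
#' @param pool list of candidates, each a list with `structure`
#'   (`na_structure`), `id` and `release_date` (`Date` or ISO string).
#' @param deadline target deadline (`Date` or ISO string).
#' @return list of class `template_hit` with `id`, `release_date`,
#'   `tm_align_score`, or `NULL` when no candidate predates the deadline.
#' @export
best_template <- function(target, pool, deadline) {
  deadline <- as.Date(deadline)
  dates <- as.Date(vapply(pool, function(p) as.character(p$release_date),
                          character(1)))
  keep <- which(dates < deadline)
  if (!length(keep)) return(NULL)
  ids <- vapply(pool[keep], `[[`, character(1), "id")
  scores <- vapply(pool[keep], function(p)
    tm_align(p$structure, target)$score, numeric(1))
  o <- order(-scores, ids)
  structure(list(id = ids[o[1]], release_date = dates[keep][o[1]],
                 tm_align_score = scores[o[1]]), class = "template_hit")
}

#' Welch t-test p-value from summary statistics
#'
#' @param mean_a,mean_b group means.
#' @param sem_a,sem_b standard errors of the means.
#' @param n_a,n_b sample sizes.
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return two-sided p-value.
#' @export
welch_summary_p <- function(mean_a, sem_a, n_a, mean_b, sem_b, n_b,
                            pooled = FALSE) {
  if (sem_a == 0 && sem_b == 0)
    return(if (mean_a == mean_b) 1 else 0)
  if (pooled) {
    sp2 <- ((n_a - 1) * sem_a^2 * n_a + (n_b - 1) * sem_b^2 * n_b) /
      (n_a + n_b - 2)
    tstat <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se2 <- sem_a^2 + sem_b^2
    tstat <- (mean_a - mean_b) / sqrt(se2)
    df <- se2^2 / (sem_a^4 / (n_a - 1) + sem_b^4 / (n_b - 1))
  }
  2 * stats::pt(-abs(tstat), df)
}

#' Era-comparison statistics on improvement over template
#'
#' Compares the per-target improvement (best predicted minus best template
#' alignment score) between two record subsets with means, standard errors
#' and a two-sample t-test (Welch by default).
#'
#' @param records data.frame with columns `delta`, `era` and
#'   `predictor_class` (plus anything else, ignored).
#' @param group_a,group_b lists with optional elements `era` and `class`
#'   used to filter records for each side.
#' @param pooled use the pooled-variance test.
#' @return list with `mean_a`, `sem_a`, `n_a`, `mean_b`, `sem_b`, `n_b`
#'   and `p`.
#' @export
improvement_stats <- function(records, group_a, group_b, pooled = FALSE) {
  pick <- function(g) {
    sel <- rep(TRUE, nrow(records))
    if (!is.null(g$era)) sel <- sel & records$era == g$era
    if (!is.null(g$class)) sel <- sel & records$predictor_class == g$class
    records$delta[sel]
  }
  a <- pick(group_a); b <- pick(group_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 records per side")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) 1 else 0
  } else {
    stats::t.test(a, b, var.equal = pooled)$p.value
  }
  list(mean_a = mean(a), sem_a = sem(a), n_a = length(a),
       mean_b = mean(b), sem_b = sem(b), n_b = length(b), p = p)
}
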
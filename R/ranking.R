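# Best-of-model reduction, outlier-trimmed Z-scores, weighted category
# combination, floor-at-zero summed ranking with participation filtering,
# and bootstrap confidence intervals.

#' Ranking configuration
#'
#' Category weights follow the assessment formulas: nucleic-acid monomers
#' blend 0.3 TM + 0.3 GDT_TS + 0.4 lDDT; multimer and hybrid categories
#' weight that monomer blend by 0.3 and the interface metrics (ICS, IPS,
#' i-lDDT, one third each) by 0.7; the ligand category is 0.5 i-lDDT +
#' 0.5 lDDT-pocket.
#'
#' @param outlier_sd low-side outlier threshold in standard deviations.
#' @param participation_min minimum fraction of category targets a group
#'   must have submitted to be ranked.
#' @param floor_at_zero floor negative per-target Z at 0 before summing.
#' @param bootstrap_B bootstrap replicates.
#' @param level central confidence level in percent.
#' @param seed seed for the bootstrap (mandatory for reproducibility).
#' @export
ranking_config <- function(outlier_sd = 2, participation_min = 0.6,
                           floor_at_zero = TRUE, bootstrap_B = 1000,
                           level = 68.2, seed = 1) {
  blend <- c(tm = 0.3, gdt_ts = 0.3, lddt = 0.4)
  list(outlier_sd = outlier_sd, participation_min = participation_min,
       floor_at_zero = floor_at_zero, bootstrap_B = bootstrap_B,
       level = level, seed = seed,
       weights = list(
         monomer = blend,
         multimer = c(0.3 * blend, ics = 0.7 / 3, ips = 0.7 / 3,
                      i_lddt = 0.7 / 3),
         hybrid = c(0.3 * blend, ics = 0.7 / 3, ips = 0.7 / 3,
                    i_lddt = 0.7 / 3),
         ligand = c(i_lddt = 0.5, lddt_pocket = 0.5)))
}

#' Default known exclusions shipped with the package
#'
#' @return data.frame with `group` and `target` rows excluded from
#'   ranking by default (overridable).
#' @export
default_exclusions <- function() {
  path <- system.file("extdata", "default_exclusions.txt", package = "nascore")
  if (path == "") return(data.frame(group = character(0), target = character(0)))
  utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Reduce per-model scores to the best per metric
#'
#' The best score per (group, target, metric) is taken over all submitted
#' models and all references, decoupled across metrics.
#'
#' @param score_table data.frame with columns `group`, `target`, `model`,
#'   `metric`, `value` (and optionally `reference`).
#' @return data.frame with one row per (group, target, metric) and column
#'   `best`.
#' @export
reduce_best <- function(score_table) {
  st <- score_table[!is.na(score_table$value), , drop = FALSE]
  if (!nrow(st)) stop("no model scores to reduce")
  agg <- stats::aggregate(value ~ group + target + metric, data = st, FUN = max)
  names(agg)[names(agg) == "value"] <- "best"
  agg
}

#' Outlier-trimmed Z-scores for one target-metric
#'
#' Scores two or more standard deviations below the initial mean are
#' treated as outliers; the mean and (sample) standard deviation are
#' recomputed once without them, and every group (outliers included) is
#' Z-scored against the trimmed statistics. A zero trimmed SD yields all
#' zeros.
#'
#' @param values named numeric vector of per-group scores.
#' @param outlier_sd trimming threshold (default 2).
#' @return named numeric vector of Z-scores.
#' @export
trimmed_z <- function(values, outlier_sd = 2) {
  z <- stats::setNames(rep(0, length(values)), names(values))
  if (length(values) < 2) return(z)
  m0 <- mean(values); s0 <- stats::sd(values)
  keep <- if (is.na(s0) || s0 == 0) rep(TRUE, length(values))
          else values > m0 - outlier_sd * s0
  m1 <- mean(values[keep]); s1 <- stats::sd(values[keep])
  if (is.na(s1) || s1 == 0) return(z)
  stats::setNames((values - m1) / s1, names(values))
}

#' Weighted category combination of component Z-scores
#'
#' @param zrow named numeric vector of component Z-scores for one group
#'   and target (`NA` components are omitted and the remaining weights
#'   renormalised, flagged in attribute `"renormalized"`).
#' @param category one of `"monomer"`, `"multimer"`, `"hybrid"`,
#'   `"ligand"`.
#' @param config a [ranking_config()].
#' @return combined Z.
#' @export
category_z <- function(zrow, category, config = ranking_config()) {
  w <- config$weights[[category]]
  if (is.null(w)) stop("unknown category: ", category)
  have <- names(w)[names(w) %in% names(zrow) & !is.na(zrow[names(w)])]
  if (!length(have)) return(NA_real_)
  renorm <- length(have) < length(w)
  wt <- w[have] / sum(w[have])
  out <- sum(wt * zrow[have])
  if (renorm) attr(out, "renormalized") <- TRUE
  out
}

#' Summed ranking with same-sequence grouping and floor at zero
#'
#' Within each same-sequence grouping set only the best per-group Z
#' contributes; negative Z are floored at 0; groups participating in less
#' than the configured fraction of (grouped) targets are excluded.
#'
#' @param ztable data.frame with columns `group`, `target`, `z`.
#' @param grouping list of character vectors of target ids scored as one
#'   unit (targets not listed form their own unit).
#' @param config a [ranking_config()].
#' @return data.frame with `group`, `sum_z`, `n_units`, `participation`,
#'   ordered by decreasing `sum_z`; per-unit floored contributions in
#'   attribute `"contributions"` (groups x units matrix).
#' @export
sum_ranking <- function(ztable, grouping = list(), config = ranking_config()) {
  targets <- unique(ztable$target)
  unit_of <- stats::setNames(targets, targets)
  for (set in grouping) {
    set <- intersect(set, targets)
    if (length(set)) unit_of[set] <- set[1]
  }
  units <- unique(unit_of)
  groups <- unique(ztable$group)
  contrib <- matrix(NA_real_, length(groups), length(units),
                    dimnames = list(groups, units))
  for (gi in seq_along(groups)) {
    rows <- ztable[ztable$group == groups[gi], , drop = FALSE]
    for (ui in seq_along(units)) {
      members <- names(unit_of)[unit_of == units[ui]]
      v <- rows$z[rows$target %in% members]
      v <- v[!is.na(v)]
      if (length(v)) contrib[gi, ui] <- max(v)  # best score within the unit
    }
  }
  participation <- rowMeans(!is.na(contrib))
  floored <- contrib
  if (config$floor_at_zero) floored[!is.na(floored) & floored < 0] <- 0
  sums <- rowSums(floored, na.rm = TRUE)
  keep <- participation >= config$participation_min
  out <- data.frame(group = groups[keep], sum_z = sums[keep],
                    n_units = rowSums(!is.na(contrib))[keep],
                    participation = participation[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$sum_z, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributions") <- floored[keep, , drop = FALSE]
  out
}

#' Bootstrap confidence interval for a summed score
#'
#' Resamples per-target contributions with replacement and returns the
#' central percentile interval of the resampled sums.
#'
#' @param contributions numeric vector of per-target (per-unit)
#'   contributions; `NA` entries count as 0.
#' @param B replicates (default 1000).
#' @param level central level in percent (default 68.2).
#' @param seed RNG seed (mandatory).
#' @return numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(contributions, B = 1000, level = 68.2, seed) {
  if (missing(seed)) stop("bootstrap_ci requires an explicit seed")
  v <- ifelse(is.na(contributions), 0, contributions)
  k <- length(v)
  if (k < 2) return(c(lo = sum(v), hi = sum(v)))
  sums <- withr::with_seed(seed, {
    idx <- matrix(sample.int(k, k * B, replace = TRUE), nrow = B)
    rowSums(matrix(v[idx], nrow = B))
  })
  alpha <- (100 - level) / 200
  q <- stats::quantile(sums, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lo = q[1], hi = q[2])
}

#' Full Z-score ranking of a reduced score table
#'
#' Computes per target-metric trimmed Z over groups, combines components
#' with the category weights, applies grouping/floor/participation rules
#' and attaches bootstrap confidence intervals.
#'
#' @param best_table output of [reduce_best()].
#' @param target_category named character vector: category per target.
#' @param grouping same-sequence grouping sets (list of target-id vectors).
#' @param config a [ranking_config()].
#' @param exclusions data.frame with `group`, `target` rows dropped before
#'   ranking (default [default_exclusions()]).
#' @return data.frame of class `ranking_result` with `group`, `sum_z`,
#'   `ci_lo`, `ci_hi` plus participation bookkeeping.
#' @export
rank_groups <- function(best_table, target_category, grouping = list(),
                        config = ranking_config(),
                        exclusions = default_exclusions()) {
  bt <- best_table
  if (nrow(exclusions)) {
    drop <- paste(bt$group, bt$target) %in%
      paste(exclusions$group, exclusions$target)
    bt <- bt[!drop, , drop = FALSE]
  }
  cats <- unique(target_category)
  per_cat <- list()
  for (cat in cats) {
    tids <- names(target_category)[target_category == cat]
    sub <- bt[bt$target %in% tids, , drop = FALSE]
    if (!nrow(sub)) next
    # trimmed Z per (target, metric) across groups
    zrows <- list()
    for (tg in unique(sub$target)) {
      stg <- sub[sub$target == tg, , drop = FALSE]
      zcomp <- list()
      for (met in unique(stg$metric)) {
        v <- stats::setNames(stg$best[stg$metric == met],
                             stg$group[stg$metric == met])
        zcomp[[met]] <- trimmed_z(v, config$outlier_sd)
      }
      for (g in unique(stg$group)) {
        zrow <- vapply(zcomp, function(zc) unname(zc[g]), numeric(1))
        zrows[[length(zrows) + 1]] <- data.frame(
          group = g, target = tg,
          z = as.numeric(category_z(zrow, cat, config)),
          stringsAsFactors = FALSE)
      }
    }
    ztable <- do.call(rbind, zrows)
    rk <- sum_ranking(ztable, grouping, config)
    contrib <- attr(rk, "contributions")
    ci <- t(vapply(seq_len(nrow(rk)), function(i)
      bootstrap_ci(contrib[rk$group[i], ], B = config$bootstrap_B,
                   level = config$level,
                   seed = config$seed + i), numeric(2)))
    rk$ci_lo <- ci[, 1]; rk$ci_hi <- ci[, 2]
    rk$category <- cat
    per_cat[[cat]] <- rk
  }
  if (!length(per_cat)) stop("no targets to rank")
  all_groups <- unique(unlist(lapply(per_cat, `[[`, "group")))
  total <- data.frame(group = all_groups, sum_z = 0, ci_lo = 0, ci_hi = 0,
                      stringsAsFactors = FALSE)
  for (rk in per_cat) {
    idx <- match(rk$group, total$group)
    total$sum_z[idx] <- total$sum_z[idx] + rk$sum_z
    total$ci_lo[idx] <- total$ci_lo[idx] + rk$ci_lo
    total$ci_hi[idx] <- total$ci_hi[idx] + rk$ci_hi
  }
  total <- total[order(-total$sum_z, total$group), , drop = FALSE]
  rownames(total) <- NULL
  attr(total, "per_category") <- per_cat
  class(total) <- c("ranking_result", class(total))
  total
}
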
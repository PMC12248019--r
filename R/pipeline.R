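# End-to-end assessment orchestration: score every submitted model against
# every reference, reduce to per-group bests, rank with trimmed Z-scores
# and bootstrap intervals, and emit tidy reports.

#' Per-chain-pair interface records for a model against a reference
#'
#' @param model,reference `na_structure` objects.
#' @param corr a [residue_correspondence()] (computed if `NULL`).
#' @param threshold contact threshold in Angstrom.
#' @return data.frame with one row per reference chain pair in contact:
#'   `chain_a`, `chain_b`, `type`, `residue_count`, `ics`, `ips`,
#'   `i_lddt`.
#' @export
interface_records <- function(model, reference, corr = NULL, threshold = 5) {
  if (is.null(corr)) corr <- residue_correspondence(model, reference)
  ch <- structure_chains(reference)
  out <- list()
  for (ai in seq_len(nrow(ch))) for (bi in seq_len(ai - 1)) {
    ca <- ch$chain_id[ai]; cb <- ch$chain_id[bi]
    ref_pair <- tryCatch(subset_chains(reference, c(ca, cb)),
                         error = function(e) NULL)
    if (is.null(ref_pair)) next
    rc <- suppressWarnings(extract_contacts(ref_pair, threshold))
    if (!length(rc$contacts)) next
    # model chains mapped onto this reference chain pair
    mkeys <- corr$model_key[sub("\\|.*", "", corr$ref_key) %in% c(ca, cb)]
    mchains <- unique(sub("\\|.*", "", mkeys))
    mdl_pair <- tryCatch(subset_chains(model, mchains), error = function(e) NULL)
    pc_contacts <- character(0)
    if (!is.null(mdl_pair) && length(mchains) >= 2) {
      pc <- suppressWarnings(extract_contacts(mdl_pair, threshold))
      # express model contacts in reference residue coordinates
      map <- stats::setNames(corr$ref_key, corr$model_key)
      pc_contacts <- vapply(strsplit(pc$contacts, "--", fixed = TRUE),
                            function(p) {
                              rk <- map[p]
                              if (anyNA(rk)) return(NA_character_)
                              pair_id(rk[1], rk[2])
                            }, character(1))
      pc_contacts <- pc_contacts[!is.na(pc_contacts)]
    }
    sub_corr <- corr[sub("\\|.*", "", corr$ref_key) %in% c(ca, cb), ,
                     drop = FALSE]
    ild <- tryCatch(interface_lddt(model, reference, sub_corr),
                    error = function(e) NA_real_)
    out[[length(out) + 1]] <- data.frame(
      chain_a = ca, chain_b = cb,
      type = interface_type(ch$polymer_type[ai], ch$polymer_type[bi]),
      residue_count = length(rc$residues),
      ics = ics(pc_contacts, rc)$f1,
      ips = {
        pres <- unique(unlist(strsplit(pc_contacts, "--", fixed = TRUE)))
        jac <- if (!length(pres) && !length(rc$residues)) NA_real_ else
          length(intersect(pres, rc$residues)) /
            length(union(pres, rc$residues))
        jac
      },
      i_lddt = ild, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain_a = character(0), chain_b = character(0),
                      type = character(0), residue_count = integer(0),
                      ics = numeric(0), ips = numeric(0),
                      i_lddt = numeric(0)))
  do.call(rbind, out)
}

# score a single model against one reference for one category
score_model <- function(model, reference, category, ligand_key = NULL,
                        chain_map = NULL) {
  corr <- residue_correspondence(model, reference, chain_map = chain_map)
  vals <- c(tm = tryCatch(tm_score(model, reference, corr),
                          error = function(e) NA_real_),
            gdt_ts = tryCatch(gdt_ts(model, reference, corr),
                              error = function(e) NA_real_),
            lddt = tryCatch(lddt(model, reference, corr),
                            error = function(e) NA_real_))
  if (category %in% c("multimer", "hybrid")) {
    rec <- interface_records(model, reference, corr)
    vals <- c(vals,
              ics = aggregate_na_interfaces(
                transform(rec, score = rec$ics)),
              ips = aggregate_na_interfaces(
                transform(rec, score = rec$ips)),
              i_lddt = aggregate_na_interfaces(
                transform(rec, score = rec$i_lddt)))
  }
  if (category == "ligand") {
    if (is.null(ligand_key)) stop("ligand category requires a ligand key")
    pocket <- define_ligand_pocket(reference, ligand_key)
    lm <- ligand_metrics(model, reference, pocket)
    vals <- c(vals, i_lddt = lm$i_lddt, lddt_pocket = lm$lddt_pocket)
  }
  vals
}

#' Validate a submitted model against its target
#'
#' Diagnostics only: reports sequence mismatches at corresponding
#' residues, chains missing relative to the reference, origin-piled atoms
#' and multimers with no meaningful inter-chain interaction (degenerate
#' models flagged for exclusion review).
#'
#' @param model,reference `na_structure` objects.
#' @return character vector of diagnostics (empty when clean).
#' @export
validate_submission <- function(model, reference) {
  out <- character(0)
  mt <- residue_table(model); rt <- residue_table(reference)
  missing_chains <- setdiff(unique(rt$chain), unique(mt$chain))
  if (length(missing_chains))
    out <- c(out, paste0("missing chain(s): ",
                         paste(missing_chains, collapse = ", ")))
  shared <- intersect(mt$key, rt$key)
  if (length(shared)) {
    mm <- sum(mt$resname[match(shared, mt$key)] !=
                rt$resname[match(shared, rt$key)])
    if (mm > 0) out <- c(out, paste0("sequence mismatch at ", mm,
                                     " position(s)"))
  }
  a <- model$atoms
  fin <- is.finite(a$x)
  at_origin <- fin & abs(a$x) < 1e-3 & abs(a$y) < 1e-3 & abs(a$z) < 1e-3
  if (sum(at_origin) > 1)
    out <- c(out, paste0(sum(at_origin), " atoms piled at the origin ",
                         "(degenerate geometry)"))
  if (length(unique(a$chain)) > 1 && detect_no_interaction(model))
    out <- c(out, "no meaningful inter-chain interaction (degenerate model)")
  out
}

#' Run a full assessment
#'
#' Scores every model of every group against all references of each
#' target (keeping the per-metric best across models and references),
#' computes trimmed Z-scores, category combinations, grouped floored sums
#' with the participation filter, and bootstrap confidence intervals.
#'
#' @param targets named list; each element is a list with `references`
#'   (list of `na_structure`), `category` (`"monomer"`, `"multimer"`,
#'   `"hybrid"` or `"ligand"`) and optionally `ligand` (residue key) and
#'   `chain_map`.
#' @param submissions nested list `models[[group]][[target]]` of model
#'   structures (as produced by [simulate_submissions()]).
#' @param grouping same-sequence grouping sets.
#' @param config a [ranking_config()].
#' @param exclusions data.frame of (group, target) exclusions.
#' @param output_dir optional directory for CSV reports.
#' @return list with `model_scores`, `best_scores`, `ranking` and
#'   `log` (character vector of exclusions/nulls recorded).
#' @export
run_assessment <- function(targets, submissions, grouping = list(),
                           config = ranking_config(),
                           exclusions = default_exclusions(),
                           output_dir = NULL) {
  stopifnot(length(targets) >= 1)
  log <- character(0)
  rows <- list()
  for (g in names(submissions)) {
    for (tname in names(submissions[[g]])) {
      tdef <- targets[[tname]]
      if (is.null(tdef)) stop("submission for unknown target: ", tname)
      for (mi in seq_along(submissions[[g]][[tname]])) {
        mdl <- submissions[[g]][[tname]][[mi]]
        for (ri in seq_along(tdef$references)) {
          vals <- tryCatch(
            score_model(mdl, tdef$references[[ri]], tdef$category,
                        ligand_key = tdef$ligand,
                        chain_map = tdef$chain_map),
            error = function(e) {
              log <<- c(log, paste0("scoring failed: ", g, "/", tname,
                                    " model ", mi, " ref ", ri, ": ",
                                    conditionMessage(e)))
              NULL
            })
          if (is.null(vals)) next
          rows[[length(rows) + 1]] <- data.frame(
            group = g, target = tname, model = mi,
            reference = tdef$references[[ri]]$id %||% as.character(ri),
            metric = names(vals), value = unname(vals),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) stop("no scoreable submissions")
  model_scores <- do.call(rbind, rows)
  best <- reduce_best(model_scores)
  target_category <- vapply(targets, `[[`, character(1), "category")
  names(target_category) <- names(targets)
  ranking <- rank_groups(best, target_category, grouping = grouping,
                         config = config, exclusions = exclusions)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(model_scores,
                     file.path(output_dir, "model_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(best, file.path(output_dir, "best_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ranking),
                     file.path(output_dir, "ranking.csv"),
                     row.names = FALSE)
  }
  list(model_scores = model_scores, best_scores = best, ranking = ranking,
       log = log)
}
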
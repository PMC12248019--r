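# Biomolecule-agnostic whole-structure metrics: Kabsch superposition,
# TM-score, GDT_TS, clash-penalised lDDT and a sequence-independent
# structural aligner. Representative atoms are C4' for nucleic acids and
# CA for proteins; lDDT uses all heavy atoms.

#' Length-dependent TM-score distance scale d0
#'
#' Nucleic acids follow the published US-align/RNA-align convention
#' (`0.6*sqrt(L - 0.5) - 2.5` for L >= 30 with stepwise values for shorter
#' chains and a floor of 0.3); proteins use the classic TM-score formula.
#'
#' @param L normalisation length.
#' @param type `"nucleic"` or `"protein"`.
#' @return d0 in Angstrom.
#' @export
d0_for_length <- function(L, type = c("nucleic", "protein")) {
  type <- match.arg(type)
  if (type == "nucleic") {
    if (L >= 30) return(max(0.6 * sqrt(L - 0.5) - 2.5, 0.3))
    if (L >= 24) return(0.7)
    if (L >= 20) return(0.6)
    if (L >= 16) return(0.5)
    if (L >= 12) return(0.4)
    return(0.3)
  }
  if (L > 21) return(max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5))
  0.5
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of point set `X` onto matched point set `Y`
#' with a proper rotation enforced.
#'
#' @param X,Y numeric n x 3 matrices of matched points, n >= 3.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom), of class `na_superposition`.
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("point sets must be matched")
  if (nrow(X) < 3) stop("need at least 3 points to superpose")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("non-finite coordinates")
  Xc <- sweep(X, 2, colMeans(X))
  if (qr(Xc)$rank < 2) stop("degenerate (collinear) point set")
  out <- cpp_kabsch(X, Y)
  out$translation <- as.numeric(out$translation)
  class(out) <- "na_superposition"
  out
}

#' Apply a superposition to coordinates
#' @param sup an `na_superposition`.
#' @param X n x 3 coordinate matrix.
#' @export
apply_superposition <- function(sup, X) {
  sweep(as.matrix(X) %*% t(sup$rotation), 2, sup$translation, "+")
}

# reference normalisation length: resolved polymer residues of the reference
reference_length <- function(reference) {
  rt <- residue_table(reference)
  sum(rt$resolved & rt$polymer_type != "ligand")
}

metric_type <- function(reference) {
  ch <- structure_chains(reference)
  if (any(ch$polymer_type %in% c("RNA", "DNA"))) "nucleic" else "protein"
}

#' TM-score of a model against a reference
#'
#' Maximum over fragment-seeded, iteratively refined superpositions of
#' `(1/L) * sum 1/(1 + (d_i/d0)^2)`, normalised by the reference length.
#' The correspondence is by sequence (chain id + residue number) unless
#' supplied.
#'
#' @param model,reference `na_structure` objects.
#' @param corr optional precomputed [residue_correspondence()].
#' @param chain_map optional model-to-reference chain map.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference, corr = NULL, chain_map = NULL) {
  if (is.null(corr))
    corr <- residue_correspondence(model, reference, chain_map = chain_map)
  cc <- corresponding_coords(model, reference, corr)
  if (nrow(cc$model) < 3) stop("fewer than 3 corresponding residues")
  L <- reference_length(reference)
  d0 <- d0_for_length(L, metric_type(reference))
  cpp_tm_search(cc$model, cc$reference, d0, L)
}

#' GDT_TS of a model against a reference
#'
#' Mean over distance thresholds 1, 2, 4, 8 Angstrom of the maximal
#' fraction of corresponding residues that fit within the threshold under
#' some superposition (iterative peeling search). Reported on a 0-1 scale.
#'
#' @inheritParams tm_score
#' @param thresholds distance thresholds in Angstrom.
#' @return GDT_TS in \[0, 1\].
#' @export
gdt_ts <- function(model, reference, corr = NULL, chain_map = NULL,
                   thresholds = c(1, 2, 4, 8)) {
  if (is.null(corr))
    corr <- residue_correspondence(model, reference, chain_map = chain_map)
  cc <- corresponding_coords(model, reference, corr)
  if (nrow(cc$model) < 3) stop("fewer than 3 corresponding residues")
  L <- reference_length(reference)
  mean(vapply(thresholds, function(th)
    cpp_gdt_count(cc$model, cc$reference, th) / L, numeric(1)))
}

#' Default lDDT parameters
#'
#' @param inclusion_radius pair inclusion radius in the reference (Angstrom).
#' @param thresholds distance-difference thresholds (Angstrom).
#' @param clash_tolerance subtracted from the van der Waals radius sum; model
#'   atom pairs closer than `vdW sum - clash_tolerance` are counted as
#'   unpreserved at every threshold (steric penalty).
#' @export
lddt_params <- function(inclusion_radius = 15,
                        thresholds = c(0.5, 1, 2, 4),
                        clash_tolerance = 1.5) {
  list(inclusion_radius = inclusion_radius, thresholds = thresholds,
       clash_tolerance = clash_tolerance)
}

# atom-level matched coordinate sets between reference and model
matched_atoms <- function(model, reference, corr) {
  ra <- reference$atoms
  ra <- ra[is.finite(ra$x) & is.finite(ra$y) & is.finite(ra$z), , drop = FALSE]
  rkey <- residue_key(ra$chain, ra$resno, ra$insert)
  keep <- rkey %in% corr$ref_key
  ra <- ra[keep, , drop = FALSE]; rkey <- rkey[keep]
  mkey_of <- corr$model_key[match(rkey, corr$ref_key)]
  ma <- model$atoms
  makey <- paste(residue_key(ma$chain, ma$resno, ma$insert), ma$elety)
  midx <- match(paste(mkey_of, ra$elety), makey)
  list(ref_xyz = cbind(ra$x, ra$y, ra$z),
       mod_xyz = cbind(ma$x[midx], ma$y[midx], ma$z[midx]),
       ref_reskey = rkey, element = ra$element,
       ref_chain = ra$chain)
}

# core lDDT computation over explicit atom sets; pair_keep is an optional
# function(i, j) -> logical over qualifying reference pairs
lddt_core <- function(ref_xyz, mod_xyz, reskey, element, params,
                      pair_keep = NULL) {
  n <- nrow(ref_xyz)
  if (n < 2) stop("no qualifying reference distances")
  dr <- as.matrix(stats::dist(ref_xyz))
  qual <- which(upper.tri(dr) & dr <= params$inclusion_radius &
                outer(reskey, reskey, "!="), arr.ind = TRUE)
  if (!is.null(pair_keep)) {
    ok <- pair_keep(qual[, 1], qual[, 2])
    qual <- qual[ok, , drop = FALSE]
  }
  if (nrow(qual) == 0) return(NA_real_)
  drv <- dr[qual]
  i <- qual[, 1]; j <- qual[, 2]
  have <- stats::complete.cases(mod_xyz[i, , drop = FALSE]) &
    stats::complete.cases(mod_xyz[j, , drop = FALSE])
  dmv <- rep(NA_real_, length(drv))
  dmv[have] <- sqrt(rowSums((mod_xyz[i[have], , drop = FALSE] -
                             mod_xyz[j[have], , drop = FALSE])^2))
  clash_lim <- vdw_radius(element[i]) + vdw_radius(element[j]) -
    params$clash_tolerance
  clash <- !is.na(dmv) & dmv < clash_lim
  fr <- vapply(params$thresholds, function(th)
    mean(!is.na(dmv) & !clash & abs(dmv - drv) < th), numeric(1))
  mean(fr)
}

#' Local distance difference test with steric penalty
#'
#' Superposition-free fraction of reference interatomic distances (within
#' the inclusion radius, excluding same-residue pairs) reproduced by the
#' model within each threshold, averaged over thresholds. Model atom pairs
#' closer than their van der Waals radius sum minus the clash tolerance are
#' counted as unpreserved at every threshold.
#'
#' @inheritParams tm_score
#' @param params see [lddt_params()].
#' @return lDDT in \[0, 1\].
#' @export
lddt <- function(model, reference, corr = NULL, chain_map = NULL,
                 params = lddt_params()) {
  if (is.null(corr))
    corr <- residue_correspondence(model, reference, chain_map = chain_map)
  m <- matched_atoms(model, reference, corr)
  out <- lddt_core(m$ref_xyz, m$mod_xyz, m$ref_reskey, m$element, params)
  if (is.na(out)) stop("no qualifying reference distances")
  out
}

# fast single-point-per-residue lDDT used as a chain-mapping objective
lddt_points <- function(Xm, Xr, params = lddt_params()) {
  n <- nrow(Xr)
  lddt_core(Xr, Xm, reskey = as.character(seq_len(n)),
            element = rep("C", n), params)
}

#' Sequence-independent structural alignment score (TM-align style)
#'
#' Finds a sequence-order-preserving residue alignment between two
#' structures by fragment seeding and iterative dynamic programming on
#' TM-weighted distances, and scores it with the TM functional form
#' normalised by the length of `structB`.
#'
#' @param structA,structB `na_structure` objects with >= 5 representative
#'   atoms each.
#' @return list with `score` and `alignment` (data.frame of matched residue
#'   keys `key_a`, `key_b`).
#' @export
tm_align <- function(structA, structB) {
  repxyz <- function(s) {
    rt <- residue_table(s)
    rt <- rt[rt$resolved & rt$polymer_type != "ligand", , drop = FALSE]
    a <- s$atoms
    akey <- paste(residue_key(a$chain, a$resno, a$insert), a$elety)
    idx <- match(paste(rt$key, rep_atom_for(rt$polymer_type)), akey)
    ok <- !is.na(idx)
    list(xyz = cbind(a$x[idx[ok]], a$y[idx[ok]], a$z[idx[ok]]),
         key = rt$key[ok])
  }
  A <- repxyz(structA); B <- repxyz(structB)
  if (nrow(A$xyz) < 5 || nrow(B$xyz) < 5)
    stop("need at least 5 representative atoms per structure")
  d0 <- d0_for_length(nrow(B$xyz), metric_type(structB))
  res <- cpp_tmalign(A$xyz, B$xyz, d0)
  list(score = res$score,
       alignment = data.frame(key_a = A$key[res$a], key_b = B$key[res$b],
                              stringsAsFactors = FALSE))
}

#' Score one model against one or more references, keeping the best
#'
#' Computes each requested metric against every reference and keeps the
#' best value per metric (decoupled across metrics).
#'
#' @param model an `na_structure`.
#' @param references list of `na_structure` references.
#' @param metrics character subset of `c("tm", "gdt_ts", "lddt")`.
#' @param chain_map optional chain map or `"search"` to run
#'   [chain_mapping_search()] per reference.
#' @return named numeric vector of best scores, with attribute
#'   `"reference_used"` naming the winning reference per metric.
#' @export
score_against_references <- function(model, references,
                                     metrics = c("tm", "gdt_ts", "lddt"),
                                     chain_map = NULL) {
  if (inherits(references, "na_structure")) references <- list(references)
  vals <- matrix(NA_real_, nrow = length(references), ncol = length(metrics),
                 dimnames = list(NULL, metrics))
  for (ri in seq_along(references)) {
    ref <- references[[ri]]
    cmap <- chain_map
    if (identical(chain_map, "search"))
      cmap <- chain_mapping_search(model, ref)
    corr <- residue_correspondence(model, ref, chain_map = cmap)
    for (m in metrics) {
      vals[ri, m] <- switch(m,
        tm = tm_score(model, ref, corr),
        gdt_ts = gdt_ts(model, ref, corr),
        lddt = lddt(model, ref, corr))
    }
  }
  best <- apply(vals, 2, max)
  ref_ids <- vapply(references, function(r) r$id, character(1))
  attr(best, "reference_used") <- ref_ids[apply(vals, 2, which.max)]
  best
}
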
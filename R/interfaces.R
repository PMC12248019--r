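# Contact-based interface scoring (ICS, IPS, i-lDDT), nucleic-acid
# interface aggregation, ligand-pocket metrics and the degenerate-model
# detector.

#' Extract inter-chain residue contacts
#'
#' A contact is an unordered pair of residues from different chains with
#' any heavy-atom pair closer than `threshold` (strict inequality).
#'
#' @param structure an `na_structure` with >= 2 chains.
#' @param threshold contact distance in Angstrom (default 5, the CASP
#'   heavy-atom convention).
#' @return list of class `contact_set`: `contacts` (character pair ids over
#'   residue keys), `residues` (interface residue keys), `threshold`.
#' @export
extract_contacts <- function(structure, threshold = 5) {
  a <- structure$atoms
  a <- a[is.finite(a$x) & is.finite(a$y) & is.finite(a$z), , drop = FALSE]
  out <- structure(list(contacts = character(0), residues = character(0),
                        threshold = threshold), class = "contact_set")
  if (length(unique(a$chain)) < 2) {
    warning("structure has a single chain; no inter-chain contacts")
    return(out)
  }
  if (threshold <= 0) return(out)
  xyz <- cbind(a$x, a$y, a$z)
  key <- residue_key(a$chain, a$resno, a$insert)
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d < threshold &
               outer(a$chain, a$chain, "!="), arr.ind = TRUE)
  if (nrow(hit) == 0) return(out)
  ids <- unique(pair_id(key[hit[, 1]], key[hit[, 2]]))
  res <- unique(c(key[hit[, 1]], key[hit[, 2]]))
  out$contacts <- ids
  out$residues <- res
  out
}

contact_ids <- function(x) if (inherits(x, "contact_set")) x$contacts else as.character(x)

#' Interface contact score (F1 over inter-chain contacts)
#'
#' @param pred,ref `contact_set` objects (or character contact-id vectors)
#'   expressed in reference residue coordinates.
#' @return a `prf1` (see [score_f1()]); an empty reference with a non-empty
#'   prediction scores 0, dual absence is a null score.
#' @export
ics <- function(pred, ref) {
  score_f1(contact_ids(pred), contact_ids(ref))
}

#' Interface patch similarity (Jaccard over interface residues)
#'
#' @inheritParams ics
#' @return Jaccard coefficient in \[0, 1\], or `NA` when both interfaces
#'   are empty.
#' @export
ips <- function(pred, ref) {
  pr <- if (inherits(pred, "contact_set")) pred$residues else
    unique(unlist(strsplit(contact_ids(pred), "--", fixed = TRUE)))
  rr <- if (inherits(ref, "contact_set")) ref$residues else
    unique(unlist(strsplit(contact_ids(ref), "--", fixed = TRUE)))
  if (!length(pr) && !length(rr)) return(NA_real_)
  length(intersect(pr, rr)) / length(union(pr, rr))
}

#' Interface lDDT
#'
#' lDDT restricted to reference atom pairs spanning different chains
#' (within the inclusion radius); the steric penalty is retained.
#'
#' @inheritParams lddt
#' @return i-lDDT in \[0, 1\], or `NA` when the reference has no
#'   inter-chain distances within the inclusion radius.
#' @export
interface_lddt <- function(model, reference, corr = NULL, chain_map = NULL,
                           params = lddt_params()) {
  if (is.null(corr))
    corr <- residue_correspondence(model, reference, chain_map = chain_map)
  m <- matched_atoms(model, reference, corr)
  lddt_core(m$ref_xyz, m$mod_xyz, m$ref_reskey, m$element, params,
            pair_keep = function(i, j) m$ref_chain[i] != m$ref_chain[j])
}

#' Interface type from two chains' polymer types
#' @param t1,t2 polymer types.
#' @export
interface_type <- function(t1, t2) {
  na1 <- t1 %in% c("RNA", "DNA"); na2 <- t2 %in% c("RNA", "DNA")
  if (na1 && na2) return("NA-NA")
  if (na1 || na2) {
    if (t1 == "protein" || t2 == "protein") return("NA-protein")
    return("NA-ligand")
  }
  "protein-protein"
}

#' Residue-count-weighted aggregate over nucleic-acid interfaces
#'
#' NA-NA and NA-protein interface scores are combined weighted by the
#' number of reference interface residues; protein-protein interfaces are
#' excluded.
#'
#' @param records data.frame with columns `type`, `residue_count` and
#'   `score`.
#' @return weighted mean, or `NA` when no NA-containing interface exists.
#' @export
aggregate_na_interfaces <- function(records) {
  keep <- records$type %in% c("NA-NA", "NA-protein") & !is.na(records$score)
  if (!any(keep)) return(NA_real_)
  r <- records[keep, , drop = FALSE]
  sum(r$score * r$residue_count) / sum(r$residue_count)
}

#' Define a ligand pocket from the reference structure
#'
#' @param reference an `na_structure` containing the ligand.
#' @param ligand_key residue key of the ligand.
#' @param radius pocket radius in Angstrom around ligand heavy atoms
#'   (default 4).
#' @return list of class `ligand_pocket`: `ligand`, `pocket_residues`
#'   (nucleotide keys), `radius`.
#' @export
define_ligand_pocket <- function(reference, ligand_key, radius = 4) {
  a <- reference$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  lig <- a[key == ligand_key, , drop = FALSE]
  if (nrow(lig) == 0) stop("ligand residue not found: ", ligand_key)
  rt <- residue_table(reference)
  na_keys <- rt$key[rt$polymer_type %in% c("RNA", "DNA")]
  keep <- key %in% na_keys & is.finite(a$x)
  xyz <- cbind(a$x[keep], a$y[keep], a$z[keep])
  lxyz <- cbind(lig$x, lig$y, lig$z)
  dmin <- apply(xyz, 1, function(p) min(sqrt(colSums((t(lxyz) - p)^2))))
  pocket <- unique(key[keep][dmin <= radius])
  structure(list(ligand = ligand_key, pocket_residues = pocket,
                 radius = radius), class = "ligand_pocket")
}

#' Ligand-pocket metrics
#'
#' Computes the nucleic-acid/ligand interface lDDT (over NA-ligand atom
#' pairs), the lDDT of the pocket nucleotides, and the RMSD of the pocket
#' nucleotides after superposing them.
#'
#' @param model,reference `na_structure` objects.
#' @param pocket a `ligand_pocket` from [define_ligand_pocket()].
#' @param params lDDT parameters.
#' @return list with `i_lddt`, `lddt_pocket`, `pocket_rmsd` and
#'   `ligand_missing`; all metrics `NA` when the model lacks the ligand.
#' @export
ligand_metrics <- function(model, reference, pocket, params = lddt_params()) {
  mt <- residue_table(model)
  if (!(pocket$ligand %in% mt$key[mt$resolved]))
    return(list(i_lddt = NA_real_, lddt_pocket = NA_real_,
                pocket_rmsd = NA_real_, ligand_missing = TRUE))
  corr <- residue_correspondence(model, reference)
  m <- matched_atoms(model, reference, corr)
  in_lig <- m$ref_reskey == pocket$ligand
  in_pocket <- m$ref_reskey %in% pocket$pocket_residues
  i_lddt <- lddt_core(m$ref_xyz, m$mod_xyz, m$ref_reskey, m$element, params,
                      pair_keep = function(i, j) xor(in_lig[i], in_lig[j]))
  lddt_pocket <- lddt_core(m$ref_xyz, m$mod_xyz, m$ref_reskey, m$element,
                           params,
                           pair_keep = function(i, j) in_pocket[i] & in_pocket[j])
  sel <- in_pocket & stats::complete.cases(m$mod_xyz)
  pocket_rmsd <- if (sum(sel) >= 3)
    cpp_kabsch(m$mod_xyz[sel, , drop = FALSE],
               m$ref_xyz[sel, , drop = FALSE])$rmsd else NA_real_
  list(i_lddt = i_lddt, lddt_pocket = lddt_pocket,
       pocket_rmsd = pocket_rmsd, ligand_missing = FALSE)
}

#' Normalise a half-pocket score against the target half-pockets
#'
#' Predictions of half a dimeric pocket are scored against the full dimer
#' and normalised by the better of the two target half-pocket scores,
#' capped at 1.
#'
#' @param score_model model score against the dimer pocket.
#' @param score_half_a,score_half_b target half-pocket scores against the
#'   dimer.
#' @return normalised score, or `NA` when both half scores are 0.
#' @export
normalize_half_pocket <- function(score_model, score_half_a, score_half_b) {
  denom <- max(score_half_a, score_half_b)
  if (denom <= 0) return(NA_real_)
  min(score_model / denom, 1)
}

#' Detect degenerate multimer models with no meaningful interaction
#'
#' Flags models whose chains are either totally separated (no inter-chain
#' contacts at 5 Angstrom) or totally overlapping (some chain pair with
#' coincident centroids within 1 Angstrom and more than half of its
#' inter-chain atom pairs clashing).
#'
#' @param model a multimeric `na_structure`.
#' @return `TRUE` when no chain pair forms a meaningful interface.
#' @export
detect_no_interaction <- function(model) {
  a <- model$atoms
  a <- a[is.finite(a$x), , drop = FALSE]
  chains <- unique(a$chain)
  if (length(chains) < 2) return(FALSE)
  meaningful <- FALSE
  for (ci in seq_along(chains)) for (cj in seq_len(ci - 1)) {
    xi <- a[a$chain == chains[ci], , drop = FALSE]
    xj <- a[a$chain == chains[cj], , drop = FALSE]
    Pi <- cbind(xi$x, xi$y, xi$z); Pj <- cbind(xj$x, xj$y, xj$z)
    dd <- sqrt(pmax(outer(rowSums(Pi^2), rowSums(Pj^2), "+") -
                      2 * Pi %*% t(Pj), 0))
    has_contact <- any(dd < 5, na.rm = TRUE)
    if (!has_contact) next
    cen_d <- sqrt(sum((colMeans(Pi) - colMeans(Pj))^2))
    # overlapping when centroids coincide and most atoms sit on top of an
    # atom of the other chain
    overlap <- cen_d < 1 && mean(apply(dd, 1, min) < 1.5) > 0.5
    if (!overlap) meaningful <- TRUE
  }
  !meaningful
}
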
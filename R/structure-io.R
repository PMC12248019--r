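# Structure parsing, validation, residue correspondence and chain mapping.
#
# A structure is held as a flat atom table plus per-chain metadata, the
# in-memory form used by bio3d and most structural packages. Residues are
# identified by author numbering (chain, number, insertion code); insertion
# codes order alphabetically after the bare number.

#' Construct a structure object from an atom table
#'
#' @param id structure identifier.
#' @param atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resname`, `elety`, `element`, `x`, `y`, `z` and optionally `occ`.
#' @param source_format `"pdb"`, `"mmcif"` or `"memory"`.
#' @return An object of class `na_structure`.
#' @export
new_structure <- function(id, atoms, source_format = "memory") {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("chain", "resno", "insert", "resname", "elety", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ", paste(miss, collapse = ", "))
  atoms$insert <- ifelse(is.na(atoms$insert), "", as.character(atoms$insert))
  if (is.null(atoms$occ)) atoms$occ <- 1
  atoms$chain <- as.character(atoms$chain)
  # order: chain (first appearance), then residue number, then insertion code
  chain_order <- unique(atoms$chain)
  o <- order(match(atoms$chain, chain_order), atoms$resno, atoms$insert)
  atoms <- atoms[o, , drop = FALSE]
  rownames(atoms) <- NULL
  x <- structure(list(id = id, atoms = atoms, source_format = source_format),
                 class = "na_structure")
  x
}

#' @export
print.na_structure <- function(x, ...) {
  ch <- structure_chains(x)
  cat("<na_structure> ", x$id, ": ", nrow(ch), " chain(s), ",
      nrow(residue_table(x)), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  for (i in seq_len(nrow(ch))) {
    cat("  chain ", ch$chain_id[i], " [", ch$polymer_type[i], "] ",
        ch$n_residues[i], " residues\n", sep = "")
  }
  invisible(x)
}

#' Per-chain summary of a structure
#'
#' Polymer type is inferred from the residue-name vocabulary (A/C/G/U for
#' RNA, DA/DC/DG/DT for DNA, the 20 amino acids for protein, anything else
#' ligand); a chain's type is the majority type of its residues.
#'
#' @param x an `na_structure`.
#' @return data.frame with `chain_id`, `polymer_type`, `n_residues`.
#' @export
structure_chains <- function(x) {
  rt <- residue_table(x)
  ids <- unique(rt$chain)
  ptype <- vapply(ids, function(cid) {
    tt <- table(rt$polymer_type[rt$chain == cid])
    names(tt)[which.max(tt)]
  }, character(1))
  data.frame(chain_id = ids, polymer_type = unname(ptype),
             n_residues = as.integer(table(rt$chain)[ids]),
             stringsAsFactors = FALSE)
}

#' Per-residue table of a structure
#'
#' A residue is `resolved` when it has at least one atom with finite
#' coordinates.
#'
#' @param x an `na_structure`.
#' @return data.frame with `chain`, `resno`, `insert`, `resname`,
#'   `polymer_type`, `resolved` and the unique residue `key`, in global
#'   residue order.
#' @export
residue_table <- function(x) {
  a <- x$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  first <- !duplicated(key)
  fin <- is.finite(a$x) & is.finite(a$y) & is.finite(a$z)
  resolved <- tapply(fin, key, any)
  rt <- data.frame(chain = a$chain[first], resno = a$resno[first],
                   insert = a$insert[first], resname = a$resname[first],
                   stringsAsFactors = FALSE)
  rt$polymer_type <- polymer_type_of(rt$resname)
  rt$key <- key[first]
  rt$resolved <- as.logical(resolved[rt$key])
  rt
}

#' Read a structure from a PDB or mmCIF file
#'
#' Parsing is delegated to bio3d; the result is normalised into the package's
#' atom-table representation. For atoms with alternate locations only the
#' highest-occupancy conformer is kept. Multi-model files yield the first
#' model unless `model` is given.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @param model 1-based model index for multi-model PDB files.
#' @param id identifier for the structure (default: file base name).
#' @return An `na_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           model = 1, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch({
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = model > 1, rm.alt = FALSE,
                      verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    }
  }, error = function(e) stop("cannot parse ", format, " file '", path,
                              "': ", conditionMessage(e)))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)
  if (model > 1) {
    if (is.null(parsed$xyz) || nrow(parsed$xyz) < model)
      stop("model index ", model, " out of range for ", path)
    xyz <- matrix(parsed$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  strip_q <- function(v) gsub('^"|"$', "", v)
  atoms <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                      resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = strip_q(trimws(at$resid)),
                      elety = strip_q(trimws(at$elety)),
                      element = if (!is.null(at$elesy)) trimws(at$elesy) else "",
                      x = at$x, y = at$y, z = at$z,
                      occ = ifelse(is.na(at$o), 1, at$o),
                      stringsAsFactors = FALSE)
  noel <- is.na(atoms$element) | atoms$element == ""
  atoms$element[noel] <- substr(gsub("[^A-Za-z].*$", "", atoms$elety[noel]), 1, 1)
  # altloc: keep highest-occupancy conformer per (chain, residue, atom name)
  akey <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(akey)) {
    keep <- unlist(lapply(split(seq_len(nrow(atoms)), akey),
                          function(ii) ii[which.max(atoms$occ[ii])]))
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  new_structure(id %||% sub("\\.[^.]*$", "", basename(path)), atoms,
                source_format = format)
}

#' Write a structure as a PDB file
#'
#' @param x an `na_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  fin <- is.finite(a$x) & is.finite(a$y) & is.finite(a$z)
  a <- a[fin, , drop = FALSE]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   elety = a$elety, o = a$occ, elesy = a$element,
                   verbose = FALSE)
  invisible(path)
}

#' Residue correspondence between a model and a reference
#'
#' In `sequence` mode residues are matched by chain identifier (optionally
#' translated through `chain_map`), author residue number and insertion
#' code. Reference residues that are unresolved are excluded, as are model
#' residues missing from the reference and vice versa.
#'
#' @param model,reference `na_structure` objects.
#' @param mode currently `"sequence"`.
#' @param chain_map optional named character vector mapping model chain ids
#'   to reference chain ids.
#' @return data.frame of class `na_correspondence` with columns `model_key`
#'   and `ref_key`.
#' @export
residue_correspondence <- function(model, reference, mode = "sequence",
                                   chain_map = NULL) {
  stopifnot(mode == "sequence")
  mt <- residue_table(model)
  rt <- residue_table(reference)
  rt <- rt[rt$resolved, , drop = FALSE]
  mt <- mt[mt$resolved, , drop = FALSE]
  mchain <- mt$chain
  if (!is.null(chain_map)) {
    unknown <- setdiff(mchain, names(chain_map))
    if (length(unknown)) stop("chain_map lacks entries for: ",
                              paste(unique(unknown), collapse = ", "))
    mchain <- unname(chain_map[mchain])
  }
  mkey_in_ref <- residue_key(mchain, mt$resno, mt$insert)
  idx <- match(mkey_in_ref, rt$key)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no correspondence between model and reference")
  out <- data.frame(model_key = mt$key[ok], ref_key = rt$key[idx[ok]],
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("na_correspondence", class(out))
  out
}

# representative-atom coordinate matrices for matched residues; rows are
# dropped pairwise when either side lacks its representative atom
corresponding_coords <- function(model, reference, corr,
                                 atom = "representative") {
  get_xyz <- function(s, keys) {
    a <- s$atoms
    akey <- residue_key(a$chain, a$resno, a$insert)
    rt <- residue_table(s)
    rep_by_key <- rep_atom_for(rt$polymer_type)
    names(rep_by_key) <- rt$key
    want <- if (atom == "representative") rep_by_key[keys] else rep(atom, length(keys))
    idx <- match(paste(keys, want), paste(akey, a$elety))
    cbind(a$x[idx], a$y[idx], a$z[idx])
  }
  Xm <- get_xyz(model, corr$model_key)
  Xr <- get_xyz(reference, corr$ref_key)
  ok <- stats::complete.cases(Xm) & stats::complete.cases(Xr)
  list(model = Xm[ok, , drop = FALSE], reference = Xr[ok, , drop = FALSE],
       model_key = corr$model_key[ok], ref_key = corr$ref_key[ok])
}

# chain sequence signature used to group chains into identity classes
chain_signature <- function(x) {
  rt <- residue_table(x)
  vapply(unique(rt$chain), function(cid)
    paste(rt$resname[rt$chain == cid], collapse = "-"), character(1))
}

#' Search for the chain mapping maximizing a scoring objective
#'
#' Model chains are matched to reference chains within sequence-identity
#' classes. When the number of label permutations is small the search is
#' exhaustive; otherwise a greedy seed-and-extend strategy superposes one
#' seed chain pair and assigns remaining chains by centroid proximity.
#' Ties break lexicographically by chain order, so the search is
#' deterministic.
#'
#' @param model,reference `na_structure` objects with compatible
#'   stoichiometry.
#' @param objective function(chain_map) -> numeric score to maximize;
#'   default is the representative-atom lDDT of the mapped model.
#' @param max_exhaustive largest number of permutations tried exhaustively.
#' @return named character vector mapping model chain ids to reference
#'   chain ids, with the achieved objective in attribute `"objective"`.
#' @export
chain_mapping_search <- function(model, reference, objective = NULL,
                                 max_exhaustive = 5000) {
  sig_m <- chain_signature(model)
  sig_r <- chain_signature(reference)
  classes <- sort(unique(sig_r))
  if (!identical(sort(table(sig_m)), sort(table(sig_r))) ||
      !setequal(sig_m, sig_r)) {
    # compare multisets of class sizes keyed by signature
    tm <- table(sig_m); tr <- table(sig_r)
    if (!identical(as.vector(tm[order(names(tm))]),
                   as.vector(tr[order(names(tr))])) ||
        !setequal(names(tm), names(tr)))
      stop("incompatible stoichiometry between model and reference")
  }
  if (is.null(objective)) {
    objective <- function(map) {
      corr <- residue_correspondence(model, reference, chain_map = map)
      cc <- corresponding_coords(model, reference, corr)
      lddt_points(cc$model, cc$reference)
    }
  }
  n_perm <- prod(vapply(classes, function(cl) factorial(sum(sig_m == cl)),
                        numeric(1)))
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  if (n_perm <= max_exhaustive) {
    per_class <- lapply(classes, function(cl)
      perms_of(names(sig_r)[sig_r == cl]))
    grids <- expand.grid(lapply(per_class, seq_along))
    best <- NULL; best_score <- -Inf
    for (g in seq_len(nrow(grids))) {
      map <- character(0)
      for (ci in seq_along(classes)) {
        mids <- names(sig_m)[sig_m == classes[ci]]
        rids <- per_class[[ci]][[grids[g, ci]]]
        map[mids] <- rids
      }
      sc <- objective(map)
      if (sc > best_score + 1e-12) { best_score <- sc; best <- map }
    }
    best <- best[order(match(names(best), names(sig_m)))]
    attr(best, "objective") <- best_score
    return(best)
  }
  # greedy: seed on first model chain against each compatible reference
  # chain, superpose, then extend by nearest centroid within class
  centroids <- function(s) {
    a <- s$atoms
    t(vapply(unique(a$chain), function(cid) {
      sel <- a$chain == cid & is.finite(a$x)
      c(mean(a$x[sel]), mean(a$y[sel]), mean(a$z[sel]))
    }, numeric(3)))
  }
  cm <- centroids(model); cr <- centroids(reference)
  seed_m <- names(sig_m)[1]
  best <- NULL; best_score <- -Inf
  for (seed_r in names(sig_r)[sig_r == sig_m[seed_m]]) {
    map1 <- stats::setNames(seed_r, seed_m)
    corr <- residue_correspondence(
      subset_chains(model, seed_m), subset_chains(reference, seed_r),
      chain_map = map1)
    cc <- corresponding_coords(subset_chains(model, seed_m),
                               subset_chains(reference, seed_r), corr)
    sup <- cpp_kabsch(cc$model, cc$reference)
    cmt <- sweep(cm %*% t(sup$rotation), 2, as.numeric(sup$translation), "+")
    map <- map1
    free_r <- setdiff(names(sig_r), seed_r)
    for (mid in setdiff(names(sig_m), seed_m)) {
      cand <- free_r[sig_r[free_r] == sig_m[mid]]
      if (!length(cand)) stop("incompatible stoichiometry during greedy extension")
      d <- sqrt(colSums((t(cr[cand, , drop = FALSE]) - cmt[match(mid, rownames(cm)), ])^2))
      pick <- cand[which.min(d)]
      map[mid] <- pick
      free_r <- setdiff(free_r, pick)
    }
    sc <- objective(map)
    if (sc > best_score + 1e-12) { best_score <- sc; best <- map }
  }
  attr(best, "objective") <- best_score
  best
}

#' Restrict a structure to a subset of chains
#' @param x an `na_structure`.
#' @param chains character vector of chain ids to keep.
#' @export
subset_chains <- function(x, chains) {
  a <- x$atoms[x$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after chain subset")
  new_structure(x$id, a, x$source_format)
}
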
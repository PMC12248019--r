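# Base-pair annotation, topology classification (crossed / singlet /
# intermolecular) and F1 scoring with the null-score conventions used for
# interaction types.

CANONICAL_COMBOS <- c("A-U", "U-A", "A-T", "T-A", "G-C", "C-G", "G-U", "U-G",
                      "DA-DT", "DT-DA", "DG-DC", "DC-DG")

base_letter <- function(resname) sub("^D", "", resname)

is_complementary <- function(a, b) {
  paste(base_letter(a), base_letter(b), sep = "-") %in%
    c("A-U", "U-A", "A-T", "T-A", "G-C", "C-G", "G-U", "U-G")
}

#' Geometric base-pair annotation
#'
#' Detects base pairs from coarse geometric criteria on the pairing
#' nitrogen (N1 for purines, N3 for pyrimidines), the C1' atoms and the
#' base plane. A detected pair is canonical when the bases are
#' complementary (Watson-Crick-Franklin A-U/A-T and G-C, or wobble G-U),
#' the N-N hydrogen-bond distance is <= 3.5 Angstrom, the base-plane angle
#' is <= 30 degrees and the C1'-C1' distance is within 10.4 +/- 1.5
#' Angstrom; other detected proximal pairs are labelled non-canonical.
#' Each residue joins at most one canonical pair (closest N-N wins).
#'
#' @param structure an `na_structure` with RNA/DNA chains.
#' @param nn_max maximum N-N distance (Angstrom) for a detected pair.
#' @param c1_target,c1_tol C1'-C1' distance window for canonical pairs.
#' @param angle_max maximum base-plane angle (degrees) for canonical pairs.
#' @return data.frame with columns `key_i`, `key_j`, `klass`
#'   (`"canonical"`/`"noncanonical"`) and `intermolecular`; `key_i`
#'   precedes `key_j` in the global residue order.
#' @export
annotate_pairs <- function(structure, nn_max = 3.5, c1_target = 10.4,
                           c1_tol = 1.5, angle_max = 30) {
  rt <- residue_table(structure)
  na_rt <- rt[rt$polymer_type %in% c("RNA", "DNA") & rt$resolved, , drop = FALSE]
  empty <- data.frame(key_i = character(0), key_j = character(0),
                      klass = character(0), intermolecular = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(na_rt) < 2) return(empty)
  a <- structure$atoms
  akey <- residue_key(a$chain, a$resno, a$insert)
  get_atom <- function(keys, names_want) {
    idx <- match(paste(keys, names_want), paste(akey, a$elety))
    cbind(a$x[idx], a$y[idx], a$z[idx])
  }
  n_name <- ifelse(base_letter(na_rt$resname) %in% c("A", "G"), "N1", "N3")
  Nxyz <- get_atom(na_rt$key, n_name)
  C1 <- get_atom(na_rt$key, "C1'")
  CEN <- get_atom(na_rt$key, "CEN")
  ok <- stats::complete.cases(Nxyz) & stats::complete.cases(C1)
  if (!all(ok)) {
    bad_ch <- unique(na_rt$chain[!ok])
    warning("skipping residues lacking base atoms in chain(s): ",
            paste(bad_ch, collapse = ", "))
  }
  na_rt <- na_rt[ok, , drop = FALSE]
  Nxyz <- Nxyz[ok, , drop = FALSE]; C1 <- C1[ok, , drop = FALSE]
  CEN <- CEN[ok, , drop = FALSE]
  m <- nrow(na_rt)
  if (m < 2) return(empty)
  dn <- as.matrix(stats::dist(Nxyz))
  cand <- which(upper.tri(dn) & dn <= nn_max, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  # covalently adjacent bases never pair
  adjacent <- na_rt$chain[cand[, 1]] == na_rt$chain[cand[, 2]] &
    abs(na_rt$resno[cand[, 1]] - na_rt$resno[cand[, 2]]) <= 1
  cand <- cand[!adjacent, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  d1 <- sqrt(rowSums((C1[cand[, 1], , drop = FALSE] -
                      C1[cand[, 2], , drop = FALSE])^2))
  # base-plane normal from C1', pairing N and base centroid
  normals <- matrix(NA_real_, m, 3)
  has_cen <- stats::complete.cases(CEN)
  v1 <- Nxyz - C1; v2 <- CEN - C1
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  normals[has_cen & nrm > 1e-6, ] <-
    (cr / nrm)[has_cen & nrm > 1e-6, , drop = FALSE]
  plane_angle <- function(i, j) {
    ni <- normals[i, ]; nj <- normals[j, ]
    if (anyNA(ni) || anyNA(nj)) return(0)  # no plane info: do not reject
    ang <- acos(pmin(1, abs(sum(ni * nj)))) * 180 / pi
    ang
  }
  ang <- vapply(seq_len(nrow(cand)),
                function(k) plane_angle(cand[k, 1], cand[k, 2]), numeric(1))
  comp <- is_complementary(na_rt$resname[cand[, 1]], na_rt$resname[cand[, 2]])
  canonical_ok <- comp & abs(d1 - c1_target) <= c1_tol & ang <= angle_max
  # greedy canonical assignment: closest N-N first, one canonical pair per
  # residue
  ordk <- order(dn[cand])
  taken <- rep(FALSE, m)
  klass <- rep("noncanonical", nrow(cand))
  for (k in ordk) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (canonical_ok[k] && !taken[i] && !taken[j]) {
      klass[k] <- "canonical"; taken[i] <- TRUE; taken[j] <- TRUE
    }
  }
  gi <- match(na_rt$key[cand[, 1]], rt$key)
  gj <- match(na_rt$key[cand[, 2]], rt$key)
  swap <- gi > gj
  ki <- ifelse(swap, na_rt$key[cand[, 2]], na_rt$key[cand[, 1]])
  kj <- ifelse(swap, na_rt$key[cand[, 1]], na_rt$key[cand[, 2]])
  data.frame(key_i = ki, key_j = kj, klass = klass,
             intermolecular = na_rt$chain[cand[, 1]] != na_rt$chain[cand[, 2]],
             stringsAsFactors = FALSE)
}

#' Decode a dot-bracket string into base pairs
#'
#' Supports multi-layer pseudoknot alphabets: `()`, `[]`, `{}`, `<>` and
#' letter layers (uppercase opens, matching lowercase closes).
#'
#' @param db dot-bracket string; dots (and `.`-like characters `,:-_`) are
#'   unpaired.
#' @return data.frame with 1-based positions `i < j` and the bracket
#'   `layer` (1 = first alphabet).
#' @export
parse_dotbracket <- function(db) {
  chars <- strsplit(db, "")[[1]]
  openers <- c("(", "[", "{", "<", LETTERS)
  closers <- c(")", "]", "}", ">", letters)
  stacks <- lapply(seq_along(openers), function(i) integer(0))
  out_i <- integer(0); out_j <- integer(0); out_l <- integer(0)
  for (p in seq_along(chars)) {
    ch <- chars[p]
    if (ch %in% c(".", ",", ":", "-", "_")) next
    oi <- match(ch, openers)
    if (!is.na(oi)) { stacks[[oi]] <- c(stacks[[oi]], p); next }
    ci <- match(ch, closers)
    if (!is.na(ci)) {
      if (length(stacks[[ci]]) == 0)
        stop("unbalanced bracket '", ch, "' at position ", p)
      i <- stacks[[ci]][length(stacks[[ci]])]
      stacks[[ci]] <- stacks[[ci]][-length(stacks[[ci]])]
      out_i <- c(out_i, i); out_j <- c(out_j, p); out_l <- c(out_l, ci)
      next
    }
    stop("unrecognised character '", ch, "' at position ", p)
  }
  left <- which(vapply(stacks, length, integer(1)) > 0)
  if (length(left))
    stop("unbalanced bracket '", openers[left[1]], "' opened at position ",
         stacks[[left[1]]][1])
  o <- order(out_i)
  data.frame(i = out_i[o], j = out_j[o], layer = out_l[o])
}

#' Ingest base-pair annotations from a file
#'
#' @param path dot-bracket text file (last non-empty line is the structure;
#'   an optional preceding line is the sequence) or a CSV with columns
#'   `chain_i,res_i,chain_j,res_j,klass`.
#' @param format `"dotbracket"` or `"csv"`.
#' @return For dot-bracket, a data.frame of 1-based positions `i`, `j`
#'   with `klass = "canonical"`; for CSV, a data.frame with residue keys
#'   `key_i`, `key_j` and `klass`. Duplicate rows are dropped with a
#'   warning.
#' @export
ingest_pairs <- function(path, format = c("dotbracket", "csv")) {
  format <- match.arg(format)
  if (format == "dotbracket") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^>", lines)]
    if (!length(lines)) stop("no dot-bracket line found in ", path)
    db <- trimws(lines[length(lines)])
    pp <- parse_dotbracket(db)
    return(data.frame(i = pp$i, j = pp$j, klass = "canonical",
                      stringsAsFactors = FALSE))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chain_i", "res_i", "chain_j", "res_j", "klass")
  if (!all(need %in% names(tab)))
    stop("pair CSV must have columns: ", paste(need, collapse = ", "))
  if (!all(tab$klass %in% c("canonical", "noncanonical")))
    stop("klass must be 'canonical' or 'noncanonical'")
  out <- data.frame(key_i = residue_key(tab$chain_i, tab$res_i),
                    key_j = residue_key(tab$chain_j, tab$res_j),
                    klass = tab$klass, stringsAsFactors = FALSE)
  id <- pair_id(out$key_i, out$key_j)
  if (anyDuplicated(id)) {
    warning("dropping ", sum(duplicated(id)), " duplicate pair(s)")
    out <- out[!duplicated(id), , drop = FALSE]
  }
  out
}

#' Classify base-pair topology into a pair inventory
#'
#' Canonical intramolecular pairs are tested for crossing (pseudoknot) and
#' singlet status against sequence positions in the global residue order;
#' intermolecular pairs are inventoried separately and excluded from the
#' topology predicates. Crossing uses the symmetric interleaving relation:
#' pairs (i,j) and (k,l) cross when `i<k<j<l` or `k<i<l<j`. A singlet is a
#' canonical pair with neither stacked neighbour pair (i+1,j-1) nor
#' (i-1,j+1) present.
#'
#' @param pairs data.frame with integer position columns `i`, `j`, a
#'   `klass` column, and optionally `intermolecular` (default `FALSE`).
#' @return list of class `pair_inventory` with pair-id character sets
#'   `all_canonical`, `crossed`, `singlet`, `noncanonical`,
#'   `intermolecular`.
#' @export
classify_topology <- function(pairs) {
  if (is.null(pairs$intermolecular))
    pairs$intermolecular <- rep(FALSE, nrow(pairs))
  if (nrow(pairs)) {
    swap <- pairs$i > pairs$j
    tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  }
  pid <- function(df) if (nrow(df)) paste(df$i, df$j, sep = "-") else character(0)
  canon <- pairs[pairs$klass == "canonical", , drop = FALSE]
  intra <- canon[!canon$intermolecular, , drop = FALSE]
  crossed <- character(0); singlet <- character(0)
  if (nrow(intra)) {
    n <- nrow(intra)
    is_crossed <- logical(n); is_singlet <- logical(n)
    key <- paste(intra$i, intra$j)
    for (a in seq_len(n)) {
      i <- intra$i[a]; j <- intra$j[a]
      k <- intra$i; l <- intra$j
      is_crossed[a] <- any((i < k & k < j & j < l) | (k < i & i < l & l < j))
      is_singlet[a] <- !(paste(i + 1, j - 1) %in% key ||
                         paste(i - 1, j + 1) %in% key)
    }
    crossed <- pid(intra[is_crossed, , drop = FALSE])
    singlet <- pid(intra[is_singlet, , drop = FALSE])
  }
  inv <- list(all_canonical = pid(canon),
              crossed = crossed,
              singlet = singlet,
              noncanonical = pid(pairs[pairs$klass == "noncanonical", ,
                                       drop = FALSE]),
              intermolecular = pid(canon[canon$intermolecular, , drop = FALSE]))
  class(inv) <- "pair_inventory"
  inv
}

#' Positions of residue-key pairs in a structure's global residue order
#'
#' @param pairs data.frame with `key_i`, `key_j` (and optional other
#'   columns, carried through).
#' @param structure the `na_structure` defining the residue order.
#' @return `pairs` with integer columns `i`, `j` added (chain-concatenated
#'   order) and `intermolecular` derived from chain membership.
#' @export
pairs_to_positions <- function(pairs, structure) {
  rt <- residue_table(structure)
  i <- match(pairs$key_i, rt$key); j <- match(pairs$key_j, rt$key)
  if (anyNA(i) || anyNA(j)) stop("pair references residue absent from structure")
  pairs$i <- pmin(i, j); pairs$j <- pmax(i, j)
  pairs$intermolecular <- rt$chain[i] != rt$chain[j]
  pairs
}

#' Precision, recall and F1 of predicted interactions
#'
#' A predicted pair matches a target pair when made of the same two
#' residues. Predicted pairs touching a reference-unresolved residue are
#' removed first and count neither for nor against the prediction. When
#' both sides are empty the result is a null score; when only the target is
#' empty, overprediction is penalised with F1 = 0.
#'
#' @param pred,target character vectors of pair ids (see [pair_id()]), or
#'   data.frames with `key_i`/`key_j`.
#' @param unresolved character vector of unresolved reference residue keys.
#' @return list of class `prf1`: `precision`, `recall`, `f1`, `null_score`.
#' @export
score_f1 <- function(pred, target, unresolved = character(0)) {
  as_ids <- function(x) {
    if (is.data.frame(x)) return(pair_id(x$key_i, x$key_j))
    unique(as.character(x))
  }
  pred <- as_ids(pred); target <- as_ids(target)
  if (length(unresolved)) {
    touches <- vapply(strsplit(pred, "--", fixed = TRUE),
                      function(p) any(p %in% unresolved), logical(1))
    pred <- pred[!touches]
  }
  if (!length(pred) && !length(target))
    return(structure(list(precision = NA_real_, recall = NA_real_,
                          f1 = NA_real_, null_score = TRUE), class = "prf1"))
  if (!length(target))
    return(structure(list(precision = 0, recall = NA_real_, f1 = 0,
                          null_score = FALSE), class = "prf1"))
  tp <- sum(pred %in% target)
  precision <- if (length(pred)) tp / length(pred) else 0
  recall <- tp / length(target)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(precision = precision, recall = recall, f1 = f1,
                 null_score = FALSE), class = "prf1")
}

#' Aggregate per-model F1 scores into per-group means
#'
#' For each group and target the best score across submitted models and
#' references is kept, where a null score (correctly predicting no
#' interaction) beats any numeric score. Groups that skipped a target get
#' 0 for it. The group mean is taken over non-null targets.
#'
#' @param f1_table data.frame with columns `group`, `target`, `f1`
#'   (numeric, `NA` for null) and `null_score` (logical); one row per
#'   model x reference.
#' @param groups,targets full rosters; defaults to those present.
#' @return data.frame with `group`, `mean_f1`, `n_scored`.
#' @export
aggregate_f1 <- function(f1_table, groups = unique(f1_table$group),
                         targets = unique(f1_table$target)) {
  res <- lapply(groups, function(g) {
    vals <- vapply(targets, function(tg) {
      rows <- f1_table[f1_table$group == g & f1_table$target == tg, ,
                       drop = FALSE]
      if (nrow(rows) == 0) return(0)            # no submission -> 0
      if (any(rows$null_score)) return(NA_real_) # null is the best score
      max(rows$f1)
    }, numeric(1))
    data.frame(group = g, mean_f1 = mean(vals, na.rm = TRUE),
               n_scored = sum(!is.na(vals)), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
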
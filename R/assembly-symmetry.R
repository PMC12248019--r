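# Stoichiometry inference and Cn/Dn point-group detection for
# homo-oligomeric assemblies.

# sequence identity between two residue-name vectors (no-gap comparison at
# offset zero; sufficient for crystallisation-mutation tolerance)
chain_seq_identity <- function(a, b) {
  L <- min(length(a), length(b))
  if (L == 0) return(0)
  sum(a[seq_len(L)] == b[seq_len(L)]) / max(length(a), length(b))
}

# cluster polymer chains into entities at >= identity_threshold
entity_clusters <- function(structure, identity_threshold = 0.95) {
  rt <- residue_table(structure)
  rt <- rt[rt$polymer_type != "ligand", , drop = FALSE]
  chains <- unique(rt$chain)
  if (!length(chains)) stop("structure has no polymer chain")
  seqs <- lapply(chains, function(cid) rt$resname[rt$chain == cid])
  names(seqs) <- chains
  entity <- integer(length(chains)); names(entity) <- chains
  ne <- 0L
  reps <- list()
  for (cid in chains) {
    hit <- 0L
    for (e in seq_len(ne)) {
      if (chain_seq_identity(seqs[[cid]], reps[[e]]) >= identity_threshold) {
        hit <- e; break
      }
    }
    if (hit == 0L) { ne <- ne + 1L; hit <- ne; reps[[ne]] <- seqs[[cid]] }
    entity[cid] <- hit
  }
  split(chains, entity)
}

#' Infer assembly stoichiometry
#'
#' Polymer chains are clustered into entities at >= 95% sequence identity
#' (tolerating minor crystallisation mutations) and reported in the CASP
#' "A4B2" dialect, entities labelled by descending copy number.
#'
#' @param structure an `na_structure` with >= 1 polymer chain.
#' @param identity_threshold entity clustering threshold.
#' @return character stoichiometry string, with the chain-to-entity
#'   assignment in attribute `"entities"`.
#' @export
infer_stoichiometry <- function(structure, identity_threshold = 0.95) {
  cl <- entity_clusters(structure, identity_threshold)
  counts <- vapply(cl, length, integer(1))
  o <- order(-counts, seq_along(counts))
  lab <- LETTERS[seq_along(cl)]
  s <- paste0(lab, counts[o], collapse = "")
  ents <- stats::setNames(rep(lab, counts[o]), unlist(cl[o]))
  structure(s, entities = ents)
}

#' Stoichiometry prediction accuracy
#'
#' @param predictions character vector of predicted stoichiometry strings.
#' @param accepted character vector of accepted (experimentally derived)
#'   stoichiometries; any match counts as correct.
#' @return percentage of correct predictions.
#' @export
stoichiometry_accuracy <- function(predictions, accepted) {
  if (!length(accepted)) stop("empty accepted stoichiometry set")
  if (!length(predictions)) return(NA_real_)
  100 * mean(as.character(predictions) %in% as.character(accepted))
}

# rotation matrix about unit axis u by angle theta (Rodrigues)
rotation_about <- function(u, theta) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Detect Cn/Dn point-group symmetry of a homo-oligomer
#'
#' Candidate groups are cyclic Ck for every divisor k >= 2 of the chain
#' count n and dihedral Dk for 2k dividing n. Symmetry axes are taken from
#' the principal axes of the chain-centroid cloud (plus chain and
#' chain-pair directions for the perpendicular two-folds); each candidate
#' rotation induces a chain permutation by nearest centroid, and the fit
#' RMSD is the optimal rigid-transform RMSD between the structure and its
#' permuted self over phosphate/C-alpha atoms. Among candidates within the
#' RMSD cutoff the assignment with the most chains involved and then the
#' most symmetry elements wins, with dihedral preferred on ties (so D4
#' beats C8). C1 is the universal fallback.
#'
#' @param structure an `na_structure`.
#' @param rmsd_cutoff acceptance cutoff in Angstrom (default 10).
#' @return list of class `symmetry_assignment`: `group` ("C" or "D"),
#'   `order`, `chains_involved`, `n_elements`, `fit_rmsd`.
#' @export
detect_symmetry <- function(structure, rmsd_cutoff = 10) {
  c1 <- structure(list(group = "C", order = 1L, chains_involved = 1L,
                       n_elements = 1L, fit_rmsd = 0),
                  class = "symmetry_assignment")
  cl <- entity_clusters(structure)
  counts <- vapply(cl, length, integer(1))
  chains <- cl[[which.max(counts)]]
  n <- length(chains)
  if (n < 2) return(c1)
  c1$chains_involved <- n
  # phosphate (NA) / C-alpha (protein) coordinates per chain, truncated to
  # the common residue count
  rt <- residue_table(structure)
  a <- structure$atoms
  akey <- residue_key(a$chain, a$resno, a$insert)
  blocks <- lapply(chains, function(cid) {
    rr <- rt[rt$chain == cid & rt$resolved, , drop = FALSE]
    want <- ifelse(rr$polymer_type %in% c("RNA", "DNA"), "P", "CA")
    idx <- match(paste(rr$key, want), paste(akey, a$elety))
    alt <- match(paste(rr$key, "C4'"), paste(akey, a$elety))
    idx[is.na(idx)] <- alt[is.na(idx)]
    idx <- idx[!is.na(idx)]
    cbind(a$x[idx], a$y[idx], a$z[idx])
  })
  L <- min(vapply(blocks, nrow, integer(1)))
  if (L < 3) return(c1)
  blocks <- lapply(blocks, function(b) b[seq_len(L), , drop = FALSE])
  X <- do.call(rbind, blocks)
  centroids <- t(vapply(blocks, colMeans, numeric(3)))
  center <- colMeans(X)
  cen_c <- sweep(centroids, 2, center)

  eval_perm <- function(perm) {
    Xp <- do.call(rbind, blocks[perm])
    cpp_kabsch(X, Xp)$rmsd
  }
  perm_from_rotation <- function(R) {
    rot <- cen_c %*% t(R)
    perm <- integer(n)
    used <- logical(n)
    for (i in seq_len(n)) {
      d <- sqrt(rowSums(sweep(cen_c, 2, rot[i, ])^2))
      d[used] <- Inf
      j <- which.min(d)
      perm[i] <- j; used[j] <- TRUE
    }
    perm
  }
  cycle_lengths <- function(perm) {
    seen <- logical(n); out <- integer(0)
    for (s in seq_len(n)) {
      if (seen[s]) next
      len <- 0L; cur <- s
      while (!seen[cur]) { seen[cur] <- TRUE; cur <- perm[cur]; len <- len + 1L }
      out <- c(out, len)
    }
    out
  }
  ev <- eigen(stats::cov(cen_c), symmetric = TRUE)$vectors
  principal_axes <- lapply(1:3, function(i) ev[, i])

  divisors <- Filter(function(k) n %% k == 0, 2:n)
  cyc <- list()  # per k: list(rmsd, axis)
  for (k in divisors) {
    best <- NULL
    if (k == 2 && n == 2) {
      best <- list(rmsd = eval_perm(c(2L, 1L)), axis = NULL)
    } else {
      for (ax in principal_axes) {
        perm <- perm_from_rotation(rotation_about(ax, 2 * pi / k))
        if (!all(cycle_lengths(perm) == k)) next
        r <- eval_perm(perm)
        if (is.null(best) || r < best$rmsd) best <- list(rmsd = r, axis = ax)
      }
    }
    if (!is.null(best)) cyc[[as.character(k)]] <- best
  }
  candidates <- list()
  for (k in names(cyc)) {
    if (cyc[[k]]$rmsd <= rmsd_cutoff) {
      kk <- as.integer(k)
      candidates[[length(candidates) + 1]] <-
        list(group = "C", order = kk, n_elements = kk, fit_rmsd = cyc[[k]]$rmsd)
    }
  }
  # dihedral: main Ck axis plus a perpendicular two-fold
  for (k in divisors) {
    if ((n %% (2 * k)) != 0) next
    ck <- cyc[[as.character(k)]]
    if (is.null(ck) || ck$rmsd > rmsd_cutoff) next
    main <- ck$axis
    if (is.null(main)) main <- principal_axes[[1]]
    perp_cands <- list()
    for (i in seq_len(n)) perp_cands[[length(perp_cands) + 1]] <- cen_c[i, ]
    for (i in seq_len(n)) for (j in seq_len(i - 1))
      perp_cands[[length(perp_cands) + 1]] <- (cen_c[i, ] + cen_c[j, ]) / 2
    best2 <- Inf
    for (v in perp_cands) {
      v <- v - sum(v * main) * main / sum(main^2)
      nv <- sqrt(sum(v^2))
      if (nv < 1e-3) next
      perm <- perm_from_rotation(rotation_about(v, pi))
      if (any(perm == seq_len(n)) || !all(cycle_lengths(perm) == 2)) next
      r <- eval_perm(perm)
      if (r < best2) best2 <- r
    }
    if (best2 <= rmsd_cutoff) {
      candidates[[length(candidates) + 1]] <-
        list(group = "D", order = k, n_elements = 2L * k,
             fit_rmsd = max(ck$rmsd, best2))
    }
  }
  if (!length(candidates)) return(c1)
  # most chains involved (all candidates involve all n chains), then most
  # symmetry elements, dihedral over cyclic on ties
  pick <- candidates[[order(
    -vapply(candidates, `[[`, numeric(1), "n_elements"),
    vapply(candidates, function(cc) ifelse(cc$group == "D", 0, 1), numeric(1)),
    vapply(candidates, `[[`, numeric(1), "fit_rmsd"))[1]]]
  structure(list(group = pick$group, order = as.integer(pick$order),
                 chains_involved = n, n_elements = as.integer(pick$n_elements),
                 fit_rmsd = pick$fit_rmsd),
            class = "symmetry_assignment")
}

#' @export
print.symmetry_assignment <- function(x, ...) {
  cat(sprintf("%s%d symmetry (%d chains, %d elements, fit RMSD %.2f A)\n",
              x$group, x$order, x$chains_involved, x$n_elements, x$fit_rmsd))
  invisible(x)
}

#' Symmetry prediction accuracy
#'
#' @param predictions list of `symmetry_assignment` objects.
#' @param reference the reference `symmetry_assignment`.
#' @return percentage of predictions with the same (group, order), or `NA`
#'   for an empty prediction list.
#' @export
symmetry_accuracy <- function(predictions, reference) {
  if (!length(predictions)) return(NA_real_)
  100 * mean(vapply(predictions, function(p)
    p$group == reference$group && p$order == reference$order, logical(1)))
}
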
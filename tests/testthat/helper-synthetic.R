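# Shared fixtures and independent oracles used across the suite.

# small hairpin reference: 4-pair stem, 4-nt loop
make_hairpin <- function(seed = 2, id = "hp") {
  spec <- secstruct_spec("GGGGACGUCCCC", "((((....))))", id = id)
  build_structure(spec, seed = seed)
}

# random folded RNA of length L with optional pseudoknot
make_random_rna <- function(L, seed, pk = FALSE, id = paste0("r", seed)) {
  ss <- simulate_secstruct(L, seed = seed, pk = pk)
  build_structure(secstruct_spec(ss$sequence, ss$dotbracket, id = id),
                  seed = seed)
}

# rigid-motion copy of a structure
rigid_copy <- function(s, angle = 0.7, axis = c(1, 2, 3), shift = c(5, -3, 8)) {
  R <- nascore:::rotation_about(axis / sqrt(sum(axis^2)), angle)
  a <- s$atoms
  fin <- is.finite(a$x)
  xyz <- as.matrix(a[fin, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  a$x[fin] <- xyz[, 1]; a$y[fin] <- xyz[, 2]; a$z[fin] <- xyz[, 3]
  new_structure(s$id, a, s$source_format)
}

# --- independent oracles -------------------------------------------------

# quaternion-method rigid superposition RMSD (Horn 1987), independent of
# the SVD/Kabsch path
quaternion_rmsd <- function(X, Y) {
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[1, 3] + S[3, 1]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE)$values)
  ss <- sum(Xc^2) + sum(Yc^2) - 2 * lam
  sqrt(max(ss, 0) / nrow(X))
}

# plain R Kabsch used inside oracles (kept separate from the C++ path)
r_kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- t(sweep(X, 2, cx)) %*% sweep(Y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cy - as.numeric(R %*% cx))
}

apply_rt_r <- function(X, rt) sweep(X %*% t(rt$R), 2, rt$t, "+")

# brute-force TM-score: superpose on every contiguous fragment (all
# starts, all lengths >= 3), refine by closest-subset iteration
oracle_tm <- function(M, Rf, d0, Lnorm) {
  n <- nrow(M)
  best <- 0
  for (len in 3:n) for (s in 1:(n - len + 1)) {
    sel <- s:(s + len - 1)
    for (iter in 1:30) {
      rt <- r_kabsch(M[sel, , drop = FALSE], Rf[sel, , drop = FALSE])
      d <- sqrt(rowSums((apply_rt_r(M, rt) - Rf)^2))
      tm <- sum(1 / (1 + (d / d0)^2)) / Lnorm
      if (tm > best) best <- tm
      nsel <- which(d < max(d0 * 2, 3.5))
      if (length(nsel) < 3) nsel <- order(d)[1:4]
      if (identical(nsel, sel)) break
      sel <- nsel
    }
  }
  best
}

# brute-force GDT fraction: superpose on every residue subset of size >= 3
oracle_gdt_fraction <- function(M, Rf, thr) {
  n <- nrow(M)
  best <- 0
  idx <- seq_len(n)
  for (size in 3:n) {
    subsets <- utils::combn(idx, size, simplify = FALSE)
    for (sel in subsets) {
      rt <- r_kabsch(M[sel, , drop = FALSE], Rf[sel, , drop = FALSE])
      d <- sqrt(rowSums((apply_rt_r(M, rt) - Rf)^2))
      best <- max(best, sum(d <= thr))
    }
  }
  best / n
}

# literal re-implementation of the crossing / singlet predicates
oracle_topology <- function(pairs) {
  n <- nrow(pairs)
  crossed <- logical(n); singlet <- logical(n)
  for (a in seq_len(n)) {
    i <- pairs$i[a]; j <- pairs$j[a]
    for (b in seq_len(n)) {
      if (a == b) next
      k <- pairs$i[b]; l <- pairs$j[b]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j))
        crossed[a] <- TRUE
    }
    has_inner <- any(pairs$i == i + 1 & pairs$j == j - 1)
    has_outer <- any(pairs$i == i - 1 & pairs$j == j + 1)
    singlet[a] <- !has_inner && !has_outer
  }
  list(crossed = paste(pairs$i, pairs$j, sep = "-")[crossed],
       singlet = paste(pairs$i, pairs$j, sep = "-")[singlet])
}

# literal two-pass re-implementation of the trimmed Z procedure
oracle_trimmed_z <- function(values, outlier_sd = 2) {
  if (length(values) < 2)
    return(stats::setNames(rep(0, length(values)), names(values)))
  m0 <- mean(values); s0 <- stats::sd(values)
  if (is.na(s0) || s0 == 0)
    return(stats::setNames(rep(0, length(values)), names(values)))
  outlier <- values <= m0 - outlier_sd * s0
  kept <- values[!outlier]
  m1 <- mean(kept); s1 <- stats::sd(kept)
  if (is.na(s1) || s1 == 0)
    return(stats::setNames(rep(0, length(values)), names(values)))
  (values - m1) / s1
}

# representative-atom coordinate matrices for a (model, reference) pair
corr_coords <- function(model, reference) {
  corr <- residue_correspondence(model, reference)
  nascore:::corresponding_coords(model, reference, corr)
}
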
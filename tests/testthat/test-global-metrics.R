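# Superposition and the TM / GDT / lDDT / alignment metrics.

test_that("kabsch recovers rigid motions exactly", {
  X <- matrix(rnorm(15, sd = 5), 5, 3)
  sup <- kabsch_superpose(X, sweep(X, 2, c(1, 0, 0), "+"))
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  sup2 <- kabsch_superpose(X, X %*% t(Rz))
  expect_lt(sup2$rmsd, 1e-10)
  expect_equal(det(sup2$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch matches the quaternion oracle on random clouds", {
  set.seed(31)
  for (k in 1:25) {
    X <- matrix(rnorm(15, sd = 4), 5, 3)
    Y <- matrix(rnorm(15, sd = 4), 5, 3)
    expect_equal(kabsch_superpose(X, Y)$rmsd, quaternion_rmsd(X, Y),
                 tolerance = 1e-6)
  }
})

test_that("degenerate point sets are rejected", {
  X <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(X, X), "degenerate")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), "at least 3")
})

test_that("self-comparison scores are exactly one", {
  s <- make_random_rna(30, seed = 8)
  expect_identical(tm_score(s, s), 1)
  expect_identical(gdt_ts(s, s), 1)
  expect_identical(lddt(s, s), 1)
})

test_that("a single far-displaced residue gives the closed-form TM", {
  s <- make_random_rna(30, seed = 12)
  a <- s$atoms
  sel <- a$resno == 15
  a[sel, c("x", "y", "z")] <- a[sel, c("x", "y", "z")] + 500
  m <- new_structure("d", a)
  L <- 30
  d0 <- d0_for_length(L, "nucleic")
  got <- tm_score(m, s)
  # superposed on the intact 29, the displaced C4' sits ~500 A away
  cc <- corr_coords(m, s)
  d <- sqrt(sum((cc$model[15, ] - cc$reference[15, ])^2))
  expect_equal(got, (29 + 1 / (1 + (d / d0)^2)) / 30, tolerance = 1e-6)
})

test_that("rigidly displaced minority block caps the GDT fractions", {
  s <- make_random_rna(20, seed = 3)
  a <- s$atoms
  sel <- a$resno > 12   # 8 of 20 residues, moved far as a rigid group
  a[sel, c("x", "y", "z")] <- a[sel, c("x", "y", "z")] + 400
  m <- new_structure("d", a)
  expect_equal(gdt_ts(m, s), 12 / 20, tolerance = 1e-9)
})

test_that("GDT matches the exhaustive subset-superposition oracle", {
  s <- make_random_rna(10, seed = 21)
  m <- perturb_model(s, perturbation_spec(1.5, "gaussian", seed = 7))
  cc <- corr_coords(m, s)
  for (thr in c(2, 4)) {
    got <- cpp_gdt_count(cc$model, cc$reference, thr) / 10
    want <- oracle_gdt_fraction(cc$model, cc$reference, thr)
    expect_lte(abs(got - want), 0.05)
  }
})

test_that("TM search matches a dense-seed brute-force oracle", {
  for (seed in c(5, 17)) {
    s <- make_random_rna(25, seed = seed)
    m <- perturb_model(s, perturbation_spec(1, "gaussian", seed = seed + 50))
    cc <- corr_coords(m, s)
    d0 <- d0_for_length(25, "nucleic")
    got <- cpp_tm_search(cc$model, cc$reference, d0, 25)
    want <- oracle_tm(cc$model, cc$reference, d0, 25)
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("lDDT equals a hand-enumerated fraction on a 3-residue toy", {
  mk <- function(xyz) {
    a <- data.frame(chain = "A", resno = rep(1:3, each = 2), insert = "",
                    resname = "A",
                    elety = rep(c("C4'", "C1'"), 3),
                    element = "C",
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    new_structure("toy", a)
  }
  ref_xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0),
                   c(6, 0, 0), c(7.5, 0, 0),
                   c(12, 0, 0), c(13.5, 0, 0))
  mod_xyz <- ref_xyz
  mod_xyz[5, 1] <- 14   # residue 3's C4' shifted 2 A
  ref <- mk(ref_xyz); mod <- mk(mod_xyz)
  # manual enumeration over all inter-residue atom pairs within 15 A
  pars <- lddt_params()
  total <- 0; per_thr <- stats::setNames(numeric(4), pars$thresholds)
  for (i in 1:6) for (j in 1:6) {
    if (i >= j) next
    ri <- (i + 1) %/% 2; rj <- (j + 1) %/% 2
    if (ri == rj) next
    dr <- abs(ref_xyz[i, 1] - ref_xyz[j, 1])
    if (dr > 15) next
    dm <- abs(mod_xyz[i, 1] - mod_xyz[j, 1])
    total <- total + 1
    for (th in pars$thresholds)
      if (abs(dm - dr) < th)
        per_thr[as.character(th)] <- per_thr[as.character(th)] + 1
  }
  expect_equal(lddt(mod, ref), mean(per_thr / total))
})

test_that("steric clashes lower the lDDT", {
  s <- make_random_rna(15, seed = 9)
  m <- perturb_model(s, perturbation_spec(0.4, "gaussian", seed = 2))
  a <- m$atoms
  # fuse two atoms from different residues at one point
  src <- which(a$resno == 3 & a$elety == "C4'")
  dst <- which(a$resno == 10 & a$elety == "C4'")
  a[dst, c("x", "y", "z")] <- a[src, c("x", "y", "z")] + 0.01
  clashed <- new_structure("c", a)
  expect_lt(lddt(clashed, s), lddt(m, s))
})

test_that("metrics are invariant to rigid motion of the model", {
  s <- make_random_rna(20, seed = 14)
  m <- perturb_model(s, perturbation_spec(1, "gaussian", seed = 5))
  mm <- rigid_copy(m)
  expect_equal(tm_score(mm, s), tm_score(m, s), tolerance = 1e-6)
  expect_equal(gdt_ts(mm, s), gdt_ts(m, s), tolerance = 1e-6)
  expect_equal(lddt(mm, s), lddt(m, s), tolerance = 1e-9)
})

test_that("mean scores degrade monotonically with perturbation size", {
  s <- make_random_rna(25, seed = 30)
  sigmas <- c(0, 0.5, 1, 2, 4)
  means <- sapply(sigmas, function(sg) {
    vals <- sapply(1:20, function(k) {
      m <- perturb_model(s, perturbation_spec(sg, "gaussian",
                                              seed = 1000 * k + sg * 10))
      c(tm_score(m, s), gdt_ts(m, s), lddt(m, s))
    })
    rowMeans(vals)
  })
  for (r in 1:3) expect_true(all(diff(means[r, ]) < 0))
})

test_that("structural alignment is sequence-independent and self-exact", {
  s <- make_random_rna(25, seed = 16)
  expect_equal(tm_align(s, s)$score, 1, tolerance = 1e-9)
  # renumber and relabel residues: score must stay 1
  a <- s$atoms
  a$resno <- a$resno + 40
  a$resname <- rep(c("C", "G", "U", "A", "G"),
                   length.out = nrow(a) / 5)[rep(seq_len(nrow(a) / 5), each = 5)]
  relab <- new_structure("relab", a)
  expect_equal(tm_align(relab, s)$score, 1, tolerance = 1e-9)
})

test_that("unrelated random walks score below the fold threshold", {
  vals <- sapply(1:8, function(k)
    tm_align(random_walk_structure(40, seed = k),
             random_walk_structure(40, seed = 200 + k))$score)
  expect_lt(max(vals), 0.3)
})

test_that("fixed-correspondence TM never exceeds the aligned score", {
  for (seed in c(3, 11, 27)) {
    s <- make_random_rna(25, seed = seed)
    m <- perturb_model(s, perturbation_spec(1.5, "gaussian", seed = seed + 5))
    expect_lte(tm_score(m, s), tm_align(m, s)$score + 1e-9)
  }
})

test_that("the best score per metric is kept across references", {
  s <- make_random_rna(20, seed = 40)
  ref2 <- perturb_model(s, perturbation_spec(1.5, "gaussian", seed = 41))
  ref2$id <- "alt"
  m <- perturb_model(s, perturbation_spec(0.8, "gaussian", seed = 42))
  best <- score_against_references(m, list(s, ref2))
  single1 <- score_against_references(m, list(s))
  single2 <- score_against_references(m, list(ref2))
  for (met in names(best))
    expect_equal(best[[met]], max(single1[[met]], single2[[met]]))
})
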
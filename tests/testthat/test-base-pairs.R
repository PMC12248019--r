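# Base-pair annotation, ingestion, topology and F1 conventions.

test_that("an ideal stem is annotated with exactly its canonical pairs", {
  s <- build_structure(secstruct_spec("GGGGAAAACCCC", "((((....))))"),
                       seed = 6)
  bp <- annotate_pairs(s)
  canon <- bp[bp$klass == "canonical", ]
  pos <- pairs_to_positions(canon, s)
  expect_setequal(paste(pos$i, pos$j), c("1 12", "2 11", "3 10", "4 9"))
  expect_false(any(canon$intermolecular))
})

test_that("an extended single strand has no pairs", {
  s <- build_structure(secstruct_spec(strrep("A", 20)), seed = 4)
  expect_equal(nrow(annotate_pairs(s)), 0)
})

test_that("duplex pairs are flagged intermolecular", {
  spec <- secstruct_spec("GGGGGGAAACCCCCCAAA", "((((((...))))))...",
                         chain_ends = 9)
  dup <- build_structure(spec, seed = 3)
  canon <- annotate_pairs(dup)
  canon <- canon[canon$klass == "canonical", ]
  expect_equal(nrow(canon), 6)
  expect_true(all(canon$intermolecular))
})

test_that("wobble pairs count as canonical and tilted pairs do not", {
  s <- build_structure(secstruct_spec("GGGGAAAAUUCC", "((((....))))"),
                       seed = 6)
  canon <- annotate_pairs(s)
  canon <- canon[canon$klass == "canonical", ]
  pos <- pairs_to_positions(canon, s)
  expect_true("3 10" %in% paste(pos$i, pos$j))  # G-U wobble
  # forced non-canonical geometry on an extra pair
  s2 <- build_structure(secstruct_spec("GGGGAAAAUUCCAAAGAAAC",
                                       "((((....))))........",
                                       noncanonical = data.frame(i = 16, j = 20)),
                        seed = 6)
  bp2 <- annotate_pairs(s2)
  pos2 <- pairs_to_positions(bp2, s2)
  row <- pos2[pos2$i == 16 & pos2$j == 20, ]
  expect_equal(nrow(row), 1)
  expect_equal(row$klass, "noncanonical")
})

test_that("dot-bracket decoding handles layers and reports imbalance", {
  expect_equal(parse_dotbracket("((..))")[, c("i", "j")],
               data.frame(i = c(1, 2), j = c(6, 5)))
  got <- parse_dotbracket("((..[[..))..]]")
  expect_setequal(paste(got$i, got$j),
                  c("1 10", "2 9", "5 14", "6 13"))
  expect_error(parse_dotbracket("((..)"), "position 1")
  expect_error(parse_dotbracket("(..))"), "position 5")
})

test_that("pair CSV ingestion validates and de-duplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("chain_i,res_i,chain_j,res_j,klass",
               "A,1,A,10,canonical",
               "A,2,A,9,canonical",
               "A,1,A,10,canonical"), f)
  expect_warning(got <- ingest_pairs(f, "csv"), "duplicate")
  expect_equal(nrow(got), 2)
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">seq", "GGGAAACCC", "(((...)))"), f2)
  db <- ingest_pairs(f2, "dotbracket")
  expect_equal(nrow(db), 3)
})

test_that("topology classification matches the worked examples", {
  inv <- classify_topology(data.frame(i = c(1, 2, 5), j = c(10, 9, 15),
                                      klass = "canonical"))
  expect_setequal(inv$crossed, c("1-10", "2-9", "5-15"))
  expect_equal(inv$singlet, "5-15")
  nested <- classify_topology(data.frame(i = 1:3, j = 10:8,
                                         klass = "canonical"))
  expect_length(nested$crossed, 0)
  expect_length(nested$singlet, 0)
  lone <- classify_topology(data.frame(i = 4, j = 20, klass = "canonical"))
  expect_length(lone$crossed, 0)
  expect_equal(lone$singlet, "4-20")
  empty <- classify_topology(data.frame(i = integer(0), j = integer(0),
                                        klass = character(0)))
  expect_length(empty$all_canonical, 0)
})

test_that("intermolecular pairs stay out of the topology predicates", {
  pairs <- data.frame(i = c(1, 2, 5), j = c(10, 9, 15),
                      klass = "canonical",
                      intermolecular = c(FALSE, FALSE, TRUE))
  inv <- classify_topology(pairs)
  expect_equal(inv$intermolecular, "5-15")
  expect_length(inv$crossed, 0)   # the crossing partner is intermolecular
  expect_length(inv$singlet, 0)
})

test_that("crossing agrees with the literal predicate on random structures", {
  for (seed in 1:120) {
    ss <- simulate_secstruct(sample(25:60, 1), seed = seed, pk = TRUE)
    pp <- parse_dotbracket(ss$dotbracket)
    pairs <- data.frame(i = pp$i, j = pp$j, klass = "canonical")
    inv <- classify_topology(pairs)
    want <- oracle_topology(pairs)
    expect_setequal(inv$crossed, want$crossed)
    expect_setequal(inv$singlet, want$singlet)
  }
})

test_that("crossing is symmetric", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(3:8, 1)
    i <- sample(1:30, n); j <- i + sample(5:20, n, replace = TRUE)
    pairs <- data.frame(i = i, j = j, klass = "canonical")
    inv <- classify_topology(pairs)
    # brute-force symmetric check
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      ia <- min(i[a], j[a]); ja <- max(i[a], j[a])
      ib <- min(i[b], j[b]); jb <- max(i[b], j[b])
      ab <- ia < ib && ib < ja && ja < jb
      ba <- ib < ia && ia < jb && jb < ja
      if (ab || ba) {
        expect_true(paste(ia, ja, sep = "-") %in% inv$crossed)
        expect_true(paste(ib, jb, sep = "-") %in% inv$crossed)
      }
    }
  }
})

test_that("F1 follows the null / overprediction / formula conventions", {
  both <- score_f1(c("1--10", "2--9"), c("1--10", "2--9"))
  expect_equal(both$f1, 1)
  half <- score_f1("1--10", c("1--10", "3--8"))
  expect_equal(half$precision, 1)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f1, 2 / 3)
  over <- score_f1("1--10", character(0))
  expect_equal(over$f1, 0)
  expect_false(over$null_score)
  nul <- score_f1(character(0), character(0))
  expect_true(nul$null_score)
  expect_true(is.na(nul$f1))
})

test_that("swapping prediction and target swaps precision and recall", {
  pred <- c("1--10", "2--9", "4--7")
  target <- c("1--10", "3--8")
  a <- score_f1(pred, target); b <- score_f1(target, pred)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)
  expect_equal(a$f1, b$f1)
})

test_that("pairs touching unresolved residues count neither way", {
  target <- c("A|1|--A|10|", "A|2|--A|9|")
  pred <- c("A|1|--A|10|", "A|5|--A|20|")
  scored <- score_f1(pred, target, unresolved = "A|20|")
  expect_equal(scored$precision, 1)   # the unresolved pair was removed
  expect_equal(scored$recall, 0.5)
  # removing unresolved-touching pairs never changes recall
  with_pair <- score_f1(pred, target)
  expect_equal(scored$recall, with_pair$recall)
})

test_that("aggregation takes best-of-models with null beating numeric", {
  tab <- data.frame(
    group = c("g1", "g1", "g1", "g1", "g2"),
    target = c("T1", "T1", "T2", "T2", "T1"),
    f1 = c(0.2, 1.0, 0.4, NA, 0.5),
    null_score = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  got <- aggregate_f1(tab, groups = c("g1", "g2"), targets = c("T1", "T2"))
  g1 <- got[got$group == "g1", ]
  # T1: best of 5 models = 1.0; T2: null wins and is excluded from the mean
  expect_equal(g1$mean_f1, 1.0)
  expect_equal(g1$n_scored, 1L)
  # g2 skipped T2 entirely -> 0 for it
  g2 <- got[got$group == "g2", ]
  expect_equal(g2$mean_f1, mean(c(0.5, 0)))
})
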
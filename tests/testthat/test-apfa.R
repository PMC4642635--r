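test_that("a degenerate single-chain model validates cleanly", {
  expect_identical(validateApfa(chainApfa(5L)), character(0))
  expect_identical(validateApfa(diamondApfa()), character(0))
})

test_that("unnormalized outgoing probabilities yield one diagnostic", {
  a <- diamondApfa(pr = c(0.5, 0.4))
  d <- validateApfa(a)
  expect_length(d, 1L)
  expect_match(d, "outgoing probabilities sum to 0.9")
})

test_that("an edge skipping a level is reported as a leveling violation", {
  # vertex U is a target at level 1 but a source of a level-2 edge
  a <- Apfa(level = c(0L, 1L, 2L),
            source = c("R", "M", "U"),
            target = c("U", "N", "S"),
            allele = c("0", "0", "0"),
            prob = c(1, 1, 1))
  d <- validateApfa(a)
  expect_true(any(grepl("vertex U: inconsistent level", d)))
})

test_that("path probability is the product of edge probabilities", {
  ch <- chainApfa(6L)
  expect_equal(haplotypeProbability(ch, apfaEdges(ch)$id), 1.0)

  dm <- diamondApfa(pr = c(0.3, 0.7))
  paths <- enumeratePaths(dm)
  probs <- vapply(paths, function(pp) haplotypeProbability(dm, pp), 0)
  expect_setequal(probs, c(0.3, 0.7))
  expect_equal(sum(probs), 1.0)

  z <- diamondApfa(pr = c(0, 1))
  p0 <- Find(function(pp) "L0E0" %in% pp, enumeratePaths(z))
  expect_equal(haplotypeProbability(z, p0), 0.0)
})

test_that("path probabilities sum to one over exhaustive enumeration", {
  set.seed(11)
  for (rep in 1:5) {
    p <- sample(2:6, 1L)
    haps <- matrix(as.character(sample(0:2, 40L * p, TRUE)), 40L, p)
    a <- buildTrieApfa(haps)
    tot <- sum(vapply(enumeratePaths(a),
                      function(pp) haplotypeProbability(a, pp), 0))
    expect_equal(tot, 1.0, tolerance = 1e-12)
  }
})

test_that("disconnected or malformed paths are rejected", {
  dm <- diamondApfa()
  ed <- apfaEdges(dm)
  lv0 <- ed$id[ed$level == 0L]
  # both level-0 branches lead to different vertices; crossing them over
  # against the level-1 continuation breaks connectivity
  paths <- enumeratePaths(dm)
  good <- paths[[1L]]
  badTail <- setdiff(ed$id[ed$level == 1L], good[2L])
  expect_error(haplotypeProbability(dm, c(good[1L], badTail)),
               "do not share a vertex")
  expect_error(haplotypeProbability(dm, good[1L]), "levels")
  expect_error(haplotypeProbability(dm, c("nope", good[2L])), "unknown edge")
})

test_that("trie construction reproduces empirical haplotype frequencies", {
  # four identical haplotypes collapse to a chain with unit probabilities
  a <- buildTrieApfa(matrix("1", 4L, 3L))
  expect_identical(nrow(apfaEdges(a)), 3L)
  expect_true(all(apfaEdges(a)$prob == 1))

  # {00, 01}: split at level 1 with probabilities 0.5 / 0.5
  b <- buildTrieApfa(rbind(c("0", "0"), c("0", "1")))
  ed <- apfaEdges(b)
  expect_equal(sort(ed$prob[ed$level == 1L]), c(0.5, 0.5))
  expect_equal(ed$prob[ed$level == 0L], 1)

  expect_error(buildTrieApfa(list()), "no haplotypes")
  expect_error(buildTrieApfa(list(c("0", "1"), c("0"))), "ragged")

  # distinct prefixes: model probability equals empirical frequency
  set.seed(4)
  haps <- matrix(as.character(sample(0:1, 60L, TRUE)), 20L, 3L)
  a <- buildTrieApfa(haps)
  key <- apply(haps, 1L, paste, collapse = "")
  emp <- table(key) / nrow(haps)
  gen <- haplotypesToGenomes(structure(haps, dimnames = list(
    rep(paste0("i", 1:10), each = 2L), NULL)), a)
  for (g in gen) {
    k1 <- paste(haps[match(g@id, paste0("i", 1:10)) * 2L - 1L, ],
                collapse = "")
    expect_equal(haplotypeProbability(a, g@hap1), unname(emp[k1]),
                 tolerance = 1e-12)
  }
})

test_that("native TSV round trip is the identity", {
  a <- buildTrieApfa(rbind(c("0", "0", "1"), c("0", "1", "1"),
                           c("1", "0", "0"), c("0", "0", "0")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeApfa(a, f)
  b <- readApfa(f)
  expect_equal(apfaEdges(b), apfaEdges(a))
  expect_identical(nIntervals(b), nIntervals(a))
})

test_that("parse errors cite the offending line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("level\tsource\ttarget\tallele\tprob",
               "0\tR\tU\t0\t1",
               "1\tU\tS\t0\tx"), f)
  expect_error(readApfa(f), "line 3.*non-numeric prob")

  writeLines(c("level\tsource\ttarget\tallele", "0\tR\tU\t0"), f)
  expect_error(readApfa(f), "missing column")

  writeLines(c("level\tsource\ttarget\tallele\tprob",
               "0\tR\tU\t0\t1",
               "2\tU\tS\t0\t1"), f)
  expect_error(readApfa(f), "gap")
})

test_that("a written fixture with five edges reads back with |E| = 5", {
  dmf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("level\tsource\ttarget\tallele\tprob",
               "0\tR\tU\t0\t0.25",
               "0\tR\tW\t1\t0.75",
               "1\tU\tS\t0\t1",
               "1\tW\tS\t0\t0.5",
               "1\tW\tS\t1\t0.5"), dmf)
  a <- readApfa(dmf)
  expect_identical(nrow(apfaEdges(a)), 5L)
  expect_identical(validateApfa(a), character(0))
})

test_that("Beagle DAG counts are normalized per parent node", {
  f <- withr::local_tempfile(fileext = ".dag")
  writeLines(c("# comment line",
               "0 r a 0 6",
               "0 r b 1 4",
               "1 a s 0 10",
               "1 b s 0 10"), f)
  a <- readBeagleDag(f)
  ed <- apfaEdges(a)
  expect_equal(sort(ed$prob[ed$level == 0L]), c(0.4, 0.6))
  expect_identical(validateApfa(a), character(0))

  writeLines(c("# only", "# comments"), f)
  expect_error(readBeagleDag(f), "no data rows")

  writeLines(c("0 r a 0 5", "0 r b 1 5", "1 a s 0 1", "1 b s 0 1"), f)
  expect_equal(sort(apfaEdges(readBeagleDag(f))$prob[1:2]), c(0.5, 0.5))

  writeLines(c("0 r a 0 5", "0 r b"), f)
  expect_error(readBeagleDag(f), "line 2")

  writeLines(c("0 r a 0 0", "1 a s 0 1"), f)
  expect_error(readBeagleDag(f), "zero total count")
})

test_that("duplicate parallel edges are collapsed on construction", {
  a <- Apfa(level = c(0L, 0L, 0L, 1L),
            source = c("R", "R", "R", "U"),
            target = c("U", "U", "U", "S"),
            allele = c("0", "0", "1", "0"),
            prob = c(0.25, 0.25, 0.5, 1))
  ed <- apfaEdges(a)
  expect_identical(nrow(ed), 3L)
  expect_equal(ed$prob[ed$level == 0L & ed$allele == "0"], 0.5)
})
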
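test_that("six-frame translation follows the genetic code and frame conventions", {
  p <- translateSixFrames("ATGGCC")
  expect_equal(unname(p["+1"]), "MA")
  expect_equal(unname(translateSixFrames("GGCCAT")["-1"]), "MA")
  expect_equal(unname(translateSixFrames("ATGNCC")["+1"]), "MX")
  # trailing remainder dropped; internal stops kept
  expect_equal(unname(translateSixFrames("ATGTAAATGG")["+1"]), "M*M")
  expect_error(translateSixFrames(""), "empty")
})

test_that("frame -k of s equals frame +k of the reverse complement", {
  set.seed(9)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1), TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    f <- translateSixFrames(s)
    g <- translateSixFrames(rc)
    for (k in 1:3)
      expect_identical(unname(f[paste0("-", k)]), unname(g[paste0("+", k)]))
  }
})

test_that("profiles are normalized and recover the generating frequencies", {
  msa <- c(a = "AAC", b = "AAD", c = "AA-")
  prof <- buildProfile(msa)
  expect_equal(colSums(prof$freq), rep(1, 3), tolerance = 1e-12)
  # all-'A' column: A dominates (pseudocount 0.1 per residue keeps the rest tiny)
  expect_gt(prof$freq["A", 1], 0.5)
  expect_gt(prof$freq["A", 1], 10 * max(prof$freq[-1, 1]))
  # long simulation: column frequencies correlate with the model's pi
  m <- loadEmpiricalModel("WAG")
  tree <- randomTree(6, seed = 71)
  sim <- evolveAlignment(tree, m, 5000, seed = 72)
  prof <- buildProfile(sim, m)
  obs <- rowMeans(prof$freq)
  expect_gt(cor(obs, m@pi), 0.9)
})

test_that("profile alignment matches the naive DP oracle on small cases", {
  set.seed(15)
  for (i in 1:20) {
    ncol <- sample(4:10, 1)
    npep <- sample(2:8, 1)
    emit <- matrix(rnorm(npep * ncol, sd = 3), npep, ncol)
    dp <- phyloplace:::.alignDP(emit)
    got <- max(dp$M[npep + 1, ], dp$Ix[npep + 1, ])
    expect_equal(got, naiveGlocalScore(emit), tolerance = 1e-9)
  }
})

test_that("self- and sub-alignments land on their own reference columns", {
  pk <- simulateRefPackage(6, 120, seed = 81)
  rows <- setNames(as.character(pk$refpkg@msa), names(pk$refpkg@msa))
  prof <- buildProfile(rows)
  # an ungapped reference row aligns to itself
  aln <- alignToReference(rows[["t001"]], prof)
  expect_identical(aln$row, rows[["t001"]])
  # the middle 50 columns fill exactly those columns
  sub <- substr(rows[["t002"]], 31, 80)
  aln2 <- alignToReference(sub, prof)
  expect_identical(substr(aln2$row, 31, 80), sub)
  expect_identical(gsub("-", "", aln2$row), sub)
})

test_that("frame selection recovers planted frames and flags random sequence", {
  pk <- simulateRefPackage(8, 150, seed = 91)
  rows <- setNames(as.character(pk$refpkg@msa), names(pk$refpkg@msa))
  prof <- buildProfile(rows)
  hits <- 0L
  for (i in 1:20) {
    g <- synthGenome(setNames(substr(rows[["t001"]], 1, 100), "m"),
                     spacer = 40, seed = 1000 + i)
    # cut a 300 nt window overlapping the marker
    frag <- substr(g$sequence, g$meta$start - 20, g$meta$start + 279)
    sel <- selectFrame(translateSixFrames(frag), prof)
    aln <- alignToReference(translateSixFrames(frag)[[sel$frame]], prof)
    if (sum(strsplit(aln$row, "")[[1]] != "-") >= 50 &&
        grepl(substr(gsub("-", "", rows[["t001"]]), 10, 30),
              gsub("-", "", aln$row), fixed = TRUE))
      hits <- hits + 1L
  }
  expect_gte(hits, 16L)
  # a random peptide scores below the shuffle-null threshold
  set.seed(5)
  pep <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 100,
                      TRUE), collapse = "")
  thr <- frameScoreNull(pep, prof, n = 50, seed = 6)
  expect_false(selectFrame(translateSixFrames(
    synthGenome(c(m = pep), spacer = 0, seed = 8)$sequence)[1:6],
    prof, threshold = Inf)$detected)
  real <- selectFrame(translateSixFrames(
    substr(synthGenome(setNames(gsub("-", "", rows[["t002"]]), "m"),
                       spacer = 0, seed = 9)$sequence, 1, 300)), prof,
    threshold = thr)
  expect_true(real$detected)
})

test_that("the hand-traced 12-column trimming toy reproduces its mask", {
  rows <- c(
    r1 = "-AAAAAACCCAA",
    r2 = "-AAAGRACCD-D",
    r3 = "-AACKNCCCC-K",
    r4 = "AAADDDCCCDAL"
  )
  # columns: 1 gappy; 2,3 highly conserved; 4-7 nonconserved island;
  # 8,9 highly conserved; 10-12 nonconserved tail
  mask <- trimColumns(rows)
  expect_identical(mask, c(FALSE, rep(TRUE, 8), FALSE, FALSE, FALSE))
  # idempotence: trimming the trimmed alignment removes nothing
  trimmed <- applyMask(rows, mask)
  expect_true(all(trimColumns(trimmed)))
})

test_that("gap-majority columns fall to the half-gap rule; identical rows survive whole", {
  rows <- c(a = "A", b = "-", c = "-", d = "-", e = "A")   # 60% gaps
  expect_identical(trimColumns(rows), FALSE)
  rows2 <- setNames(rep("MKVAW", 4), letters[1:4])
  expect_true(all(trimColumns(rows2)))
  # trimming idempotence on random gappy alignments
  set.seed(123)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV-", "")[[1]]
  for (i in 1:5) {
    rows <- vapply(1:6, function(j)
      paste(sample(aa, 40, TRUE, prob = c(rep(1, 20), 8)), collapse = ""),
      "")
    names(rows) <- paste0("s", 1:6)
    mask <- trimColumns(rows)
    if (any(mask))
      expect_true(all(trimColumns(applyMask(rows, mask))))
  }
})

test_that("the post-trim length filter is inclusive at the boundary", {
  expect_false(lengthFilter(paste0(strrep("M", 49), strrep("-", 30))))
  expect_true(lengthFilter(paste0(strrep("M", 50), strrep("-", 30))))
  expect_false(lengthFilter(""))
  expect_false(lengthFilter(strrep("-", 100)))
})

test_that("marker concatenation adds columns and log-likelihoods", {
  tree <- randomTree(5, seed = 201)
  m <- loadEmpiricalModel("WAG")
  msa1 <- evolveAlignment(tree, m, 100, seed = 202)
  msa2 <- evolveAlignment(tree, m, 120, seed = 203)
  cc <- concatenateMarkers(list(m1 = msa1, m2 = msa2))
  expect_equal(unique(nchar(cc$msa)), 220L)
  # single marker passes through
  expect_identical(concatenateMarkers(list(m1 = msa1))$msa[sort(names(msa1))],
                   msa1[sort(names(msa1))])
  # independent sites: logL of the concatenation is the sum of parts
  expect_equal(logLikelihood(tree, cc$msa, m),
               logLikelihood(tree, msa1, m) + logLikelihood(tree, msa2, m),
               tolerance = 1e-8)
  # query rows: a missing marker becomes gaps
  q <- concatenateMarkers(list(m1 = msa1, m2 = msa2),
                          queryRows = list(m1 = msa1[[1]]))
  expect_equal(nchar(q$query), 220L)
  expect_identical(substr(q$query, 101, 220), strrep("-", 120))
  # mismatched taxon sets are rejected
  expect_error(concatenateMarkers(list(m1 = msa1, m2 = msa2[-1])),
               "mismatched")
})
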
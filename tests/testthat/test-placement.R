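test_that("a query identical to a reference leaf lands on its pendant branch", {
  fix <- smallFixture()
  leaf <- "t004"
  query <- as.character(fix$pkg@msa[[leaf]])
  res <- placeQueryML(fix$fitted, query, "copy")
  rt <- fix$fitted@tree
  # pendant branch of the leaf = branch whose distal side is exactly {leaf}
  splits <- phyloplace:::.edgeSplits(rt@phy)
  pend <- rt@branchId[which(vapply(splits, identical, TRUE, leaf))]
  expect_equal(bestBranch(res), pend)
  tb <- placements(res)
  expect_lt(tb$pendant[1], 1e-6)
})

test_that("insertion conserves the split of the original branch length", {
  fix <- smallFixture()
  q <- plantQuery(fix$sim, branch = 1, pendant = 0.1, seed = 55)
  res <- placeQueryML(fix$fitted, q$query, "q")
  tb <- res@table
  bl <- branchLengths(fix$fitted)
  expect_equal(tb$distal + tb$proximal, unname(bl[as.character(tb$branch)]),
               tolerance = 1e-9)
  expect_true(all(tb$pendant >= 1e-8 - 1e-15))
  expect_true(all(is.finite(tb$logLik)))
})

test_that("a huge pendant length decouples the query (saturation limit)", {
  fix <- smallFixture()
  eng <- fix$fitted@engine
  q <- plantQuery(fix$sim, branch = 0, pendant = 0.3, seed = 3)
  qcode <- phyloplace:::.encodeSeq(q$query)
  jp <- phyloplace:::.jointPatterns(eng, qcode)
  e <- which(eng$branchId == 4L)
  # the pendant must saturate even the slowest Gamma rate category
  sl <- phyloplace:::.insertionSiteLogLik(eng, eng$msgs$up[[e]],
                                          eng$msgs$down[[e]], jp,
                                          eng$lens[e] / 2, eng$lens[e] / 2,
                                          1000)
  got <- sum(jp$jw * sl)
  expected <- fix$fitted@logLik +
    sum(log(fix$fitted@model@pi[qcode[qcode > 0]]))
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("placement rejects uninformative queries and is order-independent", {
  fix <- smallFixture()
  nsite <- fix$fitted@engine$nsite
  expect_error(placeQueryML(fix$fitted, strrep("X", nsite), "allx"),
               "informative")
  expect_error(placeQueryML(fix$fitted, "MKV", "short"), "columns")
  # determinism: repeated scoring gives the identical table
  q <- plantQuery(fix$sim, branch = 6, pendant = 0.05, seed = 12)
  r1 <- placeQueryML(fix$fitted, q$query, "q")
  r2 <- placeQueryML(fix$fitted, q$query, "q")
  expect_identical(r1@table, r2@table)
  # scoring one branch directly agrees with the full table
  one <- scoreInsertion(fix$fitted, q$query, 3L)
  expect_equal(one$logLik, r1@table$logLik[r1@table$branch == 3L],
               tolerance = 1e-9)
})

test_that("candidate selection takes the ceiling and always keeps rank 1", {
  fix <- smallFixture()
  q <- plantQuery(fix$sim, branch = 2, pendant = 0.05, seed = 18)
  res <- placeQueryML(fix$fitted, q$query, "q")
  B <- nBranches(fix$fitted@tree)
  expect_length(selectCandidates(res, 0.10), ceiling(0.10 * B))
  expect_length(selectCandidates(res, 1.0), B)
  for (fr in c(0.05, 0.1, 0.33))
    expect_true(bestBranch(res) %in% selectCandidates(res, fr))
  # 37 branches at 10% -> 4 candidates (ceiling rule)
  fake <- res
  fake@table <- data.frame(branch = 0:36, logLik = -(1:37), distal = 0.1,
                           proximal = 0.1, pendant = 0.1,
                           lwr = rep(1 / 37, 37), rank = 1:37)
  expect_length(selectCandidates(fake, 0.10), 4L)
})

test_that("bootstrap supports are reproducible, normalized, and concentrate on a clone", {
  fix <- smallFixture()
  leaf <- "t002"
  query <- as.character(fix$pkg@msa[[leaf]])
  s <- bootstrapPlacements(fix$fitted, query, B = 10, fraction = 0.10,
                           seed = 42)
  expect_equal(sum(s), 1)
  rt <- fix$fitted@tree
  splits <- phyloplace:::.edgeSplits(rt@phy)
  pend <- rt@branchId[which(vapply(splits, identical, TRUE, leaf))]
  expect_equal(unname(s[as.character(pend)]), 1)
  # RNG contract
  q <- plantQuery(fix$sim, branch = 5, pendant = 0.1, seed = 77)
  s1 <- bootstrapPlacements(fix$fitted, q$query, B = 50, seed = 7)
  s2 <- bootstrapPlacements(fix$fitted, q$query, B = 50, seed = 7)
  expect_identical(s1, s2)
  expect_equal(sum(s1), 1)
})

test_that("MP insertion scores equal the rebuilt-tree Fitch oracle", {
  skip_if_not_installed("phangorn")
  skip_if_not_installed("phytools")
  pk <- simulateRefPackage(8, 60, seed = 301)
  q <- plantQuery(pk$sim, branch = 4, pendant = 0.2, seed = 302)
  res <- placeQueryMP(pk$refpkg, q$query, "q")
  for (b in res@table$branch) {
    expect_equal(-res@table$logLik[res@table$branch == b],
                 fitchInsertionOracle(pk$refpkg, q$query, b))
  }
})

test_that("MP degenerate cases: leaf clone adds nothing, wildcards tie to branch 0", {
  pk <- simulateRefPackage(7, 80, seed = 401)
  ref <- parsimonyScore(pk$refpkg)
  leaf <- "t003"
  res <- placeQueryMP(pk$refpkg, as.character(pk$refpkg@msa[[leaf]]), "clone")
  best <- placements(res)[1, ]
  expect_equal(-best$logLik, ref)
  rt <- pk$refpkg@tree
  splits <- phyloplace:::.edgeSplits(rt@phy)
  pend <- rt@branchId[which(vapply(splits, identical, TRUE, leaf))]
  expect_equal(best$branch, pend)

  allx <- placeQueryMP(pk$refpkg, strrep("X", 80), "wild")
  expect_equal(length(unique(allx@table$logLik)), 1L)
  expect_equal(-allx@table$logLik[1], ref)
  expect_equal(bestBranch(allx), 0L)
})

test_that("batches equal unions of singleton runs and survive bad queries", {
  fix <- smallFixture()
  q1 <- plantQuery(fix$sim, branch = 1, pendant = 0.05, seed = 1)$query
  q2 <- plantQuery(fix$sim, branch = 8, pendant = 0.05, seed = 2)$query
  batch <- placeBatch(fix$fitted, c(a = q1, b = q2))
  single <- placeQueryML(fix$fitted, q2, "b")
  expect_equal(batch[["b"]]@table, single@table)
  expect_length(placeBatch(fix$fitted, character()), 0L)
  mixed <- placeBatch(fix$fitted, c(good = q1, bad = "XXX"))
  expect_length(mixed, 1L)
  expect_match(attr(mixed, "errors")[["bad"]], "columns|informative")
})

test_that("placement accuracy does not degrade with longer queries", {
  fix <- smallFixture()
  ids <- sort(fix$pkg@tree@branchId)
  ndShort <- integer(0)
  ndLong <- integer(0)
  for (i in 1:15) {
    b <- ids[(7 * i) %% length(ids) + 1]
    q <- plantQuery(fix$sim, branch = b, pendant = 0.1, seed = 4000 + i)$query
    chars <- strsplit(q, "")[[1]]
    short <- chars
    short[-(1:60)] <- "-"          # same query restricted to 60 columns
    rl <- placeQueryML(fix$fitted, q, "long")
    rs <- placeQueryML(fix$fitted, paste(short, collapse = ""), "short")
    ndLong <- c(ndLong, nodeDistance(fix$fitted@tree, bestBranch(rl), b))
    ndShort <- c(ndShort, nodeDistance(fix$fitted@tree, bestBranch(rs), b))
  }
  expect_gte(median(ndShort), median(ndLong))
})

test_that("the reference tree and cached engine are untouched by placements", {
  pk <- simulateRefPackage(6, 100, seed = 501)
  fitted <- fitReference(pk$refpkg)
  before <- list(branchLengths(fitted), fitted@engine$lens,
                 fitted@engine$msgs$down[[1]]$F)
  q <- plantQuery(pk$sim, branch = 2, pendant = 0.05, seed = 502)
  for (i in 1:3) invisible(placeQueryML(fitted, q$query, "q"))
  invisible(bootstrapPlacements(fitted, q$query, B = 20, seed = 1))
  after <- list(branchLengths(fitted), fitted@engine$lens,
                fitted@engine$msgs$down[[1]]$F)
  expect_identical(before, after)
})
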
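## Query placement: per-branch ML insertion with three-length optimization,
## the candidate-branch bootstrap heuristic, and Fitch parsimony insertion.
##
## The efficiency contract: reference conditional vectors are computed once
## by fitReference() and only read here; inserting a query into branch e uses
## the cached messages at the two ends of e and never touches the rest of the
## tree. The reference tree object is never modified.

## joint compression of (reference pattern, query residue) pairs: sites with
## the same reference pattern and the same query residue are interchangeable
.jointPatterns <- function(eng, qcode) {
  key <- paste0(eng$map, "_", qcode)
  first <- !duplicated(key)
  jmap <- match(key, key[first])
  list(jref = eng$map[first], jq = qcode[first],
       jw = as.numeric(tabulate(jmap, sum(first))), jmap = jmap)
}

## per-joint-pattern log-likelihood of the tree with the query attached to a
## branch at distal length x (toward the branch's distal end), proximal
## length b - x and pendant length p; scales included so values are
## comparable across branches
## per-rate products pi * (P(y) A) * (P(x) B) at the attachment node; the
## expensive part of an insertion evaluation, cached while the pendant
## length is optimized with the split point held fixed
.insertC <- function(eng, A, B, x, y) {
  model <- eng$model
  Px <- .rateTrans(model, x)
  Py <- .rateTrans(model, y)
  C <- lapply(seq_along(model@rates), function(k)
    model@pi * (matrix(Py[[k]] %*% matrix(A$F[, , k], 20L), 20L) *
                  (Px[[k]] %*% matrix(B$F[, , k], 20L))))
  list(C = C, C0 = lapply(C, colSums))   # C0: missing-residue marginal
}

.siteLogLikFromC <- function(eng, CC, A, B, jp, p) {
  K <- length(CC$C)
  Pp <- .rateTrans(eng$model, p)
  acc <- numeric(length(jp$jref))
  obs <- jp$jq > 0L
  idx <- cbind(jp$jref[obs], jp$jq[obs])
  for (k in seq_len(K)) {
    Gk <- crossprod(CC$C[[k]], Pp[[k]])  # refpat x residue
    v <- numeric(length(jp$jref))
    v[obs] <- Gk[idx]
    v[!obs] <- CC$C0[[k]][jp$jref[!obs]]
    acc <- acc + v
  }
  log(acc / K) + (A$sc + B$sc)[jp$jref]
}

.insertionSiteLogLik <- function(eng, A, B, jp, x, y, p) {
  .siteLogLikFromC(eng, .insertC(eng, A, B, x, y), A, B, jp, p)
}

## coordinate-sweep optimization of the three insertion lengths:
## start at distal = proximal = b/2, pendant = 0.1; at most 8 rounds,
## stop when the log-likelihood improves by < 1e-6
.optimizeInsertion <- function(eng, A, B, jp, b, rounds = 8L) {
  x <- b / 2
  p <- 0.1
  obj <- function(x, p) sum(jp$jw * .insertionSiteLogLik(eng, A, B, jp, x, b - x, p))
  cur <- obj(x, p)
  for (i in seq_len(rounds)) {
    CC <- .insertC(eng, A, B, x, b - x)
    op <- .maximize1d(function(pp)
      sum(jp$jw * .siteLogLikFromC(eng, CC, A, B, jp, pp)), .MINBL, .MAXBL)
    p <- op$par
    if (b > 1e-12) {
      ox <- .maximize1d(function(xx) obj(xx, p), 0, b)
      x <- ox$par
      val <- ox$value
    } else val <- op$value
    if (val - cur < 1e-6) { cur <- val; break }
    cur <- val
  }
  list(distal = x, proximal = b - x, pendant = max(p, .MINBL), logLik = cur,
       siteLogLik = .insertionSiteLogLik(eng, A, B, jp, x, b - x, p))
}

.queryCodes <- function(query, nsite) {
  code <- .encodeSeq(query)
  if (length(code) != nsite)
    stop("query row has ", length(code), " columns; reference has ", nsite)
  code
}

## score every branch; returns the ranked table plus per-branch site
## log-likelihood vectors (joint-pattern space) for bootstrap re-weighting
.scoreAllBranches <- function(fitted, query) {
  eng <- fitted@engine
  qcode <- .queryCodes(query, eng$nsite)
  jp <- .jointPatterns(eng, qcode)
  ids <- sort(eng$branchId)
  SL <- matrix(0, length(jp$jref), length(ids))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    e <- which(eng$branchId == ids[i])
    fit <- .optimizeInsertion(eng, eng$msgs$up[[e]], eng$msgs$down[[e]], jp,
                              eng$lens[e])
    SL[, i] <- fit$siteLogLik
    rows[[i]] <- data.frame(branch = ids[i], logLik = fit$logLik,
                            distal = fit$distal, proximal = fit$proximal,
                            pendant = fit$pendant)
  }
  tb <- do.call(rbind, rows)
  ## ranking: logLik descending, ties closer than 1e-9 broken by smallest id
  q <- floor(tb$logLik / 1e-9)
  ord <- order(-q, tb$branch)
  tb$rank <- NA_integer_
  tb$rank[ord] <- seq_len(nrow(tb))
  w <- exp(tb$logLik - max(tb$logLik))
  tb$lwr <- w / sum(w)
  list(table = tb, SL = SL, jp = jp, nsite = eng$nsite)
}

#' Score the insertion of a query into one branch
#'
#' Attaches the query to the given branch, optimizes the three branch lengths
#' at the insertion point (distal, proximal, pendant) by coordinate sweeps on
#' the cached reference vectors, and reports the resulting log-likelihood.
#' distal + proximal equals the original branch length; the reference tree is
#' not modified.
#'
#' @param fitted a \linkS4class{FittedReference}.
#' @param query aligned peptide row (one symbol per reference column).
#' @param branch branch id.
#' @return one-row data.frame: branch, logLik, distal, proximal, pendant.
#' @export
scoreInsertion <- function(fitted, query, branch) {
  eng <- fitted@engine
  e <- .branchEdgeRow(fitted@tree, branch)
  qcode <- .queryCodes(query, eng$nsite)
  jp <- .jointPatterns(eng, qcode)
  fit <- .optimizeInsertion(eng, eng$msgs$up[[e]], eng$msgs$down[[e]], jp,
                            eng$lens[e])
  data.frame(branch = as.integer(branch), logLik = fit$logLik,
             distal = fit$distal, proximal = fit$proximal,
             pendant = fit$pendant)
}

#' Maximum-likelihood placement of one query
#'
#' Scores the insertion of the query into every placement branch and reports
#' the full ranked table; like-weight ratios are the normalized likelihood
#' weights over all evaluated branches. Ties closer than 1e-9 log-units are
#' broken by the smallest branch id.
#'
#' @param fitted a \linkS4class{FittedReference}.
#' @param query aligned peptide row in reference coordinates.
#' @param queryId identifier carried into the result.
#' @return a \linkS4class{PlacementResult}.
#' @export
placeQueryML <- function(fitted, query, queryId = "query") {
  qcode <- .queryCodes(query, fitted@engine$nsite)
  if (!any(qcode > 0L))
    stop("query '", queryId, "' has no informative (non-missing) columns")
  sc <- .scoreAllBranches(fitted, query)
  new("PlacementResult", queryId = queryId, method = "ML", table = sc$table,
      support = numeric(), markers = character())
}

#' Candidate branches for bootstrap re-scoring
#'
#' The top \code{ceiling(fraction * B)} branches (at least one) of a ranked
#' placement, as scored on the original (non-resampled) alignment; always
#' contains the rank-1 branch by construction.
#'
#' @param result a \linkS4class{PlacementResult}.
#' @param fraction candidate fraction (default 0.10).
#' @return integer vector of branch ids.
#' @export
selectCandidates <- function(result, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  tb <- placements(result)
  n <- max(1L, as.integer(ceiling(fraction * nrow(tb))))
  tb$branch[seq_len(min(n, nrow(tb)))]
}

#' Non-parametric bootstrap support for a placement
#'
#' Resamples alignment columns with replacement \code{B} times. Each
#' replicate re-scores the candidate branches under the resampled column
#' weights, using the insertion lengths optimized on the original alignment,
#' and is awarded to the best-scoring branch (ties to the smallest id);
#' support is the fraction of replicates won. With \code{fraction = 1} all
#' branches are candidates (full-search bootstrap); the default re-enacts
#' the top-10 percent candidate heuristic. Seeded runs are reproducible.
#'
#' @param fitted a \linkS4class{FittedReference}.
#' @param query aligned peptide row.
#' @param B replicate count.
#' @param fraction candidate fraction.
#' @param seed RNG seed.
#' @return named numeric: support per candidate branch id, summing to 1.
#' @export
bootstrapPlacements <- function(fitted, query, B = 100L, fraction = 0.10,
                                seed = NULL) {
  sc <- .scoreAllBranches(fitted, query)
  .bootstrapFromScores(sc, B = B, fraction = fraction, seed = seed)
}

## replicate scoring given the per-branch site log-likelihood vectors
.bootstrapFromScores <- function(sc, B = 100L, fraction = 0.10, seed = NULL) {
  stopifnot(B >= 1)
  tb <- sc$table[order(sc$table$rank), ]
  n <- max(1L, as.integer(ceiling(fraction * nrow(tb))))
  cand <- sort(tb$branch[seq_len(min(n, nrow(tb)))])
  ci <- match(cand, sc$table$branch)
  nsite <- sc$nsite
  njoint <- length(sc$jp$jw)
  .withSeed(seed, {
    wins <- setNames(numeric(length(cand)), cand)
    for (r in seq_len(B)) {
      idx <- sample.int(nsite, nsite, replace = TRUE)
      w <- tabulate(sc$jp$jmap[idx], njoint)
      scores <- as.numeric(w %*% sc$SL[, ci, drop = FALSE])
      best <- which(scores >= max(scores) - 1e-9)[1L]
      wins[best] <- wins[best] + 1
    }
    wins / B
  })
}

## ---- Maximum Parsimony ----

.fitchMasks <- function(seqs) {
  full <- bitwShiftL(1L, 20L) - 1L
  do.call(rbind, lapply(seqs, function(s) {
    code <- .encodeSeq(s)
    m <- bitwShiftL(1L, pmax(code, 1L) - 1L)
    m[code == 0L] <- full
    m
  }))
}

.fitchCombine <- function(s1, c1, s2, c2) {
  inter <- bitwAnd(s1, s2)
  empty <- inter == 0L
  set <- inter
  set[empty] <- bitwOr(s1, s2)[empty]
  list(set = set, cost = c1 + c2 + as.integer(empty))
}

## directional Fitch sets/costs per edge (both components), binary trees
.fitchMessages <- function(rt, masks) {
  phy <- rt@phy
  L <- length(phy$tip.label)
  E <- nrow(phy$edge)
  po <- ape::reorder.phylo(phy, "postorder")
  poEdges <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                   paste(phy$edge[, 1L], phy$edge[, 2L]))
  childEdges <- split(seq_len(E), phy$edge[, 1L])
  parentEdge <- rep(NA_integer_, max(phy$edge))
  parentEdge[phy$edge[, 2L]] <- seq_len(E)
  zero <- integer(ncol(masks))
  down <- vector("list", E)
  for (e in poEdges) {
    v <- phy$edge[e, 2L]
    down[[e]] <- if (v <= L) list(set = masks[v, ], cost = zero) else {
      ce <- childEdges[[as.character(v)]]
      Reduce(function(a, bb) .fitchCombine(a$set, a$cost, bb$set, bb$cost),
             down[ce])
    }
  }
  up <- vector("list", E)
  for (e in rev(poEdges)) {
    u <- phy$edge[e, 1L]
    parts <- down[setdiff(childEdges[[as.character(u)]], e)]
    pe <- parentEdge[u]
    if (!is.na(pe)) parts <- c(parts, list(up[[pe]]))
    up[[e]] <- Reduce(function(a, bb) .fitchCombine(a$set, a$cost, bb$set, bb$cost),
                      parts)
  }
  list(down = down, up = up)
}

#' Maximum-parsimony placement of one query
#'
#' For every branch, the Fitch parsimony score (uniform costs, 20-letter
#' alphabet, gaps/'X'/'*' as wildcards) of the reference tree with the query
#' attached to that branch; the minimal-score branch wins, ties go to the
#' smallest branch id. Scores are reported negated in the \code{logLik}
#' column so that rank 1 is always the best placement.
#'
#' @param refpkg a \linkS4class{RefPackage} (or a \linkS4class{FittedReference}).
#' @param query aligned peptide row in reference coordinates.
#' @param queryId identifier carried into the result.
#' @return a \linkS4class{PlacementResult} with \code{method = "MP"}.
#' @export
placeQueryMP <- function(refpkg, query, queryId = "query") {
  if (is(refpkg, "FittedReference")) refpkg <- refpkg@refpkg
  rt <- refpkg@tree
  phy <- rt@phy
  seqs <- setNames(as.character(refpkg@msa), names(refpkg@msa))[phy$tip.label]
  nsite <- nchar(seqs[[1]])
  qcode <- .queryCodes(query, nsite)
  masks <- .fitchMasks(seqs)
  qmask <- .fitchMasks(setNames(query, "q"))[1L, ]
  msgs <- .fitchMessages(rt, masks)
  ids <- sort(rt@branchId)
  score <- integer(length(ids))
  for (i in seq_along(ids)) {
    e <- which(rt@branchId == ids[i])
    ab <- .fitchCombine(msgs$up[[e]]$set, msgs$up[[e]]$cost,
                        msgs$down[[e]]$set, msgs$down[[e]]$cost)
    extra <- as.integer(bitwAnd(ab$set, qmask) == 0L)
    score[i] <- sum(ab$cost + extra)
  }
  b <- branchLengths(rt)[as.character(ids)]
  tb <- data.frame(branch = ids, logLik = -as.numeric(score),
                   distal = b / 2, proximal = b / 2, pendant = 0)
  ord <- order(score, tb$branch)
  tb$rank <- NA_integer_
  tb$rank[ord] <- seq_len(nrow(tb))
  w <- exp(tb$logLik - max(tb$logLik))
  tb$lwr <- w / sum(w)
  new("PlacementResult", queryId = queryId, method = "MP", table = tb,
      support = numeric(), markers = character())
}

#' Reference-tree Fitch parsimony score (no query)
#'
#' @param refpkg a \linkS4class{RefPackage}.
#' @return integer parsimony score of the reference alignment on the tree.
#' @export
parsimonyScore <- function(refpkg) {
  rt <- refpkg@tree
  phy <- rt@phy
  seqs <- setNames(as.character(refpkg@msa), names(refpkg@msa))[phy$tip.label]
  masks <- .fitchMasks(seqs)
  msgs <- .fitchMessages(rt, masks)
  ab <- .fitchCombine(msgs$up[[1L]]$set, msgs$up[[1L]]$cost,
                      msgs$down[[1L]]$set, msgs$down[[1L]]$cost)
  sum(ab$cost)
}

#' Place a batch of queries
#'
#' The reference is fitted once; each query is placed independently, so
#' results do not depend on batch order or partitioning and aggregation of
#' split runs is concatenation. Per-query failures are collected (attribute
#' \code{"errors"}) without aborting the batch.
#'
#' @param refpkg a \linkS4class{RefPackage} or prepared \linkS4class{FittedReference}.
#' @param queries named character vector of aligned query rows.
#' @param method "ML" or "MP".
#' @param bootstrap bootstrap replicate count (0 = none; ML only).
#' @param fraction candidate fraction for the bootstrap heuristic.
#' @param seed RNG seed for the bootstrap.
#' @return list of \linkS4class{PlacementResult}, one per successful query,
#'   with failed query messages in \code{attr(, "errors")}.
#' @export
placeBatch <- function(refpkg, queries, method = c("ML", "MP"),
                       bootstrap = 0L, fraction = 0.10, seed = NULL) {
  method <- match.arg(method)
  fitted <- if (is(refpkg, "FittedReference")) refpkg
            else if (method == "ML") fitReference(refpkg) else NULL
  results <- list()
  errors <- character()
  for (i in seq_along(queries)) {
    qid <- if (!is.null(names(queries))) names(queries)[i] else paste0("query", i)
    res <- tryCatch({
      r <- if (method == "ML") placeQueryML(fitted, queries[[i]], qid)
           else placeQueryMP(if (is.null(fitted)) refpkg else fitted,
                             queries[[i]], qid)
      if (method == "ML" && bootstrap > 0L)
        r@support <- bootstrapPlacements(fitted, queries[[i]], B = bootstrap,
                                         fraction = fraction,
                                         seed = if (is.null(seed)) NULL
                                                else seed + i)
      r
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errors[qid] <- res else results[[qid]] <- res
  }
  attr(results, "errors") <- errors
  results
}
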
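## Felsenstein-pruning likelihood on a fixed topology.
##
## The engine works on the unrooted placement view. For every branch e with
## ends (u, v) it maintains two conditional-likelihood messages: F_{v,e}, the
## likelihood of the data in the component containing v given the state at v
## ("down", the ape-distal side), and F_{u,e} likewise for the other component
## ("up"). The likelihood can then be read off any branch as
##   L = sum_k (1/K) sum_i pi_i F_{u,e}[i] (P_k(t_e) F_{v,e})[i]
## which is what both branch-length optimization and query insertion consume.
## Underflow is handled by per-message scaling factors accumulated in log
## space (one scale per site pattern, shared across rate categories so the
## rate mixture stays exact).

.MINBL <- 1e-8
.MAXBL <- 20
.ALPHA_BOUNDS <- c(0.02, 100)

.encodeSeq <- function(s) {
  code <- match(strsplit(toupper(s), "")[[1]], AA_ORDER)
  code[is.na(code)] <- 0L   # '-', 'X', '*' and anything unknown = missing
  code
}

.compressPatterns <- function(codes) {
  key <- apply(codes, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(codes = codes[, first, drop = FALSE],
       weights = as.numeric(tabulate(map, sum(first))),
       map = map)
}

.tipMessage <- function(code, K) {
  npat <- length(code)
  F <- matrix(0, 20L, npat)
  obs <- code > 0L
  F[cbind(code[obs], which(obs))] <- 1
  F[, !obs] <- 1
  list(F = array(F, c(20L, npat, K)), sc = numeric(npat))
}

.propagate <- function(Plist, F) {
  out <- array(0, dim(F))
  for (k in seq_along(Plist)) out[, , k] <- Plist[[k]] %*% F[, , k]
  out
}

.combineMsgs <- function(parts) {
  F <- parts[[1L]]$F
  sc <- parts[[1L]]$sc
  for (i in seq_along(parts)[-1L]) {
    F <- F * parts[[i]]$F
    sc <- sc + parts[[i]]$sc
  }
  if (length(parts) > 1L) {
    ## scale by the per-pattern total mass (summed over states and rates):
    ## cheap, strictly positive, and shared across rates so the mixture is
    ## unaffected
    m <- rowSums(colSums(F, dims = 1L))
    m[m <= 0] <- 1
    F <- F / rep(m, each = dim(F)[1L])
    sc <- sc + log(m)
  }
  list(F = F, sc = sc)
}

.buildEngine <- function(rt, msa, model, alpha = NULL) {
  phy <- rt@phy
  L <- length(phy$tip.label)
  seqs <- setNames(as.character(msa), names(msa))
  miss <- setdiff(phy$tip.label, names(seqs))
  if (length(miss))
    stop("leaf without sequence: ", paste(miss, collapse = ", "))
  if (!is.null(alpha) && !is.na(alpha)) model <- setModelAlpha(model, alpha)
  codes <- do.call(rbind, lapply(seqs[phy$tip.label], .encodeSeq))
  if (length(unique(vapply(seqs[phy$tip.label], nchar, 0L))) != 1L)
    stop("alignment rows differ in length")
  pat <- .compressPatterns(codes)
  K <- length(model@rates)
  E <- nrow(phy$edge)
  po <- ape::reorder.phylo(phy, "postorder")
  poEdges <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                   paste(phy$edge[, 1L], phy$edge[, 2L]))
  childEdges <- split(seq_len(E), phy$edge[, 1L])
  parentEdge <- rep(NA_integer_, max(phy$edge))
  parentEdge[phy$edge[, 2L]] <- seq_len(E)
  tips <- lapply(seq_len(L), function(i) .tipMessage(pat$codes[i, ], K))
  list(edge = phy$edge, lens = phy$edge.length, E = E, L = L,
       root = L + 1L, po = poEdges, childEdges = childEdges,
       parentEdge = parentEdge, tips = tips,
       patCodes = pat$codes, weights = pat$weights, map = pat$map,
       nsite = ncol(codes), model = model, branchId = rt@branchId)
}

.edgeTrans <- function(eng) {
  lapply(seq_len(eng$E), function(e) .rateTrans(eng$model, eng$lens[e]))
}

## down messages plus their propagated versions P(t_e) F (each message is
## propagated once and reused by the parent combine and the sibling up-pass)
.downPass <- function(eng, Pt) {
  down <- vector("list", eng$E)
  pdown <- vector("list", eng$E)
  for (e in eng$po) {
    v <- eng$edge[e, 2L]
    down[[e]] <- if (v <= eng$L) eng$tips[[v]] else
      .combineMsgs(pdown[eng$childEdges[[as.character(v)]]])
    pdown[[e]] <- list(F = .propagate(Pt[[e]], down[[e]]$F),
                       sc = down[[e]]$sc)
  }
  list(down = down, pdown = pdown)
}

.computeMessages <- function(eng) {
  Pt <- .edgeTrans(eng)
  dp <- .downPass(eng, Pt)
  down <- dp$down
  pdown <- dp$pdown
  up <- vector("list", eng$E)
  pup <- vector("list", eng$E)
  for (e in rev(eng$po)) {
    u <- eng$edge[e, 1L]
    sibs <- setdiff(eng$childEdges[[as.character(u)]], e)
    parts <- pdown[sibs]
    pe <- eng$parentEdge[u]
    if (!is.na(pe)) parts <- c(parts, list(pup[[pe]]))
    up[[e]] <- .combineMsgs(parts)
    pup[[e]] <- list(F = .propagate(Pt[[e]], up[[e]]$F), sc = up[[e]]$sc)
  }
  list(down = down, up = up)
}

## log-likelihood read off branch e with candidate length t, given messages
.edgeLogLikMsgs <- function(eng, A, B, t) {
  Pl <- .rateTrans(eng$model, t)
  K <- length(Pl)
  npat <- dim(A$F)[2L]
  acc <- numeric(npat)
  for (k in seq_len(K)) {
    Fa <- matrix(A$F[, , k], 20L)
    Fb <- matrix(B$F[, , k], 20L)
    acc <- acc + colSums(eng$model@pi * (Fa * (Pl[[k]] %*% Fb)))
  }
  lp <- log(acc / K) + A$sc + B$sc
  sum(eng$weights * lp)
}

.rootLogLik <- function(eng) {
  Pt <- .edgeTrans(eng)
  dp <- .downPass(eng, Pt)
  ce <- eng$childEdges[[as.character(eng$root)]]
  m <- .combineMsgs(dp$pdown[ce])
  K <- dim(m$F)[3L]
  acc <- numeric(dim(m$F)[2L])
  for (k in seq_len(K))
    acc <- acc + colSums(eng$model@pi * matrix(m$F[, , k], 20L))
  sum(eng$weights * (log(acc / K) + m$sc))
}

#' Log-likelihood of an alignment on a fixed tree
#'
#' Standard pruning likelihood under the given substitution model with
#' discrete-Gamma rates; gaps, 'X' and '*' are treated as missing data
#' (all-ones partial vectors). The value is independent of where the tree is
#' virtually rooted (the model is reversible).
#'
#' @param tree a \linkS4class{ReferenceTree}.
#' @param msa named character vector or \code{AAStringSet} covering all leaves.
#' @param model a \linkS4class{SubstitutionModel}.
#' @return log-likelihood in nats.
#' @export
logLikelihood <- function(tree, msa, model) {
  eng <- .buildEngine(tree, msa, model)
  .rootLogLik(eng)
}

## maximize f over [lo, hi]; golden-section/parabolic via stats::optimize,
## with explicit boundary checks so boundary optima land exactly on a bound
.maximize1d <- function(f, lo, hi, tol = 1e-6) {
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  best <- opt$maximum; val <- opt$objective
  flo <- f(lo)
  if (flo >= val) { best <- lo; val <- flo }
  fhi <- f(hi)
  if (fhi >= val) { best <- hi; val <- fhi }
  list(par = best, value = val)
}

#' Optimize one branch length of a fitted reference
#'
#' One-dimensional likelihood maximization of a single branch length (all
#' other branches and the model held fixed), using the cached conditional
#' vectors at the two ends of the branch. The log-likelihood never decreases
#' and the length is confined to [1e-8, 20].
#'
#' @param fitted a \linkS4class{FittedReference}.
#' @param branch branch id.
#' @return the optimized branch length.
#' @export
optimizeBranchLength <- function(fitted, branch) {
  eng <- fitted@engine
  e <- which(eng$branchId == as.integer(branch))
  if (!length(e)) stop("unknown branch id: ", branch)
  msgs <- fitted@engine$msgs
  A <- msgs$up[[e]]; B <- msgs$down[[e]]
  .maximize1d(function(t) .edgeLogLikMsgs(eng, A, B, t), .MINBL, .MAXBL)$par
}

## push placement-view lengths back into the rooted reporting tree; the
## merged root branch is split in proportion to the original two segments
.updateTreeLengths <- function(rt, lens) {
  rt@phy$edge.length <- lens
  if (!rt@rooted) {
    rt@phyRooted <- rt@phy
    return(rt)
  }
  rphy <- rt@phyRooted
  usplits <- .edgeSplits(rt@phy)
  rsplits <- .edgeSplits(rphy)
  allTips <- sort(rt@phy$tip.label)
  keyOf <- function(s) {
    if (length(s) * 2L > length(allTips) ||
        (length(s) * 2L == length(allTips) && !(allTips[1] %in% s)))
      s <- setdiff(allTips, s)
    paste(s, collapse = "\r")
  }
  ukeys <- vapply(usplits, keyOf, "")
  root <- length(rphy$tip.label) + 1L
  rootRows <- which(rphy$edge[, 1L] == root)
  for (i in seq_len(nrow(rphy$edge))) {
    k <- keyOf(rsplits[[i]])
    j <- match(k, ukeys)
    if (i %in% rootRows) {
      tot <- lens[j]
      orig <- sum(rphy$edge.length[rootRows])
      frac <- if (orig > 0) rphy$edge.length[i] / orig else 0.5
      rt@phyRooted$edge.length[i] <- tot * frac
    } else {
      rt@phyRooted$edge.length[i] <- lens[j]
    }
  }
  rt
}

## One exact coordinate-ascent sweep over all branch lengths. Edges are
## visited depth-first from the (virtual) root; messages are maintained
## incrementally so that when an edge is optimized both of its conditional
## vectors reflect all length updates made so far — each edge costs one up
## combine, one down combine and two propagations per sweep instead of a
## full recomputation.
.sweepBranchLengths <- function(eng) {
  env <- new.env(parent = emptyenv())
  env$Pt <- .edgeTrans(eng)
  dp <- .downPass(eng, env$Pt)
  env$down <- dp$down
  env$pdown <- dp$pdown
  env$up <- vector("list", eng$E)
  env$pup <- vector("list", eng$E)
  visit <- function(e) {
    env$pup[[e]] <- list(F = .propagate(env$Pt[[e]], env$up[[e]]$F),
                         sc = env$up[[e]]$sc)
    v <- eng$edge[e, 2L]
    if (v > eng$L) {
      kids <- eng$childEdges[[as.character(v)]]
      for (ce in kids) {
        env$up[[ce]] <- .combineMsgs(c(env$pdown[setdiff(kids, ce)],
                                       list(env$pup[[e]])))
        visit(ce)
      }
      env$down[[e]] <- .combineMsgs(env$pdown[kids])
    }
    A <- env$up[[e]]; B <- env$down[[e]]
    opt <- .maximize1d(function(t) .edgeLogLikMsgs(eng, A, B, t),
                       .MINBL, .MAXBL)
    if (opt$value >= .edgeLogLikMsgs(eng, A, B, eng$lens[e])) {
      eng$lens[e] <<- opt$par
      env$Pt[[e]] <- .rateTrans(eng$model, opt$par)
    }
    env$pdown[[e]] <- list(F = .propagate(env$Pt[[e]], env$down[[e]]$F),
                           sc = env$down[[e]]$sc)
  }
  rootKids <- eng$childEdges[[as.character(eng$root)]]
  for (ce in rootKids) {
    env$up[[ce]] <- .combineMsgs(env$pdown[setdiff(rootKids, ce)])
    visit(ce)
  }
  eng$lens
}

#' Fit a reference package: branch lengths and Gamma shape
#'
#' Repeated coordinate sweeps over all branch lengths (each a bracketed 1-D
#' maximization in [1e-8, 20]) followed by optimization of the Gamma shape in
#' [0.02, 100] (skipped when the package pins \code{alpha}), until the total
#' log-likelihood improves by less than \code{tol}. The log-likelihood is
#' monotone across sweeps; non-convergence after \code{maxSweeps} sweeps is
#' an error carrying the sweep trace.
#'
#' @param refpkg a \linkS4class{RefPackage}.
#' @param K number of Gamma rate categories.
#' @param tol convergence tolerance on the total log-likelihood.
#' @param maxSweeps sweep limit.
#' @param optimizeBranches set \code{FALSE} to keep the tree's lengths and only
#'   fit alpha (or nothing, if alpha is pinned).
#' @return a \linkS4class{FittedReference} with cached per-branch messages.
#' @export
fitReference <- function(refpkg, K = 4L, tol = 1e-4, maxSweeps = 100L,
                         optimizeBranches = TRUE) {
  model <- loadEmpiricalModel(refpkg@modelName,
                              alpha = if (is.na(refpkg@alpha)) 1 else refpkg@alpha,
                              K = K)
  eng <- .buildEngine(refpkg@tree, refpkg@msa, model)
  fitAlpha <- is.na(refpkg@alpha)
  cur <- .rootLogLik(eng)
  trace <- cur
  for (sweep in seq_len(maxSweeps)) {
    if (optimizeBranches) eng$lens <- .sweepBranchLengths(eng)
    if (fitAlpha) {
      f <- function(a) {
        eng$model <- setModelAlpha(eng$model, a)
        .rootLogLik(eng)
      }
      opt <- .maximize1d(f, .ALPHA_BOUNDS[1], .ALPHA_BOUNDS[2], tol = 1e-4)
      eng$model <- setModelAlpha(eng$model, opt$par)
    }
    new <- .rootLogLik(eng)
    trace <- c(trace, new)
    if (new < cur - 1e-6)
      stop("log-likelihood decreased during sweep ", sweep)
    if (new - cur < tol) { cur <- new; break }
    cur <- new
    if (sweep == maxSweeps)
      stop("branch-length optimization did not converge after ", maxSweeps,
           " sweeps; logLik trace: ",
           paste(format(trace, digits = 12), collapse = ", "))
    if (!optimizeBranches && !fitAlpha) break
  }
  eng$msgs <- .computeMessages(eng)
  tree <- .updateTreeLengths(refpkg@tree, eng$lens)
  new("FittedReference", refpkg = refpkg, tree = tree,
      model = eng$model, engine = eng, logLik = cur)
}

#' Reference package with the fitted branch lengths and Gamma shape
#'
#' Repackages a \linkS4class{FittedReference} as a \linkS4class{RefPackage}
#' whose tree carries the optimized lengths and whose config pins the fitted
#' alpha, so the fit can be serialized with
#' \code{\link{writeReferencePackage}} and reloaded without re-optimizing.
#'
#' @param fitted a \linkS4class{FittedReference}.
#' @return a \linkS4class{RefPackage}.
#' @export
fittedPackage <- function(fitted) {
  stopifnot(is(fitted, "FittedReference"))
  new("RefPackage", tree = fitted@tree, msa = fitted@refpkg@msa,
      taxonomy = fitted@refpkg@taxonomy,
      modelName = fitted@refpkg@modelName,
      alpha = fitted@model@alpha)
}
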
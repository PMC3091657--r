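# Independent oracles and shared fixtures, kept deliberately naive:
# each re-derives its quantity from first principles so it cannot share a
# defect with the implementation path it checks.

# equal-rates ("uniform") model: closed forms are available for P(t) and the
# two-sequence likelihood, with beta = 20/19 from the normalization
uniformModel <- function(alpha = 1, K = 1L) {
  S <- matrix(1, 20, 20)
  diag(S) <- 0
  makeSubstitutionModel("UNIF", S, rep(1 / 20, 20), alpha = alpha, K = K)
}

uniformP <- function(t) {
  beta <- 20 / 19
  off <- (1 - exp(-beta * t)) / 20
  P <- matrix(off, 20, 20)
  diag(P) <- exp(-beta * t) + off
  P
}

# exhaustive likelihood: sum over all internal-node state assignments,
# mixing rate categories per site; only usable for tiny trees
bruteForceLogLik <- function(rt, seqs, model) {
  phy <- rt@phy
  L <- length(phy$tip.label)
  nnode <- max(phy$edge)
  internals <- setdiff(seq_len(nnode), seq_len(L))
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  codes <- lapply(phy$tip.label, function(l) {
    x <- match(strsplit(toupper(seqs[[l]]), "")[[1]], aa)
    ifelse(is.na(x), 0L, x)
  })
  nsite <- length(codes[[1]])
  K <- length(model@rates)
  root <- L + 1L
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
  for (site in seq_len(nsite)) {
    Lsite <- 0
    for (k in seq_len(K)) {
      Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
        transitionMatrix(model, phy$edge.length[e], model@rates[k]))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(nnode)
        st[internals] <- grid[g, ]
        p <- unname(model@pi[st[root]])
        for (e in seq_len(nrow(phy$edge))) {
          par <- st[phy$edge[e, 1L]]
          ch <- phy$edge[e, 2L]
          p <- p * if (ch <= L) {
            obs <- codes[[ch]][site]
            if (obs == 0L) 1 else Ps[[e]][par, obs]
          } else Ps[[e]][par, st[ch]]
        }
        tot <- tot + p
      }
      Lsite <- Lsite + tot / K
    }
    total <- total + log(Lsite)
  }
  total
}

# node distance re-derived as breadth-first search on the line graph
# (vertices = branches, adjacent iff they share a tree node)
lineGraphDistance <- function(rt, a, b) {
  phy <- rt@phy
  E <- nrow(phy$edge)
  ids <- rt@branchId
  adj <- lapply(seq_len(E), function(i)
    setdiff(which(phy$edge[, 1L] %in% phy$edge[i, ] |
                    phy$edge[, 2L] %in% phy$edge[i, ]), i))
  src <- which(ids == a)
  dst <- which(ids == b)
  dist <- rep(NA_integer_, E)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    n <- queue[1L]
    queue <- queue[-1L]
    for (m in adj[[n]]) if (is.na(dist[m])) {
      dist[m] <- dist[n] + 1L
      queue <- c(queue, m)
    }
  }
  dist[dst]
}

# naive cell-by-cell affine-gap glocal DP (no vectorization tricks)
naiveGlocalScore <- function(emit, open = 11, ext = 1) {
  m <- nrow(emit)
  n <- ncol(emit)
  NEG <- -1e18
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)
  Iy <- matrix(NEG, m + 1, n + 1)
  M[1, ] <- 0
  for (i in 1:m) {
    for (j in 0:n) {
      if (j >= 1)
        M[i + 1, j + 1] <- emit[i, j] + max(M[i, j], Ix[i, j], Iy[i, j])
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - ext)
      if (j >= 1)
        Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - ext)
    }
  }
  max(M[m + 1, ], Ix[m + 1, ])
}

# parsimony oracle: physically rebuild the tree with the query attached to
# a branch and run phangorn's Fitch from scratch
fitchInsertionOracle <- function(refpkg, query, branch) {
  skip_if_not_installed("phangorn")
  rt <- refpkg@tree
  phy <- rt@phy
  e <- which(rt@branchId == branch)
  v <- phy$edge[e, 2L]
  pos <- phy$edge.length[e] / 2
  joined <- phytools::bind.tip(phy, "QUERY__", edge.length = 0.1,
                               where = v, position = pos)
  seqs <- c(setNames(as.character(refpkg@msa), names(refpkg@msa)),
            QUERY__ = query)
  mat <- do.call(rbind, strsplit(toupper(seqs[joined$tip.label]), ""))
  rownames(mat) <- joined$tip.label
  dat <- phangorn::phyDat(mat, type = "AA")
  as.integer(phangorn::parsimony(joined, dat))
}

# small shared fixture: an 8-leaf simulated package with its fitted reference
# (built once per test run)
fixtureEnv <- new.env()
smallFixture <- function() {
  if (is.null(fixtureEnv$fix)) {
    pk <- simulateRefPackage(8, 200, seed = 101)
    fixtureEnv$fix <- list(pkg = pk$refpkg, sim = pk$sim,
                           fitted = fitReference(pk$refpkg))
  }
  fixtureEnv$fix
}
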
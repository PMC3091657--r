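## Synthetic data: random reference packages, sequence evolution along trees,
## planted queries, synthetic genomes, bootstrap column statistic.
## Every operation is a pure function of (inputs, seed).

.withSeed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(force(code))
  glob <- globalenv()
  had <- exists(".Random.seed", envir = glob, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = glob) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = glob)
    else if (exists(".Random.seed", envir = glob, inherits = FALSE))
      rm(".Random.seed", envir = glob)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random unrooted reference topology with exponential branch lengths
#'
#' Topology by sequential random attachment of tips to a uniformly chosen
#' existing branch; branch lengths i.i.d. exponential with the given mean
#' (expected substitutions per site). Deterministic under \code{seed}.
#'
#' @param nLeaves number of leaves (>= 3).
#' @param seed RNG seed.
#' @param meanLength mean branch length (default 0.1).
#' @return a \linkS4class{ReferenceTree}.
#' @export
randomTree <- function(nLeaves, seed = NULL, meanLength = 0.1) {
  stopifnot(nLeaves >= 3)
  .withSeed(seed, {
    phy <- ape::rtopology(nLeaves, rooted = FALSE,
                          tip.label = sprintf("t%03d", seq_len(nLeaves)))
    phy$edge.length <- rexp(nrow(phy$edge), rate = 1 / meanLength)
    .newReferenceTree(phy)
  })
}

.sampleTransition <- function(parentStates, rateCat, Plist) {
  out <- integer(length(parentStates))
  grp <- split(seq_along(parentStates),
               list(s = parentStates, k = rateCat), drop = TRUE)
  for (g in grp) {
    s <- parentStates[g[1L]]
    k <- rateCat[g[1L]]
    out[g] <- sample.int(20L, length(g), replace = TRUE, prob = Plist[[k]][s, ])
  }
  out
}

#' Simulate an alignment by evolving sites along a tree
#'
#' Root states are drawn from the model's equilibrium frequencies; each site
#' is assigned one discrete-Gamma rate category; child states follow the
#' transition matrices P(rate x branch length) down the tree.
#'
#' @param tree a \linkS4class{ReferenceTree}.
#' @param model a \linkS4class{SubstitutionModel} (its alpha/rates are used).
#' @param nSites number of sites.
#' @param seed RNG seed.
#' @param detail when TRUE also return internal node states and site rate
#'   categories (needed to plant queries on known branches).
#' @return named character vector of leaf rows, or a detailed list.
#' @export
evolveAlignment <- function(tree, model, nSites, seed = NULL, detail = FALSE) {
  stopifnot(is(tree, "ReferenceTree"), nSites >= 1)
  phy <- tree@phy
  L <- length(phy$tip.label)
  K <- length(model@rates)
  .withSeed(seed, {
    rateCat <- sample.int(K, nSites, replace = TRUE)
    states <- matrix(0L, max(phy$edge), nSites)
    root <- L + 1L
    states[root, ] <- sample.int(20L, nSites, replace = TRUE, prob = model@pi)
    po <- ape::reorder.phylo(phy, "postorder")
    edgeOrder <- rev(match(paste(po$edge[, 1L], po$edge[, 2L]),
                           paste(phy$edge[, 1L], phy$edge[, 2L])))
    for (e in edgeOrder) {
      Plist <- .rateTrans(model, phy$edge.length[e])
      states[phy$edge[e, 2L], ] <-
        .sampleTransition(states[phy$edge[e, 1L], ], rateCat, Plist)
    }
    rows <- apply(states[seq_len(L), , drop = FALSE], 1L,
                  function(s) paste(AA_ORDER[s], collapse = ""))
    names(rows) <- phy$tip.label
    if (!detail) return(rows)
    list(msa = rows, states = states, rateCat = rateCat,
         tree = tree, model = model)
  })
}

#' Plant a query sequence on a known branch
#'
#' Draws the ancestral states at the midpoint of the chosen branch by bridge
#' sampling conditional on the simulated states at both branch ends (so the
#' query is jointly consistent with the reference alignment realization),
#' then evolves the query along a pendant edge of the given length using the
#' same per-site rate categories. With \code{pendant = 0} the query equals
#' the sampled ancestral midpoint sequence.
#'
#' @param sim detailed simulation from \code{evolveAlignment(..., detail = TRUE)}.
#' @param branch branch id to plant on.
#' @param pendant pendant branch length.
#' @param seed RNG seed.
#' @return list with \code{query} (peptide string) and \code{branch} (true id).
#' @export
plantQuery <- function(sim, branch, pendant, seed = NULL) {
  tree <- sim$tree
  e <- .branchEdgeRow(tree, branch)
  phy <- tree@phy
  b <- phy$edge.length[e]
  u <- phy$edge[e, 1L]; v <- phy$edge[e, 2L]
  model <- sim$model
  K <- length(model@rates)
  .withSeed(seed, {
    Px <- .rateTrans(model, b / 2)
    n <- length(sim$rateCat)
    mid <- integer(n)
    su <- sim$states[u, ]; sv <- sim$states[v, ]
    for (i in seq_len(n)) {
      k <- sim$rateCat[i]
      p <- Px[[k]][su[i], ] * Px[[k]][, sv[i]]
      mid[i] <- sample.int(20L, 1L, prob = p)
    }
    qs <- if (pendant > 0) {
      Pp <- .rateTrans(model, pendant)
      .sampleTransition(mid, sim$rateCat, Pp)
    } else mid
    list(query = paste(AA_ORDER[qs], collapse = ""), branch = as.integer(branch))
  })
}

.CODON_TABLE <- NULL

.codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Synthesize a nucleotide "genome" embedding marker coding sequences
#'
#' Marker peptides are back-translated with uniformly chosen synonymous
#' codons and embedded, each on a random strand, between random intergenic
#' spacers (uniform ACGT). Metadata records coordinates and strand so
#' translation truth can be checked downstream.
#'
#' @param markers named character vector of marker peptides (no gaps).
#' @param spacer length of each intergenic spacer in nt.
#' @param seed RNG seed.
#' @return list with \code{sequence} (nt string) and \code{meta} (data.frame
#'   with marker, start, end, strand).
#' @export
synthGenome <- function(markers, spacer = 300L, seed = NULL) {
  stopifnot(length(markers) >= 1L, !is.null(names(markers)))
  tab <- .codonTable()
  .withSeed(seed, {
    parts <- character()
    meta <- data.frame(marker = character(), start = integer(),
                       end = integer(), strand = character(),
                       stringsAsFactors = FALSE)
    pos <- 0L
    rspacer <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")
    for (m in names(markers)) {
      sp <- rspacer(spacer)
      parts <- c(parts, sp); pos <- pos + spacer
      pep <- strsplit(gsub("-", "", markers[[m]]), "")[[1]]
      cds <- paste(vapply(pep, function(a) {
        opts <- tab[[a]]
        if (is.null(opts)) "NNN" else opts[sample.int(length(opts), 1L)]
      }, ""), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cds else .revComp(cds)
      parts <- c(parts, ins)
      meta <- rbind(meta, data.frame(
        marker = m, start = pos + 1L, end = pos + nchar(ins),
        strand = strand, stringsAsFactors = FALSE))
      pos <- pos + nchar(ins)
    }
    parts <- c(parts, rspacer(spacer))
    list(sequence = paste(parts, collapse = ""), meta = meta)
  })
}

#' Mean percentage of distinct columns per bootstrap replicate
#'
#' For each replicate, n column indices are drawn with replacement and the
#' fraction of distinct columns recorded; the mean (in percent) is returned.
#' The expectation is 100 (1 - (1 - 1/n)^n), approaching 100 (1 - 1/e),
#' about 63.2 percent, for large n: most of the reason an individual
#' bootstrap replicate carries less information than the original alignment.
#'
#' @param nColumns alignment width n.
#' @param B replicate count.
#' @param seed RNG seed.
#' @return mean distinct-column percentage across replicates.
#' @export
bootstrapDistinctFraction <- function(nColumns, B, seed = NULL) {
  stopifnot(nColumns >= 1, B >= 1)
  .withSeed(seed, {
    fr <- vapply(seq_len(B), function(i)
      length(unique(sample.int(nColumns, nColumns, replace = TRUE))) / nColumns,
      0)
    mean(fr) * 100
  })
}

## synthetic 7-rank taxonomy from the tree: rank r of a leaf is its ancestor
## at depth min(r-1, leaf depth-1) from the reporting root, rank 7 the leaf
## itself; nested by construction
.synthTaxonomy <- function(rt) {
  phy <- rt@phyRooted
  L <- length(phy$tip.label)
  parent <- rep(NA_integer_, max(phy$edge))
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  out <- list()
  for (i in seq_len(L)) {
    path <- i
    n <- i
    while (!is.na(parent[n])) { n <- parent[n]; path <- c(n, path) }
    anc <- path[-length(path)]
    lin <- character(7L)
    for (r in 1:6) {
      idx <- min(r, length(anc))
      lin[r] <- paste0("clade", anc[idx])
    }
    lin[7] <- phy$tip.label[i]
    out[[phy$tip.label[i]]] <- lin
  }
  out
}

#' Simulate a complete reference package
#'
#' Random tree, alignment evolved under the chosen empirical model with
#' discrete-Gamma rates, and a tree-consistent synthetic 7-rank taxonomy.
#'
#' @param nLeaves leaf count.
#' @param nCols alignment columns.
#' @param model model name (default WAG).
#' @param alpha Gamma shape used for simulation; stored in the package unless
#'   \code{pinAlpha = FALSE} (then left to be estimated at fit time).
#' @param seed RNG seed.
#' @param meanLength mean branch length.
#' @param pinAlpha store alpha in the package config.
#' @return list with \code{refpkg} (\linkS4class{RefPackage}) and \code{sim}
#'   (the detailed evolution object, for planting queries).
#' @export
simulateRefPackage <- function(nLeaves, nCols, model = "WAG", alpha = 1,
                               seed = NULL, meanLength = 0.1, pinAlpha = TRUE) {
  .withSeed(seed, {
    tree <- randomTree(nLeaves, seed = NULL, meanLength = meanLength)
    mod <- loadEmpiricalModel(model, alpha = alpha)
    sim <- evolveAlignment(tree, mod, nCols, seed = NULL, detail = TRUE)
    pkg <- new("RefPackage", tree = tree,
               msa = .asAAStringSet(sim$msa),
               taxonomy = .synthTaxonomy(tree),
               modelName = toupper(model),
               alpha = if (pinAlpha) alpha else NA_real_)
    validObject(pkg)
    list(refpkg = pkg, sim = sim)
  })
}
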
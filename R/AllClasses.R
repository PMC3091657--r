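#' @import methods
#' @importFrom stats optimize qgamma pgamma runif rexp setNames quantile
#' @importFrom utils read.table write.table head tail
NULL

setOldClass("phylo")

## Residues in PAML order; this ordering is shared by the shipped model
## matrices, the likelihood engine and the parsimony bitmasks.
AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' ReferenceTree: a fixed reference phylogeny with stable branch identifiers
#'
#' Wraps an \code{ape} \code{phylo} object in two views: the tree as parsed
#' (possibly rooted, used for reporting and taxonomy orientation) and the
#' unrooted placement view on which branch identifiers live. An unrooted
#' binary tree over L >= 3 leaves exposes 2L-3 placement branches; a rooted
#' binary input is unrooted internally (the two root-adjacent branches merge
#' into one, conserving total tree length) and the root position is retained.
#'
#' Branch ids are integers \code{0..B-1} and are a pure function of the
#' topology and the leaf labels: the tree is traversed in postorder from the
#' internal node adjacent to the alphabetically smallest leaf label, visiting
#' children ordered by the smallest leaf label in their subtree; each branch
#' receives its id when its subtree is completed (so leaves come before the
#' internal branches above them), and the pendant branch of the smallest leaf
#' receives the final id. This makes ids stable across runs, platforms and
#' serialization, and is the edge numbering used in jplace output.
#'
#' @slot phy unrooted placement view (\code{phylo}).
#' @slot phyRooted the tree as parsed (equal to \code{phy} for unrooted input).
#' @slot branchId integer vector, one 0-based id per row of \code{phy$edge}.
#' @slot rooted logical, whether the input carried a root.
#' @slot rootSplit leaf labels on one side of the stored root (empty if unrooted).
#' @export
setClass("ReferenceTree", representation(
  phy = "phylo",
  phyRooted = "phylo",
  branchId = "integer",
  rooted = "logical",
  rootSplit = "character"
))

setValidity("ReferenceTree", function(object) {
  phy <- object@phy
  msgs <- character()
  tl <- phy$tip.label
  if (anyDuplicated(tl)) msgs <- c(msgs, "duplicate leaf labels")
  if (any(!nzchar(tl))) msgs <- c(msgs, "empty leaf labels")
  bl <- phy$edge.length
  if (is.null(bl) || any(!is.finite(bl)) || any(bl < 0))
    msgs <- c(msgs, "branch lengths must be finite and >= 0")
  if (length(object@branchId) != nrow(phy$edge))
    msgs <- c(msgs, "branchId must have one entry per edge")
  if (length(object@branchId) &&
      !identical(sort(object@branchId), seq_len(nrow(phy$edge)) - 1L))
    msgs <- c(msgs, "branchId must be a permutation of 0..B-1")
  if (length(msgs)) msgs else TRUE
})

#' SubstitutionModel: empirical amino-acid model with discrete-Gamma rates
#'
#' Holds a symmetric exchangeability matrix S, equilibrium frequencies pi, the
#' derived reversible rate matrix Q (normalized so that -sum(pi_i Q_ii) = 1,
#' i.e. one expected substitution per site per unit branch length), a Gamma
#' shape alpha and K discrete rates with equal category probabilities and mean
#' exactly 1. The symmetric eigendecomposition of Q is cached so transition
#' matrices P(t) = exp(Q r t) can be assembled per branch and rate category.
#'
#' @slot name model name (e.g. "WAG").
#' @slot S 20x20 symmetric exchangeability matrix (diagonal ignored).
#' @slot pi equilibrium frequencies, length 20, summing to 1.
#' @slot Q normalized reversible rate matrix.
#' @slot alpha Gamma shape (> 0).
#' @slot rates K discrete rates, mean 1, equal category probability 1/K.
#' @slot eig cached eigendecomposition (values, U1, U2 with P = U1 diag(e^{lt}) U2).
#' @export
setClass("SubstitutionModel", representation(
  name = "character",
  S = "matrix",
  pi = "numeric",
  Q = "matrix",
  alpha = "numeric",
  rates = "numeric",
  eig = "list"
))

setValidity("SubstitutionModel", function(object) {
  msgs <- character()
  if (!isTRUE(all.equal(sum(object@pi), 1, tolerance = 1e-8)))
    msgs <- c(msgs, "frequencies must sum to 1")
  if (any(object@pi <= 0)) msgs <- c(msgs, "frequencies must be positive")
  if (abs(sum(rowSums(object@Q))) > 1e-8) msgs <- c(msgs, "Q rows must sum to 0")
  off <- object@Q; diag(off) <- 0
  if (any(off < -1e-12)) msgs <- c(msgs, "Q off-diagonals must be >= 0")
  if (object@alpha <= 0) msgs <- c(msgs, "alpha must be > 0")
  if (length(object@rates) &&
      !isTRUE(all.equal(mean(object@rates), 1, tolerance = 1e-12)))
    msgs <- c(msgs, "discrete rates must have mean 1")
  if (length(msgs)) msgs else TRUE
})

#' RefPackage: a reference package (tree + alignment + taxonomy + model)
#'
#' The unit the placement pipeline consumes: a \linkS4class{ReferenceTree},
#' the matching amino-acid reference alignment, an optional per-leaf taxonomy
#' (seven ranks: domain;phylum;class;order;family;genus;species), the name of
#' the substitution model, and an optional fixed Gamma shape (estimated from
#' the data when \code{NA}).
#'
#' @slot tree \linkS4class{ReferenceTree}.
#' @slot msa \code{AAStringSet} of aligned rows, one per tree leaf.
#' @slot taxonomy named list mapping leaf label to a character(7) lineage, or empty.
#' @slot modelName one of the shipped empirical models.
#' @slot alpha Gamma shape, \code{NA_real_} to estimate.
#' @export
setClass("RefPackage", representation(
  tree = "ReferenceTree",
  msa = "ANY",
  taxonomy = "list",
  modelName = "character",
  alpha = "numeric"
))

setValidity("RefPackage", function(object) {
  msgs <- character()
  tl <- object@tree@phy$tip.label
  rows <- names(object@msa)
  miss <- setdiff(tl, rows)
  if (length(miss))
    msgs <- c(msgs, paste0("tree leaves missing from alignment: ",
                           paste(miss, collapse = ", ")))
  w <- Biostrings::width(object@msa)
  if (length(w) && length(unique(w)) != 1L)
    msgs <- c(msgs, "alignment rows differ in length")
  if (anyDuplicated(rows)) msgs <- c(msgs, "duplicate alignment row labels")
  if (length(object@taxonomy)) {
    miss <- setdiff(tl, names(object@taxonomy))
    if (length(miss))
      msgs <- c(msgs, paste0("taxonomy missing leaves: ",
                             paste(miss, collapse = ", ")))
    depth <- lengths(object@taxonomy)
    if (length(unique(depth)) != 1L)
      msgs <- c(msgs, "taxonomy lineages have ragged depth")
  }
  if (length(msgs)) msgs else TRUE
})

#' FittedReference: reference tree with optimized branch lengths and model
#'
#' Produced by \code{\link{fitReference}}. Carries the optimized tree and
#' model, the site-pattern compression of the reference alignment (pattern
#' weights sum to the alignment length), per-edge conditional likelihood
#' vectors cached toward both ends of every branch (the placement stage reads
#' these and never recomputes reference vectors), and the total log-likelihood.
#'
#' @slot refpkg the originating \linkS4class{RefPackage}.
#' @slot tree tree with optimized branch lengths.
#' @slot model model with the fitted Gamma shape.
#' @slot engine internal likelihood engine state (patterns, messages).
#' @slot logLik total log-likelihood in nats.
#' @export
setClass("FittedReference", representation(
  refpkg = "RefPackage",
  tree = "ReferenceTree",
  model = "SubstitutionModel",
  engine = "list",
  logLik = "numeric"
))

#' PlacementResult: ranked per-branch placement of one query
#'
#' @slot queryId query identifier.
#' @slot method "ML" or "MP".
#' @slot table data.frame with one row per evaluated branch: \code{branch},
#'   \code{logLik} (for MP: minus the parsimony score, so rank 1 is best),
#'   \code{distal}, \code{proximal}, \code{pendant}, \code{lwr}
#'   (like-weight ratio over all evaluated branches), \code{rank}.
#' @slot support named numeric of bootstrap supports per branch id (possibly empty).
#' @slot markers marker names that contributed.
#' @export
setClass("PlacementResult", representation(
  queryId = "character",
  method = "character",
  table = "data.frame",
  support = "numeric",
  markers = "character"
))

setValidity("PlacementResult", function(object) {
  msgs <- character()
  tb <- object@table
  need <- c("branch", "logLik", "distal", "proximal", "pendant", "lwr", "rank")
  if (!all(need %in% names(tb))) msgs <- c(msgs, "table missing columns")
  else {
    if (nrow(tb) && abs(sum(tb$lwr) - 1) > 1e-6)
      msgs <- c(msgs, "like-weight ratios must sum to 1")
    if (nrow(tb) && tb$logLik[which(tb$rank == 1L)] < max(tb$logLik) - 1e-9)
      msgs <- c(msgs, "rank 1 must have maximal logLik")
  }
  if (length(object@support) &&
      (any(object@support < 0) || any(object@support > 1)))
    msgs <- c(msgs, "supports must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})
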
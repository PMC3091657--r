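#' Number of placement branches of a tree-like object
#' @param x a \linkS4class{ReferenceTree}, \linkS4class{RefPackage} or
#'   \linkS4class{FittedReference}.
#' @return integer branch count (2L-3 for an unrooted binary tree on L leaves).
#' @export
setGeneric("nBranches", function(x) standardGeneric("nBranches"))

#' Branch lengths indexed by branch id
#' @param x a tree-like object.
#' @return numeric vector named by branch id, in id order.
#' @export
setGeneric("branchLengths", function(x) standardGeneric("branchLengths"))

#' The reference tree of an object
#' @param x a \linkS4class{RefPackage} or \linkS4class{FittedReference}.
#' @export
setGeneric("refTree", function(x) standardGeneric("refTree"))

#' The reference alignment of an object
#' @param x a \linkS4class{RefPackage} or \linkS4class{FittedReference}.
#' @export
setGeneric("refMsa", function(x) standardGeneric("refMsa"))

#' Per-leaf taxonomy of a reference package
#' @param x a \linkS4class{RefPackage}.
#' @return named list of character(7) lineages (empty list if absent).
#' @export
setGeneric("taxonomyMap", function(x) standardGeneric("taxonomyMap"))

#' Ranked placement table of a result
#' @param x a \linkS4class{PlacementResult}.
#' @return data.frame ordered by rank.
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' Best (rank-1) branch id of a placement
#' @param x a \linkS4class{PlacementResult}.
#' @export
setGeneric("bestBranch", function(x) standardGeneric("bestBranch"))

setMethod("nBranches", "ReferenceTree", function(x) nrow(x@phy$edge))
setMethod("nBranches", "RefPackage", function(x) nBranches(x@tree))
setMethod("nBranches", "FittedReference", function(x) nBranches(x@tree))

setMethod("branchLengths", "ReferenceTree", function(x) {
  bl <- x@phy$edge.length[order(x@branchId)]
  names(bl) <- seq_along(bl) - 1L
  bl
})
setMethod("branchLengths", "RefPackage", function(x) branchLengths(x@tree))
setMethod("branchLengths", "FittedReference", function(x) branchLengths(x@tree))

setMethod("refTree", "RefPackage", function(x) x@tree)
setMethod("refTree", "FittedReference", function(x) x@tree)
setMethod("refMsa", "RefPackage", function(x) x@msa)
setMethod("refMsa", "FittedReference", function(x) x@refpkg@msa)
setMethod("taxonomyMap", "RefPackage", function(x) x@taxonomy)

setMethod("placements", "PlacementResult", function(x)
  x@table[order(x@table$rank), , drop = FALSE])
setMethod("bestBranch", "PlacementResult", function(x)
  x@table$branch[which(x@table$rank == 1L)])

setMethod("show", "ReferenceTree", function(object) {
  cat("ReferenceTree:", length(object@phy$tip.label), "leaves,",
      nBranches(object), "placement branches",
      if (object@rooted) "(rooted input)" else "(unrooted)", "\n")
})

setMethod("show", "RefPackage", function(object) {
  cat("RefPackage:", length(object@tree@phy$tip.label), "leaves,",
      ncol(.msaMatrix(object@msa)), "alignment columns, model",
      object@modelName,
      if (length(object@taxonomy)) "with taxonomy" else "without taxonomy",
      "\n")
})

setMethod("show", "SubstitutionModel", function(object) {
  cat("SubstitutionModel:", object@name, "+G, alpha =",
      format(object@alpha, digits = 4), "with", length(object@rates),
      "rate categories\n")
})

setMethod("show", "FittedReference", function(object) {
  cat("FittedReference:", length(object@tree@phy$tip.label), "leaves, logLik =",
      format(object@logLik, digits = 10), ", alpha =",
      format(object@model@alpha, digits = 4), "\n")
})

setMethod("show", "PlacementResult", function(object) {
  tb <- placements(object)
  cat("PlacementResult for", object@queryId, "[", object@method, "]:",
      nrow(tb), "branches evaluated; best branch", tb$branch[1],
      "(lwr", format(tb$lwr[1], digits = 3), ")\n")
})
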
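## Validation machinery: genome fragmentation, leave-one-out pruning,
## node-distance scoring, taxonomy assignment, aggregate accuracy reports.

#' Fragment a nucleotide sequence into non-overlapping windows
#'
#' Consecutive non-overlapping fragments of the given size; a trailing
#' remainder shorter than \code{size} is discarded. Fragments carry their
#' source offsets.
#'
#' @param sequence nucleotide string.
#' @param size fragment size in nt (default 1000).
#' @return data.frame with id, start, end, seq (possibly zero rows).
#' @export
fragmentGenome <- function(sequence, size = 1000L) {
  n <- nchar(sequence)
  k <- n %/% size
  if (k == 0L)
    return(data.frame(id = character(), start = integer(), end = integer(),
                      seq = character(), stringsAsFactors = FALSE))
  starts <- (seq_len(k) - 1L) * size + 1L
  data.frame(id = sprintf("frag%04d", seq_len(k)), start = starts,
             end = starts + size - 1L,
             seq = substring(sequence, starts, starts + size - 1L),
             stringsAsFactors = FALSE)
}

.findBranchBySplit <- function(rt, leafset) {
  splits <- .edgeSplits(rt@phy)
  allT <- sort(rt@phy$tip.label)
  set <- sort(leafset)
  comp <- sort(setdiff(allT, set))
  hit <- which(vapply(splits, function(s)
    identical(s, set) || identical(s, comp), TRUE))
  if (!length(hit)) return(NA_integer_)
  rt@branchId[hit[1L]]
}

#' Prune taxa from a reference package, recording the attachment branch
#'
#' Removes the given leaves (which must form one side of a split, i.e. a
#' single leaf or a clade), suppresses the resulting degree-2 node with
#' branch lengths summed, drops the alignment rows and taxonomy entries, and
#' records the branch of the reduced tree where the pruned taxa were
#' attached (the "true branch" for leave-one-out validation).
#'
#' @param refpkg a \linkS4class{RefPackage}.
#' @param labels leaf labels to remove.
#' @return list with \code{refpkg} (reduced package) and \code{trueBranch}
#'   (branch id in the reduced tree).
#' @export
pruneTaxa <- function(refpkg, labels) {
  rt <- refpkg@tree
  phy <- rt@phy
  miss <- setdiff(labels, phy$tip.label)
  if (length(miss)) stop("labels not in tree: ", paste(miss, collapse = ", "))
  if (length(phy$tip.label) - length(labels) < 3L)
    stop("pruning would leave fewer than 3 leaves")
  allT <- sort(phy$tip.label)
  set <- sort(labels)
  splits <- .edgeSplits(phy)
  estar <- which(vapply(splits, function(s)
    identical(s, set) || identical(s, sort(setdiff(allT, set))), TRUE))
  if (!length(estar)) stop("pruned labels do not form a clade")
  estar <- estar[1L]
  attachNode <- if (identical(splits[[estar]], set)) phy$edge[estar, 1L]
                else phy$edge[estar, 2L]
  others <- setdiff(which(phy$edge[, 1L] == attachNode |
                            phy$edge[, 2L] == attachNode), estar)
  e1 <- others[1L]
  s1 <- if (phy$edge[e1, 1L] == attachNode) splits[[e1]]
        else setdiff(allT, splits[[e1]])
  trueSplit <- sort(setdiff(s1, set))
  newphy <- ape::drop.tip(rt@phyRooted, labels)
  newrt <- .newReferenceTree(newphy)
  trueBranch <- .findBranchBySplit(newrt, trueSplit)
  keep <- setdiff(names(refpkg@msa), labels)
  tax <- refpkg@taxonomy
  if (length(tax)) tax <- tax[setdiff(names(tax), labels)]
  out <- new("RefPackage", tree = newrt, msa = refpkg@msa[keep],
             taxonomy = tax, modelName = refpkg@modelName,
             alpha = refpkg@alpha)
  validObject(out)
  list(refpkg = out, trueBranch = trueBranch)
}

#' Node distance between two branches
#'
#' The number of internal nodes strictly between the two branches along the
#' unique connecting path: 0 for the same branch, 1 for branches sharing an
#' endpoint (e.g. the two pendant branches of a cherry), 2 for pendant
#' branches of an "uncle" pair, and so on.
#'
#' @param tree a \linkS4class{ReferenceTree}.
#' @param a,b branch ids.
#' @return non-negative integer.
#' @export
nodeDistance <- function(tree, a, b) {
  ea <- .branchEdgeRow(tree, a)
  eb <- .branchEdgeRow(tree, b)
  if (ea == eb) return(0L)
  phy <- tree@phy
  nn <- max(phy$edge)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  src <- phy$edge[ea, ]
  dist <- rep(NA_integer_, nn)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    n <- queue[1L]; queue <- queue[-1L]
    for (m in adj[[n]]) if (is.na(dist[m])) {
      dist[m] <- dist[n] + 1L
      queue <- c(queue, m)
    }
  }
  min(dist[phy$edge[eb, ]]) + 1L
}

.commonPrefix <- function(lineages) {
  if (!length(lineages)) return(character())
  depth <- min(lengths(lineages))
  out <- character()
  for (r in seq_len(depth)) {
    vals <- unique(vapply(lineages, `[[`, "", r))
    if (length(vals) != 1L) break
    out <- c(out, vals)
  }
  out
}

#' Taxonomic assignment for a placement branch
#'
#' Takes the leaf set of the clade below the placement branch (leafward in
#' the rooted reporting orientation; the branch carrying the root maps to the
#' whole tree) and returns the longest lineage prefix shared by all those
#' leaves. An empty prefix (no agreement even at domain rank) is possible.
#'
#' @param refpkg a \linkS4class{RefPackage} with taxonomy.
#' @param branch branch id.
#' @return character vector, a prefix of the 7-rank lineage.
#' @export
assignTaxonomy <- function(refpkg, branch) {
  if (!length(refpkg@taxonomy)) stop("reference package has no taxonomy")
  rt <- refpkg@tree
  e <- .branchEdgeRow(rt, branch)
  splits <- .edgeSplits(rt@phy)
  d <- splits[[e]]
  allT <- sort(rt@phy$tip.label)
  clade <- if (rt@rooted) {
    s1 <- sort(rt@rootSplit)
    s2 <- setdiff(allT, s1)
    dc <- setdiff(allT, d)
    if (identical(sort(d), s1) || identical(sort(d), s2)) allT # root branch
    else if (all(d %in% s1) || all(d %in% s2)) d
    else dc
  } else d                          # reporting orientation = parse orientation
  miss <- setdiff(clade, names(refpkg@taxonomy))
  if (length(miss))
    stop("missing lineage for leaves: ", paste(miss, collapse = ", "))
  .commonPrefix(refpkg@taxonomy[clade])
}

.deepestCorrectRank <- function(assigned, truth) {
  r <- 0L
  for (i in seq_len(min(length(assigned), length(truth)))) {
    if (assigned[i] != truth[i]) break
    r <- i
  }
  r
}

#' Leave-one-out validation of one reference taxon
#'
#' Prunes the target from the reference package (avoiding circularity),
#' fragments its genome into non-overlapping windows, runs the full
#' preprocessing chain (six-frame translation, frame selection against the
#' pruned reference profile, profile alignment, column trimming by the
#' reference mask, 50-aa length filter) and places every surviving fragment
#' with the chosen engine, scoring node distances to the recorded true
#' branch and taxonomy agreement. Per-fragment failures are recorded and do
#' not abort the run.
#'
#' @param refpkg a \linkS4class{RefPackage}.
#' @param target leaf label to hold out.
#' @param genome nucleotide genome of the target; when \code{NULL} a
#'   synthetic genome embedding the target's (ungapped) marker row is built.
#' @param method "ML" or "MP".
#' @param fragmentSize fragment size in nt.
#' @param minLen post-trim residue threshold.
#' @param seed RNG seed (genome synthesis).
#' @param fitted optional pre-fitted pruned reference (as returned in the
#'   \code{fitted} element) to reuse across calls.
#' @param pruneLabels labels to prune (default just the target; pass a clade
#'   to emulate removal of progressively deeper reference information).
#' @return list: \code{records} (data.frame, one row per placed fragment),
#'   \code{dropped} (data.frame of skipped fragments with reasons),
#'   \code{trueBranch}, \code{fitted} (reusable pruned fit).
#' @export
leaveOneOut <- function(refpkg, target, genome = NULL,
                        method = c("ML", "MP"), fragmentSize = 1000L,
                        minLen = 50L, seed = NULL, fitted = NULL,
                        pruneLabels = target) {
  method <- match.arg(method)
  stopifnot(target %in% refpkg@tree@phy$tip.label, target %in% pruneLabels)
  if (is.null(genome)) {
    pep <- gsub("[-*X]", "", as.character(refpkg@msa[[target]]))
    genome <- synthGenome(setNames(pep, "marker1"), seed = seed)
  }
  if (is.null(fitted)) {
    pr <- pruneTaxa(refpkg, pruneLabels)
    mask <- trimColumns(setNames(as.character(pr$refpkg@msa),
                                 names(pr$refpkg@msa)))
    rows <- setNames(as.character(pr$refpkg@msa), names(pr$refpkg@msa))
    trimmedPkg <- new("RefPackage", tree = pr$refpkg@tree,
                      msa = .asAAStringSet(applyMask(rows, mask)),
                      taxonomy = pr$refpkg@taxonomy,
                      modelName = pr$refpkg@modelName,
                      alpha = pr$refpkg@alpha)
    profile <- buildProfile(rows)
    fitted <- list(pruned = pr$refpkg, trimmed = trimmedPkg, mask = mask,
                   profile = profile, trueBranch = pr$trueBranch,
                   fit = if (method == "ML") fitReference(trimmedPkg) else NULL)
  }
  trueBranch <- fitted$trueBranch
  truth <- if (length(refpkg@taxonomy)) refpkg@taxonomy[[target]] else NULL
  frags <- fragmentGenome(genome$sequence, fragmentSize)
  records <- list()
  dropped <- list()
  for (i in seq_len(nrow(frags))) {
    fid <- frags$id[i]
    rec <- tryCatch({
      peps <- translateSixFrames(frags$seq[i])
      sel <- selectFrame(peps, fitted$profile)
      row <- applyMask(setNames(sel$row, "q"), fitted$mask)[[1L]]
      if (!lengthFilter(row, minLen))
        stop("fewer than ", minLen, " residues after trimming")
      res <- if (method == "ML")
        placeQueryML(fitted$fit, row, fid)
      else placeQueryMP(fitted$trimmed, row, fid)
      obs <- bestBranch(res)
      nd <- nodeDistance(fitted$trimmed@tree, trueBranch, obs)
      assigned <- if (length(refpkg@taxonomy))
        assignTaxonomy(fitted$trimmed, obs) else character()
      data.frame(fragment = fid, method = method,
                 trueBranch = trueBranch, observedBranch = obs,
                 nodeDist = nd, correct2 = nd <= 2L,
                 assignedLineage = paste(assigned, collapse = ";"),
                 deepestCorrectRank = if (is.null(truth)) NA_integer_
                                      else .deepestCorrectRank(assigned, truth),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(fragment = fid, reason = conditionMessage(e),
                 stringsAsFactors = FALSE))
    if ("reason" %in% names(rec)) dropped[[fid]] <- rec
    else records[[fid]] <- rec
  }
  list(records = do.call(rbind, c(records, list(NULL))),
       dropped = do.call(rbind, c(dropped, list(NULL))),
       trueBranch = trueBranch, fitted = fitted)
}

#' Aggregate placement accuracy over evaluation records
#'
#' Fractions placed at node distance 0 and within two nodes, per-rank
#' taxonomic correctness (a record is correct at a rank when its assigned
#' lineage prefix matches the truth through that rank), and per-branch
#' placement counts. Optional per-record weights (e.g. assembly depth)
#' scale each record's contribution. When records carry more than one
#' method, per-method columns are reported side by side.
#'
#' @param records data.frame from \code{\link{leaveOneOut}} (rbind-able).
#' @param weights optional numeric weights, one per record.
#' @return list: \code{summary} (per-method accuracy table),
#'   \code{perRank} (per-method correctness at each named rank),
#'   \code{branchCounts} (weighted placements per branch).
#' @export
aggregateReport <- function(records, weights = NULL) {
  if (is.null(records) || !nrow(records)) stop("no evaluation records")
  if (is.null(weights)) weights <- rep(1, nrow(records))
  stopifnot(length(weights) == nrow(records))
  ranks <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
             family = 5L, genus = 6L, species = 7L)
  methods <- unique(records$method)
  one <- function(idx) {
    w <- weights[idx]; rc <- records[idx, , drop = FALSE]
    tot <- sum(w)
    c(pctDist0 = 100 * sum(w * (rc$nodeDist == 0L)) / tot,
      pctWithin2 = 100 * sum(w * rc$correct2) / tot,
      meanNodeDist = sum(w * rc$nodeDist) / tot,
      n = sum(idx))
  }
  oneRank <- function(idx) {
    w <- weights[idx]; rc <- records[idx, , drop = FALSE]
    vapply(ranks, function(r)
      100 * sum(w * (!is.na(rc$deepestCorrectRank) &
                       rc$deepestCorrectRank >= r)) / sum(w), 0)
  }
  summary <- do.call(cbind, lapply(methods, function(m)
    one(records$method == m)))
  colnames(summary) <- methods
  perRank <- do.call(cbind, lapply(methods, function(m)
    oneRank(records$method == m)))
  colnames(perRank) <- methods
  counts <- tapply(weights, records$observedBranch, sum)
  branchCounts <- data.frame(branch = as.integer(names(counts)),
                             count = as.numeric(counts))
  branchCounts <- branchCounts[order(branchCounts$branch), , drop = FALSE]
  rownames(branchCounts) <- NULL
  list(summary = as.data.frame(summary),
       perRank = as.data.frame(perRank),
       branchCounts = branchCounts)
}
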
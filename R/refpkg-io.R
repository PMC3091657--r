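## Reference-package I/O: newick, FASTA, taxonomy TSV, jplace.

## deterministic branch ids: postorder from the smallest leaf label,
## children ordered by the smallest label in their subtree
.assignBranchIds <- function(phy) {
  E <- nrow(phy$edge)
  nnode <- max(phy$edge)
  inc <- vector("list", nnode)           # incident edge rows per node
  for (i in seq_len(E)) {
    a <- phy$edge[i, 1L]; b <- phy$edge[i, 2L]
    inc[[a]] <- c(inc[[a]], i)
    inc[[b]] <- c(inc[[b]], i)
  }
  other <- function(e, n) if (phy$edge[e, 1L] == n) phy$edge[e, 2L] else phy$edge[e, 1L]
  tl <- phy$tip.label
  start <- which(tl == min(tl))          # alphabetically smallest leaf
  minlab <- new.env(parent = emptyenv()) # memo: smallest label beyond directed edge
  minLabel <- function(e, from) {        # component of other(e, from)
    key <- paste0(e, ".", from)
    if (!is.null(v <- minlab[[key]])) return(v)
    n <- other(e, from)
    v <- if (n <= length(tl)) tl[n] else {
      min(vapply(setdiff(inc[[n]], e), minLabel, "", from = n))
    }
    minlab[[key]] <- v
    v
  }
  ids <- integer(E)
  counter <- 0L
  visit <- function(node, fromEdge) {
    kids <- setdiff(inc[[node]], fromEdge)
    kids <- kids[order(vapply(kids, minLabel, "", from = node))]
    for (e in kids) {
      ch <- other(e, node)
      if (ch > length(tl)) visit(ch, e)
      ids[e] <<- counter
      counter <<- counter + 1L
    }
  }
  pend <- inc[[start]]
  visit(other(pend, start), pend)
  ids[pend] <- counter
  ids
}

## leaf-label set on the distal (edge[,2]) side of every edge
.edgeSplits <- function(phy) {
  E <- nrow(phy$edge)
  L <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  below <- vector("list", max(phy$edge))
  for (i in seq_len(L)) below[[i]] <- phy$tip.label[i]
  for (k in seq_len(E)) {
    par <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  lapply(seq_len(E), function(i) sort(below[[phy$edge[i, 2L]]]))
}

.branchEdgeRow <- function(rt, branch) {
  row <- match(as.integer(branch), rt@branchId)
  if (any(is.na(row)))
    stop("unknown branch id: ", paste(branch[is.na(row)], collapse = ", "))
  row
}

.checkNewickText <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || tail(depth, 1) != 0)
    stop("unbalanced parentheses in newick input near position ",
         if (any(depth < 0)) which(depth < 0)[1] else length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop("newick input lacks terminating ';'")
}

.newReferenceTree <- function(phy) {
  if (is.null(phy$edge.length))
    stop("newick input lacks branch lengths")
  if (any(is.na(phy$edge.length)) || any(!is.finite(phy$edge.length)))
    stop("missing or non-finite branch length")
  neg <- phy$edge.length < 0
  if (any(neg))
    stop("negative branch length ", phy$edge.length[neg][1])
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf label: ",
         phy$tip.label[duplicated(phy$tip.label)][1])
  rooted <- ape::is.rooted(phy) && length(phy$tip.label) >= 3L
  rootSplit <- character()
  if (rooted) {
    root <- length(phy$tip.label) + 1L
    kid <- phy$edge[phy$edge[, 1L] == root, 2L][1]
    rootSplit <- sort(phy$tip.label[.descendantTips(phy, kid)])
    uphy <- ape::unroot(phy)
  } else {
    uphy <- phy
  }
  new("ReferenceTree", phy = uphy, phyRooted = phy,
      branchId = .assignBranchIds(uphy), rooted = rooted,
      rootSplit = rootSplit)
}

.descendantTips <- function(phy, node) {
  L <- length(phy$tip.label)
  if (node <= L) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    n <- stack[1]; stack <- stack[-1]
    ch <- phy$edge[phy$edge[, 1L] == n, 2L]
    out <- c(out, ch[ch <= L])
    stack <- c(stack, ch[ch > L])
  }
  out
}

#' Parse a newick string into a ReferenceTree
#'
#' Branch ids are assigned deterministically from topology and labels (see
#' \linkS4class{ReferenceTree}). Rooted binary inputs are unrooted for
#' placement (the two root-adjacent branches merge, conserving total length)
#' and the root position is stored for rooted reporting.
#'
#' @param text a newick string with branch lengths.
#' @return a \linkS4class{ReferenceTree}.
#' @export
parseNewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .checkNewickText(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("newick parse error: ",
                                           conditionMessage(e)))
  if (is.null(phy) || !inherits(phy, "phylo"))
    stop("newick parse error: could not read tree")
  if (length(phy$tip.label) < 2L) stop("tree needs at least 2 leaves")
  validObject(rt <- .newReferenceTree(phy))
  rt
}

#' Serialize a ReferenceTree back to newick
#'
#' Writes the tree as parsed (rooted if the input was rooted), with branch
#' lengths printed to at least 10 significant digits so that
#' parse-write-parse round trips preserve topology, labels and lengths.
#'
#' @param tree a \linkS4class{ReferenceTree}.
#' @param file optional path; when given the string is also written there.
#' @return the newick string, invisibly when \code{file} is given.
#' @export
writeNewick <- function(tree, file = NULL) {
  stopifnot(is(tree, "ReferenceTree"))
  phy <- tree@phyRooted
  s <- ape::write.tree(phy, digits = 12)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a FASTA file into a named character vector
#'
#' Order is preserved, wrapped lines are joined, and '*' stop symbols are
#' tolerated in peptides. Duplicate headers and empty files are errors.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences (upper case).
#' @export
readFasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("FASTA file does not start with a header: ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids))
    stop("duplicate FASTA header: ", ids[duplicated(ids)][1])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), "")
  out <- setNames(character(length(ids)), ids)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- ids
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.msaMatrix <- function(msa) {
  seqs <- as.character(msa)
  do.call(rbind, strsplit(seqs, ""))
}

.asAAStringSet <- function(seqs) {
  x <- Biostrings::AAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  x
}

.readTaxonomy <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) != 2L) stop("taxonomy TSV must have 2 columns (leaf, lineage)")
  lin <- strsplit(tab[[2]], ";", fixed = TRUE)
  lin <- lapply(lin, trimws)
  depth <- lengths(lin)
  if (length(unique(depth)) != 1L)
    stop("ragged taxonomy lineage depth: ", paste(unique(depth), collapse = ", "))
  if (depth[1] != 7L)
    stop("taxonomy lineages must have 7 ranks, found ", depth[1])
  setNames(lin, tab[[1]])
}

.writeTaxonomy <- function(taxonomy, path) {
  lines <- vapply(names(taxonomy), function(n)
    paste0(n, "\t", paste(taxonomy[[n]], collapse = ";")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Load a reference package from a directory
#'
#' Expects \code{tree.nwk} and \code{alignment.fasta}, plus optional
#' \code{taxonomy.tsv} (leaf TAB semicolon-delimited 7-rank lineage) and
#' \code{config} (flat key=value: \code{model}, \code{alpha}).
#'
#' @param dir directory path.
#' @return a validated \linkS4class{RefPackage}.
#' @export
loadReferencePackage <- function(dir) {
  treeFile <- file.path(dir, "tree.nwk")
  alnFile <- file.path(dir, "alignment.fasta")
  if (!file.exists(treeFile)) stop("missing ", treeFile)
  if (!file.exists(alnFile)) stop("missing ", alnFile)
  tree <- parseNewick(paste(readLines(treeFile), collapse = ""))
  msa <- .asAAStringSet(readFasta(alnFile))
  taxonomy <- list()
  taxFile <- file.path(dir, "taxonomy.tsv")
  if (file.exists(taxFile)) taxonomy <- .readTaxonomy(taxFile)
  modelName <- "WAG"
  alpha <- NA_real_
  cfgFile <- file.path(dir, "config")
  if (file.exists(cfgFile)) {
    kv <- readLines(cfgFile)
    kv <- kv[nzchar(kv) & !grepl("^#", kv)]
    keys <- sub("=.*", "", kv)
    vals <- trimws(sub("^[^=]*=", "", kv))
    names(vals) <- trimws(keys)
    if ("model" %in% names(vals)) modelName <- vals[["model"]]
    if ("alpha" %in% names(vals)) alpha <- as.numeric(vals[["alpha"]])
  }
  pkg <- new("RefPackage", tree = tree, msa = msa, taxonomy = taxonomy,
             modelName = modelName, alpha = alpha)
  validObject(pkg)
  pkg
}

#' Write a reference package to a directory in the standard layout
#'
#' @param refpkg a \linkS4class{RefPackage}.
#' @param dir output directory (created if needed).
#' @export
writeReferencePackage <- function(refpkg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeNewick(refpkg@tree, file.path(dir, "tree.nwk"))
  writeFasta(setNames(as.character(refpkg@msa), names(refpkg@msa)),
             file.path(dir, "alignment.fasta"))
  if (length(refpkg@taxonomy))
    .writeTaxonomy(refpkg@taxonomy, file.path(dir, "taxonomy.tsv"))
  cfg <- c(paste0("model=", refpkg@modelName))
  if (!is.na(refpkg@alpha)) cfg <- c(cfg, paste0("alpha=", refpkg@alpha))
  writeLines(cfg, file.path(dir, "config"))
  invisible(dir)
}

## edge-numbered newick: label:length{branchId}
.jplaceTreeString <- function(rt) {
  phy <- rt@phy
  L <- length(phy$tip.label)
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1L])
  fmt <- function(x) format(x, digits = 12, trim = TRUE, scientific = FALSE)
  sub <- function(edgeRow) {
    ch <- phy$edge[edgeRow, 2L]
    body <- if (ch <= L) phy$tip.label[ch] else {
      paste0("(", paste(vapply(kids[[as.character(ch)]], sub, ""),
                        collapse = ","), ")")
    }
    paste0(body, ":", fmt(phy$edge.length[edgeRow]),
           "{", rt@branchId[edgeRow], "}")
  }
  root <- L + 1L
  paste0("(", paste(vapply(kids[[as.character(root)]], sub, ""),
                    collapse = ","), ");")
}

#' Write placements as a jplace (version 3) document
#'
#' Fields are \code{edge_num, likelihood, like_weight_ratio, distal_length,
#' pendant_length}; edge numbers in the embedded newick are the stable branch
#' ids of the reference tree, so output is reproducible across runs.
#' Like-weight ratios per query sum to 1 over the reported placements.
#'
#' @param results list of \linkS4class{PlacementResult}.
#' @param tree the \linkS4class{ReferenceTree} placed against.
#' @param file optional output path.
#' @param top report at most this many best branches per query (default all).
#' @return the jplace document as a list (written as JSON when \code{file} given).
#' @export
writeJplace <- function(results, tree, file = NULL, top = Inf) {
  stopifnot(is(tree, "ReferenceTree"))
  if (is(results, "PlacementResult")) results <- list(results)
  B <- nBranches(tree)
  pqueries <- lapply(results, function(res) {
    tb <- placements(res)
    if (any(tb$branch < 0 | tb$branch >= B))
      stop("unknown branch id in placement for ", res@queryId)
    if (is.finite(top) && nrow(tb) > top) {
      tb <- tb[seq_len(top), , drop = FALSE]
      tb$lwr <- tb$lwr / sum(tb$lwr)
    }
    p <- lapply(seq_len(nrow(tb)), function(i)
      list(tb$branch[i], tb$logLik[i], tb$lwr[i], tb$distal[i], tb$pendant[i]))
    list(p = p, n = list(res@queryId))
  })
  doc <- list(
    version = 3L,
    tree = .jplaceTreeString(tree),
    fields = list("edge_num", "likelihood", "like_weight_ratio",
                  "distal_length", "pendant_length"),
    placements = pqueries,
    metadata = list(invocation = "phyloplace")
  )
  if (!is.null(file))
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA)
  invisible(doc)
}
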
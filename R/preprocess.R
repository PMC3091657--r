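## Preprocessing: six-frame translation, profile construction and alignment
## of query peptides into reference coordinates, conserved-block column
## trimming, the post-trim length filter, and multi-marker concatenation.

.revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Translate a nucleotide sequence in all six reading frames
#'
#' Standard genetic code (translation table 1, via Biostrings); frames
#' -1..-3 translate the reverse complement. A trailing 1-2 nt remainder is
#' dropped. Any codon containing a non-ACGT base yields 'X'; internal stops
#' are kept as '*' (both are treated as missing data downstream).
#'
#' @param nt nucleotide sequence (IUPAC; case-insensitive).
#' @return named character vector of 6 peptides ("+1","+2","+3","-1","-2","-3").
#' @export
translateSixFrames <- function(nt) {
  nt <- toupper(nt)
  if (!nzchar(nt)) stop("empty nucleotide sequence")
  gc <- Biostrings::GENETIC_CODE
  one <- function(s) {
    n <- nchar(s)
    if (n < 3L) return("")
    starts <- seq(1L, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"   # codon contains a non-ACGT base
    paste(aa, collapse = "")
  }
  rc <- .revComp(nt)
  out <- c(one(nt), one(substring(nt, 2L)), one(substring(nt, 3L)),
           one(rc), one(substring(rc, 2L)), one(substring(rc, 3L)))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Per-column residue profile of a reference alignment
#'
#' Column-wise residue frequencies with a pseudocount of 0.1 per residue;
#' gaps and unknowns are not counted. The background distribution is the
#' substitution model's equilibrium frequencies (used for log-odds scores).
#'
#' @param msa named character vector or \code{AAStringSet} of aligned rows.
#' @param model a \linkS4class{SubstitutionModel} supplying the background
#'   (default: WAG frequencies).
#' @return list with \code{freq} (20 x columns matrix, columns sum to 1),
#'   \code{background} (length 20) and \code{logOdds} (20 x columns).
#' @export
buildProfile <- function(msa, model = NULL) {
  mat <- .msaMatrix(.asAAStringSet(as.character(msa)))
  if (!ncol(mat)) stop("empty alignment")
  if (is.null(model)) model <- loadEmpiricalModel("WAG")
  bg <- model@pi
  counts <- apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = AA_ORDER))
    as.numeric(tab)
  })
  counts <- counts + 0.1
  freq <- sweep(counts, 2L, colSums(counts), "/")
  rownames(freq) <- AA_ORDER
  list(freq = freq, background = bg, logOdds = log(freq / bg))
}

## glocal affine-gap DP of a peptide against profile columns:
## global in the peptide, local in the reference (flanking columns free);
## emissions are per-column log-odds, gap open 11, gap extend 1.
## Rows are vectorized over reference columns; the within-row deletion
## recurrence is a max-plus prefix scan (cummax trick).
.GAP_OPEN <- 11
.GAP_EXT <- 1

.alignDP <- function(emit) {
  m <- nrow(emit)   # peptide length
  n <- ncol(emit)   # reference columns
  NEG <- -1e18
  M <- matrix(NEG, m + 1L, n + 1L)
  Ix <- matrix(NEG, m + 1L, n + 1L)  # insertion: peptide consumed, no column
  Iy <- matrix(NEG, m + 1L, n + 1L)  # deletion: column consumed, no peptide
  M[1L, ] <- 0                       # free leading reference columns
  for (i in seq_len(m)) {
    prev <- pmax(M[i, ], Ix[i, ], Iy[i, ])
    M[i + 1L, 2L:(n + 1L)] <- prev[1L:n] + emit[i, ]
    Ix[i + 1L, ] <- pmax(M[i, ] - .GAP_OPEN, Ix[i, ] - .GAP_EXT)
    ## Iy[i+1, j] = max(M[i+1, j-1] - open, Iy[i+1, j-1] - ext)
    ##           = -open + max_{k<j} (M[i+1, k] + (k - j + 1) * ext) with
    ## open constant, solved by a running cummax of M + k * ext
    run <- cummax(M[i + 1L, 1L:n] - .GAP_OPEN + seq_len(n) * .GAP_EXT)
    Iy[i + 1L, 2L:(n + 1L)] <- run - seq_len(n) * .GAP_EXT
  }
  list(M = M, Ix = Ix, Iy = Iy)
}

#' Align a query peptide to reference columns via profile DP
#'
#' Glocal (global in the peptide, local in the reference) affine-gap dynamic
#' programming against per-column log-odds emissions (gap open 11, extend 1).
#' The output row has exactly one symbol per reference column ('-' where no
#' peptide residue matches); peptide insertions relative to the reference are
#' scored but discarded, keeping the reference column space fixed.
#'
#' @param peptide query peptide (non-empty).
#' @param profile profile from \code{\link{buildProfile}}.
#' @return list with \code{row} (aligned string, one char per column) and
#'   \code{score} (alignment log-odds score).
#' @export
alignToReference <- function(peptide, profile) {
  pep <- strsplit(toupper(peptide), "")[[1]]
  if (!length(pep)) stop("empty peptide")
  n <- ncol(profile$logOdds)
  code <- match(pep, AA_ORDER)
  emit <- matrix(0, length(pep), n)
  obs <- !is.na(code)
  emit[obs, ] <- profile$logOdds[code[obs], , drop = FALSE]
  dp <- .alignDP(emit)
  m <- length(pep)
  ## free trailing reference columns: best cell in the last peptide row
  lastM <- dp$M[m + 1L, ]
  lastIx <- dp$Ix[m + 1L, ]
  endState <- if (max(lastM) >= max(lastIx)) "M" else "Ix"
  j <- which.max(if (endState == "M") lastM else lastIx) - 1L
  score <- max(lastM, lastIx)
  ## traceback
  row <- rep("-", n)
  i <- m
  state <- endState
  jj <- j
  while (i > 0L) {
    if (state == "M") {
      row[jj] <- pep[i]
      prevs <- c(M = dp$M[i, jj], Ix = dp$Ix[i, jj], Iy = dp$Iy[i, jj])
      i <- i - 1L; jj <- jj - 1L
      state <- names(prevs)[which.max(prevs)]
      if (i == 0L) break
      if (jj == 0L && state != "Ix") break
    } else if (state == "Ix") {
      prevs <- c(M = dp$M[i, jj + 1L] - .GAP_OPEN,
                 Ix = dp$Ix[i, jj + 1L] - .GAP_EXT)
      i <- i - 1L
      state <- names(prevs)[which.max(prevs)]
    } else {   # Iy
      prevs <- c(M = dp$M[i + 1L, jj] - .GAP_OPEN,
                 Iy = dp$Iy[i + 1L, jj] - .GAP_EXT)
      jj <- jj - 1L
      state <- names(prevs)[which.max(prevs)]
    }
  }
  list(row = paste(row, collapse = ""), score = score)
}

#' Null distribution threshold for frame detection
#'
#' Aligns shuffled versions of a peptide to the profile and returns the 99th
#' percentile of the null scores; a frame whose score does not exceed this is
#' flagged as below the detection threshold.
#'
#' @param peptide a representative peptide (its residues are shuffled).
#' @param profile profile from \code{\link{buildProfile}}.
#' @param n number of shuffles.
#' @param seed RNG seed.
#' @return numeric threshold.
#' @export
frameScoreNull <- function(peptide, profile, n = 100L, seed = NULL) {
  pep <- strsplit(toupper(peptide), "")[[1]]
  .withSeed(seed, {
    scores <- vapply(seq_len(n), function(i)
      alignToReference(paste(sample(pep), collapse = ""), profile)$score, 0)
    as.numeric(quantile(scores, 0.99, names = FALSE))
  })
}

#' Choose the best reading frame against a reference profile
#'
#' Aligns all six frame translations to the profile and returns the frame
#' with the best glocal log-odds score; ties are broken in frame order
#' +1, +2, +3, -1, -2, -3. When a \code{threshold} is supplied the result is
#' flagged \code{detected = FALSE} if no frame exceeds it.
#'
#' @param peptides the 6 frame translations (from \code{\link{translateSixFrames}}).
#' @param profile profile from \code{\link{buildProfile}}.
#' @param threshold optional detection threshold (see \code{\link{frameScoreNull}}).
#' @return list: \code{frame} (name), \code{score}, \code{row} (aligned row),
#'   \code{detected}.
#' @export
selectFrame <- function(peptides, profile, threshold = NULL) {
  stopifnot(length(peptides) == 6L)
  alns <- lapply(peptides, function(p)
    if (nzchar(p)) alignToReference(p, profile) else list(row = NULL, score = -Inf))
  scores <- vapply(alns, function(a) a$score, 0)
  best <- which.max(scores)   # first maximum = frame order tie-break
  list(frame = names(peptides)[best], score = scores[best],
       row = alns[[best]]$row,
       detected = if (is.null(threshold)) TRUE else scores[best] > threshold)
}

#' Trimming parameters (Gblocks parameter scheme)
#'
#' \code{b1}: minimum sequences for a conserved position (default
#' floor(rows/2) + 1, i.e. more than half); \code{b2}: minimum sequences for
#' a flank position (default ceiling(0.55 rows), clamped to at least b1);
#' \code{b3}: maximum contiguous nonconserved positions (15); \code{b4}:
#' minimum block length (3); \code{b5} = "h": columns with more than half
#' gaps are nonconserved and always removed.
#'
#' @param rows number of alignment rows.
#' @param b3,b4 see above.
#' @param b2 override for the flank threshold.
#' @return list of parameters.
#' @export
trimParams <- function(rows, b3 = 15L, b4 = 3L, b2 = NULL) {
  b1 <- rows %/% 2L + 1L
  if (is.null(b2)) b2 <- as.integer(ceiling(0.55 * rows))
  b2 <- max(b2, b1)
  stopifnot(b4 >= 1L, b3 >= 0L)
  list(b1 = b1, b2 = b2, b3 = as.integer(b3), b4 = as.integer(b4),
       halfGap = TRUE)
}

#' Conserved-block column trimming (Gblocks-style)
#'
#' Columns are classified by the count of the most frequent residue (gaps do
#' not count as residues): nonconserved below \code{b1}, conserved at or
#' above \code{b1}, highly conserved at or above \code{b2}; columns with more
#' than half gaps are nonconserved regardless. Stretches of more than
#' \code{b3} contiguous nonconserved columns are rejected, the remaining
#' blocks are trimmed at both flanks up to the first highly conserved
#' position, gap-majority columns are removed, and blocks shorter than
#' \code{b4} are dropped.
#'
#' @param msa named character vector or \code{AAStringSet} (may include a query row).
#' @param params from \code{\link{trimParams}} (computed from the row count
#'   when omitted).
#' @return logical column mask of surviving columns.
#' @export
trimColumns <- function(msa, params = NULL) {
  mat <- .msaMatrix(.asAAStringSet(as.character(msa)))
  rows <- nrow(mat); n <- ncol(mat)
  if (is.null(params)) params <- trimParams(rows)
  isGap <- !(mat %in% AA_ORDER)
  dim(isGap) <- dim(mat)
  gapCount <- colSums(isGap)
  most <- vapply(seq_len(n), function(j) {
    col <- mat[!isGap[, j], j]
    if (!length(col)) 0L
    else max(tabulate(match(col, AA_ORDER), 20L))
  }, 0L)
  gappy <- gapCount * 2L > rows
  noncons <- most < params$b1 | gappy
  highly <- most >= params$b2 & !gappy
  keep <- rep(TRUE, n)
  ## reject runs of > b3 contiguous nonconserved columns
  r <- rle(noncons)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values))
    if (r$values[i] && r$lengths[i] > params$b3)
      keep[starts[i]:ends[i]] <- FALSE
  ## gap-majority columns are always removed
  keep[gappy] <- FALSE
  ## trim block flanks to the first highly conserved position, then b4
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    blk <- starts[i]:ends[i]
    hc <- which(highly[blk])
    if (!length(hc)) { keep[blk] <- FALSE; next }
    trimmed <- blk[min(hc):max(hc)]
    keep[blk] <- FALSE
    if (length(trimmed) >= params$b4) keep[trimmed] <- TRUE
  }
  keep
}

#' Post-trim length filter
#'
#' Keep an aligned row iff it has at least \code{minLen} non-gap residues
#' (inclusive threshold; the default mirrors the 50-aa pipeline gate).
#'
#' @param row aligned peptide row (post-trim).
#' @param minLen minimum residue count (default 50).
#' @return logical.
#' @export
lengthFilter <- function(row, minLen = 50L) {
  res <- strsplit(toupper(row), "")[[1]]
  sum(res %in% AA_ORDER) >= minLen
}

#' Concatenate per-marker alignments (and a fragment's per-marker rows)
#'
#' Column-wise concatenation in the given marker order; all markers must
#' share the same reference taxon set. A taxon absent from a marker is
#' filled with gaps; a fragment row missing a marker likewise.
#'
#' @param markerMsas named list of reference alignments (named character
#'   vectors), one per marker, all over the same taxa.
#' @param queryRows optional named list of aligned query rows per marker
#'   (same marker names; missing markers allowed).
#' @return list with \code{msa} (concatenated reference rows) and
#'   \code{query} (concatenated query row, if \code{queryRows} given).
#' @export
concatenateMarkers <- function(markerMsas, queryRows = NULL) {
  stopifnot(length(markerMsas) >= 1L)
  taxa <- sort(names(markerMsas[[1L]]))
  widths <- integer(length(markerMsas))
  for (i in seq_along(markerMsas)) {
    if (!identical(sort(names(markerMsas[[i]])), taxa))
      stop("marker '", names(markerMsas)[i], "' has a mismatched taxon set")
    widths[i] <- unique(nchar(markerMsas[[i]]))
  }
  msa <- setNames(vapply(taxa, function(tx)
    paste(vapply(markerMsas, function(m) m[[tx]], ""), collapse = ""), ""),
    taxa)
  out <- list(msa = msa)
  if (!is.null(queryRows)) {
    parts <- vapply(seq_along(markerMsas), function(i) {
      nm <- names(markerMsas)[i]
      if (!is.null(queryRows[[nm]])) queryRows[[nm]]
      else strrep("-", widths[i])
    }, "")
    out$query <- paste(parts, collapse = "")
  }
  out
}

#' Apply a column mask to aligned rows
#' @param rows named character vector of aligned rows.
#' @param mask logical column mask.
#' @return rows restricted to surviving columns.
#' @export
applyMask <- function(rows, mask) {
  vapply(rows, function(s) {
    ch <- strsplit(s, "")[[1]]
    paste(ch[mask], collapse = "")
  }, "")
}
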
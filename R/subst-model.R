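## Empirical amino-acid substitution models with discrete-Gamma rates.
##
## Model files under inst/extdata/models are plain text: a comment line, then
## 19 lines giving the lower triangle of the symmetric exchangeability matrix
## in PAML residue order (ARNDCQEGHILKMFPSTWYV), then one line of 20
## equilibrium frequencies.

.MODEL_REGISTRY <- c(WAG = "wag.dat", RTREV = "rtrev.dat",
                     CPREV = "cprev.dat", BLOSUM62 = "blosum62.dat")

.readModelFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 20L) stop("malformed model file: ", path)
  S <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  for (i in 2:20) {
    vals <- as.numeric(strsplit(trimws(lines[i - 1L]), "\\s+")[[1]])
    if (length(vals) != i - 1L) stop("malformed triangle row in ", path)
    S[i, seq_len(i - 1L)] <- vals
  }
  S <- S + t(S)
  pi <- as.numeric(strsplit(trimws(lines[20]), "\\s+")[[1]])
  if (length(pi) != 20L) stop("malformed frequency line in ", path)
  names(pi) <- AA_ORDER
  list(S = S, pi = pi / sum(pi))
}

#' Build a normalized reversible rate matrix from exchangeabilities
#'
#' \eqn{Q_{ij} = c\,S_{ij}\pi_j} for \eqn{i \ne j}, with the diagonal set so
#' rows sum to zero and the scale \eqn{c} chosen so that
#' \eqn{-\sum_i \pi_i Q_{ii} = 1}: branch lengths are then expected
#' substitutions per site. The result satisfies detailed balance
#' \eqn{\pi_i Q_{ij} = \pi_j Q_{ji}}.
#'
#' @param S symmetric non-negative 20x20 exchangeability matrix (diagonal ignored).
#' @param pi equilibrium distribution over the 20 residues (all entries > 0).
#' @return normalized rate matrix Q.
#' @export
buildRateMatrix <- function(S, pi) {
  stopifnot(is.matrix(S), nrow(S) == 20L, ncol(S) == 20L, length(pi) == 20L)
  if (any(pi <= 0)) stop("equilibrium frequencies must all be positive")
  if (max(abs(S - t(S))) > 1e-10) stop("exchangeability matrix must be symmetric")
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q / scale
}

#' Discrete-Gamma rate categories (mean-per-quantile convention)
#'
#' Approximates Gamma(shape = alpha, mean = 1) rate heterogeneity by K
#' equal-probability categories, each represented by its conditional mean
#' over the corresponding quantile interval (computed from the incomplete
#' Gamma function), then renormalized so the category mean is exactly 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param K number of categories.
#' @return numeric vector of K rates, mean exactly 1.
#' @export
discretizeGamma <- function(alpha, K = 4L) {
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be > 0")
  K <- as.integer(K)
  stopifnot(K >= 1L)
  if (K == 1L) return(1)
  cuts <- qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
  ## category mean: K * (I(upper; alpha+1) - I(lower; alpha+1)) for mean-1 Gamma
  cdf1 <- pgamma(c(0, cuts, Inf), shape = alpha + 1, rate = alpha)
  rates <- K * diff(cdf1)
  rates / mean(rates)
}

.modelEigen <- function(Q, pi) {
  sq <- sqrt(pi)
  B <- Q * (sq / rep(sq, each = length(sq)))   # diag(sq) Q diag(1/sq), symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U1 = e$vectors / sq,                     # diag(1/sq) U
       U2 = t(e$vectors * sq))                  # t(U) diag(sq)
}

#' Load a shipped empirical amino-acid model
#'
#' Available models: WAG, RTREV, CPREV, BLOSUM62 (published exchangeabilities
#' and frequencies, shipped as plain-text data files). The returned model has
#' a normalized rate matrix, a cached eigendecomposition and \code{K}
#' discrete-Gamma rates at the given shape.
#'
#' @param name model name (case-insensitive).
#' @param alpha Gamma shape (default 1).
#' @param K number of rate categories (default 4).
#' @return a \linkS4class{SubstitutionModel}.
#' @export
loadEmpiricalModel <- function(name, alpha = 1, K = 4L) {
  key <- toupper(name)
  if (!key %in% names(.MODEL_REGISTRY))
    stop("unknown model '", name, "'; available: ",
         paste(names(.MODEL_REGISTRY), collapse = ", "))
  path <- system.file("extdata", "models", .MODEL_REGISTRY[[key]],
                      package = "phyloplace", mustWork = TRUE)
  dat <- .readModelFile(path)
  makeSubstitutionModel(key, dat$S, dat$pi, alpha = alpha, K = K)
}

#' Construct a SubstitutionModel from exchangeabilities and frequencies
#'
#' @param name model label.
#' @param S symmetric exchangeability matrix.
#' @param pi equilibrium frequencies.
#' @param alpha Gamma shape.
#' @param K rate categories.
#' @return a \linkS4class{SubstitutionModel}.
#' @export
makeSubstitutionModel <- function(name, S, pi, alpha = 1, K = 4L) {
  pi <- pi / sum(pi)
  Q <- buildRateMatrix(S, pi)
  m <- new("SubstitutionModel", name = name, S = S, pi = pi, Q = Q,
           alpha = alpha, rates = discretizeGamma(alpha, K),
           eig = .modelEigen(Q, pi))
  validObject(m)
  m
}

#' Replace the Gamma shape of a model (rates re-discretized)
#' @param model a \linkS4class{SubstitutionModel}.
#' @param alpha new shape.
#' @return updated model.
#' @export
setModelAlpha <- function(model, alpha) {
  model@alpha <- alpha
  model@rates <- discretizeGamma(alpha, length(model@rates))
  model
}

#' Transition probability matrix P(t) = exp(Q r t)
#'
#' Assembled from the cached symmetric eigendecomposition; rows sum to 1 and
#' tiny negative entries from roundoff are clamped to 0.
#'
#' @param model a \linkS4class{SubstitutionModel}.
#' @param t branch length (>= 0).
#' @param r rate multiplier (default 1).
#' @return 20x20 stochastic matrix.
#' @export
transitionMatrix <- function(model, t, r = 1) {
  stopifnot(t >= 0, r >= 0)
  e <- model@eig
  P <- e$U1 %*% (exp(e$values * (t * r)) * e$U2)
  if (min(P) < -1e-8) stop("transition matrix entry below tolerance")
  P[P < 0] <- 0
  P
}

## list of K transition matrices, one per rate category
.rateTrans <- function(model, t) {
  lapply(model@rates, function(r) transitionMatrix(model, t, r))
}
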
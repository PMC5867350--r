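#' Maximum-likelihood Brownian-motion ancestral states
#'
#' Reconstructs a continuous character (here: diploid chromosome number) at
#' every internal node under Brownian motion. The estimates are the joint
#' ML states, computed by solving the edge-weighted graph Laplacian system
#' (the sparse-linear-algebra form of the re-rooted weighted-average
#' recursion); they coincide with the generalized-least-squares
#' reconstruction from the full phylogenetic covariance matrix. Per-node
#' variances are the conditional variances of the ancestral state given the
#' tip data, scaled by the ML rate estimate, and 95% intervals use the
#' normal quantile.
#'
#' @param tree `phylo` with positive branch lengths.
#' @param x Named numeric vector of tip values (one per leaf).
#' @return Object of class `bm_asr`: a list with a `nodes` data.frame
#'   (`node`, `label`, `estimate`, `variance`, `ci_lower`, `ci_upper`),
#'   `sigma2` (ML rate, squared-character units per unit branch length) and
#'   `root` (the root estimate).
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' bm_asr(tr, c(A = 0, B = 0, C = 3))
#' @export
bm_asr <- function(tree, x) {
  n <- ape::Ntip(tree)
  if (is.null(names(x)) || !setequal(names(x), tree$tip.label))
    stop("x must be named with exactly the tree's tip labels")
  x <- x[tree$tip.label]
  if (anyNA(x) || any(!is.finite(x))) stop("tip values must be finite")
  el <- tree$edge.length
  if (is.null(el)) stop("tree has no branch lengths")
  if (any(el < 0)) stop("negative branch lengths")
  if (any(el == 0)) {
    eps <- 1e-8 * max(node_heights(tree))
    warning("zero-length branches replaced by ", signif(eps, 3), call. = FALSE)
    el[el == 0] <- eps
    tree$edge.length <- el
  }
  N <- n + tree$Nnode
  w <- 1 / el
  p <- tree$edge[, 1]; ch <- tree$edge[, 2]
  W <- Matrix::sparseMatrix(i = c(p, ch), j = c(ch, p), x = c(w, w),
                            dims = c(N, N))
  L <- Matrix::Diagonal(N, Matrix::rowSums(W)) - W
  I <- (n + 1L):N
  LII <- L[I, I, drop = FALSE]
  rhs <- W[I, seq_len(n), drop = FALSE] %*% x
  Sii <- solve(LII)                   # conditional covariance / sigma2
  ahat <- as.numeric(Sii %*% rhs)
  # ML rate from the standardized independent contrasts
  tr2 <- if (ape::is.binary(tree)) tree else ape::multi2di(tree)
  pic <- ape::pic(x[tr2$tip.label], tr2)
  sigma2 <- sum(pic^2) / n
  v <- sigma2 * Matrix::diag(Sii)
  z <- stats::qnorm(0.975)
  labs <- if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
          else ifelse(nzchar(tree$node.label), tree$node.label, NA)
  nodes <- data.frame(node = I, label = labs, estimate = ahat, variance = v,
                      ci_lower = ahat - z * sqrt(v),
                      ci_upper = ahat + z * sqrt(v),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, sigma2 = sigma2,
                 root = ahat[1L], tree = tree, x = x),
            class = "bm_asr")
}

#' @export
print.bm_asr <- function(x, ...) {
  cat("Brownian-motion ancestral state reconstruction\n")
  cat(sprintf("  %d tips, %d internal nodes, sigma2 = %.4g\n",
              ape::Ntip(x$tree), nrow(x$nodes), x$sigma2))
  cat(sprintf("  root estimate %.3f (95%% CI %.3f - %.3f)\n",
              x$root, x$nodes$ci_lower[1], x$nodes$ci_upper[1]))
  invisible(x)
}

#' @export
summary.bm_asr <- function(object, ...) {
  print(object)
  print(utils::head(object$nodes, 20), row.names = FALSE)
  invisible(object$nodes)
}

#' @export
as.data.frame.bm_asr <- function(x, ...) x$nodes

#' Write a per-node ancestral-state table
#' @param asr A [bm_asr()] result.
#' @param path Output TSV path.
#' @export
write_asr_table <- function(asr, path) {
  utils::write.table(asr$nodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# profile BM log-likelihood on a lambda-transformed covariance
bm_profile_loglik <- function(C, x, lambda = 1) {
  n <- length(x)
  V <- C * lambda
  diag(V) <- diag(C)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  one <- rep(1, n)
  iVx <- backsolve(R, forwardsolve(t(R), x))
  iV1 <- backsolve(R, forwardsolve(t(R), one))
  mu <- sum(iVx) / sum(iV1)
  q <- sum((x - mu) * backsolve(R, forwardsolve(t(R), x - mu)))
  s2 <- q / n
  -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(R))) + n)
}

#' Phylogenetic signal: Pagel's lambda and Blomberg's K
#'
#' Pagel's lambda multiplies the off-diagonal entries of the Brownian
#' covariance; `lambda_hat` maximizes the profile likelihood over
#' `[0, lambda_max]` where `lambda_max` keeps the transformed covariance
#' valid (so values slightly above 1 are attainable when terminal branches
#' permit), and the p-value is a chi-squared(1) likelihood-ratio test
#' against lambda = 0 (no signal). Blomberg's K is the observed
#' mean-squared-error ratio MSE0/MSE divided by its Brownian-motion
#' expectation on the same tree; its p-value is a one-tailed tip-label
#' permutation test on MSE (add-one rule, observed included).
#'
#' @param tree Ultrametric (or at least fully lengthed) `phylo`.
#' @param x Named numeric tip values; must not be constant.
#' @param n_permutations Number of permutations for the K test.
#' @param seed Integer seed for the permutation draw (mandatory).
#' @return Object of class `phylo_signal` with fields `lambda_hat`,
#'   `lambda_logL`, `lambda_p`, `k_stat`, `k_p`, `n_permutations`, `seed`.
#' @export
phylo_signal <- function(tree, x, n_permutations = 1000, seed) {
  if (missing(seed)) stop("seed is required for the permutation test")
  n <- ape::Ntip(tree)
  if (n < 4L) stop("need at least 4 tips for a meaningful signal test")
  if (is.null(names(x)) || !setequal(names(x), tree$tip.label))
    stop("x must be named with exactly the tree's tip labels")
  x <- x[tree$tip.label]
  if (stats::sd(x) == 0) stop("trait is constant; signal undefined")
  if (n_permutations < 100)
    warning("fewer than 100 permutations; p-value will be coarse",
            call. = FALSE)
  C <- ape::vcv(tree)
  off <- C; diag(off) <- 0
  lambda_max <- max(diag(C)) / max(off)

  # the profile likelihood can spike in a narrow window below lambda_max,
  # so scan a grid densified toward the boundary, then polish locally
  f <- function(l) bm_profile_loglik(C, x, l)
  cand <- sort(unique(c(seq(0, lambda_max, length.out = 21),
                        lambda_max * (1 - 10^seq(-1, -8)))))
  vals <- vapply(cand, f, numeric(1))
  b <- which.max(vals)
  lo <- if (b > 1) cand[b - 1] else 0
  hi <- if (b < length(cand)) cand[b + 1] else lambda_max
  best <- list(lambda = cand[b], logL = vals[b])
  o <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  if (o$objective > best$logL)
    best <- list(lambda = o$maximum, logL = o$objective)
  logL0 <- f(0)
  lambda_p <- stats::pchisq(2 * (best$logL - logL0), df = 1,
                            lower.tail = FALSE)

  # Blomberg's K
  iV <- solve(C)
  s <- sum(iV)
  one <- rep(1, n)
  a <- as.numeric(iV %*% one)
  mse_of <- function(y) {
    mu <- sum(a * y) / s
    sum((y - mu) * (iV %*% (y - mu))) / (n - 1)
  }
  mu <- sum(a * x) / s
  mse <- mse_of(x)
  mse0 <- sum((x - mu)^2) / (n - 1)
  expected <- (sum(diag(C)) - n / s) / (n - 1)
  k_stat <- (mse0 / mse) / expected
  set.seed(as.integer(seed))
  hits <- 0L
  for (i in seq_len(n_permutations))
    if (mse_of(sample(x)) <= mse) hits <- hits + 1L
  k_p <- (hits + 1) / (n_permutations + 1)

  structure(list(lambda_hat = best$lambda, lambda_logL = best$logL,
                 lambda_p = lambda_p, k_stat = k_stat, k_p = k_p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, ...) {
  cat("Phylogenetic signal\n")
  cat(sprintf("  Pagel's lambda = %.4f (logL %.3f, LRT p = %.3g)\n",
              x$lambda_hat, x$lambda_logL, x$lambda_p))
  cat(sprintf("  Blomberg's K   = %.4f (permutation p = %.3g, %d perms)\n",
              x$k_stat, x$k_p, x$n_permutations))
  invisible(x)
}

#' Profile log-likelihood of a lambda value (exposed for testing/plots)
#' @param tree `phylo`; @param x named tip values; @param lambda value.
#' @return Log-likelihood (sigma2 and root profiled out).
#' @export
pagel_loglik <- function(tree, x, lambda) {
  x <- x[tree$tip.label]
  bm_profile_loglik(ape::vcv(tree), x, lambda)
}
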
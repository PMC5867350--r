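#' Expected fusion/fission events per branch (stochastic mapping)
#'
#' Samples full character histories conditional on the tip data and fitted
#' rates, and averages per-branch event counts. Node states are drawn from
#' their joint conditional distribution (root from its posterior, children
#' conditionally along a preorder sweep); the path along each branch is
#' then drawn exactly, conditional on its endpoints, by uniformization
#' (jump count from the endpoint-conditioned Poisson mixture, intermediate
#' states by backward sampling), so no maps are rejected. Gains (+1 steps)
#' are fissions and losses (-1 steps) fusions; duplication and
#' demi-duplication steps are tallied separately.
#'
#' @param fit A [fit_chrom_ctmc()] result.
#' @param n_maps Number of sampled histories (>= 100).
#' @param seed Integer seed (mandatory).
#' @return Object of class `branch_events_mc`: data.frame `branches` with
#'   per-branch `expected_gains`, `expected_losses`, `expected_dupl`,
#'   `mc_error_gains`, `mc_error_losses`; and `totals`, the tree-wide
#'   expected event counts with Monte-Carlo standard errors.
#' @export
expected_events <- function(fit, n_maps = 1000, seed) {
  stopifnot(inherits(fit, "chrom_fit"))
  if (missing(seed)) stop("seed is required")
  if (n_maps < 100) stop("n_maps must be >= 100")
  tree <- fit$tree; spec <- fit$spec
  states <- spec$n_min:spec$n_max
  ns <- length(states)
  Q <- suppressWarnings(build_rate_matrix(spec, fit$rates))
  P <- transition_probs(Q, tree$edge.length)
  dp <- ctmc_downpass(tree, fit$tip_states, spec, P)
  n <- ape::Ntip(tree)
  rnode <- n + 1L
  pi <- root_frequencies(dp$partial[rnode, ], fit$root)
  root_post <- pi * dp$partial[rnode, ]
  root_post <- root_post / sum(root_post)

  lam <- max(-diag(Q))
  E <- nrow(tree$edge)
  preorder <- rev(ape::postorder(tree))
  gains <- losses <- dupl <- demi <- matrix(0, n_maps, E)
  if (lam > 0) {
    R <- diag(ns) + Q / lam
    Rpow <- list(diag(ns), R)   # Rpow[[k]] = R^(k-1)
    get_pow <- function(k) {    # R^k
      while (length(Rpow) < k + 1L)
        Rpow[[length(Rpow) + 1L]] <<- Rpow[[length(Rpow)]] %*% R
      Rpow[[k + 1L]]
    }
    ncap <- max(3, stats::qpois(1 - 1e-12, lam * max(tree$edge.length))) + 2L

    sample_path <- function(a, b, t, pab) {
      # jump count N | endpoints, then backward state sampling
      if (pab <= 1e-300)
        stop("endpoint probability underflow in stochastic mapping; ",
             "branch too improbable under the fitted rates")
      u <- stats::runif(1) * pab
      acc <- 0; N <- NA_integer_
      for (nn in 0:ncap) {
        acc <- acc + stats::dpois(nn, lam * t) * get_pow(nn)[a, b]
        if (acc >= u) { N <- nn; break }
      }
      if (is.na(N)) N <- ncap
      if (N == 0L) return(integer(0))
      s <- integer(N + 1L); s[1] <- a; s[N + 1L] <- b
      if (N > 1L) for (k in 2:N) {
        w <- pmax(R[s[k - 1L], ] * get_pow(N - k + 1L)[, b], 0)
        s[k] <- sample.int(ns, 1L, prob = w)
      }
      s
    }
  }

  node_state <- integer(n + tree$Nnode)
  set.seed(as.integer(seed))
  for (m in seq_len(n_maps)) {
    node_state[rnode] <- sample.int(ns, 1L, prob = root_post)
    for (e in preorder) {
      pa <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
      w <- pmax(P[[e]][node_state[pa], ], 0) * dp$partial[chd, ]
      node_state[chd] <- sample.int(ns, 1L, prob = w)
      if (lam == 0) next
      s <- sample_path(node_state[pa], node_state[chd],
                       tree$edge.length[e],
                       P[[e]][node_state[pa], node_state[chd]])
      if (length(s) > 1L) {
        from <- states[s[-length(s)]]; to <- states[s[-1]]
        real <- from != to
        d <- to[real] - from[real]
        gains[m, e] <- sum(d == 1)
        losses[m, e] <- sum(d == -1)
        dupl[m, e] <- sum(to[real] == 2 * from[real] & d != 1)
        demi[m, e] <- sum(d > 1 & to[real] != 2 * from[real])
      }
    }
  }

  child <- tree$edge[, 2]
  labs <- node_label(tree, child)
  branches <- data.frame(
    child = child, label = labs,
    expected_gains = colMeans(gains), expected_losses = colMeans(losses),
    expected_dupl = colMeans(dupl) + colMeans(demi),
    mc_error_gains = apply(gains, 2, stats::sd) / sqrt(n_maps),
    mc_error_losses = apply(losses, 2, stats::sd) / sqrt(n_maps),
    stringsAsFactors = FALSE)
  tot <- function(mat) c(mean(rowSums(mat)),
                         stats::sd(rowSums(mat)) / sqrt(n_maps))
  tg <- tot(gains); tl <- tot(losses); td <- tot(dupl + demi)
  totals <- data.frame(event = c("gain (fission)", "loss (fusion)",
                                 "duplication"),
                       expected = c(tg[1], tl[1], td[1]),
                       mc_error = c(tg[2], tl[2], td[2]),
                       stringsAsFactors = FALSE)
  structure(list(branches = branches, totals = totals,
                 n_maps = as.integer(n_maps), seed = as.integer(seed)),
            class = "branch_events_mc")
}

#' @export
print.branch_events_mc <- function(x, ...) {
  cat(sprintf("Stochastic mapping, %d maps (seed %d)\n", x$n_maps, x$seed))
  print(x$totals, row.names = FALSE, digits = 4)
  invisible(x)
}

# display label for a node: tip label, node label, or ape number
node_label <- function(tree, nodes) {
  n <- ape::Ntip(tree)
  vapply(nodes, function(v) {
    if (v <= n) tree$tip.label[v]
    else if (!is.null(tree$node.label) &&
             nzchar(tree$node.label[v - n])) tree$node.label[v - n]
    else as.character(v)
  }, character(1))
}
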
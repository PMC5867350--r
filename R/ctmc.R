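#' The eight chromosome-number rate-model families
#'
#' Haploid chromosome number evolves on a bounded integer state space by a
#' continuous-time Markov chain with single-step gains (fissions), losses
#' (fusions), optional whole-complement duplication (n -> 2n) and optional
#' demi-duplication (n -> 1.5n). Constant-rate families use one rate per
#' event type; linear families let gain and loss rates vary linearly with
#' the state. DEMI families tie the demi rate to the duplication rate;
#' DEMI_EST estimates it freely; NO_DUPL families drop duplication.
#'
#' @format Character vector of the eight family names.
#' @export
CHROM_FAMILIES <- c("CONST_RATE", "CONST_RATE_DEMI", "CONST_RATE_DEMI_EST",
                    "CONST_RATE_NO_DUPL", "LINEAR_RATE", "LINEAR_RATE_DEMI",
                    "LINEAR_RATE_DEMI_EST", "LINEAR_RATE_NO_DUPL")

family_params <- function(family) {
  switch(family,
    CONST_RATE          = c("gain_const", "loss_const", "dupl"),
    CONST_RATE_DEMI     = c("gain_const", "loss_const", "dupl"),
    CONST_RATE_DEMI_EST = c("gain_const", "loss_const", "dupl", "demi"),
    CONST_RATE_NO_DUPL  = c("gain_const", "loss_const"),
    LINEAR_RATE         = c("gain_const", "gain_linear", "loss_const",
                            "loss_linear", "dupl"),
    LINEAR_RATE_DEMI    = c("gain_const", "gain_linear", "loss_const",
                            "loss_linear", "dupl"),
    LINEAR_RATE_DEMI_EST = c("gain_const", "gain_linear", "loss_const",
                             "loss_linear", "dupl", "demi"),
    LINEAR_RATE_NO_DUPL = c("gain_const", "gain_linear", "loss_const",
                            "loss_linear"),
    stop("unknown model family: ", family))
}

#' Specify a chromosome-number rate model
#'
#' @param family One of [CHROM_FAMILIES]. Parameter counts: 2
#'   (CONST_RATE_NO_DUPL), 3 (CONST_RATE, CONST_RATE_DEMI), 4
#'   (CONST_RATE_DEMI_EST, LINEAR_RATE_NO_DUPL), 5 (LINEAR_RATE,
#'   LINEAR_RATE_DEMI), 6 (LINEAR_RATE_DEMI_EST). In DEMI (non-EST)
#'   families the demi rate equals the duplication rate.
#' @param n_min,n_max Haploid state-space bounds (`n_min >= 1`,
#'   `n_max > n_min`).
#' @return Object of class `rate_model_spec`.
#' @export
rate_model_spec <- function(family, n_min, n_max) {
  family <- match.arg(family, CHROM_FAMILIES)
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  stopifnot(n_min >= 1L, n_max > n_min)
  structure(list(family = family, n_min = n_min, n_max = n_max,
                 parameter_names = family_params(family),
                 linear = grepl("^LINEAR", family),
                 has_dupl = !grepl("NO_DUPL", family),
                 has_demi = grepl("DEMI", family),
                 demi_tied = grepl("DEMI$", family)),
            class = "rate_model_spec")
}

#' @export
print.rate_model_spec <- function(x, ...) {
  cat(sprintf("%s on haploid states %d..%d (%d parameters: %s)\n",
              x$family, x$n_min, x$n_max, length(x$parameter_names),
              paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

#' Build the CTMC rate matrix of a model
#'
#' States are haploid counts `n_min .. n_max`. Entry (n, n+1) is the gain
#' (fission) rate, (n, n-1) the loss (fusion) rate, (n, 2n) the duplication
#' rate and (n, 1.5n) the demi-duplication rate (odd `n`: rate split
#' equally between floor and ceiling targets). Linear families use
#' `rate(n) = const + linear * (n - n_min)`, clamped at 0 (with a warning).
#' Transitions leaving the state space are truncated; the diagonal makes
#' every row sum to zero.
#'
#' @param spec A [rate_model_spec()].
#' @param rates Named numeric vector covering `spec$parameter_names`.
#' @return Square rate matrix with state dimnames.
#' @export
build_rate_matrix <- function(spec, rates) {
  stopifnot(inherits(spec, "rate_model_spec"))
  missing_par <- setdiff(spec$parameter_names, names(rates))
  if (length(missing_par))
    stop("missing rate parameters: ", paste(missing_par, collapse = ", "))
  states <- spec$n_min:spec$n_max
  ns <- length(states)
  Q <- matrix(0, ns, ns, dimnames = list(states, states))
  rate_of <- function(const, linear) {
    r <- rep(const, ns) +
      if (spec$linear) linear * (states - spec$n_min) else 0
    if (any(r < 0)) {
      warning("negative effective rate clamped to 0", call. = FALSE)
      r <- pmax(r, 0)
    }
    r
  }
  g <- rate_of(rates[["gain_const"]],
               if (spec$linear) rates[["gain_linear"]] else 0)
  l <- rate_of(rates[["loss_const"]],
               if (spec$linear) rates[["loss_linear"]] else 0)
  for (i in seq_len(ns)) {
    n <- states[i]
    if (n + 1L <= spec$n_max) Q[i, i + 1L] <- Q[i, i + 1L] + g[i]
    if (n - 1L >= spec$n_min) Q[i, i - 1L] <- Q[i, i - 1L] + l[i]
    if (spec$has_dupl) {
      d <- rates[["dupl"]]
      if (2L * n <= spec$n_max) Q[i, match(2L * n, states)] <-
          Q[i, match(2L * n, states)] + d
    }
    if (spec$has_demi) {
      dm <- if (spec$demi_tied) rates[["dupl"]] else rates[["demi"]]
      t15 <- 1.5 * n
      targets <- unique(c(floor(t15), ceiling(t15)))
      targets <- targets[targets >= spec$n_min & targets <= spec$n_max &
                           targets != n]
      for (tg in targets)
        Q[i, match(tg, states)] <- Q[i, match(tg, states)] +
          dm / length(unique(c(floor(t15), ceiling(t15))))
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# transition-probability matrices for the unique branch lengths of a tree
transition_probs <- function(Q, lengths) {
  key <- as.character(signif(lengths, 12))
  uniq <- !duplicated(key)
  P <- lapply(lengths[uniq], function(t) {
    M <- as.matrix(Matrix::expm(Q * t))
    M[M < 0] <- 0          # scrub tiny negative round-off entries
    M
  })
  names(P) <- key[uniq]
  P[key]
}

# postorder conditional (downpass) likelihoods with log scaling.
# returns list(partial = [node x state], logscale = per-node log factors)
ctmc_downpass <- function(tree, tip_states, spec, P) {
  states <- spec$n_min:spec$n_max
  ns <- length(states)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  partial <- matrix(0, N, ns)
  logscale <- numeric(N)
  for (i in seq_len(n)) {
    s <- tip_states[[tree$tip.label[i]]]
    if (is.na(s) || s < spec$n_min || s > spec$n_max)
      stop("tip state ", s, " for ", tree$tip.label[i],
           " outside state bounds [", spec$n_min, ", ", spec$n_max, "]")
    partial[i, match(s, states)] <- 1
  }
  partial[(n + 1L):N, ] <- 1
  # edge postorder: every edge below a node is applied before the node's
  # own parent edge, so partial[child, ] is always complete when used
  for (e in ape::postorder(tree)) {
    v <- tree$edge[e, 1]; c_node <- tree$edge[e, 2]
    partial[v, ] <- partial[v, ] * as.numeric(P[[e]] %*% partial[c_node, ])
    logscale[v] <- logscale[v] + logscale[c_node]
    m <- max(partial[v, ])
    if (m <= 0) stop("likelihood underflow: data impossible under model")
    partial[v, ] <- partial[v, ] / m
    logscale[v] <- logscale[v] + log(m)
  }
  list(partial = partial, logscale = logscale)
}

root_frequencies <- function(root_partial, root = c("weighted", "flat")) {
  root <- match.arg(root)
  if (root == "weighted") root_partial / sum(root_partial)
  else rep(1 / length(root_partial), length(root_partial))
}

#' CTMC log-likelihood of haploid tip states on a tree
#'
#' Felsenstein pruning with per-branch matrix exponentials. At the root the
#' conditional likelihoods are combined with root frequencies; the default
#' `"weighted"` convention weights each state by its own normalized
#' conditional likelihood (a data-driven root), `"flat"` uses a uniform
#' prior.
#'
#' @param tree `phylo` with branch lengths.
#' @param tip_states Named integer vector/list of haploid numbers.
#' @param spec A [rate_model_spec()].
#' @param rates Named rate vector.
#' @param root Root-frequency convention.
#' @return Log-likelihood (scalar).
#' @export
ctmc_loglik <- function(tree, tip_states, spec, rates,
                        root = c("weighted", "flat")) {
  Q <- suppressWarnings(build_rate_matrix(spec, rates))
  P <- transition_probs(Q, tree$edge.length)
  dp <- ctmc_downpass(tree, tip_states, spec, P)
  rnode <- ape::Ntip(tree) + 1L
  pi <- root_frequencies(dp$partial[rnode, ], root)
  log(sum(pi * dp$partial[rnode, ])) + dp$logscale[rnode]
}

#' AIC from a log-likelihood and parameter count
#' @param logL Maximized log-likelihood. @param k Number of free parameters.
#' @return `2 k - 2 logL`.
#' @export
aic <- function(logL, k) 2 * k - 2 * logL

#' Fit one chromosome-number CTMC family by maximum likelihood
#'
#' Rates are optimized in log space (linear slope terms on the natural
#' scale, since they may be negative) by L-BFGS-B from multiple
#' Latin-hypercube starting points; the best optimum is kept.
#'
#' @param tree `phylo` with branch lengths.
#' @param tip_states Named haploid numbers (see [haploid_states()]).
#' @param family Model family name, or a ready [rate_model_spec()].
#' @param n_min,n_max State bounds; defaults follow the data:
#'   `max(1, min - 10)` and `2 * max + 10`, so duplication targets of
#'   observed states are never truncated.
#' @param n_restarts Number of optimization restarts (default 10).
#' @param seed Seed for the restart draws.
#' @param root Root-frequency convention, see [ctmc_loglik()].
#' @return Object of class `chrom_fit` with elements `spec`, `rates`,
#'   `logL`, `aic`, `k`, `converged`, plus the data needed by downstream
#'   methods. Supports `logLik()`, `AIC()`, `coef()`, `print()`,
#'   `summary()` and `simulate()`.
#' @export
fit_chrom_ctmc <- function(tree, tip_states, family = "CONST_RATE_NO_DUPL",
                           n_min = NULL, n_max = NULL, n_restarts = 10,
                           seed = 1, root = "weighted") {
  tip_states <- unlist(tip_states)
  if (inherits(family, "rate_model_spec")) {
    spec <- family
  } else {
    if (is.null(n_min)) n_min <- max(1L, min(tip_states) - 10L)
    if (is.null(n_max)) n_max <- 2L * max(tip_states) + 10L
    spec <- rate_model_spec(family, n_min, n_max)
  }
  pn <- spec$parameter_names
  is_slope <- grepl("_linear$", pn)
  k <- length(pn)

  to_rates <- function(par) {
    r <- ifelse(is_slope, par, exp(par))
    names(r) <- pn
    r
  }
  negll <- function(par) {
    r <- to_rates(par)
    ll <- tryCatch(suppressWarnings(
      ctmc_loglik(tree, tip_states, spec, r, root = root)),
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lower <- ifelse(is_slope, -5, log(1e-8))
  upper <- ifelse(is_slope, 5, log(200))
  set.seed(as.integer(seed))
  starts <- lhs::randomLHS(n_restarts, k)
  starts <- sweep(sweep(starts, 2, upper - lower, "*"), 2, lower, "+")
  # anchor one start at a moderate constant-rate guess
  starts[1, ] <- ifelse(is_slope, 0, log(1))
  best <- NULL
  conv <- FALSE
  for (i in seq_len(n_restarts)) {
    o <- tryCatch(stats::optim(starts[i, ], negll, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(factr = 1e4, maxit = 500)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-9) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimization restarts failed")
  rates <- to_rates(best$par)
  logL <- -best$value
  structure(list(spec = spec, rates = rates, logL = logL,
                 aic = aic(logL, k), k = k, converged = conv,
                 root = root, tree = tree, tip_states = tip_states,
                 seed = as.integer(seed)),
            class = "chrom_fit")
}

#' @export
print.chrom_fit <- function(x, ...) {
  cat(sprintf("%s fit: logL = %.3f, AIC = %.3f (k = %d)%s\n",
              x$spec$family, x$logL, x$aic, x$k,
              if (x$converged) "" else " [not converged]"))
  cat("  rates:", paste(sprintf("%s = %.4g", names(x$rates), x$rates),
                        collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.chrom_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  states %d..%d, root convention %s, %d tips\n",
              object$spec$n_min, object$spec$n_max, object$root,
              length(object$tip_states)))
  invisible(object)
}

#' @export
logLik.chrom_fit <- function(object, ...) {
  structure(object$logL, df = object$k, nobs = length(object$tip_states),
            class = "logLik")
}

#' @export
coef.chrom_fit <- function(object, ...) object$rates

#' @export
simulate.chrom_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("seed is required")
  root_h <- as.integer(names(which.max(table(object$tip_states))))
  lapply(seq_len(nsim), function(i)
    simulate_chrom_ctmc(object$tree, object$spec, object$rates,
                        root_haploid = root_h, seed = seed + i - 1L))
}

#' Fit several families and select by AIC
#'
#' @inheritParams fit_chrom_ctmc
#' @param families Character vector of family names (default: all eight).
#' @return Object of class `chrom_fit_set`: list of fits, a comparison
#'   `table` (family, logL, AIC, k, converged) in the given family order,
#'   and `best`, the fit with the lowest AIC (ties: fewest parameters,
#'   then family-name order).
#' @export
select_chrom_ctmc <- function(tree, tip_states, families = CHROM_FAMILIES,
                              n_min = NULL, n_max = NULL, n_restarts = 10,
                              seed = 1, root = "weighted") {
  stopifnot(length(families) >= 1L)
  fits <- lapply(families, function(f)
    fit_chrom_ctmc(tree, tip_states, f, n_min = n_min, n_max = n_max,
                   n_restarts = n_restarts, seed = seed, root = root))
  names(fits) <- families
  tab <- data.frame(family = families,
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    AIC = vapply(fits, `[[`, numeric(1), "aic"),
                    k = vapply(fits, `[[`, integer(1), "k"),
                    converged = vapply(fits, `[[`, logical(1), "converged"),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(tab$AIC, tab$k, tab$family)
  best <- fits[[ord[1]]]
  structure(list(fits = fits, table = tab, best = best),
            class = "chrom_fit_set")
}

#' @export
print.chrom_fit_set <- function(x, ...) {
  tab <- x$table
  tab$best <- ifelse(tab$family == x$best$spec$family, "*", "")
  cat("Chromosome-number model comparison (lowest AIC preferred)\n")
  print(tab, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Haploid states from a karyotype table
#'
#' Haploid number is 2n / 2; species whose diploid number is odd in one
#' sex use the even female complement (or male, by preference). An odd
#' resolved diploid number is an error.
#'
#' @param records Karyotype table (list of records).
#' @param prefer Sex preference.
#' @return Named integer vector of haploid numbers.
#' @export
haploid_states <- function(records, prefer = "female") {
  d <- diploid_numbers(records, prefer)
  odd <- d %% 2 != 0
  if (any(odd))
    stop("odd diploid number for ", paste(names(d)[odd], collapse = ", "),
         "; choose a sex whose complement is even")
  stats::setNames(as.integer(d / 2), names(d))
}

#' Marginal ancestral haploid states
#'
#' Standard two-pass (conditional downpass + re-rooting uppass) marginal
#' posterior at every internal node under the fitted model; the reported
#' diploid value is exactly twice the argmax haploid state.
#'
#' @param fit A [fit_chrom_ctmc()] result (or the `best` element of a
#'   [select_chrom_ctmc()] set).
#' @return Object of class `chrom_asr`: data.frame `nodes` (`node`,
#'   `label`, `best_haploid`, `best_diploid`, `posterior_max`) with the
#'   full posterior matrix in `posterior` (nodes x states).
#' @export
marginal_ancestral_states <- function(fit) {
  stopifnot(inherits(fit, "chrom_fit"))
  tree <- fit$tree; spec <- fit$spec
  states <- spec$n_min:spec$n_max
  ns <- length(states)
  Q <- suppressWarnings(build_rate_matrix(spec, fit$rates))
  P <- transition_probs(Q, tree$edge.length)
  dp <- ctmc_downpass(tree, fit$tip_states, spec, P)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  rnode <- n + 1L
  pi <- root_frequencies(dp$partial[rnode, ], fit$root)
  # uppass: U[v,] = likelihood of everything outside the subtree of v,
  # as a function of v's state
  U <- matrix(0, N, ns)
  U[rnode, ] <- pi
  for (e in rev(ape::postorder(tree))) {   # preorder over edges
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    sibs <- setdiff(which(tree$edge[, 1] == par), e)
    m <- U[par, ]
    for (se in sibs)
      m <- m * as.numeric(P[[se]] %*% dp$partial[tree$edge[se, 2], ])
    u <- as.numeric(m %*% P[[e]])
    s <- max(u)
    U[chd, ] <- if (s > 0) u / s else u
  }
  post <- dp$partial * U
  post <- post / rowSums(post)
  idx <- (n + 1L):N
  labs <- if (is.null(tree$node.label)) rep(NA_character_, tree$Nnode)
          else ifelse(nzchar(tree$node.label), tree$node.label, NA)
  best_h <- states[max.col(post[idx, , drop = FALSE], ties.method = "first")]
  nodes <- data.frame(node = idx, label = labs, best_haploid = best_h,
                      best_diploid = 2L * best_h,
                      posterior_max = apply(post[idx, , drop = FALSE], 1, max),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes,
                 posterior = post[idx, , drop = FALSE],
                 states = states, fit = fit),
            class = "chrom_asr")
}

#' @export
print.chrom_asr <- function(x, ...) {
  cat("Marginal ancestral haploid states (", x$fit$spec$family, ")\n",
      sep = "")
  print(x$nodes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.chrom_asr <- function(x, ...) x$nodes
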
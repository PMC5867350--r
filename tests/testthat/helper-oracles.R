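# Independent oracles used across the suite. These deliberately take the
# slow, direct route (full covariance inversion, exhaustive enumeration)
# so they share no code with the package's pruning/Laplacian algorithms.

# GLS ancestral-state oracle: explicit covariance over ALL nodes.
gls_asr_oracle <- function(tree, x) {
  x <- x[tree$tip.label]
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  nd <- ape::node.depth.edgelength(tree)      # distance from root
  mr <- ape::mrca(tree, full = TRUE)          # MRCA of every node pair
  Cfull <- matrix(nd[mr], N, N)
  Ctt <- Cfull[1:n, 1:n]
  iC <- solve(Ctt)
  one <- rep(1, n)
  mu <- as.numeric(one %*% iC %*% x) / as.numeric(one %*% iC %*% one)
  anc <- (n + 1):N
  Cat <- Cfull[anc, 1:n, drop = FALSE]
  as.numeric(mu + Cat %*% iC %*% (x - mu))
}

# Exhaustive-enumeration CTMC likelihood oracle for tiny trees.
enum_ctmc_loglik <- function(tree, tips, spec, rates,
                             root = c("weighted", "flat")) {
  root <- match.arg(root)
  states <- spec$n_min:spec$n_max
  ns <- length(states)
  Q <- suppressWarnings(build_rate_matrix(spec, rates))
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  internals <- (n + 1):N
  rnode <- n + 1
  tip_idx <- match(unlist(tips[tree$tip.label]), states)
  # likelihood of the tips for each root state, summing over all other
  # internal assignments
  others <- setdiff(internals, rnode)
  grids <- if (length(others))
    do.call(expand.grid, rep(list(seq_len(ns)), length(others)))
  else data.frame(row.names = 1)
  Lroot <- numeric(ns)
  for (r in seq_len(ns)) {
    tot <- 0
    for (g in seq_len(nrow(grids))) {
      assign_state <- integer(N)
      assign_state[1:n] <- tip_idx
      assign_state[rnode] <- r
      if (length(others))
        assign_state[others] <- as.integer(grids[g, ])
      p <- 1
      for (e in seq_len(nrow(tree$edge)))
        p <- p * P[[e]][assign_state[tree$edge[e, 1]],
                        assign_state[tree$edge[e, 2]]]
      tot <- tot + p
    }
    Lroot[r] <- tot
  }
  pi <- if (root == "weighted") Lroot / sum(Lroot) else rep(1 / ns, ns)
  list(logL = log(sum(pi * Lroot)), Lroot = Lroot, pi = pi)
}

# Per-node marginal posteriors by the same brute force.
enum_ctmc_marginals <- function(tree, tips, spec, rates,
                                root = c("weighted", "flat")) {
  root <- match.arg(root)
  states <- spec$n_min:spec$n_max
  ns <- length(states)
  Q <- suppressWarnings(build_rate_matrix(spec, rates))
  P <- lapply(tree$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  internals <- (n + 1):N
  tip_idx <- match(unlist(tips[tree$tip.label]), states)
  grids <- do.call(expand.grid, rep(list(seq_len(ns)), length(internals)))
  en <- enum_ctmc_loglik(tree, tips, spec, rates, root)
  post <- matrix(0, length(internals), ns)
  for (g in seq_len(nrow(grids))) {
    assign_state <- integer(N)
    assign_state[1:n] <- tip_idx
    assign_state[internals] <- as.integer(grids[g, ])
    p <- en$pi[assign_state[n + 1]]
    for (e in seq_len(nrow(tree$edge)))
      p <- p * P[[e]][assign_state[tree$edge[e, 1]],
                      assign_state[tree$edge[e, 2]]]
    for (k in seq_along(internals))
      post[k, assign_state[internals[k]]] <-
        post[k, assign_state[internals[k]]] + p
  }
  post / rowSums(post)
}

fixture_records <- function() {
  read_karyotype_table(karyevol_example("karyotypes"))
}

fixture_tree <- function() {
  read_newick(karyevol_example("tree"))
}

fixture_diploids <- function() {
  og <- utils::read.delim(karyevol_example("outgroups"))
  c(diploid_numbers(fixture_records()),
    stats::setNames(as.numeric(og$diploid_number), og$species))
}

record_by_species <- function(records, species) {
  recs <- select_sex(records)
  sp <- vapply(recs, function(r) r$species, character(1))
  recs[[match(paste0("Brachyhypopomus_", species), sp)]]
}

random_karyotype <- function() {
  d2n <- 2L * sample(10:30, 1)
  b <- 2L * (sample.int(d2n %/% 2L + 1L, 1) - 1L)
  karyotype_record(paste0("sp", sample.int(1e6, 1)), d2n,
                   biarmed = b, uniarmed = d2n - b)
}
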
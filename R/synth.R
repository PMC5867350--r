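#' Random Yule (pure-birth) tree scaled to root height 1
#'
#' @param n_tips Number of leaves (>= 2).
#' @param birth_rate Speciation rate (only sets the pre-scaling time
#'   scale; the returned tree is rescaled to unit root height, matching
#'   the Grafen-prepared empirical trees used elsewhere in the package).
#' @param seed Integer seed (mandatory; same seed, same tree).
#' @return Ultrametric `phylo` with tips `t1..tn`.
#' @export
random_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_tips >= 2, birth_rate > 0)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h
  tr
}

#' Simulate a Brownian-motion trait with tunable lambda
#'
#' Draws tip values from the multivariate normal with mean `root_value`
#' and covariance `sigma2` times the lambda-transformed shared-path-length
#' matrix (off-diagonals scaled by `lambda_signal`; 1 = pure Brownian
#' motion, 0 = independent tips).
#'
#' @param tree Ultrametric `phylo`.
#' @param sigma2 BM rate (squared character units per unit branch length).
#' @param root_value Trait value at the root.
#' @param lambda_signal Signal strength in `[0, 1]`.
#' @param seed Integer seed (mandatory).
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, sigma2, root_value = 0, lambda_signal = 1,
                        seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(sigma2 >= 0, lambda_signal >= 0, lambda_signal <= 1)
  n <- ape::Ntip(tree)
  C <- ape::vcv(tree)
  V <- C * lambda_signal
  diag(V) <- diag(C)
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  x <- if (sigma2 == 0) rep(root_value, n)
       else root_value + sqrt(sigma2) * as.numeric(t(chol(V)) %*% z)
  stats::setNames(x, tree$tip.label)
}

#' Simulate chromosome-number evolution along a tree
#'
#' Gillespie simulation of the bounded gain/loss/duplication chain down
#' every branch, recording each event. Each branch uses its own seeded
#' random stream (derived from `seed` and the branch's child node id), so
#' the draws on one branch do not depend on the traversal order of the
#' others. Events whose target would leave the state space cannot occur
#' (their rate is zero in the truncated generator).
#'
#' @param tree `phylo` with branch lengths.
#' @param spec A [rate_model_spec()].
#' @param rates Named rate vector for `spec`.
#' @param root_haploid Starting haploid number (within bounds).
#' @param seed Integer seed (mandatory).
#' @return List with `tips` (named haploid vector) and `events`
#'   (data.frame `child`, `time`, `from`, `to`, `type`).
#' @export
simulate_chrom_ctmc <- function(tree, spec, rates, root_haploid, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(spec, "rate_model_spec"),
            root_haploid >= spec$n_min, root_haploid <= spec$n_max)
  Q <- suppressWarnings(build_rate_matrix(spec, rates))
  states <- spec$n_min:spec$n_max
  n <- ape::Ntip(tree)
  node_state <- integer(n + tree$Nnode)
  node_state[n + 1L] <- as.integer(root_haploid)
  events <- list()
  for (e in rev(ape::postorder(tree))) {   # preorder: parents first
    pa <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    set.seed((as.integer(seed) + 7919L * chd) %% .Machine$integer.max)
    s <- node_state[pa]
    t <- 0; tmax <- tree$edge.length[e]
    repeat {
      i <- match(s, states)
      rate <- -Q[i, i]
      if (rate <= 0) break
      t <- t + stats::rexp(1, rate)
      if (t >= tmax) break
      w <- Q[i, ]; w[i] <- 0
      j <- sample.int(length(states), 1L, prob = w)
      to <- states[j]
      type <- if (to == s + 1L) "gain" else if (to == s - 1L) "loss"
              else if (to == 2L * s) "dupl" else "demi"
      events[[length(events) + 1L]] <-
        data.frame(child = node_label(tree, chd), time = t, from = s,
                   to = to, type = type, stringsAsFactors = FALSE)
      s <- to
    }
    node_state[chd] <- s
  }
  tips <- stats::setNames(node_state[seq_len(n)], tree$tip.label)
  ev <- if (length(events)) do.call(rbind, events)
        else data.frame(child = character(), time = numeric(),
                        from = integer(), to = integer(),
                        type = character(), stringsAsFactors = FALSE)
  list(tips = tips, events = ev, node_states = node_state)
}

#' Fabricate an internally consistent random karyotype table
#'
#' Generates even diploid numbers, a consistent bi-armed/uni-armed split
#' (even bi-armed counts, so pair arithmetic works), and a handful of
#' random CH band sites per species — a no-download stand-in for a real
#' cytogenetic compilation.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed (mandatory).
#' @return A `karyotype_table` list of [karyotype_record()] objects.
#' @export
fabricate_karyotype_table <- function(n_species, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_species >= 2)
  set.seed(as.integer(seed))
  recs <- lapply(seq_len(n_species), function(i) {
    d2n <- 2L * sample(18:26, 1)
    npairs <- d2n %/% 2L
    biarmed <- 2L * (sample.int(npairs + 1L, 1) - 1L)
    extra <- sample(0:4, 1)
    bands <- "cen:all"
    if (extra > 0) {
      codes <- sample(c("int", "prox", "dist", "peri"), extra, replace = TRUE)
      sites <- paste0(sample.int(npairs, extra, replace = TRUE),
                      sample(c("p", "q"), extra, replace = TRUE))
      bands <- paste(c(bands, paste0(codes, ":", sites)), collapse = ";")
    }
    karyotype_record(sprintf("Species_%02d", i), d2n,
                     biarmed = biarmed, uniarmed = d2n - biarmed,
                     ch_bands = bands)
  })
  structure(recs, class = "karyotype_table")
}
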
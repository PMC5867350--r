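test_that("rate matrix entries follow the gain/loss/dupl rules", {
  spec <- rate_model_spec("CONST_RATE_NO_DUPL", 1, 3)
  Q <- build_rate_matrix(spec, c(gain_const = 1, loss_const = 2))
  expect_equal(unname(Q),
               matrix(c(-1, 1, 0, 2, -3, 1, 0, 2, -2), 3, byrow = TRUE))

  demi <- rate_model_spec("CONST_RATE_DEMI", 2, 12)
  Qd <- build_rate_matrix(demi, c(gain_const = 0, loss_const = 0, dupl = 0.7))
  expect_equal(Qd["4", "8"], 0.7)   # duplication 4 -> 8
  expect_equal(Qd["4", "6"], 0.7)   # demi-duplication 4 -> 1.5*4
  # odd state splits the demi rate between floor and ceiling targets
  expect_equal(Qd["5", "7"], 0.35)
  expect_equal(Qd["5", "8"], 0.35)

  est <- rate_model_spec("CONST_RATE_DEMI_EST", 2, 12)
  Qe <- build_rate_matrix(est, c(gain_const = 0, loss_const = 0,
                                 dupl = 0.7, demi = 0.2))
  expect_equal(Qe["4", "8"], 0.7)
  expect_equal(Qe["4", "6"], 0.2)
})

test_that("every family's rate matrix conserves probability", {
  set.seed(5)
  for (fam in CHROM_FAMILIES) {
    spec <- rate_model_spec(fam, 3, 14)
    rates <- stats::setNames(stats::runif(length(spec$parameter_names), 0, 2),
                             spec$parameter_names)
    Q <- suppressWarnings(build_rate_matrix(spec, rates))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    P <- as.matrix(Matrix::expm(Q * 0.37))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= -1e-12))
  }
})

test_that("linear rates clamp at zero with a warning", {
  spec <- rate_model_spec("LINEAR_RATE_NO_DUPL", 1, 10)
  expect_warning(
    Q <- build_rate_matrix(spec, c(gain_const = 1, gain_linear = -0.5,
                                   loss_const = 1, loss_linear = 0)),
    "clamped")
  expect_equal(unname(Q["5", "6"]), 0)  # 1 - 0.5*4 < 0 -> 0
  expect_equal(unname(Q["2", "3"]), 0.5)
})

test_that("single-branch likelihood matches the 2-state closed form", {
  # gain-only chain on {1,2}: P(stay) = exp(-g t), P(move) = 1 - exp(-g t)
  spec <- rate_model_spec("CONST_RATE_NO_DUPL", 1, 2)
  g <- 0.9
  for (t in c(0.2, 1, 3)) {
    tr <- read_newick(text = sprintf("(A:%f,B:%f);", t, t))
    # both tips at 1: conditional on root state, with the weighted root
    # convention logL = log(sum Lr^2 / sum Lr)
    rates <- c(gain_const = g, loss_const = 0)
    L1 <- exp(-g * t)^2     # root 1: both branches stay
    L2 <- 0                 # root 2: absorbing top state, cannot reach 1
    expect_equal(ctmc_loglik(tr, c(A = 1, B = 1), spec, rates),
                 log(L1^2 / L1), tolerance = 1e-12)
    mixed <- ctmc_loglik(tr, c(A = 1, B = 2), spec, rates)
    Lr1 <- exp(-g * t) * (1 - exp(-g * t))
    expect_equal(mixed, log(Lr1^2 / Lr1), tolerance = 1e-12)
  }
})

test_that("pruning likelihood equals exhaustive enumeration", {
  set.seed(23)
  trees <- list(read_newick(text = "((A:0.4,B:0.7):0.5,C:1.1);"),
                read_newick(text = "((A:0.3,B:0.3):0.4,(C:0.2,D:0.9):0.5);"),
                read_newick(text = "(((A:0.2,B:0.2):0.2,C:0.4):0.3,D:0.7);"))
  for (tr in trees) {
    for (fam in c("CONST_RATE", "CONST_RATE_DEMI_EST", "LINEAR_RATE",
                  "CONST_RATE_NO_DUPL")) {
      spec <- rate_model_spec(fam, 2, 7)
      rates <- stats::setNames(stats::runif(length(spec$parameter_names),
                                            0.1, 1.5),
                               spec$parameter_names)
      tips <- stats::setNames(sample(2:7, ape::Ntip(tr), replace = TRUE),
                              tr$tip.label)
      for (root in c("weighted", "flat")) {
        expect_lt(abs(ctmc_loglik(tr, tips, spec, rates, root = root) -
                        enum_ctmc_loglik(tr, tips, spec, rates, root)$logL),
                  1e-10)
      }
    }
  }
})

test_that("short-branch limit concentrates likelihood on the tip state", {
  spec <- rate_model_spec("CONST_RATE_NO_DUPL", 1, 5)
  rates <- c(gain_const = 1, loss_const = 1)
  tr <- read_newick(text = "((A:1e-9,B:1e-9):1e-9,C:2e-9);")
  tips <- c(A = 3, B = 3, C = 3)
  # weighted root: all mass on state 3, log(1) = 0
  expect_equal(ctmc_loglik(tr, tips, spec, rates), 0, tolerance = 1e-6)
  # flat root: log of the uniform prior mass at that state
  expect_equal(ctmc_loglik(tr, tips, spec, rates, root = "flat"),
               log(1 / 5), tolerance = 1e-6)
})

test_that("AIC identity holds, reproducing published model-table arithmetic", {
  expect_equal(aic(-29.83, 2), 63.66)
  expect_equal(aic(-29.83, 3), 65.66)
  expect_equal(aic(-30.1, 6), 72.2)
  tr <- random_yule_tree(8, 1, seed = 61)
  sim <- simulate_chrom_ctmc(tr, rate_model_spec("CONST_RATE_NO_DUPL", 5, 30),
                             c(gain_const = 0.1, loss_const = 1.5),
                             root_haploid = 20, seed = 62)
  fit <- fit_chrom_ctmc(tr, sim$tips, "CONST_RATE_NO_DUPL",
                        n_restarts = 3, seed = 1)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$logL, tolerance = 1e-9)
  expect_equal(AIC(logLik(fit)), fit$aic, tolerance = 1e-9)
})

test_that("model selection flags the lowest-AIC family and breaks ties by k", {
  tr <- random_yule_tree(10, 1, seed = 71)
  sim <- simulate_chrom_ctmc(tr, rate_model_spec("CONST_RATE_NO_DUPL", 5, 30),
                             c(gain_const = 0, loss_const = 2),
                             root_haploid = 20, seed = 72)
  one <- select_chrom_ctmc(tr, sim$tips, families = "CONST_RATE",
                           n_restarts = 2, seed = 1)
  expect_equal(one$best$spec$family, "CONST_RATE")
  both <- select_chrom_ctmc(tr, sim$tips,
                            families = c("CONST_RATE", "CONST_RATE_NO_DUPL"),
                            n_restarts = 3, seed = 1)
  # loss-only data: dropping the duplication parameter cannot hurt the
  # fit, so the 2-parameter family must win on AIC
  expect_equal(both$best$spec$family, "CONST_RATE_NO_DUPL")
  expect_lte(abs(diff(both$table$logL)), 0.2)
})

test_that("marginal ancestral posteriors match brute-force enumeration", {
  tr <- read_newick(text = "((A:0.4,B:0.7):0.5,C:1.1);")
  spec <- rate_model_spec("CONST_RATE", 3, 6)
  rates <- c(gain_const = 0.8, loss_const = 1.3, dupl = 0.4)
  tips <- c(A = 4L, B = 3L, C = 6L)
  for (root in c("weighted", "flat")) {
    fit <- structure(list(spec = spec, rates = rates, logL = NA, aic = NA,
                          k = 3L, converged = TRUE, root = root, tree = tr,
                          tip_states = tips, seed = 1L),
                     class = "chrom_fit")
    mine <- marginal_ancestral_states(fit)
    oracle <- enum_ctmc_marginals(tr, tips, spec, rates, root)
    expect_lt(max(abs(mine$posterior - oracle)), 1e-10)
    expect_equal(mine$nodes$best_diploid, 2L * mine$nodes$best_haploid)
    expect_equal(rowSums(mine$posterior), rep(1, nrow(mine$posterior)),
                 tolerance = 1e-9)
  }
})

test_that("near-zero rates pin every ancestral state to the shared tip state", {
  tr <- random_yule_tree(6, 1, seed = 81)
  tips <- stats::setNames(rep(12L, 6), tr$tip.label)
  spec <- rate_model_spec("CONST_RATE_NO_DUPL", 5, 20)
  fit <- structure(list(spec = spec,
                        rates = c(gain_const = 1e-9, loss_const = 1e-9),
                        logL = NA, aic = NA, k = 2L, converged = TRUE,
                        root = "weighted", tree = tr, tip_states = tips,
                        seed = 1L), class = "chrom_fit")
  asr <- marginal_ancestral_states(fit)
  expect_true(all(asr$nodes$best_haploid == 12L))
  expect_true(all(asr$nodes$posterior_max > 0.999))
})

test_that("tips outside the state bounds are rejected", {
  tr <- read_newick(text = "(A:1,B:1);")
  spec <- rate_model_spec("CONST_RATE_NO_DUPL", 5, 10)
  expect_error(ctmc_loglik(tr, c(A = 4, B = 6), spec,
                           c(gain_const = 1, loss_const = 1)),
               "outside state bounds")
})
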
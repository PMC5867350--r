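as_karyotable <- function(karyotypes) {
  if (is.character(karyotypes)) read_karyotype_table(karyotypes)
  else karyotypes
}

as_tree <- function(tree) {
  if (is.character(tree) && file.exists(tree)) read_newick(tree) else tree
}

read_diploid_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(d$diploid_number), d$species)
}

write_provenance <- function(out_dir, stage, config) {
  info <- list(stage = stage, config = config,
               package = as.character(utils::packageVersion("karyevol")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(info, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Divergence-matrix and UPGMA stage
#'
#' Computes the all-pairs karyotype divergence matrix (female complements
#' by default) and its UPGMA phenogram, and writes both.
#'
#' @param karyotypes Path to a karyotype TSV or a `karyotype_table`.
#' @param out_dir Output directory (created if needed).
#' @param sex Sex preference for species with sex-chromosome systems.
#' @param mode UPGMA mode, see [upgma_tree()].
#' @return Invisible list with `matrix` and `tree`.
#' @export
run_divergence <- function(karyotypes, out_dir, sex = "female",
                           mode = "direct") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recs <- select_sex(as_karyotable(karyotypes), sex)
  m <- divergence_matrix(recs)
  tr <- upgma_tree(m, mode = mode)
  write_divergence_matrix(m, file.path(out_dir, "divergence_matrix.tsv"))
  write_divergence_matrix(m, file.path(out_dir, "divergence_matrix.phy"),
                          format = "phylip")
  write_newick(tr, file.path(out_dir, "upgma_phenogram.nwk"))
  write_provenance(out_dir, "divergence",
                   list(sex = sex, mode = mode,
                        units = "chromosome-pair changes (raw index units)"))
  invisible(list(matrix = m, tree = tr))
}

# shared preparation: prune to taxa with data, Grafen lengths, trait vector
prepare_tree_data <- function(tree, karyotypes, extra_diploids, sex) {
  tree <- as_tree(tree)
  recs <- as_karyotable(karyotypes)
  d <- diploid_numbers(recs, sex)
  if (!is.null(extra_diploids)) {
    if (is.character(extra_diploids))
      extra_diploids <- read_diploid_table(extra_diploids)
    d <- c(d, extra_diploids[setdiff(names(extra_diploids), names(d))])
  }
  keep <- intersect(tree$tip.label, names(d))
  if (length(keep) < 2L) stop("fewer than 2 tree tips have diploid data")
  tree <- prune_to_taxa(tree, keep)
  tree <- grafen_lengths(tree)
  list(tree = tree, diploid = d[tree$tip.label], records = recs)
}

#' Brownian-motion ancestral-state and signal stage
#'
#' Prunes the tree to taxa with diploid data, applies Grafen branch
#' lengths (root height 1), reconstructs ancestral diploid numbers by ML
#' Brownian motion and computes Pagel's lambda and Blomberg's K.
#'
#' @inheritParams run_divergence
#' @param tree Newick path or `phylo`.
#' @param extra_diploids Optional named vector or two-column TSV path
#'   (`species`, `diploid_number`) for tips absent from the karyotype
#'   table (outgroups).
#' @param n_permutations Permutations for the K test.
#' @param seed Integer seed.
#' @return Invisible list with `asr` ([bm_asr()]) and `signal`
#'   ([phylo_signal()]).
#' @export
run_asr <- function(tree, karyotypes, out_dir, extra_diploids = NULL,
                    sex = "female", n_permutations = 1000, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_tree_data(tree, karyotypes, extra_diploids, sex)
  asr <- bm_asr(prep$tree, prep$diploid)
  sig <- phylo_signal(prep$tree, prep$diploid,
                      n_permutations = n_permutations, seed = seed)
  write_asr_table(asr, file.path(out_dir, "asr_nodes.tsv"))
  utils::write.table(
    data.frame(statistic = c("lambda", "lambda_logL", "lambda_p",
                             "K", "K_p", "n_permutations", "seed"),
               value = c(sig$lambda_hat, sig$lambda_logL, sig$lambda_p,
                         sig$k_stat, sig$k_p, sig$n_permutations, sig$seed)),
    file.path(out_dir, "signal.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_newick(prep$tree, file.path(out_dir, "analysis_tree.nwk"))
  write_provenance(out_dir, "asr",
                   list(sex = sex, n_permutations = n_permutations,
                        seed = seed, branch_lengths = "grafen rho=1"))
  invisible(list(asr = asr, signal = sig, tree = prep$tree))
}

#' Chromosome-number CTMC stage
#'
#' Fits the requested rate-model families to the haploid tip states on the
#' Grafen-scaled tree, selects the best by AIC, reconstructs marginal
#' ancestral haploid numbers (doubled to diploid), runs stochastic mapping
#' for per-branch expected fusion/fission counts, and derives the
#' discrete per-branch event table (fusions, fissions, inversions on
#' cherries) for the clade of karyotyped species.
#'
#' @inheritParams run_asr
#' @param families Model families to fit (default all eight).
#' @param n_maps Stochastic-mapping sample size.
#' @param n_restarts Optimizer restarts per family.
#' @return Invisible list with `selection`, `asr`, `events`, `branch_table`.
#' @export
run_chromevol <- function(tree, karyotypes, out_dir, extra_diploids = NULL,
                          sex = "female", families = CHROM_FAMILIES,
                          seed = 1, n_maps = 1000, n_restarts = 10) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  prep <- prepare_tree_data(tree, karyotypes, extra_diploids, sex)
  odd <- prep$diploid %% 2 != 0
  if (any(odd)) stop("odd diploid numbers: ",
                     paste(names(prep$diploid)[odd], collapse = ", "))
  tips_h <- stats::setNames(as.integer(prep$diploid / 2), names(prep$diploid))
  sel <- select_chrom_ctmc(prep$tree, tips_h, families = families,
                           seed = seed, n_restarts = n_restarts)
  asr <- marginal_ancestral_states(sel$best)
  ev <- expected_events(sel$best, n_maps = n_maps, seed = seed)

  # discrete event narrative on the karyotyped (ingroup) clade
  recs <- as_karyotable(karyotypes)
  sp <- unique(vapply(recs, function(r) r$species, character(1)))
  insp <- intersect(prep$tree$tip.label, sp)
  anc <- stats::setNames(asr$nodes$best_diploid,
                         ifelse(is.na(asr$nodes$label),
                                as.character(asr$nodes$node),
                                asr$nodes$label))
  branch_table <- NULL
  if (length(insp) >= 2) {
    mrca <- ape::getMRCA(prep$tree, insp)
    clade <- ape::extract.clade(prep$tree, mrca)
    branch_table <- annotate_tree_events(clade, anc, recs,
                                         tip_diploids = prep$diploid)
    utils::write.table(branch_table,
                       file.path(out_dir, "branch_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab <- sel$table
  tab$best <- tab$family == sel$best$spec$family
  utils::write.table(tab, file.path(out_dir, "model_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(asr$nodes, file.path(out_dir, "chrom_asr.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$branches, file.path(out_dir, "expected_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$totals, file.path(out_dir, "event_totals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(out_dir, "chromevol",
                   list(sex = sex, families = families, seed = seed,
                        n_maps = n_maps, n_restarts = n_restarts,
                        root = sel$best$root,
                        terminology = "gain = fission, loss = fusion",
                        branch_lengths = "grafen rho=1"))
  invisible(list(selection = sel, asr = asr, events = ev,
                 branch_table = branch_table, tree = prep$tree))
}

#' Run the full comparative-cytogenetics pipeline
#'
#' Divergence + UPGMA, Brownian-motion ancestral states with signal
#' statistics, and the chromosome-number CTMC stage, on one karyotype
#' table and tree. With no arguments it runs on the packaged example
#' data set.
#'
#' @inheritParams run_chromevol
#' @param n_permutations Permutations for the K test.
#' @return Invisible list of the three stage results.
#' @export
run_pipeline <- function(karyotypes = karyevol_example("karyotypes"),
                         tree = karyevol_example("tree"),
                         extra_diploids = karyevol_example("outgroups"),
                         out_dir = tempfile("karyevol_run_"),
                         sex = "female", seed = 1, n_permutations = 1000,
                         families = CHROM_FAMILIES, n_maps = 1000,
                         n_restarts = 10) {
  div <- run_divergence(karyotypes, out_dir, sex = sex)
  asr <- run_asr(tree, karyotypes, out_dir, extra_diploids = extra_diploids,
                 sex = sex, n_permutations = n_permutations, seed = seed)
  chr <- run_chromevol(tree, karyotypes, out_dir,
                       extra_diploids = extra_diploids, sex = sex,
                       families = families, seed = seed, n_maps = n_maps,
                       n_restarts = n_restarts)
  invisible(list(divergence = div, asr = asr, chromevol = chr,
                 out_dir = out_dir))
}
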
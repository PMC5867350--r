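#' Fusions/fissions implied by two diploid numbers
#'
#' A Robertsonian fusion joins two uni-armed chromosomes into one bi-armed
#' chromosome and lowers 2n by 2; a fission is the reverse. Between a
#' parent and child diploid number the net event count is `|delta 2n| / 2`,
#' in one direction only.
#'
#' @param parent_2n,child_2n Even positive diploid numbers.
#' @return Named integer vector `fusions`, `fissions` (one of them 0).
#' @examples
#' infer_fusion_fission(48, 38)  # five fusions
#' @export
infer_fusion_fission <- function(parent_2n, child_2n) {
  stopifnot(parent_2n > 0, child_2n > 0)
  if (parent_2n %% 2 != 0 || child_2n %% 2 != 0)
    stop("diploid numbers must be even (whole-pair rearrangements)")
  d <- parent_2n - child_2n
  if (d %% 2 != 0) stop("odd diploid difference")
  if (d >= 0) c(fusions = d %/% 2L, fissions = 0L)
  else c(fusions = 0L, fissions = (-d) %/% 2L)
}

#' Pericentric inversions between two karyotypes
#'
#' A pericentric inversion toggles one chromosome pair between uni-armed
#' and bi-armed without changing 2n. With equal diploid numbers the count
#' is simply the absolute difference in bi-armed pair counts. When the
#' diploid numbers differ, each of the `f = |delta 2n| / 2` Robertsonian
#' fusions converts two uni-armed pairs into one bi-armed pair, so the
#' lower-2n karyotype is expected to carry the higher-2n karyotype's
#' bi-armed pairs plus `f`; the inversion count is the deviation of its
#' observed bi-armed pairs from that expectation.
#'
#' @param a,b [karyotype_record()] objects with even bi-armed counts.
#' @return Non-negative integer inversion count (symmetric in `a`, `b`).
#' @examples
#' x <- karyotype_record("brevirostris", 38, "38st-a")
#' y <- karyotype_record("hendersoni", 38, "34m-sm/4st-a")
#' infer_pericentric_inversions(x, y)  # 17
#' @export
infer_pericentric_inversions <- function(a, b) {
  stopifnot(inherits(a, "karyotype_record"), inherits(b, "karyotype_record"))
  if (a$biarmed_count %% 2 != 0 || b$biarmed_count %% 2 != 0)
    stop("odd bi-armed chromosome count; pair counts must be integers")
  ma <- a$biarmed_count %/% 2L; mb <- b$biarmed_count %/% 2L
  if (a$diploid_number == b$diploid_number) return(abs(ma - mb))
  f <- abs(a$diploid_number - b$diploid_number) %/% 2L
  if (a$diploid_number < b$diploid_number) {
    abs(ma - (mb + f))
  } else {
    abs(mb - (ma + f))
  }
}

#' Per-branch rearrangement events on a reconstructed tree
#'
#' Combines reconstructed ancestral diploid numbers with observed tip
#' karyotypes into a per-branch event table: fusion/fission counts from the
#' parent-to-child diploid change on every branch; pericentric inversions
#' between sister tips of a cherry (karyotype formulas are observed only at
#' the tips); and a CH-change flag on cherries whose band sets differ.
#'
#' @param tree `phylo` (internal node labels used in output where present).
#' @param ancestral Named vector of internal-node diploid numbers; names
#'   are node labels or ape node numbers. Typically
#'   `2 * best_haploid` from [marginal_ancestral_states()] or rounded
#'   [bm_asr()] estimates.
#' @param records Karyotype table covering the karyotyped tips (one record
#'   per species after [select_sex()]).
#' @param tip_diploids Optional named vector of diploid numbers for tips
#'   without a karyotype record (e.g. outgroups known only by 2n); such
#'   tips get fusion/fission counts but no inversion or CH comparison.
#' @return Data.frame (class `branch_events`) with columns `child`,
#'   `parent`, `fusions`, `fissions`, `pericentric_inversions` (NA off
#'   cherries), `ch_changed` (NA off cherries).
#' @export
annotate_tree_events <- function(tree, ancestral, records,
                                 tip_diploids = NULL) {
  n <- ape::Ntip(tree)
  recs <- select_sex(records)
  sp <- vapply(recs, function(r) r$species, character(1))
  state_of <- function(v) {
    if (v <= n) {
      i <- match(tree$tip.label[v], sp)
      if (is.na(i)) {
        d <- tip_diploids[tree$tip.label[v]]
        if (is.null(d) || is.na(d))
          stop("no karyotype record or diploid number for tip ",
               tree$tip.label[v])
        return(as.numeric(d))
      }
      # even (female) complement for divergence along branches
      d <- recs[[i]]$diploid_number
      if (d %% 2 != 0) stop("odd diploid number at tip ", tree$tip.label[v])
      d
    } else {
      key <- node_label(tree, v)
      val <- ancestral[key]
      if (is.na(val)) val <- ancestral[as.character(v)]
      if (is.na(val)) stop("missing ancestral state for node ", key)
      as.numeric(val)
    }
  }
  ev <- lapply(seq_len(nrow(tree$edge)), function(e) {
    pa <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    ff <- infer_fusion_fission(state_of(pa), state_of(chd))
    inv <- NA_integer_; chch <- NA
    if (chd <= n) {
      sib <- setdiff(tree$edge[tree$edge[, 1] == pa, 2], chd)
      ia <- match(tree$tip.label[chd], sp)
      ib <- if (length(sib) == 1L && sib <= n) match(tree$tip.label[sib], sp)
            else NA_integer_
      if (!is.na(ia) && !is.na(ib)) {   # cherry with two observed KFs
        ra <- recs[[ia]]; rb <- recs[[ib]]
        inv <- infer_pericentric_inversions(ra, rb)
        cmpb <- compare_ch_bands(ra, rb)
        chch <- cmpb[["a_only"]] + cmpb[["b_only"]] > 0
      }
    }
    data.frame(child = node_label(tree, chd), parent = node_label(tree, pa),
               fusions = ff[["fusions"]], fissions = ff[["fissions"]],
               pericentric_inversions = inv, ch_changed = chch,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ev)
  class(out) <- c("branch_events", "data.frame")
  out
}
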
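#' Parsimony protein inference
#'
#' Assembles observed peptides into the smallest set of protein groups that
#' explains them all:
#'
#' 1. accessions with identical peptide sets are merged into one
#'    indistinguishable group (representative = lexicographically smallest
#'    accession);
#' 2. groups whose peptide set is a strict subset of another group's are
#'    subsumed (removed, recorded in `subsumed_accessions`);
#' 3. groups that are the sole owner of some peptide are selected first
#'    (they belong to every cover); the remaining peptides are covered
#'    greedily by descending count of still-unexplained peptides, ties
#'    broken lexicographically by representative;
#' 4. each peptide is assigned to exactly one selected group — the one with
#'    the most total peptides (razor rule), ties lexicographic.
#'
#' Greedy set cover may exceed the true minimum cover; on small instances an
#' exhaustive oracle in the test-suite quantifies the (rare) gap.
#'
#' @param pep_map named list mapping each peptide sequence to a character
#'   vector of parent accessions (as from [peptide_to_protein_map()]),
#'   decoys already removed.
#' @return list of class `inference_result`: `protein_groups` (list of
#'   character vectors of member accessions, named by representative, in
#'   selection order), `peptide_assignment` (named character vector
#'   peptide -> representative), `subsumed_accessions` (character).
#' @export
assemble_parsimony <- function(pep_map) {
  if (length(pep_map) == 0L) {
    return(structure(list(protein_groups = list(),
                          peptide_assignment = character(0),
                          subsumed_accessions = character(0)),
                     class = "inference_result"))
  }
  if (any(lengths(pep_map) == 0L)) {
    stop("peptide with empty accession set")
  }
  peptides <- sort(names(pep_map))
  # accession -> peptide set
  acc_pep <- split(rep(peptides, lengths(pep_map[peptides])),
                   unlist(pep_map[peptides]))
  acc_pep <- lapply(acc_pep, function(p) sort(unique(p)))

  # (1) merge accessions with identical peptide sets
  key <- vapply(acc_pep, paste, character(1), collapse = "\r")
  groups <- split(names(acc_pep), key)
  groups <- lapply(groups, sort)
  reps <- vapply(groups, `[`, character(1), 1L)
  names(groups) <- reps
  grp_pep <- acc_pep[reps]
  ord <- order(reps)
  groups <- groups[ord]; grp_pep <- grp_pep[ord]; reps <- reps[ord]

  # (2) subsume strict-subset groups
  sizes <- lengths(grp_pep)
  subsumed <- logical(length(reps))
  for (i in seq_along(reps)) {
    for (j in seq_along(reps)) {
      if (i == j || subsumed[i]) next
      if (sizes[i] < sizes[j] && all(grp_pep[[i]] %in% grp_pep[[j]])) {
        subsumed[i] <- TRUE
        break
      }
    }
  }
  subsumed_acc <- sort(unlist(groups[subsumed], use.names = FALSE))
  groups <- groups[!subsumed]; grp_pep <- grp_pep[!subsumed]
  reps <- reps[!subsumed]

  # (3) greedy cover. Groups that are the sole owner of some peptide are in
  # every cover, so they are selected first; the remainder is covered
  # greedily by descending unexplained-peptide count, ties lexicographic.
  inv <- split(rep(names(grp_pep), lengths(grp_pep)),
               unlist(grp_pep, use.names = FALSE))
  essentials <- sort(unique(unlist(inv[lengths(inv) == 1L],
                                   use.names = FALSE)))
  selected <- essentials
  unexplained <- setdiff(peptides,
                         unlist(grp_pep[selected], use.names = FALSE))
  while (length(unexplained) > 0L) {
    gain <- vapply(grp_pep, function(p) sum(p %in% unexplained), integer(1))
    cand <- setdiff(names(grp_pep)[gain == max(gain)], selected)
    if (max(gain) == 0L || length(cand) == 0L) {
      stop("peptides left unexplained by any group")  # cannot happen if map total
    }
    pick <- sort(cand)[1L]
    selected <- c(selected, pick)
    unexplained <- setdiff(unexplained, grp_pep[[pick]])
  }

  # (4) razor assignment: shared peptides to the selected group with most
  # total peptides, ties lexicographic (selected groups are scanned in
  # total-size order, so the first containing group wins)
  sel_sizes <- lengths(grp_pep[selected])
  razor_order <- selected[order(-sel_sizes, selected)]
  assignment <- setNames(rep(NA_character_, length(peptides)), peptides)
  for (g in razor_order) {
    p <- grp_pep[[g]]
    take <- p[is.na(assignment[p])]
    assignment[take] <- g
  }
  structure(list(protein_groups = groups[selected],
                 peptide_assignment = assignment,
                 subsumed_accessions = subsumed_acc),
            class = "inference_result")
}

#' Number of unique protein groups
#'
#' The statistic reported as "unique proteins identified" for any dataset:
#' the number of parsimonious protein groups.
#'
#' @param result an `inference_result`.
#' @return integer count.
#' @export
count_unique_proteins <- function(result) {
  length(result$protein_groups)
}

#' Exhaustive minimum set cover (oracle-sized instances only)
#'
#' Finds the true minimum number of protein-peptide sets covering all
#' peptides by enumerating subsets. Exponential; intended for instances with
#' at most ~15 proteins as an independent check on the greedy assembly.
#'
#' @param pep_map named list peptide -> accession vector.
#' @return minimum cover size (integer).
#' @export
min_cover_size_exhaustive <- function(pep_map) {
  if (length(pep_map) == 0L) return(0L)
  peptides <- names(pep_map)
  accs <- sort(unique(unlist(pep_map)))
  if (length(accs) > 20L) stop("instance too large for exhaustive search")
  acc_pep <- lapply(accs, function(a) {
    peptides[vapply(pep_map, function(p) a %in% p, logical(1))]
  })
  for (k in seq_along(accs)) {
    combs <- utils::combn(length(accs), k, simplify = FALSE)
    for (cmb in combs) {
      covered <- unique(unlist(acc_pep[cmb]))
      if (length(covered) == length(peptides)) return(k)
    }
  }
  length(accs)
}
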
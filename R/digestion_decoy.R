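AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Create a protein entry table
#'
#' A protein database is represented as a data.frame with columns
#' `accession`, `sequence` and `is_decoy`. Sequences must be uppercase and
#' restricted to the 20 canonical amino acids; decoy accessions carry the
#' reserved decoy prefix.
#'
#' @param accession character vector of unique accessions.
#' @param sequence character vector of amino-acid sequences.
#' @param is_decoy logical vector (default all `FALSE`).
#' @return data.frame with class `protein_db`.
#' @export
protein_db <- function(accession, sequence, is_decoy = FALSE) {
  stopifnot(length(accession) == length(sequence))
  if (anyDuplicated(accession)) {
    stop("duplicate accessions in protein database")
  }
  sequence <- toupper(sequence)
  bad <- grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")), sequence)
  if (any(bad)) {
    stop("non-canonical residues in sequence(s): ",
         paste(utils::head(accession[bad], 5), collapse = ", "))
  }
  if (any(nchar(sequence) == 0)) stop("empty protein sequence")
  db <- data.frame(accession = unname(as.character(accession)),
                   sequence = unname(sequence),
                   is_decoy = rep_len(unname(as.logical(is_decoy)),
                                      length(accession)),
                   stringsAsFactors = FALSE)
  class(db) <- c("protein_db", "data.frame")
  db
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the
#' following residue is proline (P), and emits all peptides spanning
#' `0..max_missed` internal missed cleavage sites, filtered to
#' `[min_len, max_len]` residues.
#'
#' @param sequence a single amino-acid sequence (or a `protein_db` row's
#'   sequence); uppercase canonical residues only.
#' @param max_missed maximum number of internal missed cleavage sites
#'   (default 2).
#' @param min_len,max_len peptide length bounds (defaults 7 and 50; set
#'   `min_len = 1`, `max_len = Inf` to disable).
#' @return data.frame with columns `peptide` and `missed_cleavages`, one row
#'   per distinct emitted peptide (first occurrence kept).
#' @export
tryptic_digest <- function(sequence, max_missed = 2L, min_len = 7L,
                           max_len = 50L) {
  stopifnot(length(sequence) == 1L, max_missed >= 0L, min_len >= 1L)
  sequence <- toupper(sequence)
  if (grepl(sprintf("[^%s]", paste(AA_CANONICAL, collapse = "")), sequence)) {
    stop("invalid residues in sequence")
  }
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # cleavage after position i iff res[i] in {K,R} and res[i+1] != P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  cut_after <- setdiff(cut_after, n)  # C-terminus is a boundary regardless
  bounds <- c(0L, cut_after, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  n_frag <- length(starts)
  out_pep <- character(0)
  out_mc <- integer(0)
  for (i in seq_len(n_frag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > n_frag) break
      len <- ends[j] - starts[i] + 1L
      if (len < min_len || len > max_len) next
      out_pep <- c(out_pep, substr(sequence, starts[i], ends[j]))
      out_mc <- c(out_mc, m)
    }
  }
  # all products kept in positional order: concatenating the
  # zero-missed-cleavage rows reconstructs the protein
  data.frame(peptide = out_pep, missed_cleavages = out_mc,
             stringsAsFactors = FALSE)
}

#' Digest a whole protein database
#'
#' Applies [tryptic_digest()] to every entry and records parent accessions.
#'
#' @param db a `protein_db`.
#' @inheritParams tryptic_digest
#' @return data.frame with columns `peptide`, `accession`, `missed_cleavages`
#'   (one row per peptide x parent).
#' @export
digest_db <- function(db, max_missed = 2L, min_len = 7L, max_len = 50L) {
  pieces <- lapply(seq_len(nrow(db)), function(i) {
    d <- tryptic_digest(db$sequence[i], max_missed, min_len, max_len)
    if (nrow(d) == 0L) return(NULL)
    d$accession <- db$accession[i]
    d
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), missed_cleavages = integer(0),
                      accession = character(0), stringsAsFactors = FALSE)
  }
  out[, c("peptide", "accession", "missed_cleavages")]
}

#' Build the concatenated reversed-decoy database
#'
#' Appends, for every target protein, a decoy entry whose sequence is the
#' full reversal of the target sequence, flagged and prefixed. FDR estimation
#' downstream counts matches to these decoys.
#'
#' @param targets a `protein_db` of target entries only.
#' @param decoy_prefix accession prefix reserved for decoys (default
#'   `"rev_"`).
#' @return a `protein_db` of `2 * nrow(targets)` entries.
#' @export
build_decoy_db <- function(targets, decoy_prefix = "rev_") {
  if (any(targets$is_decoy)) stop("input must contain target entries only")
  if (any(startsWith(targets$accession, decoy_prefix))) {
    stop("target accessions must not carry the decoy prefix")
  }
  rev_seq <- vapply(strsplit(targets$sequence, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
  decoys <- protein_db(paste0(decoy_prefix, targets$accession), rev_seq,
                       is_decoy = TRUE)
  out <- rbind(as.data.frame(targets), as.data.frame(decoys))
  class(out) <- c("protein_db", "data.frame")
  out
}

#' Map peptides to the proteins containing them
#'
#' @param digest a digest table from [digest_db()] (columns `peptide`,
#'   `accession`).
#' @param decoy_prefix prefix identifying decoy accessions, used to flag
#'   peptides shared between a target and a decoy.
#' @return named list mapping each peptide sequence to its character vector
#'   of parent accessions, with attribute `shared_with_decoy` (character
#'   vector of peptides having both target and decoy parents).
#' @export
peptide_to_protein_map <- function(digest, decoy_prefix = "rev_") {
  if (nrow(digest) == 0L) {
    m <- list()
    attr(m, "shared_with_decoy") <- character(0)
    return(m)
  }
  m <- lapply(split(digest$accession, digest$peptide), function(a) {
    sort(unique(a))
  })
  is_dec <- vapply(m, function(a) any(startsWith(a, decoy_prefix)), logical(1))
  is_tgt <- vapply(m, function(a) any(!startsWith(a, decoy_prefix)), logical(1))
  attr(m, "shared_with_decoy") <- names(m)[is_dec & is_tgt]
  m
}

#' Read / write protein databases as FASTA
#'
#' Thin wrappers over Biostrings; the decoy flag is recovered from the
#' accession prefix on read.
#'
#' @param db a `protein_db`.
#' @param path file path.
#' @param decoy_prefix accession prefix reserved for decoys.
#' @return `read_fasta_db` returns a `protein_db`; `write_fasta_db` returns
#'   `path` invisibly.
#' @export
write_fasta_db <- function(db, path) {
  x <- Biostrings::AAStringSet(db$sequence)
  names(x) <- db$accession
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta_db
#' @export
read_fasta_db <- function(path, decoy_prefix = "rev_") {
  x <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(x))
  protein_db(acc, as.character(x),
             is_decoy = startsWith(acc, decoy_prefix))
}
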
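#' Needleman-Wunsch global alignment
#'
#' Global pairwise alignment used by the duplication detector, the
#' subgroup classifier and the progressive aligner. Protein mode scores
#' with BLOSUM62 (gap opening 10, gap extension 1); nucleotide mode uses
#' match +2 / mismatch -3 (gap opening 5, extension 2). The dynamic
#' programming engine is [Biostrings::pairwiseAlignment()]; a gap of
#' length L costs `opening + L * extension`.
#'
#' @param a,b Sequences (plain character strings).
#' @param mode `"aa"` or `"nt"`.
#' @return List with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `identity` (identical columns / aligned columns),
#'   `coverage` (columns where both sequences are ungapped, divided by
#'   the length of the longer input) and `score`.
#' @export
global_align <- function(a, b, mode = c("aa", "nt")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) .stopf("global_align: empty sequence")
  a <- toupper(a); b <- toupper(b)
  if (mode == "nt") {
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b))
      .stopf("global_align: non-ACGT letter in nucleotide mode")
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                   baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                        Biostrings::DNAString(b),
                                        substitutionMatrix = sm,
                                        gapOpening = 5, gapExtension = 2,
                                        type = "global")
  } else {
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", a) || grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", b))
      .stopf("global_align: non-amino-acid letter in protein mode")
    # '*' and 'X' are tolerated but scored via 'X' (never a good match)
    a2 <- gsub("*", "X", a, fixed = TRUE)
    b2 <- gsub("*", "X", b, fixed = TRUE)
    sm <- get_blosum62()
    pa <- Biostrings::pairwiseAlignment(Biostrings::AAString(a2),
                                        Biostrings::AAString(b2),
                                        substitutionMatrix = sm,
                                        gapOpening = 10, gapExtension = 1,
                                        type = "global")
  }
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "")[[1L]]
  cb <- strsplit(al_b, "")[[1L]]
  both <- ca != "-" & cb != "-"
  n_cols <- sum(ca != "-" | cb != "-")
  identity <- if (n_cols == 0L) 0 else sum(ca == cb & both) / n_cols
  coverage <- sum(both) / max(nchar(a), nchar(b))
  list(aligned_a = al_a, aligned_b = al_b, identity = identity,
       coverage = coverage, score = Biostrings::score(pa))
}

# Vectorized protein alignment of one query against many subjects with
# the same scoring as global_align(mode = "aa"); used by the all-pairs
# duplication screen.
.batch_align_aa <- function(query, subjects) {
  q <- gsub("*", "X", toupper(query), fixed = TRUE)
  s <- gsub("*", "X", toupper(subjects), fixed = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAStringSet(s),
                                      Biostrings::AAString(q),
                                      substitutionMatrix = get_blosum62(),
                                      gapOpening = 10, gapExtension = 1,
                                      type = "global")
  # global alignments never contain both-gap columns, so the alignment
  # length is the column count and nmatch/nmismatch count the ungapped
  # aligned columns
  n_match <- Biostrings::nmatch(pa)
  n_mismatch <- Biostrings::nmismatch(pa)
  n_cols <- Biostrings::nchar(pa)
  list(identity = ifelse(n_cols == 0, 0, n_match / n_cols),
       coverage = (n_match + n_mismatch) /
         pmax(nchar(query), nchar(subjects)))
}

# p-distance (mismatches over ungapped aligned columns) between a query
# and many references, without materializing alignment strings.
.batch_p_distance <- function(query, refs) {
  q <- gsub("*", "X", toupper(query), fixed = TRUE)
  s <- gsub("*", "X", toupper(refs), fixed = TRUE)
  pa <- Biostrings::pairwiseAlignment(Biostrings::AAStringSet(s),
                                      Biostrings::AAString(q),
                                      substitutionMatrix = get_blosum62(),
                                      gapOpening = 10, gapExtension = 1,
                                      type = "global")
  n_match <- Biostrings::nmatch(pa)
  n_mismatch <- Biostrings::nmismatch(pa)
  both <- n_match + n_mismatch
  ifelse(both == 0, 1, n_mismatch / both)
}

# BLOSUM62 fetched once from Biostrings' bundled data.
get_blosum62 <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      mat <<- e$BLOSUM62
    }
    mat
  }
})
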
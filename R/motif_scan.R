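# Conserved-motif scanning: the packaged family consensus motifs (MEME
# consensus strings reported for this family, including the NLS
# [motif13], HARF [motif16] and Leu-zipper [motif7] motifs) and the
# transcriptional coactivator patterns LXXLL / LXLXLX.

#' Packaged WRKY motif consensus table
#'
#' @return Data frame with `motif_id`, `width` (as reported) and
#'   `consensus` (amino-acid string; `x` matches any residue).
#' @export
load_wrky_motifs <- function() {
  path <- system.file("extdata", "wrky_motifs.tsv", package = "wrkyscan",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Scan a protein for a consensus motif
#'
#' Sliding-window Hamming comparison against a packaged consensus
#' string: every window of the motif's length is tested, and a hit is
#' reported when the number of mismatches is at most
#' `floor(max_mismatch_frac * width)`. `x` in the consensus matches any
#' residue. Overlapping hits are all reported.
#'
#' @param protein Amino-acid string.
#' @param motif_id One of the ids in [load_wrky_motifs()].
#' @param max_mismatch_frac Mismatch tolerance as a fraction of motif
#'   width (0 = exact matching).
#' @param motifs Motif table (defaults to the packaged one).
#' @return Data frame with `motif_id`, `start` (1-based), `match`
#'   (the matched subsequence) and `mismatches`.
#' @export
scan_consensus <- function(protein, motif_id, max_mismatch_frac = 0.2,
                           motifs = load_wrky_motifs()) {
  row <- motifs[motifs$motif_id == motif_id, , drop = FALSE]
  if (nrow(row) != 1L) .stopf("unknown motif id: %s", motif_id)
  consensus <- toupper(row$consensus)
  w <- nchar(consensus)
  cons <- strsplit(consensus, "")[[1L]]
  wild <- cons == "X"
  prot <- strsplit(toupper(protein), "")[[1L]]
  n <- length(prot)
  max_mm <- floor(max_mismatch_frac * w)
  hits <- list()
  if (n >= w) {
    for (s in seq_len(n - w + 1L)) {
      win <- prot[s:(s + w - 1L)]
      mm <- sum(win != cons & !wild)
      if (mm <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(
          motif_id = motif_id, start = s,
          match = paste(win, collapse = ""), mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(motif_id = character(0), start = integer(0),
                      match = character(0), mismatches = integer(0)))
  do.call(rbind, hits)
}

#' Scan for coactivator motifs (LXXLL / LXLXLX)
#'
#' Reports every (possibly overlapping) match of the two leucine-rich
#' coactivator patterns, where X is any residue.
#'
#' @param protein Amino-acid string.
#' @return Data frame with `motif_id` (`"LXXLL"` or `"LXLXLX"`),
#'   `start` (1-based) and `match`.
#' @export
scan_coactivator <- function(protein) {
  protein <- toupper(protein)
  out <- list()
  for (spec in list(c("LXXLL", "(?=(L..LL))"), c("LXLXLX", "(?=(L.L.L.))"))) {
    m <- gregexpr(spec[2L], protein, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    starts <- as.integer(m)
    w <- nchar(spec[1L])
    out[[length(out) + 1L]] <- data.frame(
      motif_id = spec[1L], start = starts,
      match = substring(protein, starts, starts + w - 1L),
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(motif_id = character(0), start = integer(0),
                      match = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
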
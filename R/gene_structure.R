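# Intron phase computation and conserved-intron (R-/V-type) typing.
#
# Two conserved introns recur in WRKY domains: a phase-2 intron spliced
# two nucleotides into an R codon between the heptapeptide and the zinc
# finger (R-type), and a phase-0 intron immediately before the codon six
# residues after the second C of a C2H2 finger (V-type, after the V that
# usually sits there).

#' Compute intron phases from coding exon structure
#'
#' @param record A `gene_record` with coding `exons` (0-based half-open,
#'   transcript frame).
#' @return Data frame with one row per intron: `index`, `length_bp`
#'   (genomic gap between the flanking coding exons), `cds_offset`
#'   (coding nucleotides upstream of the junction), `phase`
#'   (`cds_offset mod 3`), `anchor_aa` (0-based protein index of the
#'   codon adjoining the splice). Single-exon genes give zero rows.
#' @export
compute_intron_phases <- function(record) {
  ex <- record$exons
  if (is.null(ex) || nrow(ex) == 0L)
    .stopf("compute_intron_phases: record %s has no coding exons",
           record$gene_id)
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
    .stopf("compute_intron_phases: overlapping exons in %s", record$gene_id)
  n_intron <- nrow(ex) - 1L
  if (n_intron == 0L)
    return(data.frame(index = integer(0), length_bp = integer(0),
                      cds_offset = integer(0), phase = integer(0),
                      anchor_aa = integer(0)))
  lens <- ex[, 2L] - ex[, 1L]
  upstream <- cumsum(lens)[seq_len(n_intron)]
  data.frame(index = seq_len(n_intron),
             length_bp = ex[-1L, 1L] - ex[-nrow(ex), 2L],
             cds_offset = as.integer(upstream),
             phase = as.integer(upstream %% 3L),
             anchor_aa = as.integer(upstream %/% 3L))
}

#' Classify introns as R-type, V-type or OTHER
#'
#' R-type: phase 2, and the codon split by the junction encodes R and
#' lies between the heptapeptide and the first zinc-finger cysteine.
#' V-type: phase 0, the domain's finger is C2H2, and the codon following
#' the junction is the one six residues after the second cysteine.
#' C2HC (group III) domains can only host R-type or OTHER introns.
#'
#' @param record A `gene_record` with exons and `protein`.
#' @param domain A `wrky_domain` (from [scan_wrky_domains()]); when
#'   `NULL` every complete domain of the record's protein is considered
#'   (a two-domain group I gene hosts its conserved intron in the
#'   C-terminal domain).
#' @return The [compute_intron_phases()] data frame with an added
#'   `type` column (`"R"`, `"V"`, `"OTHER"`).
#' @export
classify_intron_type <- function(record, domain = NULL) {
  introns <- compute_intron_phases(record)
  introns$type <- rep("OTHER", nrow(introns))
  if (nrow(introns) == 0L) return(introns)
  domains <- if (is.null(domain)) {
    doms <- scan_wrky_domains(record$protein)
    Filter(function(d) isTRUE(d$complete), doms)
  } else if (isTRUE(domain$complete)) list(domain) else list()
  if (!length(domains)) return(introns)
  aa <- strsplit(record$protein, "")[[1L]]
  for (i in seq_len(nrow(introns))) {
    idx <- introns$anchor_aa[i]
    for (dom in domains) {
      first_c <- dom$zf_coords[1L]
      second_c <- dom$zf_coords[2L]
      if (introns$phase[i] == 2L &&
          idx > dom$hepta_start + 6L && idx < first_c &&
          idx + 1L <= length(aa) && aa[idx + 1L] == "R") {
        introns$type[i] <- "R"
        break
      } else if (introns$phase[i] == 0L && dom$zf_class == "C2H2" &&
                 idx == second_c + 6L) {
        introns$type[i] <- "V"
        break
      }
    }
  }
  introns
}

#' Summarize conserved (R-/V-type) intron lengths
#'
#' @param annotations Data frame of typed introns (rows from
#'   [classify_intron_type()], possibly over many genes).
#' @return Data frame with `n`, `mean_bp`, `median_bp` over R- and
#'   V-type introns only; `n = 0` with `NA` statistics when there are
#'   none.
#' @export
intron_length_summary <- function(annotations) {
  cons <- annotations[annotations$type %in% c("R", "V"), , drop = FALSE]
  if (nrow(cons) == 0L)
    return(data.frame(n = 0L, mean_bp = NA_real_, median_bp = NA_real_))
  data.frame(n = nrow(cons), mean_bp = mean(cons$length_bp),
             median_bp = median(cons$length_bp))
}
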
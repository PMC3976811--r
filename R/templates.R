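# Synthetic WRKY domain templates.
#
# One grammar-conformant domain per family class, written by hand so the
# planted ground truth of the synthetic genome is exact. These are NOT
# real gene sequences: the heptapeptide, zinc-finger skeleton and
# class-specific finger spacings follow the family's published domain
# grammar, while linker/spacer residues are arbitrary (no W/C/H, so no
# accidental heptapeptides or fingers). Layout per template:
#
#   heptapeptide (7 aa) + linker (12 aa, R at linker position 3, the
#   R-type intron anchor) + zinc finger.
#
# Finger spacings by class: CX4CX22HXH (In, IIx), CX4CX23HXH (Ic, IIe),
# CX5CX23HXH (IIa, IIb, IIc, IId), and CX6CX26HXC for group III. In all
# C2H2 templates the 6th residue after the second C is V (the V-type
# intron anchor).

.wrky_templates <- local({
  mk <- function(hepta, linker, sA, sB, hx, last) {
    paste0(hepta, linker, "C", sA, "C", sB, "H", hx, last)
  }
  tpl <- c(
    In  = mk("WKKYGQK", "ADRSTGLEPKVM", "GDKA",   "IRADDVLYTKEGSQPNMEITRG",    "T", "H"),
    Ic  = mk("WRKYGQK", "TQRNELGSPDAK", "PVRG",   "QGSEKVTDLNRAYPMEQGITDSK",   "S", "H"),
    IIa = mk("WRKYGQK", "SERAGTKLNQPD", "AGDKS",  "RPTLEVNAKDYQSGMETIRLPDN",   "N", "H"),
    IIb = mk("WRKYGQK", "KDRLSPANGETQ", "KQTDG",  "SGALEVDKNQYTRPMSEGILDAN",   "A", "H"),
    IIc = mk("WRKYGQK", "GNRQTDSEPLAK", "TDNLG",  "EKSAQVGDLPYRNTMAESIQKGD",   "K", "H"),
    IId = mk("WRKYGQK", "PSRKGELQDTNA", "QESAG",  "LNDTKVRPGAYMSEQDLITNKPA",   "R", "H"),
    IIe = mk("WRKYGQK", "LTRDNQGAKSEP", "NTEG",   "DMAKLVSQRTYENGPDIAKLSTQ",   "G", "H"),
    IIx = mk("WKKYGQK", "EARGDSLKQTNP", "SEQG",   "KTLDEVAGNRYSPQMDKLEITA",    "D", "H"),
    III = mk("WRKYGQK", "NKRLTEGQSDPA", "GQENKA", "TKDLSEAGRNYPQMVEDITAKSLGNQ", "T", "C")
  )
  tpl
})

#' Packaged WRKY domain templates
#'
#' Synthetic reference domains, one per family class (`In`, `Ic`,
#' `IIa`-`IIe`, `IIx`, `III`). Used both as the labeled reference set
#' for nearest-reference subgroup assignment and as the seeds from which
#' [generate_genome()] plants genes.
#'
#' @param classes Optional subset of class names.
#' @return Named character vector of domain amino-acid sequences.
#' @export
wrky_domain_templates <- function(classes = NULL) {
  if (is.null(classes)) return(.wrky_templates)
  missing <- setdiff(classes, names(.wrky_templates))
  if (length(missing)) .stopf("unknown template class: %s", missing[[1L]])
  .wrky_templates[classes]
}

#' Labeled reference domains for group II subgroup assignment
#'
#' The group II members of [wrky_domain_templates()], named by subgroup.
#'
#' @return Named character vector (names `IIa`, `IIb`, `IIc`, `IId`,
#'   `IIe`, `IIx`).
#' @export
wrky_reference_domains <- function() {
  wrky_domain_templates(c("IIa", "IIb", "IIc", "IId", "IIe", "IIx"))
}
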
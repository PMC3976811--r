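# WRKY domain detection and family classification.
#
# The detector is a sequence grammar, not a profile HMM: a heptapeptide
# W[RKLSV][RKC]YG[QYELK]K (the union of the family's named WRKYGQK
# variants and the observed single-residue substitutions) followed,
# within 50 residues, by a zinc finger matching either
#   C2H2:  C-X(4,5)-C-X(22,23)-H-X-H
#   C2HC:  C-X(5,8)-C-X(25,28)-H-X(1,2)-C
# C2H2 is tried first when both could match.

.HEPTA_PATTERN <- "W[RKLSV][RKC]YG[QYELK]K"
.C2H2_PATTERN <- "(C)[^*]{4,5}(C)[^*]{22,23}(H)[^*](H)"
.C2HC_PATTERN <- "(C)[^*]{5,8}(C)[^*]{25,28}(H)[^*]{1,2}(C)"
.ZF_WINDOW <- 50L

#' Scan a protein for WRKY domains
#'
#' Finds every heptapeptide match of the domain grammar and attaches the
#' nearest downstream zinc finger starting within 50 residues of the
#' heptapeptide end (C2H2 takes precedence over C2HC). Domains are
#' returned in sequence order; in multi-domain proteins the first is
#' labeled `N` and the later ones `C`, otherwise `SINGLE`.
#'
#' @param protein Amino-acid string (standard alphabet; `X` tolerated
#'   but never matches a conserved position).
#' @return List of `wrky_domain` objects, each with fields
#'   `hepta_start` (0-based), `heptapeptide`, `zf_class` (`"C2H2"`,
#'   `"C2HC"` or `"ABSENT"`), `zf_coords` (0-based positions of the
#'   conserved C/H residues), `terminal`, `complete`, `span` (residues
#'   from heptapeptide start through zinc-finger end).
#' @export
scan_wrky_domains <- function(protein) {
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    .stopf("scan_wrky_domains: protein must be a non-empty string")
  protein <- toupper(protein)
  hits <- gregexpr(.HEPTA_PATTERN, protein, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(list())
  domains <- lapply(as.integer(hits), function(start1) {
    hepta_end1 <- start1 + 6L                      # 1-based inclusive
    tail_seq <- substr(protein, hepta_end1 + 1L, nchar(protein))
    zf <- .find_zinc_finger(tail_seq)
    if (!is.null(zf) && zf$rel_start <= .ZF_WINDOW) {
      # zf$coords are 0-based within the tail, which itself starts at
      # 0-based protein position hepta_end1
      zf_coords <- zf$coords + hepta_end1
      dom_end <- max(zf_coords) + 1L               # 0-based exclusive
      structure(list(hepta_start = start1 - 1L,
                     heptapeptide = substr(protein, start1, hepta_end1),
                     zf_class = zf$class, zf_coords = zf_coords,
                     terminal = "SINGLE", complete = TRUE,
                     span = dom_end - (start1 - 1L)),
                class = "wrky_domain")
    } else {
      structure(list(hepta_start = start1 - 1L,
                     heptapeptide = substr(protein, start1, hepta_end1),
                     zf_class = "ABSENT", zf_coords = integer(0),
                     terminal = "SINGLE", complete = FALSE, span = 7L),
                class = "wrky_domain")
    }
  })
  if (length(domains) >= 2L) {
    domains[[1L]]$terminal <- "N"
    for (i in 2:length(domains)) domains[[i]]$terminal <- "C"
  }
  domains
}

# Leftmost zinc finger in `s`; C2H2 has precedence over C2HC.
# Returns rel_start (1-based in s), class, and 0-based coords within s
# of the four conserved residues, or NULL.
.find_zinc_finger <- function(s) {
  for (spec in list(list(p = .C2H2_PATTERN, class = "C2H2"),
                    list(p = .C2HC_PATTERN, class = "C2HC"))) {
    m <- regexpr(spec$p, s, perl = TRUE)
    if (m[1L] > 0L) {
      cs <- attr(m, "capture.start")[1L, ]
      return(list(rel_start = as.integer(m[1L]), class = spec$class,
                  coords = as.integer(cs) - 1L))
    }
  }
  NULL
}

#' Classify a gene into WRKY group I, II or III
#'
#' Group I: two (or more) heptapeptide matches with at least one
#' complete domain -- an incomplete C-terminal domain does not demote
#' the gene. Group II / III: a single complete domain with a C2H2 /
#' C2HC zinc finger. Anything else is `UNCLASSIFIED`.
#'
#' @param domains Output of [scan_wrky_domains()].
#' @return List with `group` and the supporting `domains`.
#' @export
classify_group <- function(domains) {
  n <- length(domains)
  complete <- vapply(domains, `[[`, logical(1), "complete")
  group <- if (n >= 2L && any(complete)) {
    "I"
  } else if (n == 1L && complete[1L]) {
    switch(domains[[1L]]$zf_class, C2H2 = "II", C2HC = "III", "UNCLASSIFIED")
  } else {
    "UNCLASSIFIED"
  }
  list(group = group, domains = domains)
}

#' Assign a group II domain to a subgroup by nearest reference
#'
#' Computes the p-distance (mismatches over ungapped aligned columns of
#' a global protein alignment) between the query domain and every
#' labeled reference; the query takes the label of the nearest
#' reference, ties broken by reference input order. A query farther than
#' `threshold` from every reference gets the label `"unplaced"` (the
#' situation that motivated the provisional IIx subgroup).
#'
#' @param domain_seq Query domain string (heptapeptide through zinc
#'   finger end).
#' @param references Named character vector of labeled reference
#'   domains; defaults to the packaged templates.
#' @param threshold Maximum p-distance to accept a reference.
#' @return List with `subgroup`, `nearest` (reference name) and
#'   `distance`.
#' @export
assign_subgroup <- function(domain_seq, references = wrky_reference_domains(),
                            threshold = 0.6) {
  if (length(references) == 0L) .stopf("assign_subgroup: empty reference set")
  d <- .batch_p_distance(domain_seq, references)
  names(d) <- names(references)
  best <- which.min(d)   # which.min takes the first minimum: tie rule
  if (d[best] > threshold)
    return(list(subgroup = "unplaced", nearest = names(references)[best],
                distance = unname(d[best])))
  list(subgroup = names(references)[best], nearest = names(references)[best],
       distance = unname(d[best]))
}

#' Detect pseudogene signatures in a CDS
#'
#' @param cds Coding sequence 5'->3'.
#' @return List with `premature_stop` (an in-frame stop codon before the
#'   final complete codon) and `frameshift` (length not divisible by 3).
#' @export
detect_pseudogene <- function(cds) {
  if (!is.character(cds) || length(cds) != 1L || nchar(cds) < 3L)
    .stopf("detect_pseudogene: CDS shorter than one codon")
  cds <- toupper(cds)
  n_codon <- nchar(cds) %/% 3L
  codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  internal <- codons[-n_codon]
  list(premature_stop = any(internal %in% c("TAA", "TAG", "TGA")),
       frameshift = (nchar(cds) %% 3L) != 0L)
}

#' Scan, classify and filter a set of proteins
#'
#' Runs [scan_wrky_domains()], [classify_group()] and (for group II
#' genes) [assign_subgroup()] over a protein set, flags pseudogenes when
#' coding sequences are supplied, and applies the candidate filter: a
#' gene is kept only if it has a classified group and a complete domain
#' spanning at least `min_domain_span` residues (two thirds of the
#' canonical ~60-aa domain). A group I gene with one complete domain is
#' kept even when its second domain is incomplete.
#'
#' @param proteins Named character vector of protein sequences.
#' @param cds Optional named character vector of coding sequences
#'   (names matching `proteins`) for pseudogene flagging.
#' @param references Reference domains for subgroup assignment.
#' @param min_domain_span Minimum complete-domain span in residues.
#' @return A data frame with one row per input protein: `gene_id`,
#'   `n_domains`, `n_complete`, `zf_classes`, `group`, `subgroup`,
#'   `max_span`, `premature_stop`, `frameshift`, `pseudogene`, `kept`.
#'   The per-gene domain lists are attached as attribute `"domains"`.
#' @export
classify_records <- function(proteins, cds = NULL,
                             references = wrky_reference_domains(),
                             min_domain_span = 40L) {
  stopifnot(!is.null(names(proteins)))
  doms <- lapply(proteins, scan_wrky_domains)
  rows <- lapply(names(proteins), function(id) {
    d <- doms[[id]]
    cl <- classify_group(d)
    complete <- vapply(d, `[[`, logical(1), "complete")
    spans <- vapply(d, `[[`, integer(1), "span")
    max_span <- if (any(complete)) max(spans[complete]) else 0L
    subgroup <- "none"
    if (cl$group == "II") {
      dom <- d[[which(complete)[1L]]]
      q <- substr(proteins[[id]], dom$hepta_start + 1L,
                  dom$hepta_start + dom$span)
      subgroup <- assign_subgroup(q, references)$subgroup
    }
    ps <- fs <- FALSE
    if (!is.null(cds) && id %in% names(cds) && !is.na(cds[[id]])) {
      fl <- detect_pseudogene(cds[[id]])
      ps <- fl$premature_stop; fs <- fl$frameshift
    }
    kept <- cl$group != "UNCLASSIFIED" && max_span >= min_domain_span
    data.frame(gene_id = id, n_domains = length(d),
               n_complete = sum(complete),
               zf_classes = paste(vapply(d, `[[`, character(1), "zf_class"),
                                  collapse = ","),
               group = cl$group, subgroup = subgroup, max_span = max_span,
               premature_stop = ps, frameshift = fs,
               pseudogene = ps || fs, kept = kept,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "domains") <- doms
  out
}

#' Split classified records into kept and excluded sets
#'
#' @param classification Data frame from [classify_records()].
#' @return List with elements `kept` and `excluded` (data frames).
#' @export
filter_candidates <- function(classification) {
  list(kept = classification[classification$kept, , drop = FALSE],
       excluded = classification[!classification$kept, , drop = FALSE])
}

#' Zinc-finger spacing report
#'
#' Diagnostic summary of the observed C2H2/C2HC spacings (CXnCXmHXkH/C)
#' per gene. Spacing classes overlap between subgroups, so this is a
#' report, never a classification input.
#'
#' @param classification Data frame from [classify_records()] (with the
#'   `"domains"` attribute).
#' @return Data frame with `gene_id`, `domain_index`, `zf_class`,
#'   `spacing` (e.g. `"CX4CX22HXH"`).
#' @export
zinc_finger_spacing <- function(classification) {
  doms <- attr(classification, "domains")
  rows <- list()
  for (id in names(doms)) {
    for (i in seq_along(doms[[id]])) {
      d <- doms[[id]][[i]]
      if (!d$complete) next
      z <- d$zf_coords
      spacing <- sprintf("CX%dCX%dHX%d%s", z[2] - z[1] - 1L, z[3] - z[2] - 1L,
                         z[4] - z[3] - 1L,
                         if (d$zf_class == "C2H2") "H" else "C")
      rows[[length(rows) + 1L]] <- data.frame(gene_id = id, domain_index = i,
                                              zf_class = d$zf_class,
                                              spacing = spacing,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), domain_index = integer(0),
                      zf_class = character(0), spacing = character(0)))
  do.call(rbind, rows)
}
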
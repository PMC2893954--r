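#' Parse an HGVS-style coding-variant descriptor
#'
#' Accepts simple c. deletions ("c.1413_1426del14", "c.7del"), insertions
#' ("c.79_80insACGT", counts allowed), deletion-insertions
#' ("c.80_83delinsACGT"), and bracketed complex alleles of the form
#' "c.[80_83del4;79_84ins22]", which are normalized to a single
#' replacement of the deleted span by the insertion (the only executable
#' reading of the combined descriptor; the normalization is recorded in
#' the label). Insertions given as a count are stored as N runs.
#'
#' @param text a single c. descriptor.
#' @return a \linkS4class{CodingVariant}.
#' @examples
#' parseCodingVariant("c.1413_1426del14")
#' @export
parseCodingVariant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  body <- sub("^c\\.", "", trimws(text))
  if (grepl("^\\[.*\\]$", body)) {
    parts <- strsplit(sub("^\\[(.*)\\]$", "\\1", body), ";")[[1]]
    parsed <- lapply(parts, parseSimpleVariantPart)
    dels <- Filter(function(p) p$type == "del", parsed)
    inss <- Filter(function(p) p$type == "ins", parsed)
    if (length(dels) != 1L || length(inss) != 1L)
      stop("unsupported complex allele '", text,
           "': expected one deletion and one insertion part")
    return(new("CodingVariant", delStart = dels[[1]]$start,
               delEnd = dels[[1]]$end, insSeq = inss[[1]]$seq,
               label = paste0(text, " (normalized: replace c.",
                              dels[[1]]$start, "_", dels[[1]]$end,
                              " by the insertion)")))
  }
  p <- parseSimpleVariantPart(body)
  if (p$type == "del")
    new("CodingVariant", delStart = p$start, delEnd = p$end, insSeq = "",
        label = text)
  else if (p$type == "ins")
    new("CodingVariant", delStart = p$end, delEnd = p$end - 1L,
        insSeq = p$seq, label = text)
  else
    new("CodingVariant", delStart = p$start, delEnd = p$end, insSeq = p$seq,
        label = text)
}

parseSimpleVariantPart <- function(body) {
  m <- regexec("^([0-9]+)(?:_([0-9]+))?del(?:ins([ACGTN]+|[0-9]+)|([ACGTN]*|[0-9]*))$",
               body)[[1]]
  if (m[1] != -1) {
    g <- regmatches(body, list(regexec(
      "^([0-9]+)(?:_([0-9]+))?del(?:ins([ACGTN]+|[0-9]+)|([ACGTN]*|[0-9]*))$",
      body)[[1]]))[[1]]
    start <- as.integer(g[2])
    end <- if (g[3] == "") start else as.integer(g[3])
    if (end < start) stop("deletion range end before start in '", body, "'")
    suffix <- g[5]
    if (grepl("^[0-9]+$", suffix) && suffix != "") {
      if (as.integer(suffix) != end - start + 1L)
        stop("deletion length ", suffix, " does not match range ",
             start, "_", end)
      suffix <- ""
    }
    if (suffix != "")   # delACGT form: sanity only, bases must match the CDS
      attr(suffix, "deletedBases") <- suffix
    ins <- g[4]
    if (ins != "") {
      if (grepl("^[0-9]+$", ins)) ins <- strrep("N", as.integer(ins))
      return(list(type = "delins", start = start, end = end, seq = ins))
    }
    return(list(type = "del", start = start, end = end, seq = ""))
  }
  m2 <- regmatches(body, regexec("^([0-9]+)_([0-9]+)ins([ACGTN]+|[0-9]+)$",
                                 body))[[1]]
  if (length(m2) == 4L) {
    lo <- as.integer(m2[2]); hi <- as.integer(m2[3])
    seq <- m2[4]
    if (grepl("^[0-9]+$", seq)) seq <- strrep("N", as.integer(seq))
    # insertion goes between lo and hi; for flanking coordinates hi = lo + 1
    return(list(type = "ins", start = lo, end = hi, seq = seq))
  }
  stop("cannot parse variant descriptor '", body, "'")
}

#' Validate a coding sequence
#'
#' A CDS must be over A,C,G,T, have length a multiple of 3, start with
#' ATG and end with a stop codon.
#'
#' @param cds character CDS (or anything coercible via as.character).
#' @return the CDS, invisibly, after validation.
#' @export
validateCodingSequence <- function(cds) {
  cds <- toupper(as.character(cds))
  if (!grepl("^[ACGT]+$", cds)) stop("CDS contains non-ACGT symbols")
  if (nchar(cds) %% 3 != 0) stop("CDS length is not a multiple of 3")
  if (substr(cds, 1, 3) != "ATG") stop("CDS does not start with ATG")
  last <- substr(cds, nchar(cds) - 2, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA"))
    stop("CDS does not end with a stop codon")
  invisible(cds)
}

#' Apply a coding indel to a CDS
#'
#' Deletes the variant's inclusive c. range and inserts its insertion at
#' that position. The output length is |cds| - deleted + inserted.
#'
#' @param cds character CDS.
#' @param variant a \linkS4class{CodingVariant} or c. descriptor string.
#' @return the mutated nucleotide string (not necessarily a valid CDS).
#' @examples
#' applyIndel("ATGAAACTCTTAGGGTAA", "c.7del") # deletes base 7
#' @export
applyIndel <- function(cds, variant) {
  if (is.character(variant)) variant <- parseCodingVariant(variant)
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (variant@delStart > n + 1L ||
      (variant@delEnd >= variant@delStart && variant@delEnd > n))
    stop("variant coordinates c.", variant@delStart, "_", variant@delEnd,
         " outside CDS of length ", n)
  if (grepl("N", variant@insSeq))
    stop("insertion sequence unreported (N placeholders); cannot apply")
  paste0(substr(cds, 1, variant@delStart - 1L), variant@insSeq,
         substr(cds, variant@delEnd + 1L, n))
}

#' Translate a nucleotide string until the first stop codon
#'
#' Standard genetic code; translation starts at position 1 and stops at
#' (and excludes) the first stop codon. A trailing partial codon is
#' ignored.
#'
#' @param nt nucleotide string (A,C,G,T), length >= 3.
#' @return list with \code{protein} (single-letter amino acids) and
#'   \code{stopped} (whether a stop codon was reached).
#' @examples
#' translateToStop("ATGAAACTCTTAGGGTAA") # MKLLG
#' @export
translateToStop <- function(nt) {
  nt <- toupper(as.character(nt))
  if (!grepl("^[ACGT]+$", nt)) stop("sequence contains non-ACGT symbols")
  if (nchar(nt) < 3L) stop("sequence shorter than one codon")
  usable <- 3L * (nchar(nt) %/% 3L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, usable)), no.init.codon = TRUE))
  stopAt <- regexpr("*", aa, fixed = TRUE)
  if (stopAt > 0)
    list(protein = substr(aa, 1, stopAt - 1L), stopped = TRUE)
  else
    list(protein = aa, stopped = FALSE)
}

#' Describe the protein consequence of a coding indel
#'
#' Compares the reference and mutant translations. The anchor is the
#' first diverging residue; for a frameshift the premature stop of the
#' new reading frame is located relative to the anchor and emitted in
#' fsX nomenclature ("p.<ref><pos><alt>fsX<offset>", single-letter amino
#' acids, X for the termination codon). Under the standard counting the
#' stop residue sits at anchor + offset for a retained anchor and at
#' anchor + offset - 1 for a substituted anchor.
#'
#' @param ref,alt translations (lists from \code{\link{translateToStop}}
#'   or plain protein strings, assumed stopped).
#' @param netIndel net nucleotide length change (inserted - deleted); when
#'   given, in-frame variants (net multiple of 3) are classified
#'   "missense-set"/"synonymous-frame" instead of frameshift. When NA,
#'   in-frame re-alignment is inferred from a matching suffix.
#' @return list: kind, refAA, pos, altAA, terOffset, stopPosition,
#'   nomenclature.
#' @export
describeFrameshift <- function(ref, alt, netIndel = NA_integer_) {
  refP <- if (is.list(ref)) ref$protein else as.character(ref)
  altP <- if (is.list(alt)) alt$protein else as.character(alt)
  altStopped <- if (is.list(alt)) isTRUE(alt$stopped) else TRUE
  nr <- nchar(refP); na <- nchar(altP)
  shared <- min(nr, na)
  refV <- strsplit(refP, "")[[1]]; altV <- strsplit(altP, "")[[1]]
  diffAt <- which(refV[seq_len(shared)] != altV[seq_len(shared)])
  d <- if (length(diffAt)) diffAt[1] else shared + 1L
  if (d > shared && nr == na)
    stop("proteins are identical: not a frameshift")
  inFrame <- if (!is.na(netIndel)) {
    netIndel %% 3L == 0L
  } else {
    # heuristic: common prefix + common suffix cover the shorter protein
    suffLen <- 0L
    while (suffLen < shared - (d - 1L) &&
           refV[nr - suffLen] == altV[na - suffLen]) suffLen <- suffLen + 1L
    (d - 1L) + suffLen >= shared
  }
  if (inFrame) {
    kind <- if (nr == na && length(diffAt)) "missense-set"
            else "synonymous-frame"
    return(list(kind = kind, refAA = NA_character_, pos = NA_integer_,
                altAA = NA_character_, terOffset = NA_integer_,
                stopPosition = NA_integer_, nomenclature = NA_character_))
  }
  if (!altStopped || d > nr)
    return(list(kind = "stop-loss", refAA = NA_character_,
                pos = NA_integer_, altAA = NA_character_,
                terOffset = NA_integer_, stopPosition = NA_integer_,
                nomenclature = NA_character_))
  refAA <- refV[d]
  if (d > na) {
    # the new frame stops right at the anchor: plain nonsense notation
    return(list(kind = "frameshift", refAA = refAA, pos = d, altAA = "X",
                terOffset = 0L, stopPosition = d,
                nomenclature = sprintf("p.%s%dX", refAA, d)))
  }
  altAA <- altV[d]
  stopPos <- na + 1L              # stop codon residue index in the mutant
  terOffset <- stopPos - d + 1L   # substituted-anchor convention
  list(kind = "frameshift", refAA = refAA, pos = d, altAA = altAA,
       terOffset = terOffset, stopPosition = stopPos,
       nomenclature = sprintf("p.%s%d%sfsX%d", refAA, d, altAA, terOffset))
}

#' Stop-codon residue position from fsX nomenclature
#'
#' Parses "p.<ref><pos><alt>fsX<offset>" and returns the absolute residue
#' position of the premature termination codon: pos + offset for a
#' retained anchor (ref == alt), pos + offset - 1 for a substituted
#' anchor. Plain nonsense notation "p.<ref><pos>X" returns pos. Some
#' published descriptions count substituted anchors as pos + offset; a
#' warning flags that the standard convention is applied.
#'
#' @param nomenclature a single p. string.
#' @return integer residue position of the stop codon.
#' @examples
#' stopPositionFromFs("p.L471LfsX56") # 527
#' @export
stopPositionFromFs <- function(nomenclature) {
  stopifnot(is.character(nomenclature), length(nomenclature) == 1L)
  m <- regmatches(nomenclature,
                  regexec("^p\\.([A-Z])([0-9]+)([A-Z])fsX([0-9]+)$",
                          nomenclature))[[1]]
  if (length(m) == 5L) {
    pos <- as.integer(m[3]); k <- as.integer(m[5])
    if (m[2] == m[4]) return(pos + k)
    warning("substituted-anchor frameshift: standard counting places the ",
            "stop at pos + offset - 1; some published usages count ",
            "pos + offset")
    return(pos + k - 1L)
  }
  m2 <- regmatches(nomenclature,
                   regexec("^p\\.([A-Z])([0-9]+)X$", nomenclature))[[1]]
  if (length(m2) == 3L) return(as.integer(m2[3]))
  stop("malformed frameshift nomenclature: '", nomenclature, "'")
}

#' Full consequence of a coding variant
#'
#' Validates the CDS, applies the indel, translates reference and mutant,
#' and describes the protein consequence with the exact net length change
#' of the variant.
#'
#' @param cds character CDS.
#' @param variant a \linkS4class{CodingVariant} or c. descriptor string.
#' @return list: variant label, mutant sequence, ref/alt translations and
#'   the consequence from \code{\link{describeFrameshift}}.
#' @export
variantConsequence <- function(cds, variant) {
  if (is.character(variant)) variant <- parseCodingVariant(variant)
  cds <- validateCodingSequence(cds)
  mut <- applyIndel(cds, variant)
  delLen <- max(0L, variant@delEnd - variant@delStart + 1L)
  net <- nchar(variant@insSeq) - delLen
  ref <- translateToStop(cds)
  alt <- translateToStop(mut)
  cons <- describeFrameshift(ref, alt, netIndel = net)
  list(variant = variant@label, mutant = mut, ref = ref, alt = alt,
       consequence = cons)
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readCdsFasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), names(s))
}
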
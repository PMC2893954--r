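# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force dual-trigger validation rule, transcribed literally.
bruteValidated <- function(z1, z2, strong = 2, weak = 1.5) {
  sameDir <- sign(z1) == sign(z2) & sign(z1) != 0
  oneStrong <- (abs(z1) > strong & abs(z2) > weak) |
               (abs(z2) > strong & abs(z1) > weak)
  sameDir & oneStrong
}

# Pooled-variance two-sample t-test p-value from first principles.
tTestOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Exhaustive hypergeometric upper tail by enumerating all size-n draws.
hyperEnumOracle <- function(k, n, K, N) {
  draws <- combn(N, n)
  inCat <- colSums(draws <= K)  # category = elements 1..K
  mean(inCat >= k)
}

# Random valid CDS with nCodons internal (non-stop) codons.
randomCds <- function(nCodons) {
  bases <- c("A", "C", "G", "T")
  codons <- character(nCodons)
  for (i in seq_len(nCodons)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

# Codon-by-codon translation oracle via seqinr (independent of Biostrings).
translateOracle <- function(nt) {
  usable <- 3 * (nchar(nt) %/% 3)
  aa <- seqinr::translate(strsplit(substr(nt, 1, usable), "")[[1]])
  stopAt <- match("*", aa)
  if (!is.na(stopAt)) list(protein = paste(aa[seq_len(stopAt - 1)],
                                           collapse = ""), stopped = TRUE)
  else list(protein = paste(aa, collapse = ""), stopped = FALSE)
}

# Small readout on the default layout with given sample-well values.
toyReadout <- function(values, plate = "p1", replicate = 1L) {
  layout <- defaultControlLayout(plate)
  wells <- wellsWithRole(layout, "sample")[seq_along(values)]
  PlateReadout(layout, setNames(values, wells), replicateId = replicate)
}
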
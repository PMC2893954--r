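#' Exact upper-tail hypergeometric p-value
#'
#' P(X >= k) where X is the number of category members among n draws
#' without replacement from a universe of N genes of which K are in the
#' category. Computed in log space via \code{stats::phyper} for numerical
#' stability at large N.
#'
#' @param k observed hits in the category.
#' @param n number of hits drawn.
#' @param K category size in the universe.
#' @param N universe size.
#' @return upper-tail probability.
#' @examples
#' hypergeometricP(3, 4, 3, 10) # 7/210
#' @export
hypergeometricP <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > n || n > N || K > N || k > K)
    stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Category fold enrichment with hypergeometric test
#'
#' Fold enrichment of a category among a hit list relative to a stated
#' background universe: (k/n) / (K/N). The universe is a required
#' explicit input; annotated genes outside it are rejected.
#'
#' @param hits character vector of hit gene ids (must lie in the universe).
#' @param annotation data.frame with columns \code{gene_id},
#'   \code{category}.
#' @param category category label to test.
#' @param universe character vector: the background gene universe.
#' @return list: category, k, n, K, N, fold, p_hyper.
#' @export
foldEnrichment <- function(hits, annotation, category, universe) {
  stopifnot(all(c("gene_id", "category") %in% names(annotation)))
  outside <- setdiff(annotation$gene_id, universe)
  if (length(outside))
    stop("annotated gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  if (!all(hits %in% universe))
    stop("hit gene(s) outside the universe")
  hits <- unique(hits); universe <- unique(universe)
  inCat <- unique(annotation$gene_id[annotation$category == category])
  k <- length(intersect(hits, inCat)); n <- length(hits)
  K <- length(inCat); N <- length(universe)
  if (n == 0 || K == 0)
    stop("fold enrichment undefined: empty hit list or empty category")
  list(category = category, k = k, n = n, K = K, N = N,
       fold = (k / n) / (K / N), p_hyper = hypergeometricP(k, n, K, N))
}

#' Enrichment table over all categories
#'
#' Runs \code{\link{foldEnrichment}} for every category in the annotation
#' and adjusts p-values across categories by Benjamini-Hochberg (the
#' adjustment can be switched off).
#'
#' @inheritParams foldEnrichment
#' @param adjust apply BH correction across categories.
#' @return data.frame: category, k, n, K, N, fold, p_hyper (and p_adj),
#'   sorted by p.
#' @export
enrichmentTable <- function(hits, annotation, universe, adjust = TRUE) {
  cats <- unique(annotation$category)
  out <- do.call(rbind, lapply(cats, function(cc) {
    as.data.frame(foldEnrichment(hits, annotation, cc, universe),
                  stringsAsFactors = FALSE)
  }))
  if (adjust) out$p_adj <- stats::p.adjust(out$p_hyper, method = "BH")
  out[order(out$p_hyper), , drop = FALSE]
}

#' Read a gene-to-category annotation TSV
#'
#' @param path TSV with columns gene_id, category.
#' @return data.frame.
#' @export
readAnnotationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("gene_id", "category") %in% names(tab)))
    stop("annotation table needs columns gene_id, category")
  tab
}
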
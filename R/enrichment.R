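# GO-term over-representation with Benjamini-Hochberg FDR control.
#
# Annotations are flat gene -> term sets (no ontology propagation); the
# universe is every annotated gene, standing in for "the genome". The test
# is the one-sided hypergeometric over-representation test (equivalent to a
# one-sided Fisher exact test), the de facto standard behind GO tools.

#' Build an annotation set from a gene-to-term table
#'
#' @param annotations data.frame with columns `gene` and `term` (one pair
#'   per row), or a path to a two-column tab-separated file with those
#'   columns.
#' @return An `annotation_set`: list with `gene_to_terms`, `term_to_genes`
#'   (named lists of character vectors) and `universe` (all annotated
#'   genes).
#' @export
annotation_set <- function(annotations) {
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  }
  check_that(is.data.frame(annotations) &&
               all(c("gene", "term") %in% names(annotations)),
             "`annotations` must have columns `gene` and `term`")
  check_that(nrow(annotations) > 0L, "annotation table is empty")
  annotations <- unique(annotations[c("gene", "term")])
  structure(
    list(gene_to_terms = split(annotations$term, annotations$gene),
         term_to_genes = split(annotations$gene, annotations$term),
         universe = sort(unique(annotations$gene))),
    class = "annotation_set"
  )
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` genes of which `K` carry the term.
#' Computed through [stats::phyper()], which works in log space and is
#' stable for genome-scale `N`.
#'
#' @param k observed hits in the candidate list.
#' @param K genes in the universe carrying the term.
#' @param n candidate list size.
#' @param N universe size.
#' @return Probability in `(0, 1]`.
#' @export
#' @examples
#' hypergeometric_upper_tail(2, 5, 2, 10)  # 10/45
hypergeometric_upper_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    check_that(is_count(v), "all arguments must be nonnegative counts")
  }
  check_that(K <= N && n <= N, "K and n must not exceed N")
  check_that(k <= min(n, K), "k must not exceed min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns `q_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1, in the input
#' order. Order-preserving: a smaller p never gets a larger q. The
#' adjustment is not idempotent -- re-applying it to already-adjusted values
#' changes them -- so apply it once per test family.
#'
#' @param p_values numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
benjamini_hochberg <- function(p_values) {
  check_that(is.numeric(p_values) && length(p_values) >= 1L,
             "`p_values` must be a non-empty numeric vector")
  check_that(!anyNA(p_values) && all(p_values > 0) && all(p_values <= 1),
             "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' GO-term over-representation of a candidate gene list
#'
#' Tests every term with at least one candidate hit; the BH family is this
#' set of tested terms, which fixes the adjustment deterministically. All
#' tested terms are returned, sorted by q then p, with `reported` flagging
#' those at `q <= q_threshold`. (The convention is the usual one: terms at
#' or below the FDR threshold are the reported set.) Candidates outside the
#' annotation universe are dropped with a warning.
#'
#' @param candidates character vector of candidate gene IDs.
#' @param annotations an [annotation_set()] (or anything it accepts).
#' @param q_threshold FDR threshold in `(0, 1]` for the `reported` flag.
#' @return data.frame with columns `term_id`, `k` (candidate hits), `n`
#'   (candidate list size in universe), `K` (universe hits), `N` (universe
#'   size), `p_value`, `q_value`, `reported`.
#' @export
enrich <- function(candidates, annotations, q_threshold = 0.05) {
  if (!inherits(annotations, "annotation_set")) {
    annotations <- annotation_set(annotations)
  }
  check_that(is_scalar_number(q_threshold) && q_threshold > 0 && q_threshold <= 1,
             "`q_threshold` must lie in (0, 1]")
  check_that(is.character(candidates) && length(candidates) >= 1L,
             "`candidates` must be a non-empty character vector")
  candidates <- unique(candidates)
  outside <- setdiff(candidates, annotations$universe)
  if (length(outside) > 0) {
    warning(length(outside), " candidate gene(s) outside the annotation ",
            "universe were dropped: ",
            paste(utils::head(outside, 5), collapse = ", "),
            if (length(outside) > 5) ", ..." else "", call. = FALSE)
    candidates <- setdiff(candidates, outside)
  }
  check_that(length(candidates) > 0L,
             "no candidate genes remain inside the annotation universe")

  N <- length(annotations$universe)
  n <- length(candidates)
  hit_terms <- sort(unique(unlist(annotations$gene_to_terms[candidates],
                                  use.names = FALSE)))
  k <- vapply(annotations$term_to_genes[hit_terms],
              function(g) length(intersect(g, candidates)), integer(1))
  K <- lengths(annotations$term_to_genes[hit_terms])
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- benjamini_hochberg(p)
  out <- data.frame(term_id = hit_terms, k = k, n = n, K = as.integer(K),
                    N = N, p_value = p, q_value = q,
                    reported = q <= q_threshold, stringsAsFactors = FALSE)
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
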
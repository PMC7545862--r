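## Gene-list over-representation: hypergeometric upper tail with Bonferroni
## correction and Benjamini-Hochberg FDR, the statistic behind web gene-list
## enrichment services.

#' Read a gene-set (GMT) file
#'
#' One term per line: `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to a GMT file.
#' @param background optional background gene universe; defaults to the
#'   union of all term genes.
#' @return a list with `terms` (named list term_id -> gene vector),
#'   `names` (term_id -> term name) and `background`.
#' @export
readGmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("parse error at line ", short[1L],
         ": a GMT line needs term id, name and at least one gene",
         call. = FALSE)
  }
  ids <- vapply(fields, `[`, character(1), 1L)
  termMap(terms = stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                                  ids),
          names = stats::setNames(vapply(fields, `[`, character(1), 2L), ids),
          background = background)
}

#' Construct a term map for enrichment testing
#'
#' @param terms named list mapping term ids to gene-id vectors.
#' @param names optional named character vector of term display names.
#' @param background optional background universe; defaults to the union of
#'   all term genes. Every term's gene set must be contained in it.
#' @return a `termMap` list (`terms`, `names`, `background`).
#' @export
termMap <- function(terms, names = NULL, background = NULL) {
  if (length(terms) == 0L) stop("empty term map", call. = FALSE)
  if (is.null(background)) {
    background <- unique(unlist(terms, use.names = FALSE))
  }
  outside <- setdiff(unique(unlist(terms, use.names = FALSE)), background)
  if (length(outside)) {
    stop("term gene(s) outside the background: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  if (is.null(names)) {
    names <- stats::setNames(base::names(terms), base::names(terms))
  }
  structure(list(terms = terms, names = names, background = background),
            class = "termMap")
}

#' Hypergeometric gene-set over-representation test
#'
#' For each term with `K` genes in a background of `N`, and a query of `n`
#' genes overlapping the term in `k`, the enrichment p-value is the
#' hypergeometric upper tail
#' `p = sum_{i = k..min(n, K)} C(K, i) C(N - K, n - i) / C(N, n)`
#' (via [stats::phyper()]). Bonferroni correction multiplies by the number
#' of tested terms (capped at 1); FDR q-values are Benjamini-Hochberg over
#' all tested terms. Results are sorted by p ascending, ties broken by term
#' id. Query genes outside the background are dropped with a warning.
#'
#' @param query character vector of query gene ids.
#' @param terms a [termMap()] (or the result of [readGmt()]).
#' @param alpha significance level for the `significant` flag, applied to
#'   the FDR q-value.
#' @return data.frame with `term_id`, `term_name`, `k`, `n`, `K`, `N`, `p`,
#'   `p_bonferroni`, `q_fdr`, `significant`.
#' @seealso [significantTerms()]
#' @examples
#' tm <- termMap(list(t1 = c("a", "b", "c"), t2 = c("d", "e")),
#'               background = letters[1:10])
#' enrich(c("a", "b", "d"), tm)
#' @export
enrich <- function(query, terms, alpha = 0.05) {
  if (!inherits(terms, "termMap")) {
    stop("'terms' must be a termMap", call. = FALSE)
  }
  query <- unique(query)
  if (length(query) == 0L) stop("empty query gene list", call. = FALSE)
  outside <- setdiff(query, terms$background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped")
    query <- intersect(query, terms$background)
    if (length(query) == 0L) {
      stop("no query genes left inside the background", call. = FALSE)
    }
  }
  N <- length(terms$background)
  n <- length(query)
  K <- lengths(terms$terms)
  k <- vapply(terms$terms, function(g) length(intersect(query, g)),
              integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  m <- length(terms$terms)
  res <- data.frame(term_id = names(terms$terms),
                    term_name = unname(terms$names[names(terms$terms)]),
                    k = unname(k), n = n, K = unname(K), N = N,
                    p = unname(p),
                    p_bonferroni = pmin(1, unname(p) * m),
                    stringsAsFactors = FALSE)
  res$q_fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res$significant <- res$q_fdr < alpha
  res
}

#' Significant terms at an FDR threshold
#'
#' @param results data.frame from [enrich()].
#' @param alpha FDR significance level in (0, 1\]; q-values are in \[0, 1\]
#'   so `alpha = 1` returns every result with `q_fdr < 1`.
#' @return the rows with `q_fdr < alpha`, preserving sort order.
#' @export
significantTerms <- function(results, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  results[results$q_fdr < alpha, , drop = FALSE]
}
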
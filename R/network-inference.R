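#' Critical Pearson correlation at a given sample size
#'
#' Two-tailed critical |r| for testing a Pearson correlation against zero:
#' `r_crit = t / sqrt(t^2 + n - 2)` with `t` the `1 - alpha/2` quantile of
#' the t distribution at `n - 2` degrees of freedom. An observed |r| at or
#' above this value is significant at level `alpha`. Edges of the
#' co-occurrence network are exactly the pairs clearing this bound at the
#' class sample size.
#'
#' @param n Sample size(s), `n >= 4`; vectorized.
#' @param alpha Two-sided significance level in (0, 1); default 0.05.
#' @return Critical |r| value(s) in (0, 1).
#' @examples
#' critical_r(5)    # 0.878, the df = 3 table value
#' critical_r(158)  # about 0.156
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(!is.finite(alpha) | alpha <= 0 | alpha >= 1)) {
    stop("alpha must be in (0, 1)")
  }
  if (any(!is.finite(n) | n < 4)) {
    stop("critical_r() requires sample sizes n >= 4")
  }
  tq <- stats::qt(1 - alpha / 2, df = n - 2)
  tq / sqrt(tq^2 + n - 2)
}

#' Pairwise Pearson correlation matrix with per-pair sample sizes
#'
#' Computes the taxon x taxon Pearson correlation matrix over
#' pairwise-complete observations, recording for every pair the number of
#' complete observations `n_eff` and the corresponding critical threshold
#' [critical_r()]. Pairs with fewer than `min_n` complete observations are
#' dropped (set to missing) and reported.
#'
#' @param x Autoscaled (or raw; Pearson r is scale-invariant) samples x
#'   taxa numeric matrix, or a [biomass_matrix()]. Missing values allowed.
#' @param alpha Significance level used for the critical threshold.
#' @param min_n Minimum complete observations per pair; default 4.
#' @return Object of class `correlation_result`: list with `taxa`, `r`
#'   (symmetric, unit diagonal), `n_eff`, `alpha`, `r_crit`, and
#'   `dropped_pairs` (data frame, possibly empty).
#' @export
pearson_matrix <- function(x, alpha = 0.05, min_n = 4) {
  x <- biomass_values(x)
  if (ncol(x) < 2L) stop("need at least two taxa")
  taxa <- colnames(x) %||% sprintf("taxon_%02d", seq_len(ncol(x)))
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  r[r > 1] <- 1
  r[r < -1] <- -1
  n_eff <- crossprod(!is.na(x))
  dropped <- which(upper.tri(n_eff) & n_eff < min_n, arr.ind = TRUE)
  dropped_pairs <- data.frame(
    taxon_a = taxa[dropped[, 1L]], taxon_b = taxa[dropped[, 2L]],
    n_eff = n_eff[dropped], stringsAsFactors = FALSE)
  if (nrow(dropped_pairs) > 0) {
    warning(nrow(dropped_pairs),
            " taxon pair(s) dropped with fewer than ", min_n,
            " complete observations")
    r[n_eff < min_n] <- NA_real_
  }
  r_crit <- matrix(NA_real_, ncol(x), ncol(x), dimnames = dimnames(n_eff))
  ok <- n_eff >= max(4, min_n)
  r_crit[ok] <- critical_r(n_eff[ok], alpha)
  diag(r) <- 1
  diag(r_crit) <- NA_real_
  dimnames(r) <- list(taxa, taxa)
  structure(list(taxa = taxa, r = r, n_eff = n_eff, alpha = alpha,
                 r_crit = r_crit, dropped_pairs = dropped_pairs),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d taxa, alpha = %g, n_eff %d-%d\n",
              length(x$taxa), x$alpha,
              min(x$n_eff[upper.tri(x$n_eff)]),
              max(x$n_eff[upper.tri(x$n_eff)])))
  invisible(x)
}

#' Construct a signed co-occurrence network
#'
#' An undirected graph whose nodes are taxa and whose edges carry the
#' Pearson correlation `r`, its sign (`"pos"`/`"neg"`), and weight `|r|`.
#' Usually produced by [threshold_network()]; this constructor builds one
#' directly from an edge table (e.g. for toy graphs or file import).
#'
#' @param edges Data frame with columns `source`, `target` and optionally
#'   `r` (default 1, i.e. a purely topological graph).
#' @param nodes Optional character vector of node names (to include
#'   isolated nodes); defaults to the nodes appearing in `edges`.
#' @param alpha Significance level recorded on the network, if any.
#' @return Object of class `signed_network` wrapping an igraph graph.
#' @export
signed_network <- function(edges, nodes = NULL, alpha = NA_real_) {
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target") %in% names(edges)))
    if (!"r" %in% names(edges)) edges$r <- 1
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    key <- paste(pmin(edges$source, edges$target),
                 pmax(edges$source, edges$target), sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges are not allowed")
    edges$sign <- ifelse(edges$r < 0, "neg", "pos")
    edges$weight <- abs(edges$r)
  } else {
    edges <- data.frame(source = character(0), target = character(0),
                        r = numeric(0), sign = character(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  nodes <- nodes %||% sort(unique(c(edges$source, edges$target)))
  g <- igraph::graph_from_data_frame(
    edges[c("source", "target", "r", "sign", "weight")],
    directed = FALSE, vertices = data.frame(name = nodes))
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  structure(list(graph = g, alpha = alpha), class = "signed_network")
}

#' Coerce a signed network (or igraph) to an igraph graph
#' @param net A `signed_network` or igraph object.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  if (inherits(net, "signed_network")) return(net$graph)
  if (inherits(net, "igraph")) return(net)
  stop("cannot coerce ", paste(class(net), collapse = "/"), " to igraph")
}

#' Wrap an igraph graph as a signed network
#'
#' Fills in missing `r`/`sign`/`weight` edge attributes (defaulting to
#' r = 1) and the per-node `isolated` flag.
#'
#' @param g An undirected igraph graph.
#' @param alpha Optional significance level to record.
#' @return A [signed_network()].
#' @export
as_signed_network <- function(g, alpha = NA_real_) {
  stopifnot(inherits(g, "igraph"))
  if (igraph::is_directed(g)) stop("signed networks are undirected")
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("n%02d", seq_len(igraph::vcount(g)))
  }
  if (is.null(igraph::E(g)$r)) igraph::E(g)$r <- 1
  igraph::E(g)$sign <- ifelse(igraph::E(g)$r < 0, "neg", "pos")
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  structure(list(graph = g, alpha = alpha), class = "signed_network")
}

#' Edge table of a signed network
#'
#' @param net A [signed_network()].
#' @return Data frame with columns source, target, r, sign, weight (one
#'   row per undirected edge; header-only when the network has no edges).
#' @export
network_edges <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      r = numeric(0), sign = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  ends <- igraph::ends(g, igraph::E(g))
  data.frame(source = ends[, 1L], target = ends[, 2L],
             r = igraph::E(g)$r, sign = igraph::E(g)$sign,
             weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
}

#' @export
print.signed_network <- function(x, ...) {
  g <- x$graph
  e <- network_edges(x)
  cat(sprintf("<signed_network> %d taxa, %d edges (%d pos, %d neg), %d isolated\n",
              igraph::vcount(g), igraph::ecount(g),
              sum(e$sign == "pos"), sum(e$sign == "neg"),
              sum(igraph::V(g)$isolated)))
  invisible(x)
}

#' Threshold a correlation matrix into a signed network
#'
#' Keeps the taxon pairs whose correlation is significant at the recorded
#' level: with `correction = "none"`, pair (i, j) becomes an edge iff
#' `|r_ij| >= r_crit(n_eff_ij, alpha)` (the critical-|r| rule at the class
#' sample size); with `correction = "benjamini_hochberg"` the per-pair
#' two-sided p-values are BH-adjusted first and edges are pairs with
#' adjusted p <= alpha. Isolated taxa are kept in the node set and flagged.
#'
#' @param cr A [pearson_matrix()] result.
#' @param correction `"none"` (default) or `"benjamini_hochberg"`.
#' @return A [signed_network()].
#' @export
threshold_network <- function(cr, correction = c("none", "benjamini_hochberg")) {
  stopifnot(inherits(cr, "correlation_result"))
  correction <- match.arg(correction)
  r <- cr$r
  p <- length(cr$taxa)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[upper.tri(r)]
  rc <- cr$r_crit[upper.tri(r)]
  nv <- cr$n_eff[upper.tri(r)]
  usable <- !is.na(rv) & !is.na(rc)
  if (correction == "none") {
    keep <- usable & abs(rv) >= rc
  } else {
    pv <- rep(NA_real_, length(rv))
    df <- nv[usable] - 2
    rr <- pmin(abs(rv[usable]), 1)
    tt <- ifelse(rr >= 1, Inf, rr * sqrt(df / (1 - rr^2)))
    pv[usable] <- 2 * stats::pt(tt, df, lower.tail = FALSE)
    padj <- rep(NA_real_, length(rv))
    padj[usable] <- stats::p.adjust(pv[usable], method = "BH")
    keep <- usable & padj <= cr$alpha
  }
  edges <- data.frame(source = cr$taxa[ut[keep, 1L]],
                      target = cr$taxa[ut[keep, 2L]],
                      r = rv[keep], stringsAsFactors = FALSE)
  net <- signed_network(edges, nodes = cr$taxa, alpha = cr$alpha)
  net$correction <- correction
  net
}
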
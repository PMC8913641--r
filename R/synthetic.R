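#' Specification for a synthetic community biomass dataset
#'
#' Parameterizes the Gaussian-copula generator: a latent multivariate
#' normal with planted correlation structure — positively correlated
#' feeding-guild blocks, negatively correlated predator-prey (antagonist)
#' pairs, background correlation elsewhere — pushed through lognormal
#' marginals to right-skewed biomass, with optional missing-at-random
#' detection zeros.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_samples Number of sampling events (>= 4).
#' @param guilds List of integer vectors (taxon indices); every pair
#'   within a guild gets latent correlation `rho_within`.
#' @param rho_within Planted within-guild correlation in [0, 1).
#' @param antagonist_pairs List of length-2 integer vectors; each pair
#'   gets latent correlation `rho_neg`.
#' @param rho_neg Planted antagonist correlation in (-1, 0].
#' @param background_rho Latent correlation for all remaining pairs
#'   (default 0).
#' @param marginal_logmean Per-taxon log-scale mean(s) of biomass
#'   (recycled to `n_taxa`).
#' @param marginal_logsd Per-taxon log-scale sd(s), positive (recycled).
#' @param zero_inflation Probability in [0, 1) that any cell is set to 0.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the spec.
#' @param taxa Optional taxon names (default `taxon_01`, ...).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_taxa, n_samples, guilds = list(),
                           rho_within = 0.6, antagonist_pairs = list(),
                           rho_neg = -0.55, background_rho = 0,
                           marginal_logmean = 0, marginal_logsd = 0.6,
                           zero_inflation = 0, seed = 1, taxa = NULL) {
  n_taxa <- as.integer(n_taxa)
  n_samples <- as.integer(n_samples)
  stopifnot(n_taxa >= 2, n_samples >= 4,
            rho_within >= 0, rho_within < 1,
            rho_neg > -1, rho_neg <= 0,
            background_rho > -1, background_rho < 1,
            zero_inflation >= 0, zero_inflation < 1,
            all(marginal_logsd >= 0))
  guilds <- lapply(guilds, as.integer)
  antagonist_pairs <- lapply(antagonist_pairs, as.integer)
  idx <- unlist(c(guilds, antagonist_pairs))
  if (length(idx) > 0 && (min(idx) < 1 || max(idx) > n_taxa)) {
    stop("guild/antagonist taxon indices must be in 1..n_taxa")
  }
  if (any(vapply(antagonist_pairs, length, 1L) != 2L)) {
    stop("antagonist_pairs must be pairs of taxon indices")
  }
  spec <- structure(list(
    n_taxa = n_taxa, n_samples = n_samples, guilds = guilds,
    rho_within = rho_within, antagonist_pairs = antagonist_pairs,
    rho_neg = rho_neg, background_rho = background_rho,
    marginal_logmean = rep_len(marginal_logmean, n_taxa),
    marginal_logsd = rep_len(marginal_logsd, n_taxa),
    zero_inflation = zero_inflation, seed = as.integer(seed),
    taxa = taxa %||% sprintf("taxon_%02d", seq_len(n_taxa))),
    class = "synthetic_spec")
  # fail early on conflicting pair assignments
  invisible(build_target_correlation(spec, quiet = TRUE))
  spec
}

#' Planted latent correlation matrix of a synthetic spec
#'
#' Builds the taxon x taxon correlation matrix the generator draws from:
#' `rho_within` inside guilds, `rho_neg` on antagonist pairs,
#' `background_rho` elsewhere, unit diagonal. If the planted matrix is
#' not positive semi-definite it is repaired by clipping negative
#' eigenvalues at zero and re-normalizing to unit diagonal; the repair is
#' reported via a warning and the attributes `repaired` / `max_drift`
#' (largest absolute entry change).
#'
#' @param spec A [synthetic_spec()].
#' @param quiet Suppress the repair warning (internal use).
#' @return Symmetric numeric matrix with attributes `repaired` and
#'   `max_drift`.
#' @export
build_target_correlation <- function(spec, quiet = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  p <- spec$n_taxa
  cmat <- matrix(spec$background_rho, p, p,
                 dimnames = list(spec$taxa, spec$taxa))
  assigned <- matrix(FALSE, p, p)
  set_pair <- function(i, j, val, what) {
    if (assigned[i, j] && cmat[i, j] != val) {
      stop(sprintf(
        "conflicting correlation for pair (%s, %s): guild and %s assignment overlap",
        spec$taxa[min(i, j)], spec$taxa[max(i, j)], what))
    }
    cmat[i, j] <<- val; cmat[j, i] <<- val
    assigned[i, j] <<- TRUE; assigned[j, i] <<- TRUE
  }
  for (g in spec$guilds) {
    for (a in seq_along(g)) for (b in seq_len(a - 1L)) {
      set_pair(g[a], g[b], spec$rho_within, "guild")
    }
  }
  for (pr in spec$antagonist_pairs) {
    if (pr[1] == pr[2]) stop("antagonist pair with identical taxa: ", pr[1])
    set_pair(pr[1], pr[2], spec$rho_neg, "antagonist")
  }
  diag(cmat) <- 1
  eig <- eigen(cmat, symmetric = TRUE)
  repaired <- FALSE
  max_drift <- 0
  if (min(eig$values) < -1e-10) {
    ev <- pmax(eig$values, 0)
    fixed <- eig$vectors %*% (ev * t(eig$vectors))
    d <- sqrt(diag(fixed))
    fixed <- fixed / tcrossprod(d)
    diag(fixed) <- 1
    max_drift <- max(abs(fixed - cmat))
    cmat <- fixed
    dimnames(cmat) <- list(spec$taxa, spec$taxa)
    repaired <- TRUE
    if (!quiet) {
      warning(sprintf(
        "planted correlation matrix was not PSD; repaired by eigenvalue clipping (max entry drift %.4g)",
        max_drift))
    }
  }
  structure(cmat, repaired = repaired, max_drift = max_drift)
}

#' Planted edge list of a synthetic spec
#'
#' The taxon pairs the generator plants a nonzero correlation on (guild
#' pairs and antagonist pairs), with the planted value — the ground truth
#' against which network recovery is scored.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `taxon_a`, `taxon_b`, `rho`.
#' @export
planted_edges <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  for (g in spec$guilds) {
    for (a in seq_along(g)) for (b in seq_len(a - 1L)) {
      i <- min(g[a], g[b]); j <- max(g[a], g[b])
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_a = spec$taxa[i], taxon_b = spec$taxa[j],
        rho = spec$rho_within, stringsAsFactors = FALSE)
    }
  }
  for (pr in spec$antagonist_pairs) {
    i <- min(pr); j <- max(pr)
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_a = spec$taxa[i], taxon_b = spec$taxa[j],
      rho = spec$rho_neg, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      rho = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generate a synthetic community biomass dataset
#'
#' Draws `n_samples` latent vectors from a zero-mean multivariate normal
#' with the planted (PSD-repaired) correlation matrix, maps coordinate
#' `i` through `exp(logmean_i + logsd_i * z)` to a positive lognormal
#' biomass, then zeroes each cell independently with probability
#' `zero_inflation`. Deterministic given the spec (including its seed).
#'
#' @param spec A [synthetic_spec()].
#' @return A [biomass_matrix()] of shape `n_samples` x `n_taxa`, with the
#'   spec and its planted edge list attached as attributes `spec` and
#'   `planted`.
#' @export
generate_biomass <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cmat <- build_target_correlation(spec) # repair, if any, surfaces as warning
  eig <- eigen(cmat, symmetric = TRUE)
  sq <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * t(eig$vectors))
  n <- spec$n_samples
  p <- spec$n_taxa
  vals <- withr::with_seed(spec$seed, {
    z <- matrix(stats::rnorm(n * p), n, p) %*% sq
    b <- exp(sweep(sweep(z, 2L, spec$marginal_logsd, "*"),
                   2L, spec$marginal_logmean, "+"))
    if (spec$zero_inflation > 0) {
      b[matrix(stats::runif(n * p) < spec$zero_inflation, n, p)] <- 0
    }
    b
  })
  colnames(vals) <- spec$taxa
  m <- biomass_matrix(vals)
  attr(m, "spec") <- spec
  attr(m, "planted") <- planted_edges(spec)
  m
}

# deterministic class specs for the three-class study fixture
.study_specs <- function(seed) {
  seed <- as.integer(seed)
  child <- function(k) (abs(seed) * 97L + k) %% 2147483647L
  list(
    HT = synthetic_spec(
      n_taxa = 27, n_samples = 158,
      guilds = list(1:9, 10:17, 18:23),
      antagonist_pairs = list(c(1, 10), c(2, 18), c(3, 24), c(10, 18),
                              c(11, 24), c(19, 25), c(4, 26), c(12, 27)),
      marginal_logmean = seq(-3, 0, length.out = 27),
      zero_inflation = 0.05, seed = child(1L)),
    MT = synthetic_spec(
      n_taxa = 28, n_samples = 180,
      guilds = list(1:6, 7:11, 12:16),
      antagonist_pairs = list(c(1, 7), c(2, 12), c(7, 17), c(12, 18),
                              c(3, 19)),
      marginal_logmean = seq(-3, 0, length.out = 28),
      zero_inflation = 0.05, seed = child(2L)),
    LT = synthetic_spec(
      n_taxa = 22, n_samples = 136,
      guilds = list(1:6, 7:11, 12:15),
      antagonist_pairs = list(c(1, 7), c(2, 12), c(7, 16), c(3, 17)),
      marginal_logmean = seq(-3, 0, length.out = 22),
      zero_inflation = 0.05, seed = child(3L)))
}

#' Three-class synthetic study fixture
#'
#' Generates the three turbidity-class biomass datasets with the study's
#' shapes — HT 158 samples x 27 taxa, MT 180 x 28, LT 136 x 22 — and a
#' planted interaction density ordered MT < LT < HT, mirroring the
#' observed ordering of network density along the turbidity gradient.
#' Each dataset carries class metadata (class label and its mean
#' turbidity: HT 31.8, MT 18.7, LT 12.6 NTU) and its planted edge list.
#'
#' @param seed Integer seed; child seeds per class are derived
#'   deterministically.
#' @return Named list `HT`, `MT`, `LT` of [biomass_matrix()] objects.
#' @examples
#' fx <- make_study_fixture(seed = 0)
#' dim(fx$HT)
#' @export
make_study_fixture <- function(seed = 0) {
  specs <- .study_specs(seed)
  ntu <- c(HT = 31.8, MT = 18.7, LT = 12.6)
  out <- lapply(names(specs), function(k) {
    m <- generate_biomass(specs[[k]])
    m$samples$sample_id <- sprintf("%s_%03d", k, seq_len(nrow(m$values)))
    rownames(m$values) <- m$samples$sample_id
    m$samples$turbidity_class <- k
    m$samples$turbidity_ntu <- ntu[[k]]
    m
  })
  names(out) <- names(specs)
  out
}
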
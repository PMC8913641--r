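#' Construct a community biomass matrix
#'
#' The raw input of the pipeline: a samples x taxa table of biomass (mg/l)
#' with per-sample metadata. Rows are sampling events, columns are
#' zooplankton taxonomic units.
#'
#' @param values Numeric matrix, samples in rows, taxa in columns. Column
#'   names are taxon names (unique after whitespace trimming); missing
#'   values are allowed and mean "not determined", not zero.
#' @param samples Optional data frame of per-sample metadata with columns
#'   among `sample_id`, `reservoir`, `date`, `site`, `turbidity_class`,
#'   `turbidity_ntu`. Defaults to generated sample ids.
#' @return An object of class `biomass_matrix` with elements `values`
#'   (numeric matrix) and `samples` (metadata data frame).
#' @examples
#' m <- biomass_matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
#'                            dimnames = list(NULL, c("Daphnia", "Keratella"))))
#' dim(m)
#' @export
biomass_matrix <- function(values, samples = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("biomass values must be numeric")
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("taxon_%02d", seq_len(p))
  }
  taxa <- trimws(colnames(values))
  colnames(values) <- taxa
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon names after whitespace normalization: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (any(!nzchar(taxa))) stop("taxon names must be non-empty")
  neg <- which(!is.na(values) & values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    cells <- apply(neg[seq_len(min(nrow(neg), 10L)), , drop = FALSE], 1L,
                   function(ij) sprintf("row %d / %s", ij[1], taxa[ij[2]]))
    stop("negative biomass values at: ", paste(cells, collapse = "; "))
  }
  if (is.null(samples)) {
    ids <- rownames(values) %||% sprintf("s%03d", seq_len(n))
    samples <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- rownames(values) %||% sprintf("s%03d", seq_len(n))
  }
  if (nrow(samples) != n) {
    stop("metadata has ", nrow(samples), " rows but biomass has ", n, " samples")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  rownames(values) <- samples$sample_id
  structure(list(values = values, samples = samples), class = "biomass_matrix")
}

#' @export
dim.biomass_matrix <- function(x) dim(x$values)

#' @export
print.biomass_matrix <- function(x, ...) {
  cat(sprintf("<biomass_matrix> %d samples x %d taxa\n",
              nrow(x$values), ncol(x$values)))
  if ("turbidity_class" %in% names(x$samples)) {
    tc <- table(x$samples$turbidity_class, useNA = "ifany")
    cat("  turbidity classes:",
        paste(sprintf("%s=%d", names(tc), tc), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the numeric biomass grid of a biomass matrix
#'
#' @param m A `biomass_matrix` or a plain numeric matrix (returned as is).
#' @return Numeric matrix, samples x taxa.
#' @export
biomass_values <- function(m) {
  if (inherits(m, "biomass_matrix")) m$values else as.matrix(m)
}

#' Taxon names of a biomass matrix
#' @param m A `biomass_matrix`.
#' @return Character vector of taxon names.
#' @export
taxa_names <- function(m) colnames(biomass_values(m))
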
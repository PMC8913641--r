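#' Turbidity class boundaries
#'
#' Defines the partition of the turbidity gradient (NTU) into the three
#' classes used throughout the pipeline: high turbidity (HT) above the
#' upper bound, low turbidity (LT) below the lower bound, and moderate
#' turbidity (MT) on the closed interval between them. Boundary values
#' fall in MT.
#'
#' @param lt_max Upper NTU bound of the LT class (exclusive); default 15.
#' @param ht_min Lower NTU bound of the HT class (exclusive); default 25.
#' @return An object of class `turbidity_class_spec`.
#' @examples
#' spec <- turbidity_class_spec()
#' @export
turbidity_class_spec <- function(lt_max = 15, ht_min = 25) {
  stopifnot(is.numeric(lt_max), is.numeric(ht_min), length(lt_max) == 1L,
            length(ht_min) == 1L, lt_max > 0, ht_min >= lt_max)
  structure(list(lt_max = lt_max, ht_min = ht_min),
            class = "turbidity_class_spec")
}

#' Assign turbidity classes to samples
#'
#' Labels every sample HT, MT or LT from its turbidity (NTU). Samples that
#' already carry a class label keep it; samples with neither an NTU value
#' nor a class are an error. NTU equal to a boundary (15 or 25 by default)
#' is assigned to MT (closed interval).
#'
#' @param m A [biomass_matrix()] whose metadata holds `turbidity_ntu`
#'   and/or `turbidity_class`.
#' @param spec A [turbidity_class_spec()].
#' @return The biomass matrix with `turbidity_class` filled in for every
#'   sample.
#' @export
assign_classes <- function(m, spec = turbidity_class_spec()) {
  stopifnot(inherits(m, "biomass_matrix"), inherits(spec, "turbidity_class_spec"))
  meta <- m$samples
  cls <- as.character(meta$turbidity_class %||% rep(NA_character_, nrow(meta)))
  cls[cls %in% c("", "unassigned")] <- NA_character_
  ntu <- meta$turbidity_ntu %||% rep(NA_real_, nrow(meta))
  need <- is.na(cls)
  missing_both <- need & is.na(ntu)
  if (any(missing_both)) {
    stop("samples lack both turbidity_ntu and turbidity_class: ",
         paste(meta$sample_id[missing_both], collapse = ", "))
  }
  if (any(!is.na(ntu) & ntu < 0)) stop("negative turbidity_ntu")
  cls[need] <- ifelse(ntu[need] > spec$ht_min, "HT",
                      ifelse(ntu[need] < spec$lt_max, "LT", "MT"))
  bad <- !cls %in% c("HT", "MT", "LT")
  if (any(bad)) {
    stop("unknown turbidity_class label(s): ",
         paste(unique(cls[bad]), collapse = ", "))
  }
  m$samples$turbidity_class <- cls
  m
}

#' Split a biomass matrix by turbidity class
#'
#' @param m A classified [biomass_matrix()] (see [assign_classes()]).
#' @return Named list of `biomass_matrix` objects, one per class present,
#'   ordered HT, MT, LT.
#' @export
split_by_class <- function(m) {
  stopifnot(inherits(m, "biomass_matrix"))
  cls <- m$samples$turbidity_class
  if (is.null(cls) || anyNA(cls)) {
    stop("samples are not fully classified; run assign_classes() first")
  }
  out <- lapply(intersect(c("HT", "MT", "LT"), unique(cls)), function(k) {
    keep <- cls == k
    biomass_matrix(m$values[keep, , drop = FALSE],
                   m$samples[keep, , drop = FALSE])
  })
  names(out) <- intersect(c("HT", "MT", "LT"), unique(cls))
  out
}

.meta_columns <- c("sample_id", "reservoir", "date", "site",
                   "turbidity_class", "turbidity_ntu")

#' Read a wide-format biomass table
#'
#' Reads a delimited text file with taxa in columns and sampling events in
#' rows. Leading metadata columns are recognized by name (`sample_id`,
#' `reservoir`, `date`, `site`, `turbidity_class`, `turbidity_ntu`); all
#' other columns are taxa. Empty cells become missing values, not zeros.
#' A decimal comma is supported via `dec = ","`.
#'
#' @param path Path to the file.
#' @param sep Field delimiter; default `","`.
#' @param dec Decimal mark, `"."` or `","`.
#' @return A validated [biomass_matrix()].
#' @export
read_biomass_table <- function(path, sep = ",", dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  names(raw) <- trimws(names(raw))
  meta_present <- intersect(.meta_columns, names(raw))
  taxa_cols <- names(raw)[!names(raw) %in% meta_present]
  if (length(taxa_cols) == 0L) stop("no taxon columns found in ", path)
  if (anyDuplicated(taxa_cols)) {
    stop("duplicate taxon names in header: ",
         paste(unique(taxa_cols[duplicated(taxa_cols)]), collapse = ", "))
  }
  parse_num <- function(x, col) {
    x0 <- trimws(x)
    # tolerate a typographic minus from exported spreadsheets
    x0 <- gsub("−", "-", x0)
    if (dec != ".") x0 <- gsub(dec, ".", x0, fixed = TRUE)
    out <- suppressWarnings(as.numeric(x0))
    bad <- which(is.na(out) & !is.na(x0))
    if (length(bad) > 0) {
      stop(sprintf("unparseable number '%s' at row %d, column '%s'",
                   x[bad[1]], bad[1], col))
    }
    out
  }
  vals <- vapply(taxa_cols, function(cn) parse_num(raw[[cn]], cn),
                 numeric(nrow(raw)))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L,
                                      dimnames = list(NULL, taxa_cols))
  colnames(vals) <- taxa_cols
  meta <- raw[meta_present]
  if ("turbidity_ntu" %in% names(meta)) {
    meta$turbidity_ntu <- parse_num(meta$turbidity_ntu, "turbidity_ntu")
  }
  if (length(meta) == 0L) meta <- NULL
  biomass_matrix(vals, meta)
}

#' Write a biomass matrix as a wide-format delimited table
#'
#' Writes metadata columns followed by one column per taxon, in the same
#' dialect [read_biomass_table()] reads, so that write -> read is an
#' identity (up to numeric print precision).
#'
#' @param m A [biomass_matrix()].
#' @param path Output path.
#' @param sep Field delimiter; default `","`.
#' @param dec Decimal mark.
#' @export
write_biomass_table <- function(m, path, sep = ",", dec = ".") {
  stopifnot(inherits(m, "biomass_matrix"))
  df <- cbind(m$samples, as.data.frame(m$values, check.names = FALSE))
  utils::write.table(df, path, sep = sep, dec = dec, row.names = FALSE,
                     quote = TRUE, na = "")
  invisible(path)
}

#' Export a signed network to a standard graph format
#'
#' Supported formats: `"edgelist"` (tab-delimited columns source, target,
#' r, sign, weight), `"graphml"` (same data as typed attributes, readable
#' by Cytoscape and igraph), and `"sif"` (Cytoscape simple interaction
#' format with interaction labels `pos`/`neg`; isolated nodes appear as
#' single-node lines).
#'
#' @param net A [signed_network()].
#' @param path Output path.
#' @param format One of `"edgelist"`, `"graphml"`, `"sif"`.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml", "sif")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  el <- network_edges(net)
  if (format == "edgelist") {
    utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    deg <- igraph::degree(g)
    lines <- character(0)
    if (nrow(el) > 0) {
      lines <- sprintf("%s\t%s\t%s", el$source, el$sign, el$target)
    }
    iso <- names(deg)[deg == 0]
    lines <- c(lines, iso)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a signed network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"edgelist"` or `"graphml"` (SIF drops the correlation
#'   value and is export-only).
#' @return A [signed_network()].
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    el <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    return(signed_network(el))
  }
  g <- igraph::read_graph(path, format = "graphml")
  as_signed_network(g)
}
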
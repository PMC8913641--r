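#' Configuration for a full pipeline run
#'
#' Exactly one of `input` (path to a wide-format biomass table) or
#' `synthetic` (TRUE: use the seeded three-class study fixture) must be
#' given.
#'
#' @param input Path to a delimited biomass table, or `NULL`.
#' @param synthetic Generate the three-class study fixture instead of
#'   reading a file.
#' @param class_spec A [turbidity_class_spec()].
#' @param alpha Edge significance level; default 0.05.
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @param log_base Logarithm base for diversity indices.
#' @param include_isolated Keep isolated taxa when computing global
#'   attributes.
#' @param community_k Optional named vector/list of target sub-network
#'   counts per class (e.g. `c(MT = 3)`); classes not named use the
#'   maximum-modularity stop.
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed driving all randomness.
#' @param sep,dec Input table dialect, passed to [read_biomass_table()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(input = NULL, synthetic = is.null(input),
                       class_spec = turbidity_class_spec(), alpha = 0.05,
                       correction = c("none", "benjamini_hochberg"),
                       log_base = exp(1), include_isolated = TRUE,
                       community_k = NULL, outdir = tempfile("zoonet_run_"),
                       seed = 1, sep = ",", dec = ".") {
  correction <- match.arg(correction)
  if (is.null(input) == !isTRUE(synthetic)) {
    stop("provide exactly one of `input` or `synthetic = TRUE`")
  }
  structure(list(input = input, synthetic = isTRUE(synthetic),
                 class_spec = class_spec, alpha = alpha,
                 correction = correction, log_base = log_base,
                 include_isolated = include_isolated,
                 community_k = community_k, outdir = outdir,
                 seed = as.integer(seed), sep = sep, dec = dec),
            class = "run_config")
}

#' Run the full turbidity-class network pipeline
#'
#' Ingests (or synthesizes) a biomass dataset, assigns turbidity classes,
#' and, for every class: autoscales, computes the pairwise Pearson
#' correlation matrix, thresholds it at the class sample size into a
#' signed network, computes global attributes, node and edge centralities
#' and the edge-betweenness sub-network partition, and tabulates
#' per-sample diversity. Classes are then compared (Shannon H' and Pielou
#' J' by ANOVA + Tukey, total biomass by Kruskal-Wallis). All tables,
#' graph exports and a JSON run manifest are written under
#' `config$outdir`.
#'
#' @param config A [run_config()].
#' @return Object of class `run_report`: list with `class_attributes`
#'   (data frame, one row per class), `networks`, `centralities`,
#'   `edge_centralities`, `communities`, `diversity`, `comparisons`,
#'   `warnings`, `files`, `manifest_path`.
#' @export
run_turbidity_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, name)
    path
  }

  withCallingHandlers({
    classes <- if (config$synthetic) {
      make_study_fixture(seed = config$seed)
    } else {
      m <- read_biomass_table(config$input, sep = config$sep, dec = config$dec)
      m <- assign_classes(m, config$class_spec)
      split_by_class(m)
    }

    attr_rows <- list()
    networks <- list()
    cents <- list()
    ecents <- list()
    comms <- list()
    divs <- list()
    for (k in names(classes)) {
      stage <- function(expr, what) {
        tryCatch(expr, error = function(e) {
          stop(sprintf("[%s/%s] %s", k, what, conditionMessage(e)),
               call. = FALSE)
        })
      }
      mk <- classes[[k]]
      z <- stage(autoscale(mk), "autoscale")
      cr <- stage(pearson_matrix(z, alpha = config$alpha), "pearson")
      net <- stage(threshold_network(cr, correction = config$correction),
                   "threshold")
      networks[[k]] <- net
      ga <- stage(global_attributes(net,
                                    include_isolated = config$include_isolated),
                  "attributes")
      attr_rows[[k]] <- cbind(data.frame(class = k, n_samples = nrow(mk$values),
                                         stringsAsFactors = FALSE), ga)
      nc <- stage(node_centralities(net), "centralities")
      eb <- stage(edge_betweenness_centrality(net), "edge_betweenness")
      cents[[k]] <- nc
      ecents[[k]] <- eb
      kk <- if (!is.null(config$community_k) &&
                k %in% names(config$community_k)) {
        config$community_k[[k]]
      } else {
        NULL
      }
      comms[[k]] <- if (igraph::ecount(as_igraph(net)) > 0) {
        stage(network_communities(net, k = kk), "communities")
      } else {
        NULL
      }
      divs[[k]] <- stage(diversity_table(mk, base = config$log_base),
                         "diversity")
      emit(network_edges(net), sprintf("network_%s_edges.tsv", k))
      gml <- file.path(config$outdir, sprintf("network_%s.graphml", k))
      write_network(net, gml, format = "graphml")
      files <- c(files, basename(gml))
      emit(nc, sprintf("centralities_%s.tsv", k))
      emit(eb, sprintf("edge_betweenness_%s.tsv", k))
      emit(divs[[k]], sprintf("diversity_%s.tsv", k))
    }
    class_attributes <- do.call(rbind, attr_rows)
    rownames(class_attributes) <- NULL
    emit(class_attributes, "class_attributes.tsv")

    div_all <- do.call(rbind, divs)
    comparisons <- list(
      shannon_h = compare_classes(div_all$shannon_h, div_all$turbidity_class,
                                  method = "anova", alpha = config$alpha,
                                  variable = "shannon_h"),
      pielou_j = compare_classes(div_all$pielou_j, div_all$turbidity_class,
                                 method = "anova", alpha = config$alpha,
                                 variable = "pielou_j"),
      total_biomass = compare_classes(
        unlist(lapply(classes, function(m) rowSums(biomass_values(m),
                                                   na.rm = TRUE))),
        rep(names(classes), vapply(classes, function(m) nrow(m$values), 1L)),
        method = "kruskal_wallis", variable = "total_biomass"))

    manifest <- list(
      package = "zoonet",
      versions = list(zoonet = as.character(utils::packageVersion("zoonet")),
                      R = paste(R.version$major, R.version$minor, sep = "."),
                      igraph = as.character(utils::packageVersion("igraph"))),
      config = list(input = config$input %||% "synthetic",
                    alpha = config$alpha, correction = config$correction,
                    log_base = config$log_base,
                    include_isolated = config$include_isolated,
                    seed = config$seed),
      classes = lapply(classes, function(m) {
        list(n_samples = nrow(m$values), n_taxa = ncol(m$values))
      }),
      warnings = as.list(warnings_log),
      files = as.list(sort(unique(files))))
    manifest_path <- file.path(config$outdir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    # timestamp kept out of the manifest so repeated runs are byte-identical
    writeLines(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               file.path(config$outdir, "timestamp.txt"))

    structure(list(class_attributes = class_attributes, networks = networks,
                   centralities = cents, edge_centralities = ecents,
                   communities = comms, diversity = div_all,
                   comparisons = comparisons, warnings = warnings_log,
                   files = sort(unique(files)), manifest_path = manifest_path),
              class = "run_report")
  }, warning = note)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$class_attributes, row.names = FALSE)
  invisible(x)
}
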
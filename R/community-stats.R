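#' Autoscale a biomass table
#'
#' Standardizes every taxon column to zero mean and unit sample standard
#' deviation over its present (non-missing) values — the normalization
#' applied before correlation. Columns with zero variance (or fewer than
#' two present values) carry no correlation information and are dropped
#' with a warning; the drop list travels on the result.
#'
#' @param m A [biomass_matrix()] or numeric matrix.
#' @return Numeric matrix of z-scores with attribute `dropped_taxa`
#'   (character vector, possibly empty). Missing cells stay missing.
#' @export
autoscale <- function(m) {
  x <- biomass_values(m)
  mu <- colMeans(x, na.rm = TRUE)
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  npresent <- colSums(!is.na(x))
  bad <- is.na(sds) | sds == 0 | npresent < 2
  if (any(bad)) {
    warning("dropping zero-variance taxa: ",
            paste(colnames(x)[bad], collapse = ", "))
  }
  keep <- which(!bad)
  z <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-"),
             2L, sds[keep], "/")
  attr(z, "dropped_taxa") <- colnames(x)[bad]
  z
}

#' Shannon diversity and Pielou evenness of one sample
#'
#' `H' = -sum(p_i log p_i)` over taxa with positive biomass, with `p_i`
#' the biomass share, and `J' = H' / log(S)` with `S` the number of taxa
#' present. `J'` is undefined (returned missing) for `S < 2`.
#'
#' @param x Non-negative biomass vector for one sample; at least one
#'   positive entry.
#' @param base Logarithm base: `exp(1)` (nats, default), 2, or 10.
#' @return One-row data frame with columns `richness`, `shannon_h`,
#'   `pielou_j`.
#' @examples
#' diversity_record(c(0.5, 0.3, 0.2))  # H' = 1.0297
#' @export
diversity_record <- function(x, base = exp(1)) {
  x <- as.numeric(x)
  if (anyNA(x)) x <- x[!is.na(x)]
  if (any(x < 0)) stop("biomass must be non-negative")
  if (length(x) == 0 || sum(x) == 0) {
    stop("diversity is undefined for an all-zero sample")
  }
  s <- sum(x > 0)
  h <- as.numeric(vegan::diversity(x, index = "shannon", base = base))
  j <- if (s >= 2) h / log(s, base = base) else NA_real_
  data.frame(richness = as.integer(s), shannon_h = h, pielou_j = j)
}

#' Per-sample diversity table
#'
#' Applies [diversity_record()] to every sample of a biomass matrix.
#' All-zero samples yield missing values with a warning rather than an
#' error, so one empty sampling event does not abort a pipeline run.
#'
#' @param m A [biomass_matrix()].
#' @param base Logarithm base passed to [diversity_record()].
#' @return Data frame with columns `sample_id`, `richness`, `shannon_h`,
#'   `pielou_j` (plus `turbidity_class` when present in the metadata).
#' @export
diversity_table <- function(m, base = exp(1)) {
  stopifnot(inherits(m, "biomass_matrix"))
  x <- biomass_values(m)
  rows <- lapply(seq_len(nrow(x)), function(i) {
    tryCatch(diversity_record(x[i, ], base = base), error = function(e) {
      warning("sample ", m$samples$sample_id[i], ": ", conditionMessage(e),
              call. = FALSE)
      data.frame(richness = NA_integer_, shannon_h = NA_real_,
                 pielou_j = NA_real_)
    })
  })
  out <- cbind(data.frame(sample_id = m$samples$sample_id,
                          stringsAsFactors = FALSE),
               do.call(rbind, rows))
  if ("turbidity_class" %in% names(m$samples)) {
    out$turbidity_class <- m$samples$turbidity_class
  }
  out
}

#' Compare a variable between turbidity classes
#'
#' One-way ANOVA (F test, with post-hoc Tukey HSD compact letter display:
#' classes sharing no letter differ at `alpha`) or the non-parametric
#' Kruskal-Wallis test.
#'
#' @param values Numeric vector of observations.
#' @param groups Class label per observation (factor or character).
#' @param method `"anova"` (default) or `"kruskal_wallis"`.
#' @param alpha Level for the Tukey letter display; default 0.05.
#' @param variable Name of the variable, echoed into the result.
#' @param tukey Compute the Tukey letter display (ANOVA only); set FALSE
#'   to skip the post hoc when only the omnibus test is needed.
#' @return Object of class `comparison_result`: list with `variable`,
#'   `test`, `statistic`, `df`, `p_value` and, for ANOVA,
#'   `tukey_groups` (named letters per class).
#' @export
compare_classes <- function(values, groups,
                            method = c("anova", "kruskal_wallis"),
                            alpha = 0.05, variable = "value",
                            tukey = TRUE) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  g <- factor(as.character(groups[ok]))
  cnt <- table(g)
  if (length(cnt) < 2) stop("need at least 2 groups")
  if (any(cnt < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  }
  if (method == "anova") {
    dat <- data.frame(y = values, g = g)
    fit <- stats::aov(y ~ g, data = dat)
    tab <- summary(fit)[[1L]]
    fstat <- tab[["F value"]][1L]
    pval <- tab[["Pr(>F)"]][1L]
    if (is.na(fstat)) { # zero residual and between-group variance
      fstat <- 0; pval <- 1
    }
    letters <- if (tukey) {
      tryCatch({
        glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
        cld <- multcomp::cld(glht, level = alpha)
        as.list(cld$mcletters$Letters)
      }, error = function(e) {
        as.list(stats::setNames(rep("a", nlevels(g)), levels(g)))
      })
    } else {
      NULL
    }
    res <- list(variable = variable, test = "anova", statistic = fstat,
                df = c(tab[["Df"]][1L], tab[["Df"]][2L]), p_value = pval,
                tukey_groups = letters)
  } else {
    kw <- suppressWarnings(stats::kruskal.test(values, g))
    stat <- as.numeric(kw$statistic)
    pval <- kw$p.value
    if (is.na(stat) && length(unique(values)) == 1L) { # all observations tied
      stat <- 0; pval <- 1
    }
    res <- list(variable = variable, test = "kruskal_wallis",
                statistic = stat, df = as.numeric(kw$parameter),
                p_value = pval, tukey_groups = NULL)
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: %s statistic = %.4g, df = %s, p = %.4g\n",
              x$variable, x$test, x$statistic,
              paste(x$df, collapse = ", "), x$p_value))
  if (!is.null(x$tukey_groups)) {
    cat("  Tukey groups:",
        paste(sprintf("%s=%s", names(x$tukey_groups),
                      unlist(x$tukey_groups)), collapse = ", "), "\n")
  }
  invisible(x)
}
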
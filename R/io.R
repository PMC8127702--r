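#' Read / write phenotype tables
#'
#' Phenotype tables travel as UTF-8 CSV with the fixed header
#' `population, block, sire, dam, individual` followed by trait columns.
#' Missing trait values are encoded as empty fields. Unknown extra columns
#' are preserved and passed through. `write_phenotypes()` /
#' [read_phenotypes()] round-trip losslessly, including missing values.
#'
#' @param path File path.
#' @param table Phenotype table to write.
#' @return `read_phenotypes()` returns the table; `write_phenotypes()`
#'   returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  check.names = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(DESIGN_COLS, names(tab))
  if (length(missing_cols) > 0L)
    stop("malformed phenotype header in '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  for (tr in trait_columns(tab)) {
    col <- tab[[tr]]
    if (is.numeric(col)) next
    conv <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(conv))
    # an entirely non-numeric column is an annotation: preserved as-is
    if (length(bad) == sum(!is.na(col))) next
    if (length(bad) > 0L)
      stop("non-numeric value in trait column '", tr, "', row ", bad[1L],
           ": '", col[bad[1L]], "'")
    tab[[tr]] <- conv
  }
  tab
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(table, path) {
  check_phenotype_table(table)
  table <- table[, c(DESIGN_COLS, trait_columns(table)), drop = FALSE]
  write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a simulation-parameter provenance sidecar
#'
#' Stores a [sim_params()] object as JSON next to a simulated dataset so the
#' generative architecture travels with the phenotypes.
#'
#' @param params A `sim_params` object.
#' @param path JSON file path.
#' @return `read_sim_params()` reconstructs the `sim_params` object.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  x <- list(traits = params$traits, mu = unname(params$mu),
            G = params$G, D = params$D, E = params$E,
            block_effects = params$block_effects,
            attrition_rate = params$attrition_rate,
            missing_rate_per_trait = params$missing_rate_per_trait,
            seed = params$seed)
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- setNames(x$mu, x$traits)
  as_mat <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(x$traits, x$traits)
    m
  }
  be <- if (is.null(x$block_effects)) NULL else as.matrix(x$block_effects)
  sim_params(mu = mu, G = as_mat(x$G), D = as_mat(x$D), E = as_mat(x$E),
             block_effects = be, attrition_rate = x$attrition_rate,
             missing_rate_per_trait = unlist(x$missing_rate_per_trait),
             seed = x$seed)
}

#' Standardize traits by their pooled (global) standard deviation
#'
#' Each trait is divided by its standard deviation pooled across all
#' populations, putting traits on a common scale before multivariate model
#' fitting. The SDs used are recorded in the attribute `trait_sd` so that
#' downstream quantities (e.g. predicted responses to selection) can be
#' back-transformed into original trait units or expressed in SD units.
#'
#' @param table Phenotype table.
#' @param traits Trait columns to standardize; default all.
#' @return The standardized table with attribute `trait_sd` (named vector of
#'   the SDs divided out).
#' @seealso [trait_sd()]
#' @export
standardize_traits <- function(table, traits = NULL) {
  check_phenotype_table(table)
  if (is.null(traits)) traits <- trait_columns(table)
  sds <- numeric(length(traits))
  names(sds) <- traits
  for (tr in traits) {
    v <- table[[tr]]
    if (sum(!is.na(v)) < 2L)
      stop("trait '", tr, "' has fewer than 2 non-missing values")
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("trait '", tr, "' has zero variance; cannot standardize")
    sds[tr] <- s
    table[[tr]] <- v / s
  }
  attr(table, "trait_sd") <- sds
  table
}

#' Recorded standardization SDs of a table
#'
#' @param table A table returned by [standardize_traits()].
#' @return Named vector of per-trait SDs, or `NULL` if the table was never
#'   standardized.
#' @export
trait_sd <- function(table) attr(table, "trait_sd")
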
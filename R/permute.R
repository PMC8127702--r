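#' Permute phenotypes within populations
#'
#' Destroys family structure while keeping the design fixed: within each
#' population, trait records are reassigned at random (without replacement)
#' to the individuals, so sires and dams receive random offspring phenotypes.
#' By default whole trait rows move jointly, which preserves the pooled
#' phenotypic covariance matrix exactly; `per_trait = TRUE` shuffles each
#' trait column independently (destroying phenotypic correlations as well).
#'
#' @param table Phenotype table.
#' @param seed Integer seed.
#' @param per_trait Shuffle traits independently instead of jointly.
#' @return The permuted table (same dimensions, same per-trait multisets).
#' @export
permute_within_population <- function(table, seed, per_trait = FALSE) {
  check_phenotype_table(table)
  if (nrow(table) == 0L) stop("cannot permute an empty table")
  traits <- trait_columns(table)
  set.seed(as.integer(seed))
  for (pop in unique(table$population)) {
    rows <- which(table$population == pop)
    if (length(rows) < 2L) next
    if (per_trait) {
      for (tr in traits)
        table[rows, tr] <- table[rows, tr][sample.int(length(rows))]
    } else {
      table[rows, traits] <- table[rows[sample.int(length(rows))], traits]
    }
  }
  table
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing a given probability mass of an
#' empirical sample: sort, slide a window of `ceiling(prob * n)` points and
#' take the narrowest.
#'
#' @param samples Numeric vector (length >= 2).
#' @param prob Probability mass in (0, 1); default 0.95.
#' @return Named vector `c(lower, upper)`, both within the sample range.
#' @export
hpd <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 2L) stop("hpd needs at least 2 finite samples")
  if (!is.numeric(prob) || prob <= 0 || prob >= 1)
    stop("'prob' must lie in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- max(1L, min(n - 1L, ceiling(prob * n) - 1L))  # window span in indices
  widths <- x[(1L + m):n] - x[seq_len(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Build a permutation null distribution for a statistic
#'
#' Implements the permutation scheme used for significance in half-sib
#' variance-component studies: create `n_datasets` randomized datasets by
#' permuting phenotypes within populations, refit / recompute the statistic
#' on each, and summarize the resulting null sample with a 95% HPD interval.
#' Sub-seeds are derived deterministically from the master seed by counter,
#' so any single permutation can be replayed in isolation. Failures of the
#' statistic on individual permutations are logged and excluded with a count
#' rather than aborting the run.
#'
#' @param table Phenotype table.
#' @param fit_and_statistic Function computing the statistic on a (permuted)
#'   table. Called as `fit_and_statistic(table, seed)` when it accepts two
#'   arguments (the sub-seed is supplied for any stochastic refit), else as
#'   `fit_and_statistic(table)`. May return a numeric scalar or vector
#'   (e.g. a set of eigenvalues); vector lengths must agree across
#'   permutations.
#' @param n_datasets Number of randomized datasets (production default 1000).
#' @param seed Master seed.
#' @param prob HPD mass.
#' @param per_trait Passed to [permute_within_population()].
#' @param statistic_label Label stored in the result.
#' @return Object of class `null_distribution`: `samples` (matrix, one row
#'   per successful permutation), `hpd_low`/`hpd_high` (per statistic
#'   component), `n_datasets`, `n_failed`, `statistic_label`, `seed`.
#' @export
build_null <- function(table, fit_and_statistic, n_datasets = 1000, seed = 1L,
                       prob = 0.95, per_trait = FALSE,
                       statistic_label = deparse(substitute(fit_and_statistic))) {
  check_phenotype_table(table)
  stopifnot(n_datasets >= 1)
  two_args <- length(formals(fit_and_statistic)) >= 2L
  seeds <- derive_seeds(seed, 2L * n_datasets)
  perm_seeds <- seeds[seq_len(n_datasets)]
  fit_seeds <- seeds[n_datasets + seq_len(n_datasets)]
  out <- vector("list", n_datasets)
  n_failed <- 0L
  for (i in seq_len(n_datasets)) {
    perm <- permute_within_population(table, perm_seeds[i], per_trait = per_trait)
    val <- tryCatch({
      if (two_args) fit_and_statistic(perm, fit_seeds[i])
      else fit_and_statistic(perm)
    }, error = function(e) {
      message("permutation ", i, " failed and was excluded: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(val) || any(!is.finite(val))) n_failed <- n_failed + 1L
    else out[[i]] <- as.numeric(val)
  }
  ok <- !vapply(out, is.null, TRUE)
  if (!any(ok)) stop("statistic failed on every permutation")
  lens <- unique(vapply(out[ok], length, 0L))
  if (length(lens) != 1L)
    stop("statistic returned values of differing lengths across permutations")
  samples <- do.call(rbind, out[ok])
  if (lens == 1L) {
    h <- hpd(samples[, 1L], prob)
    hl <- h[[1L]]; hh <- h[[2L]]
  } else {
    hs <- apply(samples, 2L, hpd, prob = prob)
    hl <- hs[1L, ]; hh <- hs[2L, ]
  }
  structure(list(statistic_label = statistic_label, samples = samples,
                 hpd_low = hl, hpd_high = hh, prob = prob,
                 n_datasets = n_datasets, n_failed = n_failed, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Permutation null for '", x$statistic_label, "': ",
      nrow(x$samples), "/", x$n_datasets, " permutations (",
      x$n_failed, " failed)\n", sep = "")
  cat(100 * x$prob, "% HPD: [", paste(signif(x$hpd_low, 5), collapse = ", "),
      "] .. [", paste(signif(x$hpd_high, 5), collapse = ", "), "]\n")
  invisible(x)
}

#' Serialize a null distribution
#'
#' Writes `<base>_samples.csv` (one row per permutation) and
#' `<base>_meta.json` (label, HPD bounds, counts, master seed).
#'
#' @param x A `null_distribution`.
#' @param base Path prefix.
#' @return `base`, invisibly.
#' @export
write_null_distribution <- function(x, base) {
  stopifnot(inherits(x, "null_distribution"))
  write.csv(as.data.frame(x$samples), paste0(base, "_samples.csv"),
            row.names = FALSE)
  meta <- list(statistic_label = x$statistic_label, prob = x$prob,
               hpd_low = x$hpd_low, hpd_high = x$hpd_high,
               n_datasets = x$n_datasets, n_failed = x$n_failed,
               seed = x$seed)
  jsonlite::write_json(meta, paste0(base, "_meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(base)
}
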
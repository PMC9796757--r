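#' Read a rank matrix from TSV/CSV
#'
#' Reads an assessors-by-items table (header row = item labels) and validates
#' it: rectangular, integer, unique labels, and every row a permutation of
#' `1:n`. Files ending in `.csv` are read as comma-separated, anything else
#' as tab-separated.
#'
#' @param path File path.
#' @return An integer rank matrix with item labels as column names.
#' @export
read_rank_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  df <- suppressWarnings(
    reader(path, show_col_types = FALSE, progress = FALSE, name_repair = "minimal")
  )
  prob <- readr::problems(df)
  if (nrow(prob) > 0) {
    stop("malformed table (ragged or non-numeric rows) in ", path, call. = FALSE)
  }
  m <- as.matrix(df)
  if (anyNA(m)) stop("missing values in ", path, call. = FALSE)
  if (any(m != round(m))) stop("non-integer rank values in ", path, call. = FALSE)
  assert_rank_matrix(m)
}

#' Write a rank matrix to TSV/CSV
#'
#' @param rankings Rank matrix (assessors x items).
#' @param path Output path; `.csv` writes comma-separated, anything else TSV.
#' @return Invisibly, `path`.
#' @export
write_rank_matrix <- function(rankings, path) {
  rankings <- assert_rank_matrix(rankings)
  df <- tibble::as_tibble(rankings)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path)
  } else {
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Convert a continuous feature matrix to per-sample rankings
#'
#' Ranks the features within each sample (row) so that the largest value
#' receives rank 1 — rank 1 is the most preferred item, i.e. the most highly
#' expressed feature. Ties are broken uniformly at random under the given
#' seed so every row is a proper permutation. Missing values must be imputed
#' upstream.
#'
#' @param x Numeric matrix or data frame, samples x features.
#' @param seed Optional integer seed governing tie-breaking.
#' @return An integer rank matrix of the same dimensions.
#' @examples
#' expression_to_ranks(rbind(c(0.1, 5.0, 2.3)))
#' @export
expression_to_ranks <- function(x, seed = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (anyNA(x)) {
    stop("missing values present; impute expression values before ranking",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- t(apply(x, 1L, function(row) rank(-row, ties.method = "random")))
  storage.mode(out) <- "integer"
  colnames(out) <- colnames(x) %||% paste0("item", seq_len(ncol(x)))
  out
}

#' Write and read generator truth objects
#'
#' Truth objects are persisted as small JSON files so that simulation runs
#' can be scored later by the evaluation tools.
#'
#' @param truth A `lowbmm_truth` object.
#' @param path File path (JSON).
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   reconstructed `lowbmm_truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_truth(x$relevant_set, x$consensus, x$alpha_true, x$process,
            x$noise_level %||% 0L)
}

#' Persist posterior samples as TSV
#'
#' Writes the kept posterior samples as a portable TSV (columns: `chain`,
#' `sample`, `rho_1..rho_n_star`, `item_1..item_n_star`) together with a JSON
#' side-car holding the metadata needed to rebuild the fit (dimensions,
#' `alpha`, item labels, acceptance rates, settings).
#'
#' @param fit A `lowbmm` fit.
#' @param path Output TSV path; the side-car gets the extension `.meta.json`.
#' @return `write_samples()` returns `path` invisibly; `read_samples()` a
#'   reconstructed `lowbmm` object.
#' @export
write_samples <- function(fit, path) {
  ns <- fit$n_star
  df <- tibble::as_tibble(cbind(
    chain = fit$chain,
    sample = seq_len(nrow(fit$rho_samples)),
    stats::setNames(as.data.frame(fit$rho_samples), paste0("rho_", seq_len(ns))),
    stats::setNames(as.data.frame(fit$aset_samples), paste0("item_", seq_len(ns)))
  ))
  readr::write_tsv(df, path)
  meta <- list(n = fit$n, n_star = ns, alpha = fit$alpha,
               item_labels = fit$item_labels,
               accept_rho = fit$accept_rho, accept_set = fit$accept_set,
               control = unclass(fit$control))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  ns <- meta$n_star
  ctl_args <- meta$control[setdiff(names(meta$control), character())]
  control <- do.call(lowbmm_control, ctl_args)
  rho_m <- as.matrix(df[paste0("rho_", seq_len(ns))])
  aset_m <- as.matrix(df[paste0("item_", seq_len(ns))])
  storage.mode(rho_m) <- "integer"
  storage.mode(aset_m) <- "integer"
  structure(
    list(rho_samples = rho_m,
         aset_samples = aset_m,
         chain = as.integer(df$chain),
         accept_rho = meta$accept_rho,
         accept_set = meta$accept_set,
         n = meta$n,
         n_star = ns,
         alpha = meta$alpha,
         item_labels = meta$item_labels,
         control = control,
         call = NULL),
    class = "lowbmm"
  )
}
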
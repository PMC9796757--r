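#' Footrule distance between two rankings
#'
#' The footrule (Spearman's footrule) distance is the L1 distance between two
#' rank vectors, \eqn{d(a, b) = \sum_i |a_i - b_i|}. It is right-invariant: a
#' common relabelling of the items leaves it unchanged.
#'
#' @param a,b Integer vectors, each a permutation of `1:m`.
#' @return A non-negative integer.
#' @examples
#' footrule(c(2, 1, 3), c(1, 3, 2))
#' @export
footrule <- function(a, b) {
  if (length(a) != length(b)) {
    stop("rankings have different dimensions: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  as.integer(sum(abs(a - b)))
}

#' Kendall distance between two rankings
#'
#' Counts the item pairs ranked in opposite order by the two rankings
#' (discordant pairs).
#'
#' @inheritParams footrule
#' @return A non-negative integer.
#' @examples
#' kendall_distance(c(1, 3, 2), c(2, 1, 3))
#' @export
kendall_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("rankings have different dimensions: ", length(a), " vs ", length(b),
         call. = FALSE)
  }
  m <- length(a)
  if (m < 2L) return(0L)
  da <- sign(outer(a, a, "-"))
  db <- sign(outer(b, b, "-"))
  as.integer(sum(da * db < 0) / 2L)
}

#' Maximum footrule distance in dimension m
#'
#' The largest attainable footrule distance between two permutations of
#' `1:m`, equal to `floor(m^2 / 2)`; it is achieved by the full reversal when
#' `m` is even.
#'
#' @param m Positive integer dimension.
#' @return A positive integer.
#' @examples
#' max_footrule(4)
#' @export
max_footrule <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  as.integer(floor(m^2 / 2))
}

#' Rank vector of a numeric vector
#'
#' Returns \eqn{r_i = \#\{j : x_i \ge x_j\}}, so the smallest value receives
#' rank 1 and tied values receive equal (maximal) counts. With ties the result
#' is not a permutation; callers needing a permutation must break ties.
#'
#' @param x Numeric vector with finite entries.
#' @return Integer vector of the same length.
#' @examples
#' rank_vector(c(0.2, 0.9, 0.5))
#' rank_vector(c(5, 5))
#' @export
rank_vector <- function(x) {
  if (length(x) == 0L) stop("`x` must be non-empty", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("`x` contains missing or non-finite entries", call. = FALSE)
  }
  as.integer(rank(x, ties.method = "max"))
}

#' Restrict a ranking to a subset of items
#'
#' Given a complete ranking of n items and a subset S of m item indices,
#' returns the induced m-dimensional ranking: the items' relative order on S,
#' re-labelled to `1:m`.
#'
#' @param ranking Integer vector, a permutation of `1:n`.
#' @param items Integer vector of distinct item indices in `1:n`.
#' @return Integer vector of length `length(items)`, a permutation of `1:m`,
#'   aligned with `items`.
#' @examples
#' restrict_ranking(c(4, 1, 3, 2, 5), c(1, 3, 5))
#' @export
restrict_ranking <- function(ranking, items) {
  n <- length(ranking)
  if (anyDuplicated(items)) stop("`items` contains duplicated indices", call. = FALSE)
  if (any(items < 1L) || any(items > n)) {
    stop("`items` is not a subset of 1:", n, call. = FALSE)
  }
  as.integer(rank(ranking[items]))
}

#' Test whether a vector is a permutation of 1:m
#'
#' @param x Vector to test.
#' @return `TRUE` if `x` contains each of `1:length(x)` exactly once.
#' @export
is_permutation <- function(x) {
  !anyNA(x) && all(sort(as.integer(x)) == seq_along(x))
}

# Validate a rank matrix (assessors x items): every row a permutation of 1..n,
# unique item labels. Returns an integer matrix with item labels as colnames.
assert_rank_matrix <- function(data) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) stop("`data` must be a matrix or data frame", call. = FALSE)
  storage.mode(data) <- "integer"
  if (is.null(colnames(data))) {
    colnames(data) <- paste0("item", seq_len(ncol(data)))
  }
  if (anyDuplicated(colnames(data))) {
    stop("item labels are not unique", call. = FALSE)
  }
  for (j in seq_len(nrow(data))) {
    if (!is_permutation(data[j, ])) {
      stop("row ", j, " is not a permutation of 1:", ncol(data),
           " (values: ", paste(head(data[j, ], 10L), collapse = ", "),
           if (ncol(data) > 10L) ", ..." else "", ")", call. = FALSE)
    }
  }
  data
}

# Clip the leap parameter into its admissible range [1, m - 1].
default_leap <- function(m) {
  max(1L, min(as.integer(round(m / 5)), max(m - 1L, 1L)))
}
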
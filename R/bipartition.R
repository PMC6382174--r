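# Bipartitions of a channel set: canonical form, enumeration, similarity,
# and JSON interchange.

#' Create a canonical bipartition of `n` channels
#'
#' A bipartition splits channels `1:n` into two disjoint non-empty groups.
#' The canonical form puts the group containing channel 1 first; group labels
#' carry no meaning.
#'
#' @param group1 Integer indices (1-based) of one group.
#' @param n Total number of channels.
#' @return An object of class `phig_bipartition` with elements `group1`,
#'   `group2` and `n`.
#' @examples
#' bipartition(c(2, 4), 5)
#' @export
bipartition <- function(group1, n) {
  n <- as.integer(n)
  group1 <- sort(unique(as.integer(group1)))
  if (n < 2) stop_invalid("a bipartition needs at least 2 channels")
  if (length(group1) == 0 || length(group1) == n) {
    stop_invalid("both groups of a bipartition must be non-empty")
  }
  if (any(group1 < 1) || any(group1 > n)) {
    stop_invalid("`group1` indices must lie in 1..n")
  }
  group2 <- setdiff(seq_len(n), group1)
  if (group2[1] < group1[1]) {
    tmp <- group1; group1 <- group2; group2 <- tmp
  }
  structure(list(group1 = group1, group2 = group2, n = n),
            class = "phig_bipartition")
}

#' @export
print.phig_bipartition <- function(x, ...) {
  cat(sprintf("<phig_bipartition> {%s} | {%s} of %d channels\n",
              paste(x$group1, collapse = ","),
              paste(x$group2, collapse = ","), x$n))
  invisible(x)
}

#' @export
format.phig_bipartition <- function(x, ...) {
  paste(x$group1, collapse = ",")
}

partition_key <- function(p) paste(p$group1, collapse = ",")

same_partition <- function(p1, p2) {
  p1$n == p2$n && identical(p1$group1, p2$group1)
}

#' Enumerate every unordered bipartition of `n` channels
#'
#' Yields each of the `2^(n-1) - 1` canonical bipartitions exactly once
#' (no duplicates under group-label swap). Guarded at `n <= 25` against
#' accidental combinatorial explosion.
#'
#' @param n Channel count, `2 <= n <= 25`.
#' @return A list of `phig_bipartition` objects.
#' @export
enumerate_bipartitions <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1 || n < 2 || n > 25) {
    stop_invalid("`n` must be an integer in [2, 25]")
  }
  rest <- 2:n
  masks <- 0:(2^(n - 1) - 2)
  bits <- vapply(seq_len(n - 1), function(b) bitwAnd(masks, bitwShiftL(1, b - 1)) > 0,
                 logical(length(masks)))
  if (is.null(dim(bits))) bits <- matrix(bits, nrow = 1)
  lapply(seq_along(masks), function(i) {
    g1 <- c(1L, rest[bits[i, ]])
    structure(list(group1 = g1, group2 = setdiff(seq_len(n), g1), n = n),
              class = "phig_bipartition")
  })
}

#' Rand index between two bipartitions
#'
#' Fraction of channel pairs on whose co-assignment the two partitions agree;
#' 1 means the partitions are identical up to group labels.
#'
#' @param p1,p2 `phig_bipartition` objects over the same channel set.
#' @return A number in \[0, 1\].
#' @export
rand_index <- function(p1, p2) {
  stopifnot(inherits(p1, "phig_bipartition"), inherits(p2, "phig_bipartition"))
  if (p1$n != p2$n) stop_invalid("partitions refer to different channel sets")
  n <- p1$n
  m1 <- seq_len(n) %in% p1$group1
  m2 <- seq_len(n) %in% p2$group1
  same1 <- outer(m1, m1, "==")
  same2 <- outer(m2, m2, "==")
  ut <- upper.tri(same1)
  sum(same1[ut] == same2[ut]) / choose(n, 2)
}

#' Read / write a bipartition as JSON
#'
#' The interchange format uses 0-based channel indices:
#' `{"group1": [...], "group2": [...]}`.
#'
#' @param path File path.
#' @param partition A `phig_bipartition`.
#' @return `read_partition_json` returns a `phig_bipartition`;
#'   `write_partition_json` returns `path` invisibly.
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$group1) || is.null(obj$group2)) {
    stop_invalid("partition JSON must contain `group1` and `group2`")
  }
  g1 <- as.integer(obj$group1) + 1L
  g2 <- as.integer(obj$group2) + 1L
  bipartition(g1, length(g1) + length(g2))
}

#' @rdname read_partition_json
#' @export
write_partition_json <- function(partition, path) {
  stopifnot(inherits(partition, "phig_bipartition"))
  jsonlite::write_json(
    list(group1 = partition$group1 - 1L, group2 = partition$group2 - 1L),
    path, auto_unbox = FALSE)
  invisible(path)
}
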
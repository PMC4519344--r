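#' Tree-likeness of one quartet
#'
#' For four taxa the three pairings of pairwise-distance sums
#' `d(x,y)+d(u,v)`, `d(x,u)+d(y,v)`, `d(x,v)+d(y,u)` are sorted as
#' `s1 <= s2 <= s3`.  On an additive (tree) metric the two largest are equal
#' (the four-point condition), so the quartet statistic
#' `(s3 - s2) / (s3 - s1)` is 0; its worst value is 1.  When all three sums
#' tie (e.g. a star metric) the statistic is defined as 0.
#'
#' @param dm symmetric distance matrix with taxa dimnames.
#' @param x,y,u,v four distinct taxa (names or indices).
#' @return a number in `[0, 1]`.
#' @examples
#' dm <- matrix(2, 4, 4) - 2 * diag(4)
#' dimnames(dm) <- list(letters[1:4], letters[1:4])
#' delta_quartet(dm, "a", "b", "c", "d")  # star metric: 0
#' @export
delta_quartet <- function(dm, x, y, u, v) {
  idx <- c(x, y, u, v)
  if (is.character(idx)) idx <- match(idx, rownames(dm))
  if (anyNA(idx) || anyDuplicated(idx)) stop("need four distinct taxa present in dm")
  s <- sort(c(dm[idx[1], idx[2]] + dm[idx[3], idx[4]],
              dm[idx[1], idx[3]] + dm[idx[2], idx[4]],
              dm[idx[1], idx[4]] + dm[idx[2], idx[3]]))
  quartet_delta_from_sums(s[1], s[2], s[3])
}

# relative tolerance for the all-equal tie; distances are ratios of small
# integer counts, so exact ties are common and must map to 0 exactly
quartet_delta_from_sums <- function(s1, s2, s3, tol = 1e-9) {
  l1 <- s3 - s1
  ifelse(l1 <= tol * pmax(s3, 0), 0, (s3 - s2) / l1)
}

#' Mean quartet delta score of a distance matrix
#'
#' Averages [delta_quartet()] over every 4-taxon subset (or a uniform random
#' subsample of quartets for large matrices).  0 means perfectly tree-like
#' (additive) distances; values toward 1 indicate conflicting, network-like
#' signal.  Published reference points for lexical data sets range from about
#' 0.15 (strongly tree-like) to above 0.4 (strongly non-tree-like).
#'
#' @param dm symmetric distance matrix with at least four taxa, e.g. from
#'   [distance_matrix()], [read_phylip_dist()] or [read_binary_nexus()] +
#'   [distance_matrix()].
#' @param subsample `NULL` for the exhaustive average, or a list
#'   `list(k = <number of quartets>, seed = <int>)` to average over a random
#'   subsample.
#' @return an object of class `"delta_result"`: list with `mean_delta`,
#'   `n_quartets`, `per_taxon_delta` (mean over the quartets containing each
#'   taxon) and `mode`.
#' @examples
#' tr <- ape::rtree(8)
#' dm <- ape::cophenetic.phylo(tr)
#' delta_score(dm)$mean_delta  # additive: 0
#' @export
delta_score <- function(dm, subsample = NULL) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 4) stop("delta score needs at least 4 taxa")
  taxa <- rownames(dm)
  if (is.null(taxa)) taxa <- rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))

  if (is.null(subsample)) {
    q <- utils::combn(n, 4)
    mode <- "exhaustive"
  } else {
    stopifnot(is.list(subsample), !is.null(subsample$k))
    k <- as.integer(subsample$k)
    if (!is.null(subsample$seed)) {
      q <- local({
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          get(".Random.seed", envir = globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
        set.seed(as.integer(subsample$seed))
        vapply(seq_len(k), function(i) sample.int(n, 4), integer(4))
      })
    } else {
      q <- vapply(seq_len(k), function(i) sample.int(n, 4), integer(4))
    }
    mode <- sprintf("subsampled(k=%d%s)", k,
                    if (is.null(subsample$seed)) "" else
                      sprintf(", seed=%d", as.integer(subsample$seed)))
  }

  x <- q[1, ]; y <- q[2, ]; u <- q[3, ]; v <- q[4, ]
  p1 <- dm[cbind(x, y)] + dm[cbind(u, v)]
  p2 <- dm[cbind(x, u)] + dm[cbind(y, v)]
  p3 <- dm[cbind(x, v)] + dm[cbind(y, u)]
  s1 <- pmin(p1, p2, p3)
  s3 <- pmax(p1, p2, p3)
  # exact median via min/max (no subtraction, so it agrees bit-for-bit with
  # a sort-based enumeration)
  s2 <- pmax(pmin(p1, p2), pmin(pmax(p1, p2), p3))
  dq <- quartet_delta_from_sums(s1, s2, s3)

  per_taxon <- as.vector(rowsum(rep(dq, 4), group = as.vector(t(q))))
  counts <- tabulate(as.vector(q), nbins = n)
  per_taxon <- ifelse(counts > 0, per_taxon / counts, NA_real_)
  names(per_taxon) <- taxa

  structure(list(mean_delta = mean(dq), n_quartets = ncol(q),
                 per_taxon_delta = per_taxon, mode = mode),
            class = "delta_result")
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("delta score: %.4f over %d quartets (%s)\n",
              x$mean_delta, x$n_quartets, x$mode))
  invisible(x)
}

#' Read a binary character matrix from a NEXUS file
#'
#' Reads a `datatype=standard`, symbols `01` DATA/CHARACTERS block (as
#' written by [write_nexus()] or exported from other lexical databases) into
#' a binary matrix suitable for [distance_matrix()] and [delta_score()].
#'
#' @param path NEXUS file.
#' @return integer matrix, taxa as rownames.
#' @export
read_binary_nexus <- function(path) {
  dat <- ape::read.nexus.data(path)
  m <- t(vapply(dat, function(v) suppressWarnings(as.integer(v)),
                integer(length(dat[[1]]))))
  rownames(m) <- names(dat)
  m
}
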
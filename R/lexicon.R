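#' Binary cognate matrix from a simulation
#'
#' Mirrors how a basic-vocabulary database is coded: for every concept, each
#' cognate still attested anywhere at the final snapshot becomes one binary
#' character, and a dialect scores 1 where it holds the cognate.  Extinct
#' cognates leave no column -- the matrix is a field-study snapshot, not a
#' history.  Columns are ordered by concept, then cognate birth time, then id,
#' so the encoding is deterministic.
#'
#' @param result a [run_simulation()] result.
#' @return an integer matrix of class `"cognate_matrix"`; rows are node ids,
#'   columns are named `c<concept>_g<cognate>`, and the attribute `concept`
#'   maps each column to its concept index.
#' @examples
#' fx <- fixture_topology("bottleneck")
#' p <- fx$params; p$n_concepts <- 4L; p$T <- 100L
#' m <- encode_binary(run_simulation(fx$topology, p, seed = 7))
#' dim(m)
#' @export
encode_binary <- function(result) {
  stopifnot(inherits(result, "sim_result"))
  taxa <- unique(unlist(lapply(result$finals, names)))
  taxa <- result$topology$nodes$id[result$topology$nodes$id %in% taxa]
  cols <- list()
  concept_of <- integer()
  for (k in seq_along(result$finals)) {
    fin <- result$finals[[k]]
    reg <- result$registry[result$registry$concept == k, ]
    alive <- sort(unique(unlist(fin, use.names = FALSE)))
    ord <- order(reg$birth_time[match(alive, reg$cognate_id)], alive)
    alive <- alive[ord]
    block <- vapply(alive, function(g)
      as.integer(taxa %in% names(fin)[vapply(fin, function(v) g %in% v, logical(1))]),
      integer(length(taxa)))
    block <- matrix(block, nrow = length(taxa),
                    dimnames = list(taxa, sprintf("c%03d_g%04d", k, alive)))
    cols[[k]] <- block
    concept_of <- c(concept_of, rep(k, length(alive)))
  }
  m <- do.call(cbind, cols)
  structure(m, concept = concept_of, class = c("cognate_matrix", class(m)))
}

#' Hamming-ratio distance matrix
#'
#' The distance between two dialects is the fraction of binary characters on
#' which they differ, taken jointly across all concepts (each dialect is one
#' long binary vector).
#'
#' @param matrix a [encode_binary()] matrix, or any binary matrix with taxa
#'   as rows.
#' @return a symmetric numeric matrix in `[0, 1]` with zero diagonal and taxa
#'   as dimnames.
#' @examples
#' m <- rbind(a = c(1, 0, 0, 1, 0), b = c(1, 0, 1, 0, 0))
#' distance_matrix(m)["a", "b"]  # 2/5
#' @export
distance_matrix <- function(matrix) {
  m <- unclass(matrix)
  if (is.null(dim(m)) || ncol(m) == 0) stop("matrix has no characters")
  if (nrow(m) < 2) stop("need at least two taxa")
  storage.mode(m) <- "double"
  # Hamming counts for 0/1 data via cross products
  ones <- m %*% t(m)
  zeros <- (1 - m) %*% t((1 - m))
  d <- 1 - (ones + zeros) / ncol(m)
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Cognate survival times
#'
#' Survival time is the number of steps between a cognate's birth and death.
#' Cognates in the initial state (birth time 0) and cognates still alive at
#' the end of the run are excluded, so the summary is not censored by the
#' simulation window.
#'
#' @param registry a registry data frame (from [run_simulation()], possibly
#'   covering many concepts) or a `"sim_result"`.
#' @return integer vector of survival times.
#' @examples
#' reg <- data.frame(cognate_id = 1:3, birth_node = "A",
#'                   birth_time = c(0L, 5L, 8L), death_time = c(NA, 12L, NA))
#' survival_times(reg)  # only the cognate born at 5 and dead at 12 counts
#' @export
survival_times <- function(registry) {
  if (inherits(registry, "sim_result")) registry <- registry$registry
  keep <- registry$birth_time > 0 & !is.na(registry$death_time)
  as.integer(registry$death_time[keep] - registry$birth_time[keep])
}

#' Write / read a square PHYLIP distance matrix
#'
#' Standard lower-plus-upper square PHYLIP format: a line with the number of
#' taxa, then one row per taxon (label, then the full row of distances).
#'
#' @param d symmetric distance matrix with taxa dimnames.
#' @param path output file.
#' @return `write_phylip_dist` returns `path` invisibly; `read_phylip_dist`
#'   returns the matrix.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  taxa <- rownames(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d))) {
    writeLines(paste(c(format(taxa[i], width = 10),
                       sprintf("%.10f", d[i, ])), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_phylip_dist
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  rows <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  taxa <- vapply(rows, `[[`, character(1), 1)
  d <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(d) <- list(taxa, taxa)
  d
}

#' Write a cognate matrix (or any matrix) as CSV with row names
#'
#' @param m matrix to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' Read a binary cognate matrix from CSV (taxa in the first column)
#'
#' @param path CSV file as written by [write_matrix_csv()].
#' @return integer matrix with taxa as rownames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
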
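# Independent oracles and small builders shared across tests.

# Brute-force quartet delta: naive loops, no shared code with delta_score().
brute_delta <- function(dm) {
  n <- nrow(dm)
  vals <- c()
  for (x in 1:(n - 3)) for (y in (x + 1):(n - 2))
    for (u in (y + 1):(n - 1)) for (v in (u + 1):n) {
      s <- sort(c(dm[x, y] + dm[u, v], dm[x, u] + dm[y, v], dm[x, v] + dm[y, u]))
      l1 <- s[3] - s[1]
      vals <- c(vals, if (l1 <= 1e-9 * max(s[3], 0)) 0 else (s[3] - s[2]) / l1)
    }
  mean(vals)
}

# Total variation distance between two discrete laws given as named vectors.
tv_dist <- function(p, q) {
  keys <- union(names(p), names(q))
  p <- p[keys]; q <- q[keys]
  p[is.na(p)] <- 0; q[is.na(q)] <- 0
  sum(abs(p - q)) / 2
}

empirical_law <- function(draws) {
  tab <- table(vapply(draws, function(v) paste(sort(v), collapse = ","), ""))
  p <- as.numeric(tab) / length(draws)
  names(p) <- names(tab)
  p
}

random_distance_matrix <- function(n, seed) {
  set.seed(seed)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 1)
  d <- d + t(d)
  dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
  d
}

# Two connected toy topologies reused across dynamics tests.
toy_pair <- function() {
  make_topology(
    nodes = data.frame(id = c("A", "B"), population = c(1, 1)),
    edges = data.frame(i = "A", j = "B", distance = 1)
  )
}

toy_triangle <- function(pops = c(2, 1, 1)) {
  make_topology(
    nodes = data.frame(id = c("A", "B", "C"), population = pops),
    edges = data.frame(i = c("A", "B", "C"), j = c("B", "C", "A"),
                       distance = c(1, 1, 1))
  )
}

# Hand-built simulation result for exact encoding tests.
fake_sim_result <- function(topology, finals, registry) {
  structure(list(topology = topology,
                 params = sim_params(s = 1, b = 1, d = 3,
                                     T = 10, n_concepts = length(finals)),
                 seed = 0L, finals = finals, registry = registry),
            class = "sim_result")
}
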
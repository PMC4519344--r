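#' Build a spatial contact network
#'
#' A topology is the spatial scaffold of the simulation: dialects are nodes
#' with a population size, contact is a weighted undirected edge whose weight
#' is a geographic (or social) distance, and the node set may grow over time
#' through timed copy events (a colony founded as an exact copy of an existing
#' dialect).
#'
#' @param nodes data frame with columns `id` (character, unique) and
#'   `population` (positive numeric).
#' @param edges data frame with columns `i`, `j` (node ids) and `distance`
#'   (positive numeric); undirected, one record per pair, no self loops.
#' @param events optional list of events created by [copy_event()]. Event
#'   target nodes must be listed in `nodes` (they carry their population
#'   there) but are absent from the network until their event fires.
#'
#' @return an object of class `"topology"`: a list with elements `nodes`,
#'   `edges`, `events` and the derived adjacency list `neighbors`.
#' @examples
#' topo <- make_topology(
#'   nodes = data.frame(id = c("A", "B"), population = c(1, 1)),
#'   edges = data.frame(i = "A", j = "B", distance = 1)
#' )
#' topo$neighbors
#' @seealso [fixture_topology()], [influence_weights()]
#' @export
make_topology <- function(nodes, edges, events = list()) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "population") %in% names(nodes)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (any(!is.finite(nodes$population) | nodes$population <= 0))
    stop("populations must be positive")

  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(i = character(), j = character(), distance = numeric())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("i", "j", "distance") %in% names(edges)))
  edges$i <- as.character(edges$i); edges$j <- as.character(edges$j)
  unknown <- setdiff(c(edges$i, edges$j), nodes$id)
  if (length(unknown))
    stop("edge endpoint not among nodes: ", paste(unknown, collapse = ", "))
  if (any(edges$i == edges$j))
    stop("self loops are not allowed; self influence is the parameter s")
  if (any(!is.finite(edges$distance) | edges$distance <= 0))
    stop("edge distances must be positive")
  key <- apply(cbind(pmin(edges$i, edges$j), pmax(edges$i, edges$j)), 1, paste, collapse = "\r")
  if (anyDuplicated(key)) stop("duplicate edge between a node pair")

  events <- lapply(events, validate_event, node_ids = nodes$id, edges = edges)
  if (length(events) > 1)
    events <- events[order(vapply(events, `[[`, numeric(1), "time"))]

  founding <- setdiff(nodes$id, vapply(events, `[[`, character(1), "target"))
  nbr <- neighbor_sets(nodes$id, edges)
  structure(
    list(nodes = nodes, edges = edges, events = events, neighbors = nbr,
         founding = founding),
    class = "topology"
  )
}

validate_event <- function(ev, node_ids, edges) {
  stopifnot(is.list(ev))
  needed <- c("time", "kind", "source", "target")
  if (!all(needed %in% names(ev))) stop("event missing fields: ",
                                        paste(setdiff(needed, names(ev)), collapse = ", "))
  if (!identical(ev$kind, "copy_node")) stop("unknown event kind: ", ev$kind)
  ev$time <- as.integer(ev$time)
  if (ev$time < 1) stop("event time must be >= 1")
  if (!ev$source %in% node_ids) stop("event source not among nodes: ", ev$source)
  if (!ev$target %in% node_ids)
    stop("event target must be declared in nodes (with its population): ", ev$target)
  touching <- edges$i == ev$target | edges$j == ev$target
  if (!any(touching))
    stop("event target ", ev$target, " has no edges; it would be isolated")
  ev
}

neighbor_sets <- function(ids, edges) {
  nbr <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    nbr[[id]] <- sort(unique(c(edges$j[edges$i == id], edges$i[edges$j == id])))
  }
  nbr
}

#' Declare a timed node-copy event
#'
#' At the end of step `time` the `target` node appears as an exact copy of the
#' `source` node's cognate sets for every concept, and participates in the
#' synchronous update from step `time + 1` on.  The target's population and
#' its edges are declared in the parent topology; before the event the target
#' simply does not exist in the network.
#'
#' @param time integer step (>= 1) at whose end the copy happens.
#' @param source,target node ids; `source` must exist from the start.
#' @return a list describing the event, for the `events` argument of
#'   [make_topology()].
#' @export
copy_event <- function(time, source, target) {
  list(time = as.integer(time), kind = "copy_node",
       source = as.character(source), target = as.character(target))
}

#' Simulation hyperparameters
#'
#' @param s self-influence multiplier (>= 0): a node's own weight is
#'   `s * p_i`, so large `s` makes dialects conservative.
#' @param b new-word score multiplier (>= 0): a fresh innovation scores
#'   `b * p_i` at node `i`.
#' @param d cardinality cost (> 1): a candidate set of size `k` is penalized
#'   by `d * k^2`, so synonym-rich states are exponentially unlikely.
#' @param T number of discrete time steps (default 1000).
#' @param n_concepts number of independent basic-vocabulary concepts
#'   simulated (default 100, the size of a Swadesh-style list).
#' @param seed optional integer master seed.
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(s, b, d, T = 1000, n_concepts = 100, seed = NULL) {
  stopifnot(is.numeric(s), length(s) == 1, s >= 0)
  stopifnot(is.numeric(b), length(b) == 1, b >= 0)
  if (!is.numeric(d) || length(d) != 1 || d <= 1)
    stop("cardinality cost d must be > 1")
  T <- as.integer(T); stopifnot(T >= 0)
  n_concepts <- as.integer(n_concepts); stopifnot(n_concepts >= 1)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(s = s, b = b, d = d, T = T, n_concepts = n_concepts, seed = seed),
            class = "sim_params")
}

#' @export
print.topology <- function(x, ...) {
  cat("contact topology:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges")
  if (length(x$events))
    cat(",", length(x$events), "timed event(s)")
  cat("\n")
  invisible(x)
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("sim_params: s=%g b=%g d=%g T=%d concepts=%d seed=%s\n",
              x$s, x$b, x$d, x$T, x$n_concepts,
              if (is.null(x$seed)) "unset" else x$seed))
  invisible(x)
}

#' Influence-weight matrix of a topology
#'
#' The influence of node `j` on node `i` is `p_j / d_ij^2` when they are
#' neighbors, `s * p_i` when `j = i`, and 0 otherwise.  Influence grows with
#' the neighbor's population and decays with the square of distance; the
#' matrix is generally asymmetric because populations differ.
#'
#' @param topology a [make_topology()] object.
#' @param s self-influence multiplier (>= 0).
#' @return a square numeric matrix with node ids as dimnames; rows index the
#'   influenced node `i`, columns the influencing node `j`.
#' @examples
#' topo <- fixture_topology("star")
#' w <- influence_weights(topo$topology, s = 2)
#' w["B", "A"]  # the center's pull on a periphery
#' @export
influence_weights <- function(topology, s) {
  stopifnot(inherits(topology, "topology"), is.numeric(s), s >= 0)
  ids <- topology$nodes$id
  p <- stats::setNames(topology$nodes$population, ids)
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(w) <- s * p
  e <- topology$edges
  if (nrow(e)) {
    ii <- match(e$i, ids); jj <- match(e$j, ids)
    w[cbind(ii, jj)] <- p[e$j] / e$distance^2
    w[cbind(jj, ii)] <- p[e$i] / e$distance^2
  }
  w
}

#' Load a topology + parameters from a YAML/JSON-style config
#'
#' The config maps directly onto the domain model:
#' ```yaml
#' nodes:  [{id: A, population: 10}, ...]
#' edges:  [{i: A, j: B, distance: 1.0}, ...]
#' events: [{time: 750, kind: copy_node, source: A, target: B}]
#' params: {s: 4.0, b: 0.1, d: 3.0, T: 1000, n_concepts: 100}
#' ```
#'
#' @param path path to a YAML file.
#' @return a list with elements `topology` and `params` (`params` is `NULL`
#'   when the file has no params block).
#' @export
read_topology_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$nodes)) stop("config has no nodes block: ", path)
  nodes <- do.call(rbind, lapply(cfg$nodes, function(x)
    data.frame(id = as.character(x$id), population = as.numeric(x$population))))
  edges <- if (length(cfg$edges)) {
    do.call(rbind, lapply(cfg$edges, function(x)
      data.frame(i = as.character(x$i), j = as.character(x$j),
                 distance = as.numeric(x$distance))))
  } else NULL
  events <- if (length(cfg$events)) cfg$events else list()
  topo <- make_topology(nodes, edges, events)
  params <- NULL
  if (!is.null(cfg$params)) {
    pp <- cfg$params
    params <- sim_params(s = pp$s, b = pp$b, d = pp$d,
                         T = if (is.null(pp$T)) 1000 else pp$T,
                         n_concepts = if (is.null(pp$n_concepts)) 100 else pp$n_concepts,
                         seed = pp$seed)
  }
  list(topology = topo, params = params)
}

#' Built-in network topologies
#'
#' Five ready-made contact networks, shipped as editable YAML configs under
#' `system.file("extdata", "fixtures", package = "dialectsim")`:
#'
#' * `grid`: 3x3 lattice of equal populations (rook adjacency) -- a spatially
#'   non-tree-like structure (s=4, b=1, d=3).
#' * `star`: one large center (population 10) with 8 small peripheries --
#'   spatially tree-like without any bottleneck (s=2, b=0.1, d=3).
#' * `two_stars`: two large centers, four exclusive peripheries each, plus
#'   two shared nodes H and K equidistant from both centers (s=2, b=1, d=3).
#' * `bottleneck`: two internally well-connected clusters (A-E and F-G-H)
#'   joined by a single long bridge edge E-F (s=4, b=0.1, d=3).
#' * `colony`: a bottleneck-style ten-node layout where at step 750 node B is
#'   created as a copy of western node A, with a large population and edges
#'   into the eastern cluster (s=4, b=0.1, d=3).
#'
#' @param name one of `"grid"`, `"star"`, `"two_stars"`, `"bottleneck"`,
#'   `"colony"`.
#' @return a list with elements `topology` and `params` (the published
#'   hyperparameters for that topology; `T = 1000`, 100 concepts).
#' @examples
#' fx <- fixture_topology("grid")
#' fx$topology
#' fx$params
#' @export
fixture_topology <- function(name) {
  name <- match.arg(name, fixture_names())
  path <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                      package = "dialectsim", mustWork = TRUE)
  read_topology_config(path)
}

#' @rdname fixture_topology
#' @export
fixture_names <- function() c("grid", "star", "two_stars", "bottleneck", "colony")
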
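#' @useDynLib dialectsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_word_token <- function(node, t) sprintf(".new|%s|%d", node, t)

is_new_word <- function(c) startsWith(c, ".new|")

#' Initial network state
#'
#' At time 0 every founding node holds the same single cognate for the
#' concept; nodes created later by copy events are absent until their event
#' fires.
#'
#' @param topology a [make_topology()] object.
#' @param initial id to use for the shared initial cognate.
#' @return a `"network_state"`: list with step counter `t` and `V`, a named
#'   list mapping node id to its (non-empty) set of cognate ids.
#' @export
network_state <- function(topology, initial = "c1") {
  V <- stats::setNames(rep(list(initial), length(topology$founding)),
                       topology$founding)
  structure(list(t = 0L, V = V), class = "network_state")
}

#' Candidate cognates for a node's next state
#'
#' The candidates at step `t` are one fresh new-word token plus everything
#' the node and its neighbors held at step `t - 1`.  A node proposes at most
#' one new cognate per step; the token's id is unique to (node, step).
#'
#' @param state the `t - 1` [network_state()].
#' @param node node id present in the state.
#' @param topology the contact topology.
#' @param params optional [sim_params()]; when given and `b * p_i` is zero,
#'   innovation is disabled and no fresh token is offered.
#' @return character vector of candidate ids; the fresh token is
#'   distinguishable via its `.new|` prefix.
#' @export
candidate_set <- function(state, node, topology, params = NULL) {
  if (!node %in% names(state$V))
    stop("node absent from network at step ", state$t, ": ", node)
  nbr <- intersect(topology$neighbors[[node]], names(state$V))
  existing <- sort(unique(unlist(state$V[c(node, nbr)], use.names = FALSE)))
  offer_new <- TRUE
  if (!is.null(params)) {
    p_i <- topology$nodes$population[match(node, topology$nodes$id)]
    offer_new <- params$b * p_i > 0
  }
  c(if (offer_new) new_word_token(node, state$t + 1L), existing)
}

#' Score of a single candidate cognate
#'
#' An existing cognate `c` scores the sum, over the node itself and its
#' neighbors that held `c` at `t - 1`, of the influence weight divided by the
#' holder's set size; sharing a cognate with many or influential neighbors
#' makes keeping it attractive, but synonyms dilute each holder's
#' contribution.  The fresh new-word token scores `b * p_i`.
#'
#' @param c candidate id (possibly the fresh token).
#' @param node node id.
#' @param state the `t - 1` [network_state()].
#' @param topology the contact topology.
#' @param weights [influence_weights()] matrix for the current `s`.
#' @param params [sim_params()] (supplies `b`).
#' @return a non-negative number.
#' @export
cognate_score <- function(c, node, state, topology, weights, params) {
  if (is_new_word(c)) {
    p_i <- topology$nodes$population[match(node, topology$nodes$id)]
    return(params$b * p_i)
  }
  holders <- intersect(c(node, topology$neighbors[[node]]), names(state$V))
  holders <- holders[vapply(state$V[holders], function(v) c %in% v, logical(1))]
  if (!length(holders))
    stop("cognate ", c, " is not a candidate at node ", node)
  sum(weights[node, holders] / lengths(state$V[holders]))
}

candidate_scores <- function(state, node, topology, weights, params) {
  cand <- candidate_set(state, node, topology, params)
  vapply(cand, cognate_score, numeric(1),
         node = node, state = state, topology = topology,
         weights = weights, params = params)
}

#' Score of a candidate set of cognates
#'
#' `sscore(v) = sum_{c in v} (wscore(c) - d |v|)`, i.e. the summed cognate
#' scores minus the quadratic cardinality penalty `d |v|^2`.
#'
#' @param v non-empty character vector of candidate ids.
#' @param scores named numeric vector of cognate scores covering `v`.
#' @param d cardinality cost (> 1).
#' @return a real number (typically negative for large sets).
#' @export
set_score <- function(v, scores, d) {
  if (!length(v)) stop("the empty set is not a valid state")
  sum(scores[v]) - d * length(v)^2
}

subset_key <- function(v) paste(sort(v), collapse = ",")

#' Exact distribution over non-empty candidate subsets
#'
#' Enumerates all `2^n - 1` non-empty subsets of the candidates and returns
#' their normalized probabilities `exp(sscore(v)) / sum exp(sscore(v'))`.
#' This is the brute-force oracle for [sample_subset()]; it refuses more than
#' `cap` candidates, above which only the factorized sampler is practical.
#'
#' @param scores named numeric vector of cognate scores.
#' @param d cardinality cost (> 1).
#' @param cap enumeration cap on the number of candidates (default 15).
#' @return named numeric vector of probabilities, one entry per non-empty
#'   subset; names are the comma-joined sorted member ids.
#' @examples
#' subset_distribution(c(c1 = 2, c2 = 1), d = 3)
#' @export
subset_distribution <- function(scores, d, cap = 15L) {
  n <- length(scores)
  if (n == 0) stop("no candidates")
  if (n > cap) stop("candidate count ", n, " above enumeration cap ", cap,
                    "; use sample_subset()")
  ids <- names(scores)
  if (is.null(ids)) ids <- paste0("c", seq_len(n))
  masks <- seq_len(2^n - 1)
  member <- vapply(seq_len(n), function(i) bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0,
                   logical(length(masks)))
  member <- matrix(member, nrow = length(masks))
  sizes <- rowSums(member)
  ssc <- as.vector(member %*% unname(scores)) - d * sizes^2
  pr <- exp(ssc - max(ssc))
  pr <- pr / sum(pr)
  names(pr) <- apply(member, 1, function(row) subset_key(ids[row]))
  pr
}

#' Sample the next cognate set
#'
#' Draws from the same distribution that [subset_distribution()] enumerates,
#' without enumerating: the target factorizes as
#' `P(v) = exp(-d |v|^2) * prod_{c in v} exp(wscore(c))`, so the set size `k`
#' is drawn with weight `e_k(x_1..x_n) * exp(-d k^2)` (elementary symmetric
#' polynomials of `x_c = exp(wscore(c))`) and then a `k`-subset with
#' probability proportional to the product of its `x_c`.
#'
#' @param scores named numeric vector of cognate scores.
#' @param d cardinality cost (> 1).
#' @param n number of independent draws.
#' @param seed optional integer; when `NULL` a seed is drawn from R's RNG so
#'   `set.seed()` governs reproducibility.
#' @return a list of `n` character vectors (subsets of `names(scores)`).
#' @examples
#' set.seed(1)
#' table(vapply(sample_subset(c(a = 2, b = 1), d = 3, n = 1000),
#'              paste, collapse = ",", FUN.VALUE = ""))
#' @export
sample_subset <- function(scores, d, n = 1L, seed = NULL) {
  if (!length(scores)) stop("no candidates")
  ids <- names(scores)
  if (is.null(ids)) ids <- paste0("c", seq_along(scores))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  draws <- .sample_subset_cpp(as.numeric(scores), d, as.integer(n), as.integer(seed))
  lapply(draws, function(idx) ids[idx])
}

#' One synchronous network update (reference implementation)
#'
#' Every node's new set is sampled from candidates built exclusively from the
#' `t - 1` state, so the update order of nodes cannot matter.  This pure-R
#' path mirrors the compiled loop used by [run_concept()] and exists for
#' inspection and testing; deaths are recorded in the registry at the first
#' step a cognate is held by no node.
#'
#' @param state the `t - 1` [network_state()].
#' @param topology,weights,params as in [cognate_score()].
#' @param registry data frame with columns `cognate_id`, `birth_node`,
#'   `birth_time`, `death_time` (NA while alive).
#' @param seed optional integer seed governing this step's draws.
#' @return list with the step-`t` `state` and the updated `registry`.
#' @export
step_network <- function(state, topology, weights, params, registry, seed = NULL) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  nodes <- names(state$V)
  newV <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_along(nodes)) {
    node <- nodes[k]
    sc <- candidate_scores(state, node, topology, weights, params)
    # per-node substream: the draw cannot depend on the sweep order
    pick <- sample_subset(sc, params$d, n = 1L,
                          seed = (seed + 7919L * k) %% .Machine$integer.max)[[1]]
    fresh <- pick[is_new_word(pick)]
    if (length(fresh)) {
      id <- sprintf("g%d", nrow(registry) + 1L)
      registry <- rbind(registry, data.frame(
        cognate_id = id, birth_node = node,
        birth_time = state$t + 1L, death_time = NA_integer_))
      pick[is_new_word(pick)] <- id
    }
    newV[[k]] <- sort(pick)
  }
  t_now <- state$t + 1L
  present <- unique(unlist(newV, use.names = FALSE))
  died <- is.na(registry$death_time) & !(registry$cognate_id %in% present)
  registry$death_time[died] <- t_now
  list(state = structure(list(t = t_now, V = newV), class = "network_state"),
       registry = registry)
}

#' Empty cognate registry
#'
#' @param initial id of the shared initial cognate (birth time 0).
#' @return data frame with one row per cognate ever born.
#' @export
new_registry <- function(initial = "c1") {
  data.frame(cognate_id = initial, birth_node = NA_character_,
             birth_time = 0L, death_time = NA_integer_)
}

#' Simulate one concept for T steps
#'
#' Runs the full discrete-time chain for a single basic-vocabulary concept:
#' all founding nodes start from one shared cognate, every step resamples all
#' nodes synchronously, timed copy events fire at the end of their step, and
#' the registry records each cognate's birth node/time and (if it goes
#' extinct) death time.  The loop is compiled; one fixture-sized concept runs
#' in milliseconds.
#'
#' @param topology a [make_topology()] object.
#' @param params a [sim_params()] object.
#' @param seed integer seed for this concept (defaults to `params$seed`, or a
#'   draw from R's RNG when both are `NULL`).
#' @param keep_history keep the per-step states (list of per-node sets, one
#'   entry per step)?  Memory grows linearly in `T`.
#' @return list with elements
#'   * `final`: named list, node id -> integer vector of cognate ids held at
#'     `T` (id 1 is the initial cognate); event nodes that never activated
#'     are absent,
#'   * `registry`: data frame `cognate_id`, `birth_node`, `birth_time`,
#'     `death_time` (`NA` = still alive at `T`),
#'   * `history` (optional): list of per-step snapshots.
#' @examples
#' fx <- fixture_topology("star")
#' run <- run_concept(fx$topology, fx$params, seed = 1)
#' lengths(run$final)
#' @export
run_concept <- function(topology, params, seed = NULL, keep_history = FALSE) {
  stopifnot(inherits(topology, "topology"), inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  ids <- topology$nodes$id
  w <- influence_weights(topology, params$s)
  active_from <- integer(length(ids))
  copy_src <- rep(-1L, length(ids))
  for (ev in topology$events) {
    k <- match(ev$target, ids)
    active_from[k] <- ev$time
    copy_src[k] <- match(ev$source, ids) - 1L
  }
  res <- .run_concept_cpp(w, topology$nodes$population, active_from, copy_src,
                          params$b, params$d, params$T, as.integer(seed),
                          isTRUE(keep_history))
  fin <- stats::setNames(res$final, ids)
  fin <- fin[lengths(fin) > 0]  # drop never-activated event nodes
  registry <- data.frame(cognate_id = res$cognate_id,
                         birth_node = ifelse(is.na(res$birth_node), NA_character_,
                                             ids[res$birth_node]),
                         birth_time = res$birth_time,
                         death_time = res$death_time)
  out <- list(final = fin, registry = registry)
  if (keep_history)
    out$history <- lapply(res$history, function(snap) stats::setNames(snap, ids))
  out
}

#' Simulate all concepts
#'
#' Repeats [run_concept()] independently for each of the `n_concepts`
#' basic-vocabulary concepts, with per-concept seeds derived deterministically
#' from the master seed (so the result does not depend on execution order).
#'
#' @param topology a [make_topology()] object.
#' @param params a [sim_params()] object; `params$seed` (or `seed`) makes the
#'   whole result reproducible.
#' @param seed optional master seed overriding `params$seed`.
#' @return an object of class `"sim_result"`: list with `topology`, `params`,
#'   `seed`, `finals` (per-concept final snapshots) and `registry` (single
#'   data frame with a `concept` column).
#' @examples
#' fx <- fixture_topology("bottleneck")
#' p <- fx$params; p$n_concepts <- 5L; p$T <- 50L
#' sim <- run_simulation(fx$topology, p, seed = 42)
#' sim
#' @export
run_simulation <- function(topology, params, seed = NULL) {
  stopifnot(inherits(topology, "topology"), inherits(params, "sim_params"))
  if (is.null(seed)) seed <- params$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seed <- as.integer(seed)
  cseeds <- derive_seeds(seed, params$n_concepts)
  runs <- lapply(seq_len(params$n_concepts), function(k)
    run_concept(topology, params, seed = cseeds[k]))
  registry <- do.call(rbind, lapply(seq_along(runs), function(k)
    cbind(concept = k, runs[[k]]$registry)))
  structure(list(topology = topology, params = params, seed = seed,
                 finals = lapply(runs, `[[`, "final"), registry = registry),
            class = "sim_result")
}

# Deterministic per-concept substreams from one master seed, independent of
# the caller's RNG state.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' @export
print.sim_result <- function(x, ...) {
  nb <- sum(x$registry$birth_time > 0)
  nd <- sum(!is.na(x$registry$death_time))
  cat(sprintf("sim_result: %d nodes, %d concepts, T=%d, seed=%d\n",
              length(x$finals[[1]]), x$params$n_concepts, x$params$T, x$seed))
  cat(sprintf("  %d cognates born, %d died, %d alive at T\n",
              nb, nd, nrow(x$registry) - nd))
  invisible(x)
}
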
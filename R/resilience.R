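#' Normalized Shannon entropy of component sizes
#'
#' Fragmentation entropy of a partition of N nodes into connected components:
#' \eqn{S = -\frac{1}{\log N}\sum_i p_i \log p_i} with \eqn{p_i = n_i/N}.
#' Equals 0 for a single component and 1 when every node is isolated.
#'
#' @param component_sizes integer vector of component sizes (all >= 1)
#' @param N total node count (>= 2); sizes must sum to N
#' @return entropy in \[0, 1\]
#' @export
shannon_diversity <- function(component_sizes, N) {
  if (N < 2) stop("normalization undefined for N < 2")
  if (any(component_sizes < 1)) stop("component sizes must be >= 1")
  if (sum(component_sizes) != N) stop("component sizes must sum to N")
  p <- component_sizes / N
  -sum(p * log(p)) / log(N)
}

#' Build a node-removal schedule
#'
#' Random schedules are uniform permutations. Targeted schedules order nodes
#' by a static, intact-network score (degree or local clustering coefficient),
#' descending, with ties permuted uniformly at random. `degree_adaptive`
#' recomputes degrees as removal proceeds and always takes the node with the
#' highest current degree — the two are equivalent in intent but not in
#' effect (on a regular graph the static order is all ties, i.e. random,
#' while the adaptive attack still finds structure). `custom` orders by the
#' supplied per-node score.
#'
#' @param net igraph network
#' @param scheme one of `"random"`, `"degree"`, `"degree_adaptive"`,
#'   `"clustering"`, `"custom"`
#' @param seed integer seed controlling the permutation / tie-breaking
#' @param aux named numeric vector of per-node scores (required for `custom`)
#' @return object of class `removal_schedule`: list with `order` (character
#'   vector of node names covering the network), `scheme`, `seed`
#' @export
build_schedule <- function(net, scheme = c("random", "degree", "degree_adaptive",
                                           "clustering", "custom"),
                           seed = 1L, aux = NULL) {
  scheme <- match.arg(scheme)
  nms <- node_names(net)
  n <- length(nms)
  if (scheme == "degree_adaptive") {
    old <- local_seed(seed)
    perm <- sample.int(n)
    restore_seed(old)
    el <- igraph::as_edgelist(net, names = FALSE)
    ord <- adaptive_degree_order_cpp(as.integer(el[, 1]), as.integer(el[, 2]),
                                     as.integer(perm), n)
    return(structure(list(order = nms[ord], scheme = scheme,
                          seed = as.integer(seed)),
                     class = "removal_schedule"))
  }
  score <- switch(scheme,
    random = NULL,
    degree = igraph::degree(net),
    clustering = igraph::transitivity(net, type = "localundirected", isolates = "zero"),
    custom = {
      if (is.null(aux)) stop("custom scheme requires per-node scores in `aux`")
      as.numeric(aux[nms])
    }
  )
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  perm <- sample.int(n)
  ord <- if (is.null(score)) perm else perm[order(-score[perm])]
  structure(list(order = nms[ord], scheme = scheme, seed = as.integer(seed)),
            class = "removal_schedule")
}

#' Fragmentation-entropy curve along a removal schedule
#'
#' Step k isolates the k-th node of the schedule: its remaining incident
#' edges are deleted and it stays as a size-1 component; the entropy
#' denominator N is the constant original node count. S is recorded on the
#' grid f = k/N, k = 0..N. Internally the schedule is processed in reverse
#' with incremental component merging, so one curve costs O((N+E) alpha).
#'
#' @param net igraph network (N >= 2)
#' @param schedule a `removal_schedule` covering every node of `net`
#' @return object of class `frag_curve`: list with `f`, `S`, `N`, `scheme`
#' @export
fragmentation_curve <- function(net, schedule) {
  n <- igraph::vcount(net)
  idx <- match(schedule$order, node_names(net))
  if (anyNA(idx) || length(idx) != n || anyDuplicated(idx) > 0) {
    stop("schedule must be a permutation of the network's nodes")
  }
  el <- igraph::as_edgelist(net, names = FALSE)
  S <- frag_curve_cpp(as.integer(el[, 1]), as.integer(el[, 2]),
                      as.integer(idx), n)
  structure(list(f = seq(0, n) / n, S = S, N = n, scheme = schedule$scheme),
            class = "frag_curve")
}

#' Resilience integral of a fragmentation curve
#'
#' \eqn{R = 1 - \int_0^1 S(f) df} by the composite trapezoid rule on the
#' recorded (f, S) points.
#'
#' @param curve a `frag_curve`
#' @return resilience in \[0, 1\]
#' @export
integrate_resilience <- function(curve) {
  f <- curve$f; S <- curve$S
  1 - sum(diff(f) * (S[-length(S)] + S[-1]) / 2)
}

#' Maximum attainable resilience at a given size
#'
#' Evaluates the fully-connected-limit entropy curve
#' \eqn{S(k/N) = k/N + \frac{N-k}{N}\frac{\log(N/(N-k))}{\log N}}
#' on the discrete removal grid and returns one minus its trapezoidal
#' integral. The continuum limit is \eqn{1/2 - 1/(4 \log N)}, approaching
#' 0.5 as N grows.
#'
#' @param N node count (>= 2)
#' @return maximum resilience
#' @export
ideal_max_resilience <- function(N) {
  stopifnot(N >= 2)
  k <- 0:(N - 1)
  S <- k / N + ((N - k) / N) * log(N / (N - k)) / log(N)
  S <- c(S, 1)
  1 - sum((S[-length(S)] + S[-1]) / 2) / N
}

#' Fragmentation curve under node-plus-first-neighbor removal
#'
#' Repeatedly selects the highest-priority node not yet isolated and isolates
#' it together with all of its still-remaining neighbors in one step; (f, S)
#' is recorded after each step, so the f spacing is irregular. Priorities
#' follow the same schemes as [build_schedule()].
#'
#' @inheritParams build_schedule
#' @param counts a `mutation_counts` object (required for the
#'   `mutation_frequency` priority)
#' @return a `frag_curve` with irregular `f`
#' @export
neighborhood_fragmentation_curve <- function(net, scheme = "random", seed = 1L,
                                             aux = NULL, counts = NULL) {
  n <- igraph::vcount(net)
  sched <- schedule_for(net, scheme, seed, aux, counts)
  prio <- match(sched$order, node_names(net))
  el <- igraph::as_edgelist(net, names = FALSE)
  grp <- neighborhood_groups_cpp(as.integer(el[, 1]), as.integer(el[, 2]),
                                 as.integer(prio), n)
  S_full <- frag_curve_cpp(as.integer(el[, 1]), as.integer(el[, 2]),
                           as.integer(grp$order), n)
  bnd <- cumsum(grp$group_sizes)
  structure(list(f = c(0, bnd / n), S = c(S_full[1], S_full[bnd + 1]),
                 N = n, scheme = paste0("neighborhood_", scheme)),
            class = "frag_curve")
}

#' Replicate resilience estimate for a network or a null-model ensemble
#'
#' For a fixed network, runs `n_reps` schedule seeds. For a [null_config()]
#' source, samples `n_networks` independent networks and runs `n_reps`
#' schedule seeds on each, pooling all runs. A single master seed spawns
#' per-network and per-replicate child seeds through one seeded draw, so
#' results are fully reproducible.
#'
#' @param net_source an igraph network or a `null_config`
#' @param scheme `"random"`, `"degree"`, `"clustering"`,
#'   `"mutation_frequency"` (requires `counts`), or `"custom"` (requires `aux`)
#' @param n_networks networks to sample (ignored for a fixed network)
#' @param n_reps schedule replicates per network
#' @param seed master seed
#' @param aux per-node scores for `custom`
#' @param counts a `mutation_counts` object for `mutation_frequency`
#' @param neighborhood if `TRUE`, use node-plus-first-neighbor removal
#' @return object of class `resilience_estimate`: `mean_R`, `sem`, `n_reps`
#'   (total runs), `per_rep_R`, `scheme`, `network_label`
#' @export
estimate_resilience <- function(net_source, scheme = "random",
                                n_networks = 1L, n_reps = 100L, seed = 1L,
                                aux = NULL, counts = NULL,
                                neighborhood = FALSE) {
  fixed <- igraph::is_igraph(net_source)
  if (fixed) n_networks <- 1L
  old <- local_seed(seed)
  net_seeds <- sample.int(.Machine$integer.max - 1L, n_networks)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_networks * n_reps),
                      nrow = n_networks)
  restore_seed(old)

  per_rep <- numeric(0)
  for (i in seq_len(n_networks)) {
    net <- if (fixed) net_source else generate_null(net_source, seed = net_seeds[i])
    for (j in seq_len(n_reps)) {
      rs <- rep_seeds[i, j]
      curve <- if (neighborhood) {
        neighborhood_fragmentation_curve(net, scheme, seed = rs, aux = aux,
                                         counts = counts)
      } else {
        sched <- schedule_for(net, scheme, rs, aux, counts)
        fragmentation_curve(net, sched)
      }
      per_rep <- c(per_rep, integrate_resilience(curve))
    }
  }
  label <- if (fixed) {
    lbl <- igraph::graph_attr(net_source, "name")
    if (is.null(lbl)) "network" else lbl
  } else {
    net_source$model
  }
  structure(list(
    mean_R = mean(per_rep),
    sem = if (length(per_rep) > 1) sd(per_rep) / sqrt(length(per_rep)) else 0,
    n_reps = length(per_rep),
    per_rep_R = per_rep,
    scheme = scheme,
    network_label = label
  ), class = "resilience_estimate")
}

# scheme dispatch shared by estimate_resilience and the impact module
schedule_for <- function(net, scheme, seed, aux = NULL, counts = NULL) {
  if (scheme == "mutation_frequency") {
    if (is.null(counts)) stop("mutation_frequency scheme requires `counts`")
    mutation_order_schedule(counts, seed = seed)
  } else {
    build_schedule(net, scheme, seed = seed, aux = aux)
  }
}

#' Welch comparison of two resilience estimates
#'
#' Two-sample Welch t test on the per-replicate resilience values.
#'
#' @param a,b `resilience_estimate` objects with at least 2 replicates each
#' @return list with `difference` (mean R of `a` minus `b`), `t_statistic`,
#'   `p_value`, `ci95`
#' @export
compare_estimates <- function(a, b) {
  x <- a$per_rep_R; y <- b$per_rep_R
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 replicates on each side")
  diff <- mean(x) - mean(y)
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate deterministic runs: no sampling variance
    return(list(difference = diff,
                t_statistic = if (diff == 0) 0 else sign(diff) * Inf,
                p_value = if (diff == 0) 1 else 0,
                ci95 = c(diff, diff)))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(difference = diff,
       t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       ci95 = unname(tt$conf.int))
}

#' @export
print.resilience_estimate <- function(x, ...) {
  cat(sprintf("Resilience estimate [%s, %s]: mean R = %.6f (sem %.2g, %d runs)\n",
              x$network_label, x$scheme, x$mean_R, x$sem, x$n_reps))
  invisible(x)
}

#' @export
print.frag_curve <- function(x, ...) {
  cat(sprintf("Fragmentation curve [%s]: N = %d, %d points, R = %.4f\n",
              x$scheme, x$N, length(x$f), integrate_resilience(x)))
  invisible(x)
}

# --- internal seed helpers ------------------------------------------------

node_names <- function(net) {
  nms <- igraph::V(net)$name
  if (is.null(nms)) as.character(seq_len(igraph::vcount(net))) else nms
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
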
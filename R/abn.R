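# Additive Bayesian network structure learning. Each node's conditional
# distribution is a GLM of the node on its parents (identity link for
# gaussian nodes, logit for bernoulli nodes); the network score is the sum
# of BIC-penalized node log-likelihoods, maximized by greedy hill climbing
# over add/delete/reverse moves, repeated from random restarts; edges
# present in a majority of the locally optimal networks form the consensus.

#' Node specifications for a Bayesian network
#'
#' @param names node (column) names, in data order.
#' @param dists per-node distribution: `"gaussian"` or `"bernoulli"`.
#' @param no_parents names of nodes constrained to have no parents
#'   (e.g. a genotype node, fixed at conception).
#' @return data.frame of class `node_specs`.
#' @export
node_specs <- function(names, dists, no_parents = character(0)) {
  dists <- match.arg(dists, c("gaussian", "bernoulli"), several.ok = TRUE)
  dists <- rep(dists, length.out = length(names))
  if (anyDuplicated(names)) stop("duplicate node names")
  bad <- setdiff(no_parents, names)
  if (length(bad)) stop("unknown node(s) in no_parents: ",
                        paste(bad, collapse = ", "))
  structure(data.frame(name = names, dist = dists,
                       no_parents = names %in% no_parents,
                       stringsAsFactors = FALSE),
            class = c("node_specs", "data.frame"))
}

#' BIC-penalized node score
#'
#' Fits the child's GLM on its parents and returns
#' `logLik - (k/2) * log(n)`, with `k` the number of estimated parameters
#' (non-aliased coefficients, plus the variance for gaussian nodes).
#' Aliased (collinear) parent columns are dropped by the fit and flagged;
#' complete separation in a logistic fit yields a finite flagged score
#' rather than an error.
#'
#' @param child child node name.
#' @param parents character vector of parent names (may be empty).
#' @param data data.frame of node values (bernoulli nodes coded 0/1).
#' @param specs a [node_specs()].
#' @return scalar score with attributes `k` and `flag`.
#' @export
node_score <- function(child, parents, data, specs) {
  if (child %in% parents) stop("child cannot be its own parent")
  spec <- specs[specs$name == child, ]
  if (nrow(spec) != 1) stop("no spec for node ", child)
  y <- data[[child]]
  n <- length(y)
  X <- if (length(parents))
    cbind(1, as.matrix(data[, parents, drop = FALSE])) else
    matrix(1, n, 1)
  storage.mode(X) <- "double"
  flag <- ""
  if (spec$dist == "gaussian") {
    fit <- stats::lm.fit(X, y)
    aliased <- sum(is.na(fit$coefficients))
    if (aliased) flag <- "collinear"
    rss <- sum(fit$residuals^2)
    sigma2 <- max(rss / n, .Machine$double.eps)
    ll <- -0.5 * n * (log(2 * pi * sigma2) + 1)
    k <- (ncol(X) - aliased) + 1 # coefficients + variance
  } else {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    aliased <- sum(is.na(fit$coefficients))
    if (aliased) flag <- "collinear"
    mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (sep_warn && (max(mu) > 1 - 1e-8 || min(mu) < 1e-8))
      flag <- paste0(flag, if (nzchar(flag)) ";" else "", "separation")
    k <- ncol(X) - aliased
  }
  structure(ll - (k / 2) * log(n), k = k, flag = flag)
}

# score with memoization; cache maps "child|p1,p2" -> score
.cached_node_score <- function(child, parents, data, specs, cache) {
  key <- paste0(child, "|", paste(sort(parents), collapse = ","))
  if (!is.null(cache[[key]])) return(cache[[key]])
  s <- as.numeric(node_score(child, parents, data, specs))
  cache[[key]] <- s
  s
}

# adjacency helpers: adj is a logical matrix, adj[i, j] TRUE = edge i -> j
.is_acyclic <- function(adj) {
  deg <- colSums(adj)
  active <- rep(TRUE, nrow(adj))
  repeat {
    src <- which(active & deg == 0)
    if (!length(src)) break
    for (s in src) {
      deg <- deg - adj[s, ] * 1
      active[s] <- FALSE
    }
  }
  !any(active)
}

.dag_score <- function(adj, data, specs, cache) {
  sum(vapply(seq_len(ncol(adj)), function(j) {
    .cached_node_score(specs$name[j], specs$name[adj[, j]], data, specs,
                       cache)
  }, numeric(1)))
}

#' Single greedy structure search
#'
#' Hill climbing over add/delete/reverse edge moves from a random
#' seed-dependent starting DAG, respecting acyclicity, `max_parents` and
#' any `no_parents` constraints, until no move improves the total
#' BIC-penalized score. Deterministic given `seed`.
#'
#' @param data data.frame of node values.
#' @param specs a [node_specs()].
#' @param seed integer seed for the random start.
#' @param max_parents maximum parents per node (default 4).
#' @param cache optional environment for score memoization (shared across
#'   searches by [consensus()]).
#' @param start_density probability of including each admissible edge in
#'   the random starting DAG.
#' @return list with `adj` (logical adjacency, `[i, j]` = edge i->j),
#'   `score`, `n_steps`.
#' @export
search_once <- function(data, specs, seed = 1L, max_parents = 4L,
                        cache = NULL, start_density = 0.15) {
  stopifnot(inherits(specs, "node_specs"))
  if (max_parents < 1) stop("max_parents must be >= 1")
  nn <- nrow(specs)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  set.seed(seed)
  nodes <- specs$name
  allowed_child <- !specs$no_parents

  adj <- matrix(FALSE, nn, nn, dimnames = list(nodes, nodes))
  if (nn > 1) {
    ord <- sample.int(nn)
    for (a in seq_len(nn - 1)) for (b in seq(a + 1, nn)) {
      i <- ord[a]; j <- ord[b]
      if (allowed_child[j] && sum(adj[, j]) < max_parents &&
          stats::runif(1) < start_density)
        adj[i, j] <- TRUE
    }
  }

  parents_of <- function(j) nodes[adj[, j]]
  score_node <- function(j, par) .cached_node_score(nodes[j], par, data,
                                                    specs, cache)
  node_sc <- vapply(seq_len(nn), function(j) score_node(j, parents_of(j)),
                    numeric(1))
  total <- sum(node_sc)

  n_steps <- 0L
  repeat {
    best_gain <- 1e-9
    best_move <- NULL
    for (i in seq_len(nn)) for (j in seq_len(nn)) {
      if (i == j) next
      if (!adj[i, j]) {
        # add i -> j
        if (!allowed_child[j] || sum(adj[, j]) >= max_parents) next
        adj[i, j] <- TRUE
        ok <- .is_acyclic(adj)
        adj[i, j] <- FALSE
        if (!ok) next
        gain <- score_node(j, c(parents_of(j), nodes[i])) - node_sc[j]
        if (gain > best_gain) {
          best_gain <- gain; best_move <- list(op = "add", i = i, j = j)
        }
      } else {
        # delete i -> j
        gain <- score_node(j, setdiff(parents_of(j), nodes[i])) - node_sc[j]
        if (gain > best_gain) {
          best_gain <- gain; best_move <- list(op = "del", i = i, j = j)
        }
        # reverse i -> j
        if (allowed_child[i] && sum(adj[, i]) < max_parents) {
          adj[i, j] <- FALSE; adj[j, i] <- TRUE
          ok <- .is_acyclic(adj)
          adj[j, i] <- FALSE; adj[i, j] <- TRUE
          if (ok) {
            gain <- (score_node(j, setdiff(parents_of(j), nodes[i])) -
                       node_sc[j]) +
              (score_node(i, c(parents_of(i), nodes[j])) - node_sc[i])
            if (gain > best_gain) {
              best_gain <- gain; best_move <- list(op = "rev", i = i, j = j)
            }
          }
        }
      }
    }
    if (is.null(best_move)) break
    n_steps <- n_steps + 1L
    i <- best_move$i; j <- best_move$j
    if (best_move$op == "add") {
      adj[i, j] <- TRUE
    } else if (best_move$op == "del") {
      adj[i, j] <- FALSE
    } else {
      adj[i, j] <- FALSE; adj[j, i] <- TRUE
      node_sc[i] <- score_node(i, parents_of(i))
    }
    node_sc[j] <- score_node(j, parents_of(j))
    total <- sum(node_sc)
  }
  stopifnot(.is_acyclic(adj))
  list(adj = adj, score = total, n_steps = n_steps)
}

#' Majority-consensus network over repeated searches
#'
#' Runs [search_once()] with seeds derived from `seed`, tabulates the
#' frequency of every directed edge across the locally optimal networks,
#' and keeps edges present in at least `threshold` of them (majority
#' consensus at the default 0.5).
#'
#' @param data data.frame of node values.
#' @param specs a [node_specs()].
#' @param n_searches number of heuristic searches.
#' @param threshold consensus frequency threshold in (0, 1].
#' @param seed base seed; search `s` uses `seed + s`.
#' @param max_parents maximum parents per node.
#' @return object of class `network_result`: list with `edge_freq`
#'   (data.frame from, to, frequency), `consensus` (logical adjacency),
#'   `scores` (per-search), `n_searches`, `threshold`.
#' @export
consensus <- function(data, specs, n_searches = 200L, threshold = 0.5,
                      seed = 1L, max_parents = 4L) {
  if (n_searches < 1) stop("n_searches must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cache <- new.env(parent = emptyenv())
  nn <- nrow(specs)
  counts <- matrix(0, nn, nn, dimnames = list(specs$name, specs$name))
  scores <- numeric(n_searches)
  for (s in seq_len(n_searches)) {
    res <- search_once(data, specs, seed = seed + s,
                       max_parents = max_parents, cache = cache)
    counts <- counts + res$adj
    scores[s] <- res$score
  }
  freq <- counts / n_searches
  cons <- freq >= threshold
  idx <- which(freq > 0, arr.ind = TRUE)
  edge_freq <- data.frame(from = specs$name[idx[, 1]],
                          to = specs$name[idx[, 2]],
                          frequency = freq[idx],
                          consensus = cons[idx],
                          stringsAsFactors = FALSE)
  edge_freq <- edge_freq[order(-edge_freq$frequency), ]
  rownames(edge_freq) <- NULL
  structure(list(edge_freq = edge_freq, consensus = cons, scores = scores,
                 n_searches = n_searches, threshold = threshold),
            class = "network_result")
}

#' @export
print.network_result <- function(x, ...) {
  cat("network_result:", x$n_searches, "searches, threshold",
      x$threshold, "\n")
  keep <- x$edge_freq[x$edge_freq$consensus, ]
  if (nrow(keep)) {
    for (r in seq_len(nrow(keep)))
      cat(sprintf("  %s -> %s  (%.2f)\n", keep$from[r], keep$to[r],
                  keep$frequency[r]))
  } else cat("  (empty consensus network)\n")
  invisible(x)
}

#' Render a consensus network in DOT format
#' @param net a `network_result`.
#' @return character scalar of DOT source.
#' @export
network_dot <- function(net) {
  keep <- net$edge_freq[net$edge_freq$consensus, ]
  lines <- c("digraph consensus {",
             sprintf("  \"%s\" -> \"%s\" [label=\"%.2f\"];",
                     keep$from, keep$to, keep$frequency),
             "}")
  paste(lines, collapse = "\n")
}
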
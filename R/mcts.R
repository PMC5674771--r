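# The search tree. Nodes are environments so that visit counts and values
# update in place during backpropagation; the tree is only ever touched
# through the four canonical steps (selection, expansion, simulation,
# backpropagation) driven by design_rna().

#' Create a search-tree node
#'
#' Fresh nodes start with visit count `v = 0`, cumulative value `w = 0` and
#' immediate value `z = 0`; selection treats an unvisited node as having an
#' infinite upper confidence bound.
#'
#' @param event The assignment event the node represents, or `NULL` for the
#'   root.
#' @param site_index Index of the event's site in the site list, or `NA`.
#' @return An environment of class `search_node` with fields `v`, `w`, `z`,
#'   `children` (list), `expansion_site` and `event`.
#' @export
new_search_node <- function(event = NULL, site_index = NA_integer_) {
  node <- new.env(parent = emptyenv())
  node$event <- event
  node$site_index <- as.integer(site_index)
  node$v <- 0L
  node$w <- 0
  node$z <- 0
  node$children <- list()
  node$expansion_site <- NA_integer_
  class(node) <- "search_node"
  node
}

#' Upper confidence bound of a node
#'
#' `w / v + C * sqrt(2 * log(v_parent) / v)`; infinite while the node is
#' unvisited, so every child is tried at least once before exploitation
#' starts.
#'
#' @param node A `search_node`.
#' @param v_parent Visit count of the parent node.
#' @param C Exploration constant (larger values favour exploration).
#' @return The UCB score, possibly `Inf`.
#' @export
ucb_score <- function(node, v_parent, C) {
  if (node$v == 0L) return(Inf)
  if (v_parent < node$v)
    stop("internal inconsistency: parent visited less often than child",
         call. = FALSE)
  node$w / node$v + C * sqrt(2 * log(v_parent) / node$v)
}

#' Select a root-to-leaf path by UCB
#'
#' From the root, repeatedly descend into the child with the largest UCB
#' score, breaking ties uniformly at random, until a childless node is
#' reached.
#'
#' @param root The root `search_node`.
#' @param C Exploration constant.
#' @return List of nodes from the root to the selected leaf (inclusive).
#' @export
select_path <- function(root, C) {
  path <- list(root)
  node <- root
  while (length(node$children) > 0L) {
    u <- vapply(node$children, ucb_score, numeric(1), v_parent = node$v, C = C)
    best <- which(u == max(u))
    pick <- if (length(best) > 1L) best[sample.int(length(best), 1L)] else best
    node <- node$children[[pick]]
    path[[length(path) + 1L]] <- node
  }
  path
}

#' Expand a leaf node
#'
#' Expansion is gated by the visit count: a leaf visited fewer than `beta`
#' times is simulated as-is (no children are created). Otherwise one of the
#' remaining sites is chosen uniformly at random and all of its assignment
#' events become children at once — four for a single site, six for a
#' paired site — each initialized unvisited; one child, chosen uniformly,
#' is returned for simulation. A leaf at full depth (no remaining sites) is
#' never expanded.
#'
#' @param leaf A childless `search_node`.
#' @param remaining Integer indices (into `sites`) of the sites not yet
#'   assigned on the path to `leaf`.
#' @param sites Site list from [target_sites()].
#' @param beta Expansion threshold (visits required before expansion).
#' @param force Expand regardless of the visit count (used for the root in
#'   the very first round, which is expanded immediately).
#' @return The node to simulate: a newly created child, or `leaf` itself
#'   when expansion was skipped.
#' @export
expand_node <- function(leaf, remaining, sites, beta, force = FALSE) {
  stopifnot(length(leaf$children) == 0L)
  if (length(remaining) == 0L) return(leaf)
  if (!force && leaf$v < beta) return(leaf)
  si <- remaining[sample.int(length(remaining), 1L)]
  site <- sites[[si]]
  values <- if (site$kind == "paired") .pair_values else .bases
  leaf$children <- lapply(values, function(val)
    new_search_node(event = list(site = site, value = val), site_index = si))
  leaf$expansion_site <- si
  leaf$children[[sample.int(length(leaf$children), 1L)]]
}

#' Backpropagate a playout value
#'
#' Adds one visit and the playout value `z` to every node on the path —
#' the simulated node itself included, so a node's cumulative value is the
#' sum over its own and its descendants' playouts — and stores `z` as the
#' simulated node's immediate value.
#'
#' @param path List of nodes from the root to the simulated node.
#' @param z Maximum reward observed in the playout.
#' @export
backpropagate <- function(path, z) {
  for (node in path) {
    node$v <- node$v + 1L
    node$w <- node$w + z
  }
  path[[length(path)]]$z <- z
  invisible(NULL)
}

#' Search parameters
#'
#' @param C Exploration constant of the UCB score.
#' @param beta Expansion threshold: visits a leaf needs before it grows
#'   children.
#' @param k Playout length: one initial sequence plus `k - 1` local updates,
#'   i.e. `k` structure predictions per simulation.
#' @param max_iterations Optional cap on search rounds.
#' @param time_limit Optional wall-clock cap in seconds. When no cap at all
#'   is given, a 600 s time limit applies.
#' @param max_fold_calls Optional cap on the number of structure
#'   predictions; checked between rounds, so a run may finish the playout
#'   in flight (at most `k` calls over budget).
#' @param seed Optional integer seed; with the reference backend a
#'   (structure, parameters, seed) triple fully determines the run.
#' @return An object of class `search_params`.
#' @export
search_params <- function(C = 0.5, beta = 1L, k = 50L,
                          max_iterations = NULL, time_limit = NULL,
                          max_fold_calls = NULL, seed = NULL) {
  stopifnot(is.numeric(C), C > 0,
            is.numeric(beta), beta >= 1, beta == as.integer(beta),
            is.numeric(k), k >= 1, k == as.integer(k))
  structure(list(C = C, beta = as.integer(beta), k = as.integer(k),
                 max_iterations = max_iterations, time_limit = time_limit,
                 max_fold_calls = max_fold_calls, seed = seed),
            class = "search_params")
}

#' Design an RNA sequence for a target structure
#'
#' Runs the full search: each round selects a path through the tree of
#' assignment events by UCB, possibly expands the reached leaf, simulates a
#' playout (initial sequence plus local updates, each folded and scored),
#' and backpropagates the playout's best reward. The run stops as soon as a
#' candidate's predicted structure is identical to the target (with
#' `require_gc = TRUE`, its GC content must additionally lie within `delta`
#' of `alpha_star`), or when the iteration/time budget is exhausted, in
#' which case the best-reward candidate seen is returned with
#' `success = FALSE`.
#'
#' @param target An `rna_target` or a dot-bracket string.
#' @param alpha_star Optional target GC content.
#' @param delta GC tolerance; defaults to 0.01 for nested targets and 0.02
#'   for pseudoknotted ones.
#' @param r_gc GC bonus weight of the reward.
#' @param params A [search_params()] object.
#' @param backend A [fold_backend()]; must support pseudoknots if the
#'   target has crossing pairs.
#' @param require_gc If `TRUE`, a design only counts as a success when its
#'   GC content is within the tolerance window as well as matching the
#'   structure.
#' @param verbose Print one line per round.
#' @return An object of class `rna_design`: `success`, `sequence`,
#'   `predicted`, `reward` (a `reward_value`), `gc`, `iterations`,
#'   `fold_calls`, `solution_depth` (tree depth at the successful round, or
#'   `NA`), `elapsed` (seconds), plus the target and the parameters used.
#' @examples
#' res <- design_rna("((((....))))", params = search_params(seed = 1))
#' res$success
#' @export
design_rna <- function(target, alpha_star = NULL, delta = NULL, r_gc = 1,
                       params = search_params(), backend = fold_backend("reference"),
                       require_gc = FALSE, verbose = FALSE) {
  if (is.character(target)) target <- parse_dotbracket(target)
  stopifnot(inherits(target, "rna_target"), inherits(params, "search_params"))
  if (target$pseudoknotted && !backend$supports_pseudoknots)
    stop(sprintf(paste0("target contains crossing pairs but backend '%s' ",
                        "predicts nested structures only; use the pkiss ",
                        "backend"), backend$name), call. = FALSE)
  if (is.null(delta))
    delta <- if (target$pseudoknotted) 0.02 else 0.01
  rpar <- reward_params(alpha_star = alpha_star, delta = delta, r_gc = r_gc)
  if (!is.null(params$seed)) set.seed(params$seed)

  max_iter <- params$max_iterations
  time_limit <- params$time_limit
  max_folds <- params$max_fold_calls
  if (is.null(max_iter) && is.null(time_limit) && is.null(max_folds))
    time_limit <- 600

  sites <- target_sites(target)
  root <- new_search_node()
  best <- NULL
  success <- FALSE
  solution_depth <- NA_integer_
  iter <- 0L
  calls0 <- backend$calls
  t0 <- proc.time()[["elapsed"]]

  is_success <- function(cand) {
    if (cand$reward$d != 0L) return(FALSE)
    if (!require_gc || is.null(alpha_star)) return(TRUE)
    abs(round(cand$reward$alpha - alpha_star, 12)) <= delta
  }

  repeat {
    if (!is.null(max_iter) && iter >= max_iter) break
    if (!is.null(time_limit) && proc.time()[["elapsed"]] - t0 > time_limit)
      break
    if (!is.null(max_folds) && backend$calls - calls0 >= max_folds) break
    iter <- iter + 1L

    path <- select_path(root, params$C)
    leaf <- path[[length(path)]]
    used <- unlist(lapply(path, function(nd) nd$site_index))
    remaining <- setdiff(seq_along(sites), used[!is.na(used)])
    node <- expand_node(leaf, remaining, sites, params$beta,
                        force = (iter == 1L && identical(leaf, root)))
    if (!identical(node, leaf)) path <- c(path, list(node))

    essential <- Filter(Negate(is.null),
                        lapply(path, function(nd) nd$event))
    cands <- simulate_playout(essential, target, rpar, params$k, backend)
    rewards <- vapply(cands, function(cc) cc$reward$r, numeric(1))
    z <- max(rewards)
    backpropagate(path, z)

    cand_best <- cands[[which.max(rewards)]]
    if (is.null(best) || cand_best$reward$r > best$reward$r)
      best <- cand_best

    hits <- Filter(is_success, cands)
    if (length(hits) > 0L) {
      best <- hits[[1]]
      success <- TRUE
      solution_depth <- length(path) - 1L
      break
    }
    if (verbose)
      message(sprintf(
        "round %d: best reward %.4f, tree depth %d, fold calls %d",
        iter, best$reward$r, length(path) - 1L, backend$calls - calls0))
  }

  if (success) {
    # termination soundness: the returned sequence must re-fold to the target
    refold <- parse_dotbracket(backend$predict(best$sequence))$dotbracket
    stopifnot(identical(refold, target$dotbracket))
  }

  structure(list(
    success = success,
    sequence = if (is.null(best)) NA_character_ else best$sequence,
    predicted = if (is.null(best)) NA_character_ else best$predicted,
    reward = if (is.null(best)) NULL else best$reward,
    gc = if (is.null(best)) NA_real_ else best$reward$alpha,
    iterations = iter,
    fold_calls = backend$calls - calls0,
    solution_depth = solution_depth,
    elapsed = proc.time()[["elapsed"]] - t0,
    target = target,
    alpha_star = alpha_star,
    delta = delta,
    r_gc = r_gc,
    require_gc = require_gc,
    params = params,
    backend = backend$name,
    tree = root
  ), class = "rna_design")
}

#' @export
print.rna_design <- function(x, ...) {
  cat("RNA inverse-folding design\n")
  cat("  target   ", x$target$dotbracket, "\n", sep = "")
  if (!is.na(x$sequence)) {
    cat("  sequence ", x$sequence, "\n", sep = "")
    cat("  predicted", " ", x$predicted, "\n", sep = "")
  }
  cat(sprintf("  success: %s | reward %.4f | GC %.3f | distance %d\n",
              x$success,
              if (is.null(x$reward)) NA_real_ else x$reward$r,
              x$gc,
              if (is.null(x$reward)) NA_integer_ else x$reward$d))
  cat(sprintf("  %d round(s), %d fold call(s), %.2f s, backend '%s'\n",
              x$iterations, x$fold_calls, x$elapsed, x$backend))
  invisible(x)
}
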
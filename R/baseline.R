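#' Local search from random initial sequences (no tree)
#'
#' The ablation baseline for the tree search: repeatedly draw a fresh random
#' initial sequence (GC-targeted if `alpha_star` is set) and refine it with
#' local updates, with no essential positions and no memory between
#' restarts. Each restart is one playout of length `k`; restarts continue
#' until a candidate matches the target or the fold-call budget is spent.
#' Comparing this against [design_rna()] at the same fold budget isolates
#' the contribution of the search tree.
#'
#' @param target An `rna_target` or dot-bracket string.
#' @param alpha_star Optional GC-content target.
#' @param delta GC tolerance (defaults as in [design_rna()]).
#' @param r_gc GC bonus weight.
#' @param k Playout length per restart.
#' @param max_fold_calls Total structure-prediction budget; checked between
#'   restarts, so the final restart may finish (at most `k` calls over).
#' @param seed Optional integer seed.
#' @param backend A [fold_backend()].
#' @return A list of class `rna_design` (same shape as [design_rna()];
#'   `solution_depth` is always `NA` and `iterations` counts restarts).
#' @export
random_restart_design <- function(target, alpha_star = NULL, delta = NULL,
                                  r_gc = 1, k = 50L, max_fold_calls = 300L,
                                  seed = NULL,
                                  backend = fold_backend("reference")) {
  if (is.character(target)) target <- parse_dotbracket(target)
  stopifnot(inherits(target, "rna_target"))
  if (target$pseudoknotted && !backend$supports_pseudoknots)
    stop("pseudoknotted target needs a pseudoknot-capable backend",
         call. = FALSE)
  if (is.null(delta))
    delta <- if (target$pseudoknotted) 0.02 else 0.01
  rpar <- reward_params(alpha_star = alpha_star, delta = delta, r_gc = r_gc)
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  success <- FALSE
  restarts <- 0L
  calls0 <- backend$calls
  t0 <- proc.time()[["elapsed"]]
  while (backend$calls - calls0 < max_fold_calls) {
    restarts <- restarts + 1L
    cands <- simulate_playout(list(), target, rpar, k, backend)
    rewards <- vapply(cands, function(cc) cc$reward$r, numeric(1))
    cand_best <- cands[[which.max(rewards)]]
    if (is.null(best) || cand_best$reward$r > best$reward$r)
      best <- cand_best
    if (cands[[length(cands)]]$reward$d == 0L) {
      best <- cands[[length(cands)]]
      success <- TRUE
      break
    }
  }

  structure(list(
    success = success,
    sequence = if (is.null(best)) NA_character_ else best$sequence,
    predicted = if (is.null(best)) NA_character_ else best$predicted,
    reward = if (is.null(best)) NULL else best$reward,
    gc = if (is.null(best)) NA_real_ else best$reward$alpha,
    iterations = restarts,
    fold_calls = backend$calls - calls0,
    solution_depth = NA_integer_,
    elapsed = proc.time()[["elapsed"]] - t0,
    target = target,
    alpha_star = alpha_star,
    delta = delta,
    r_gc = r_gc,
    require_gc = FALSE,
    params = list(seed = seed, k = k, max_fold_calls = max_fold_calls),
    backend = backend$name,
    tree = NULL
  ), class = "rna_design")
}
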
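#' Generate a random valid target structure
#'
#' Samples a random dot-bracket target for testing and benchmarking: pairs
#' are added one at a time, each drawn uniformly from the positions that
#' keep the structure nested and honour the minimum hairpin loop, until the
#' requested number of pairs is reached. With `pseudoknot = TRUE` one
#' additional pair is drawn from the placements that cross at least one
#' existing pair, giving a two-layer pseudoknot. Deterministic for a given
#' seed.
#'
#' @param n Structure length (`n >= 1`).
#' @param density Target pair density, `n_pairs = round(density * n)`;
#'   must lie in `[0, 0.5]`. Ignored when `n_pairs` is given.
#' @param n_pairs Number of base pairs to place (overrides `density`).
#' @param pseudoknot Add one crossing pair on a second bracket layer.
#' @param min_loop Minimum unpaired span enclosed by any pair.
#' @param seed Optional integer seed.
#' @return An `rna_target`.
#' @examples
#' generate_fixture(13, n_pairs = 3, seed = 1)
#' @export
generate_fixture <- function(n, density = 0.25, n_pairs = NULL,
                             pseudoknot = FALSE, min_loop = 3L, seed = NULL) {
  stopifnot(n >= 1)
  if (is.null(n_pairs)) {
    stopifnot(density >= 0, density <= 0.5)
    n_pairs <- round(density * n)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)

  # A placement can dead-end (earlier pairs may isolate the remaining free
  # positions), so the whole draw is retried a bounded number of times.
  # Pairs that extend an existing helix are preferred (probability
  # `stack_bias`) whenever one is available: real stems are stacked, and
  # unbiased placement cannot reach realistic pair densities at all.
  stack_bias <- 0.75
  for (attempt in 1:100) {
    pairs <- matrix(integer(0), ncol = 2L)
    paired <- rep(FALSE, n)
    for (p in seq_len(n_pairs)) {
      cand <- .pair_candidates(n, pairs, paired, min_loop, crossing = FALSE)
      if (nrow(cand) == 0L) break
      stacking <- rep(FALSE, nrow(cand))
      for (q in seq_len(nrow(pairs))) {
        stacking <- stacking |
          (cand[, 1L] == pairs[q, 1L] + 1L & cand[, 2L] == pairs[q, 2L] - 1L) |
          (cand[, 1L] == pairs[q, 1L] - 1L & cand[, 2L] == pairs[q, 2L] + 1L)
      }
      pool <- if (any(stacking) && stats::runif(1) < stack_bias)
        which(stacking) else seq_len(nrow(cand))
      pick <- cand[pool[sample.int(length(pool), 1L)], ]
      pairs <- rbind(pairs, pick)
      paired[pick] <- TRUE
    }
    if (nrow(pairs) == n_pairs) break
  }
  if (nrow(pairs) != n_pairs)
    stop(sprintf(paste0("cannot place %d pairs in a structure of length ",
                        "%d with minimum loop %d"), n_pairs, n, min_loop),
         call. = FALSE)
  if (pseudoknot) {
    cand <- .pair_candidates(n, pairs, paired, min_loop, crossing = TRUE)
    if (nrow(cand) == 0L)
      stop("no crossing pair can be placed; increase length or lower density",
           call. = FALSE)
    pick <- cand[sample.int(nrow(cand), 1L), ]
    pairs <- rbind(pairs, pick)
    paired[pick] <- TRUE
  }
  new_rna_target(.pair_matrix(pairs[, 1L], pairs[, 2L]), n)
}

# All (i, j) placements with both positions unpaired, span >= min_loop,
# and either nesting-compatible with every existing pair (crossing = FALSE)
# or crossing at least one (crossing = TRUE).
.pair_candidates <- function(n, pairs, paired, min_loop, crossing) {
  out_i <- integer(0); out_j <- integer(0)
  free <- which(!paired)
  for (i in free) {
    js <- free[free > i + min_loop]
    for (j in js) {
      x <- FALSE
      ok <- TRUE
      for (p in seq_len(nrow(pairs))) {
        a <- pairs[p, 1L]; b <- pairs[p, 2L]
        if ((i < a && a < j && j < b) || (a < i && i < b && b < j)) x <- TRUE
      }
      ok <- if (crossing) x else !x
      if (ok) { out_i <- c(out_i, i); out_j <- c(out_j, j) }
    }
  }
  cbind(out_i, out_j)
}

#' Build a parameter-sweep run grid
#'
#' Enumerates one row per design run for a sweep protocol: every structure
#' crossed with every GC-content target and every replicate, each run given
#' its own seed (`base_seed`, `base_seed + 1`, ...). The canonical tuning
#' protocol — 8 structures, 7 GC targets, 10 replicates — yields 560 runs
#' per dataset.
#'
#' @param structure_ids Character or integer vector identifying the targets.
#' @param gc_targets Numeric vector of GC-content targets.
#' @param runs_per_structure Replicates per (structure, GC target) cell.
#' @param base_seed First seed; consecutive integers follow.
#' @return A data.frame with columns `structure_id`, `gc_target`,
#'   `replicate`, `seed`.
#' @examples
#' nrow(protocol_grid(1:8, seq(0.2, 0.8, by = 0.1), 10))  # 560
#' @export
protocol_grid <- function(structure_ids, gc_targets, runs_per_structure = 10L,
                          base_seed = 1L) {
  grid <- expand.grid(replicate = seq_len(runs_per_structure),
                      gc_target = gc_targets,
                      structure_id = structure_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("structure_id", "gc_target", "replicate")]
  grid$seed <- base_seed + seq_len(nrow(grid)) - 1L
  grid
}

#' Run several independent designs of one target
#'
#' Repeats [design_rna()] `n_designs` times with consecutive seeds
#' (`seed`, `seed + 1`, ...), the standard per-structure evaluation
#' protocol.
#'
#' @param target An `rna_target` or dot-bracket string.
#' @param n_designs Number of independent runs.
#' @param seed Seed of the first run.
#' @param backend_name Which [fold_backend()] to create for each run.
#' @param ... Passed to [design_rna()] (e.g. `alpha_star`, `params`).
#' @return List of class `rna_design_set`: the `rna_design` objects, plus a
#'   `summary` data.frame (one row per run: seed, success, gc, distance,
#'   reward, iterations, fold_calls).
#' @export
design_rna_many <- function(target, n_designs, seed = 1L,
                            backend_name = "reference", ...) {
  if (is.character(target)) target <- parse_dotbracket(target)
  dots <- list(...)
  runs <- vector("list", n_designs)
  for (r in seq_len(n_designs)) {
    args <- dots
    base_params <- if (!is.null(args$params)) args$params else search_params()
    base_params$seed <- seed + r - 1L
    args$params <- base_params
    args$target <- target
    args$backend <- fold_backend(backend_name)
    runs[[r]] <- do.call(design_rna, args)
  }
  summary <- data.frame(
    seed = seed + seq_len(n_designs) - 1L,
    success = vapply(runs, function(x) x$success, logical(1)),
    gc = vapply(runs, function(x) x$gc, numeric(1)),
    distance = vapply(runs, function(x)
      if (is.null(x$reward)) NA_integer_ else x$reward$d, integer(1)),
    reward = vapply(runs, function(x)
      if (is.null(x$reward)) NA_real_ else x$reward$r, numeric(1)),
    iterations = vapply(runs, function(x) x$iterations, integer(1)),
    fold_calls = vapply(runs, function(x) x$fold_calls, integer(1))
  )
  structure(list(runs = runs, summary = summary, target = target),
            class = "rna_design_set")
}

#' @export
print.rna_design_set <- function(x, ...) {
  cat(sprintf("%d design run(s) for target %s\n",
              nrow(x$summary), x$target$dotbracket))
  cat(sprintf("  successes: %d / %d\n",
              sum(x$summary$success), nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write design results to FASTA and JSON
#'
#' The FASTA file holds one record per run (the best sequence found, whether
#' or not the run succeeded), with a header carrying the seed, realized GC
#' content, structural distance, reward and success flag. The JSON report
#' holds the full diagnostics of every run plus the configuration, so a run
#' can be replayed exactly.
#'
#' @param results An `rna_design_set` or a list of `rna_design` objects.
#' @param fasta_path,json_path Output paths (`NULL` to skip either).
#' @param config Optional named list echoed into the JSON report.
#' @param target_id Identifier written into FASTA headers.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, fasta_path = NULL, json_path = NULL,
                          config = NULL, target_id = "target") {
  runs <- if (inherits(results, "rna_design_set")) results$runs else results
  stopifnot(length(runs) > 0L)
  runs <- Filter(function(x) !is.na(x$sequence), runs)

  if (!is.null(fasta_path) && length(runs) > 0L) {
    headers <- vapply(runs, function(x) {
      sprintf("%s design seed=%s gc=%.4f d=%d reward=%.4f success=%s",
              target_id,
              if (is.null(x$params$seed)) "NA" else x$params$seed,
              x$gc, x$reward$d, x$reward$r, x$success)
    }, character(1))
    seqs <- lapply(runs, function(x) strsplit(x$sequence, "")[[1]])
    seqinr::write.fasta(sequences = seqs, names = headers,
                        file.out = fasta_path, as.string = FALSE)
  }

  if (!is.null(json_path)) {
    report <- list(
      config = config,
      designs = lapply(runs, function(x) list(
        sequence = x$sequence,
        predicted = x$predicted,
        target = x$target$dotbracket,
        success = x$success,
        gc = x$gc,
        distance = x$reward$d,
        reward = x$reward$r,
        iterations = x$iterations,
        fold_calls = x$fold_calls,
        solution_depth = x$solution_depth,
        elapsed = x$elapsed,
        seed = x$params$seed,
        backend = x$backend,
        alpha_star = x$alpha_star,
        delta = x$delta,
        r_gc = x$r_gc,
        C = x$params$C,
        beta = x$params$beta,
        k = x$params$k
      ))
    )
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(c(fasta = fasta_path, json = json_path))
}
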
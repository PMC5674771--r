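# The playout machinery: assignment events over design sites, GC-targeted
# initial sequences, and the two local rewriting rules. All randomness is
# drawn from R's global RNG stream, so a (target, parameters, seed) triple
# fully determines a run with the deterministic reference backend.

.bases <- c("A", "C", "G", "U")
.pair_values <- c("AU", "UA", "GU", "UG", "CG", "GC")

#' Enumerate the design sites of a target structure
#'
#' A *site* is either one unpaired position (single site, 4 possible base
#' assignments) or one base pair of the target (paired site, 6 possible
#' pair assignments). The number of sites equals `target$ell`, the maximum
#' depth of the search tree.
#'
#' @param target An `rna_target`.
#' @return A list of sites; each is a list with `kind` (`"single"` or
#'   `"paired"`) and `pos` (one or two 1-based positions).
#' @export
target_sites <- function(target) {
  stopifnot(inherits(target, "rna_target"))
  sites <- list()
  for (p in seq_len(nrow(target$pairs)))
    sites[[length(sites) + 1L]] <-
      list(kind = "paired", pos = c(target$pairs[p, 1L], target$pairs[p, 2L]))
  for (s in target$single_sites)
    sites[[length(sites) + 1L]] <- list(kind = "single", pos = s)
  sites
}

#' Randomly assign a base or base pair to a site
#'
#' Single sites receive one of A, C, G, U with equal probability; paired
#' sites one of the six admissible pairs AU, UA, GU, UG, CG, GC with equal
#' probability.
#'
#' @param site A site from [target_sites()].
#' @return An assignment event: list with `site` and `value`.
#' @export
random_assignment <- function(site) {
  value <- if (site$kind == "paired") {
    .pair_values[sample.int(6L, 1L)]
  } else {
    .bases[sample.int(4L, 1L)]
  }
  list(site = site, value = value)
}

# Write an event's base(s) into a character vector of per-position bases.
apply_event <- function(bases, event) {
  pos <- event$site$pos
  if (event$site$kind == "paired") {
    bases[pos[1L]] <- substr(event$value, 1L, 1L)
    bases[pos[2L]] <- substr(event$value, 2L, 2L)
  } else {
    bases[pos[1L]] <- event$value
  }
  bases
}

essential_positions <- function(essential) {
  if (length(essential) == 0L) return(integer(0))
  sort(unlist(lapply(essential, function(e) e$site$pos)))
}

#' Generate an initial candidate sequence
#'
#' Positions fixed by `essential` (the events on the path from the search
#' root to the current leaf) always keep their assigned bases. When a GC
#' target `alpha_star` is set, the remaining sites are visited in random
#' order and given G/C (single sites) or GC/CG (paired sites) until the
#' running GC count of the whole sequence reaches `N * alpha_star`; the
#' sites left over receive A/U or AU/UA. A paired placement may overshoot
#' the target count by one base, which is what "approximately `N * alpha_star`
#' GCs" means here. If the essential positions alone already meet the target,
#' the GC placement loop is skipped entirely. With no GC target every
#' non-essential site is filled by [random_assignment()].
#'
#' @param target An `rna_target`.
#' @param essential List of assignment events (possibly empty) with pairwise
#'   disjoint sites.
#' @param alpha_star Target GC content or `NULL`.
#' @return An RNA sequence string of length `target$n`.
#' @export
generate_initial <- function(target, essential = list(), alpha_star = NULL) {
  bases <- rep(NA_character_, target$n)
  for (e in essential) bases <- apply_event(bases, e)
  ess_pos <- essential_positions(essential)

  sites <- target_sites(target)
  free_sites <- Filter(function(s) !any(s$pos %in% ess_pos), sites)

  if (is.null(alpha_star)) {
    for (s in free_sites) bases <- apply_event(bases, random_assignment(s))
  } else {
    gc_count <- sum(bases %in% c("G", "C"), na.rm = TRUE)
    need <- target$n * alpha_star
    ord <- if (length(free_sites) > 1L) sample(length(free_sites)) else
      seq_along(free_sites)
    for (idx in ord) {
      s <- free_sites[[idx]]
      if (gc_count < need) {
        value <- if (s$kind == "paired") {
          c("GC", "CG")[sample.int(2L, 1L)]
        } else {
          c("G", "C")[sample.int(2L, 1L)]
        }
        gc_count <- gc_count + length(s$pos)
      } else {
        value <- if (s$kind == "paired") {
          c("AU", "UA")[sample.int(2L, 1L)]
        } else {
          c("A", "U")[sample.int(2L, 1L)]
        }
      }
      bases <- apply_event(bases, list(site = s, value = value))
    }
  }
  paste(bases, collapse = "")
}

#' Apply one pass of the local rewriting rules
#'
#' Two rules narrow the gap between the predicted and the target structure,
#' acting only where *both* positions of a pair are non-essential:
#' \describe{
#'   \item{rule (i)}{a target pair absent from the predicted structure is
#'     rewritten to one of AU, UA, CG, GC (chosen uniformly), to encourage
#'     the pair to form;}
#'   \item{rule (ii)}{a predicted pair that is not a target pair is broken:
#'     AU/UA becomes AA or UU, GC/CG becomes CC or GG, and GU/UG becomes one
#'     of AC, CA, AG, GA, CU, UC — six options chosen so that breaking a
#'     pair never changes the GC count of the sequence.}
#' }
#' One call makes one exhaustive pass against the fixed `predicted`
#' structure: rule (i) sites in ascending order of the opening position,
#' then rule (ii) sites likewise; positions rewritten by rule (i) are not
#' touched again by rule (ii) in the same pass. The caller re-folds before
#' the next pass, so each local update costs exactly one structure
#' prediction.
#'
#' @param sequence Current candidate sequence.
#' @param target An `rna_target`.
#' @param predicted Dot-bracket structure predicted for `sequence`.
#' @param essential List of assignment events whose positions must not move.
#' @return The rewritten sequence.
#' @export
local_update <- function(sequence, target, predicted, essential = list()) {
  stopifnot(nchar(sequence) == target$n, nchar(predicted) == target$n)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ess_pos <- essential_positions(essential)
  pred_pairs <- dotbracket_pairs(predicted)

  key <- function(m) if (nrow(m) == 0L) character(0) else
    paste(m[, 1L], m[, 2L], sep = ",")
  target_keys <- key(target$pairs)
  pred_keys <- key(pred_pairs)
  touched <- rep(FALSE, target$n)

  # rule (i): target pairs missing from the prediction
  for (p in seq_len(nrow(target$pairs))) {
    i <- target$pairs[p, 1L]; j <- target$pairs[p, 2L]
    if (i %in% ess_pos || j %in% ess_pos) next
    if (target_keys[p] %in% pred_keys) next
    value <- c("AU", "UA", "CG", "GC")[sample.int(4L, 1L)]
    bases[i] <- substr(value, 1L, 1L)
    bases[j] <- substr(value, 2L, 2L)
    touched[c(i, j)] <- TRUE
  }

  # rule (ii): predicted pairs that should not exist
  for (p in seq_len(nrow(pred_pairs))) {
    i <- pred_pairs[p, 1L]; j <- pred_pairs[p, 2L]
    if (i %in% ess_pos || j %in% ess_pos) next
    if (pred_keys[p] %in% target_keys) next
    if (touched[i] || touched[j]) next
    cur <- paste0(bases[i], bases[j])
    value <- if (cur %in% c("AU", "UA")) {
      c("AA", "UU")[sample.int(2L, 1L)]
    } else if (cur %in% c("GC", "CG")) {
      c("CC", "GG")[sample.int(2L, 1L)]
    } else if (cur %in% c("GU", "UG")) {
      c("AC", "CA", "AG", "GA", "CU", "UC")[sample.int(6L, 1L)]
    } else {
      next  # bases no longer form an admissible pair; leave them alone
    }
    bases[i] <- substr(value, 1L, 1L)
    bases[j] <- substr(value, 2L, 2L)
  }

  paste(bases, collapse = "")
}

#' Run one playout: an initial sequence plus successive local updates
#'
#' Generates up to `k` candidate sequences: the first from
#' [generate_initial()], each following one from [local_update()] against
#' the previous candidate's predicted structure. Every candidate is folded
#' once and scored with [reward()], so a full playout consumes exactly `k`
#' structure predictions. The playout stops early the moment a candidate's
#' predicted structure equals the target. When every position is essential
#' (the search path has full depth), the sequence is fully determined and
#' the playout folds it once and returns.
#'
#' @param essential List of assignment events fixed by the search path.
#' @param target An `rna_target`.
#' @param params A [reward_params()].
#' @param k Number of candidates (1 initial + `k - 1` local updates).
#' @param backend A [fold_backend()].
#' @return List of candidates; each has `sequence`, `predicted`, `reward`
#'   (a `reward_value`).
#' @export
simulate_playout <- function(essential, target, params, k, backend) {
  stopifnot(k >= 1L)
  score <- function(sequence, predicted)
    .reward_value(target$n, .dist_canonical(target$dotbracket, predicted),
                  .gc_fast(sequence), params)

  seq_cur <- generate_initial(target, essential, params$alpha_star)
  pred_cur <- fold(seq_cur, backend)$structure
  rv <- score(seq_cur, pred_cur)
  cands <- list(list(sequence = seq_cur, predicted = pred_cur, reward = rv))
  if (rv$d == 0L) return(cands)
  fully_determined <-
    length(essential_positions(essential)) == target$n
  if (fully_determined) return(cands)

  for (step in seq_len(k - 1L)) {
    seq_cur <- local_update(seq_cur, target, pred_cur, essential)
    pred_cur <- fold(seq_cur, backend)$structure
    rv <- score(seq_cur, pred_cur)
    cands[[length(cands) + 1L]] <-
      list(sequence = seq_cur, predicted = pred_cur, reward = rv)
    if (rv$d == 0L) break
  }
  cands
}
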
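#' GC content of an RNA sequence
#'
#' @param sequence A non-empty string over `A`, `C`, `G`, `U`.
#' @return Fraction of positions holding `G` or `C`.
#' @examples
#' gc_content("GACU")  # 0.5
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L)
    stop("empty sequence", call. = FALSE)
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "U")))
    stop("sequence must use the RNA alphabet A/C/G/U", call. = FALSE)
  sum(bases %in% c("G", "C")) / length(bases)
}

#' Reward-function parameters
#'
#' Bundles the GC-content target `alpha_star`, its tolerance `delta`, and the
#' GC bonus weight `r_gc` used by [reward()]. The defaults mirror the search
#' defaults: `r_gc = 1`; `delta` of 0.01 is appropriate for nested targets
#' and 0.02 for pseudoknotted ones (see [run_config()], which switches the
#' default automatically).
#'
#' @param alpha_star Target GC content in `[0, 1]`, or `NULL` for no GC
#'   objective.
#' @param delta Allowed deviation of the realized GC content from
#'   `alpha_star` (closed interval), `0 <= delta < 1`.
#' @param r_gc Bonus added to the reward when the GC content is within
#'   tolerance; must be positive.
#' @return An object of class `reward_params`.
#' @export
reward_params <- function(alpha_star = NULL, delta = 0.01, r_gc = 1) {
  if (!is.null(alpha_star)) {
    stopifnot(is.numeric(alpha_star), length(alpha_star) == 1L,
              alpha_star >= 0, alpha_star <= 1)
  }
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0, delta < 1)
  stopifnot(is.numeric(r_gc), length(r_gc) == 1L, r_gc > 0)
  structure(list(alpha_star = alpha_star, delta = delta, r_gc = r_gc),
            class = "reward_params")
}

#' Score a candidate sequence against the target structure
#'
#' The reward is `(N - d) / N`, where `d` is the Hamming distance between
#' the canonical dot-bracket renderings of the target and the predicted
#' structure, plus a bonus `r_gc` when a GC target is set and the realized
#' GC content `alpha` lies within the closed window
#' `alpha_star - delta <= alpha <= alpha_star + delta`. With no GC target
#' the reward is `(N - d) / N` unconditionally. A perfect design with the
#' GC bonus therefore scores `1 + r_gc`.
#'
#' @param sequence Candidate RNA sequence.
#' @param target An `rna_target` from [parse_dotbracket()].
#' @param predicted Predicted dot-bracket structure of `sequence`.
#' @param params A [reward_params()] object.
#' @return An object of class `reward_value`: list with `r` (the reward),
#'   `alpha` (realized GC content), `d` (structural distance), and
#'   `gc_bonus` (`TRUE` if the bonus branch fired; `NA` when no GC target).
#' @examples
#' ts <- parse_dotbracket("((((....))))")
#' reward("GCGAAAAAUCGC", ts, "((((....))))",
#'        reward_params(alpha_star = 0.5, delta = 0.01))$r  # 2
#' @export
reward <- function(sequence, target, predicted, params = reward_params()) {
  stopifnot(inherits(target, "rna_target"), inherits(params, "reward_params"))
  if (nchar(sequence) != target$n || nchar(predicted) != target$n)
    stop("sequence, predicted structure and target must have equal length",
         call. = FALSE)
  d <- structure_distance(target$dotbracket, predicted)
  alpha <- gc_content(sequence)
  .reward_value(target$n, d, alpha, params)
}

# Shared reward arithmetic. The playout loop calls this directly with a
# distance computed on already-canonical strings, bypassing the re-parse
# that the public reward() contract performs.
.reward_value <- function(n, d, alpha, params) {
  base <- (n - d) / n
  if (is.null(params$alpha_star)) {
    bonus <- NA
    r <- base
  } else {
    # round before the window test so representation noise cannot flip the
    # branch at an exact boundary
    bonus <- abs(round(alpha - params$alpha_star, 12)) <= params$delta
    r <- if (bonus) params$r_gc + base else base
  }
  structure(list(r = r, alpha = alpha, d = d, gc_bonus = bonus),
            class = "reward_value")
}

# Hamming distance between two same-length canonical dot-bracket strings.
.dist_canonical <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# GC fraction without alphabet validation (hot path).
.gc_fast <- function(sequence) {
  1 - nchar(gsub("[GC]", "", sequence)) / nchar(sequence)
}
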
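# Folding backends share one contract: an environment with a `name`, a
# `supports_pseudoknots` flag, a monotone `calls` counter, and a `predict`
# closure mapping an RNA sequence to a raw dot-bracket string. `fold()`
# validates, canonicalizes and counts; everything upstream (playouts, the
# search loop) only ever talks to `fold()`.

#' Create a structure-prediction backend
#'
#' Three backends are available:
#' \describe{
#'   \item{`reference`}{the built-in deterministic maximum-pairing folder
#'     (see [reference_fold()]); nested structures only, self-contained.}
#'   \item{`vienna`}{an external RNAfold-compatible program (sequence on
#'     stdin, structure line on stdout); nested structures only.}
#'   \item{`pkiss`}{an external pKiss-compatible program; supports
#'     pseudoknots.}
#' }
#' The backend keeps a running count of predictions (`calls`), so the fold
#' budget a run consumed is always available in its diagnostics.
#'
#' @param name One of `"reference"`, `"vienna"`, `"pkiss"`.
#' @param command Program to invoke for the external backends; defaults to
#'   `"RNAfold"` / `"pKiss"`.
#' @param args Extra command-line arguments for the external program.
#' @param max_len Length cap of the reference folder.
#' @param min_loop Minimum hairpin-loop size of the reference folder.
#' @return An environment of class `fold_backend`.
#' @export
fold_backend <- function(name = c("reference", "vienna", "pkiss"),
                         command = NULL, args = NULL,
                         max_len = 200L, min_loop = 3L) {
  name <- match.arg(name)
  be <- new.env(parent = emptyenv())
  be$name <- name
  be$calls <- 0L
  be$canonical_output <- FALSE
  if (name == "reference") {
    be$supports_pseudoknots <- FALSE
    be$canonical_output <- TRUE  # renders via canonical_dotbracket itself
    be$predict <- function(sequence) {
      if (nchar(sequence) > max_len)
        stop(sprintf(paste0("reference folder caps sequence length at %d ",
                            "(got %d); use an external backend"),
                     max_len, nchar(sequence)), call. = FALSE)
      pairing_to_dotbracket(nussinov_pairing(sequence, min_loop))
    }
  } else if (name == "vienna") {
    be$supports_pseudoknots <- FALSE
    be$command <- if (is.null(command)) "RNAfold" else command
    be$args <- if (is.null(args)) "--noPS" else args
    be$predict <- function(sequence) .external_predict(be, sequence)
  } else {
    be$supports_pseudoknots <- TRUE
    be$command <- if (is.null(command)) "pKiss" else command
    be$args <- args
    be$predict <- function(sequence) .external_predict(be, sequence)
  }
  class(be) <- "fold_backend"
  be
}

# Run the external engine, feed the sequence on stdin, and pull the first
# stdout token that looks like a dot-bracket of the right length. Energy
# annotations and any decoration the engine prints are discarded.
.external_predict <- function(be, sequence) {
  if (Sys.which(be$command) == "")
    stop(sprintf("folding engine '%s' not found on PATH", be$command),
         call. = FALSE)
  out <- suppressWarnings(
    system2(be$command, args = be$args, input = sequence,
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L)
    stop(sprintf("folding engine '%s' exited with status %d: %s",
                 be$command, status, paste(out, collapse = " / ")),
         call. = FALSE)
  pat <- "^[.()\\[\\]{}<>]+$"
  for (line in out) {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    if (length(tok) >= 1L && grepl(pat, tok[1], perl = TRUE) &&
        grepl("[.()]", tok[1])) {
      if (nchar(tok[1]) != nchar(sequence))
        stop(sprintf(paste0("folding engine '%s' returned a structure of ",
                            "length %d for a sequence of length %d"),
                     be$command, nchar(tok[1]), nchar(sequence)),
             call. = FALSE)
      return(tok[1])
    }
  }
  stop(sprintf("no dot-bracket line found in output of '%s'", be$command),
       call. = FALSE)
}

#' Predict the secondary structure of a sequence
#'
#' Dispatches to the backend's engine, canonicalizes the returned structure
#' (so pseudoknot layer labels are engine-independent) and increments the
#' backend's prediction counter by exactly one.
#'
#' @param sequence RNA sequence over `A`, `C`, `G`, `U`.
#' @param backend A [fold_backend()].
#' @return A list of class `fold_result` with `structure` (canonical
#'   dot-bracket) and `backend` (the backend name).
#' @examples
#' be <- fold_backend("reference")
#' fold("GGGGAAAACCCC", be)$structure  # "((((....))))"
#' @export
fold <- function(sequence, backend) {
  stopifnot(inherits(backend, "fold_backend"))
  .check_rna(sequence)
  raw <- backend$predict(sequence)
  backend$calls <- backend$calls + 1L
  canon <- if (isTRUE(backend$canonical_output)) raw else
    parse_dotbracket(raw)$dotbracket
  if (nchar(canon) != nchar(sequence))
    stop("backend returned a structure of the wrong length", call. = FALSE)
  structure(list(structure = canon, backend = backend$name),
            class = "fold_result")
}

#' Deterministic maximum-pairing reference folder
#'
#' A Nussinov-style dynamic program over the six admissible pairs (AU, UA,
#' GC, CG, GU, UG) with a minimum hairpin loop of `min_loop` unpaired bases.
#' Ties are broken deterministically: pairing the leftmost position is
#' preferred over leaving it unpaired, and among optimal partners the
#' smallest index wins, so the folder is a pure function of the sequence.
#' It scores structures by pair count, not free energy: it exists so the
#' whole design loop can run without an external engine, and the design loop
#' only ever compares candidates against this same folder's predictions.
#'
#' @param sequence RNA sequence; length at most `max_len`.
#' @param max_len Length cap (guards the cubic dynamic program).
#' @param min_loop Minimum hairpin-loop size.
#' @return A `fold_result` (see [fold()]).
#' @export
reference_fold <- function(sequence, max_len = 200L, min_loop = 3L) {
  fold(sequence, fold_backend("reference", max_len = max_len,
                              min_loop = min_loop))
}

.check_rna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L || grepl("[^ACGU]", sequence))
    stop("sequence must be a non-empty string over A/C/G/U", call. = FALSE)
  invisible(sequence)
}

#' @export
print.fold_backend <- function(x, ...) {
  cat(sprintf("<fold backend '%s'%s, %d call(s)>\n", x$name,
              if (x$supports_pseudoknots) " (pseudoknots)" else "", x$calls))
  invisible(x)
}
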
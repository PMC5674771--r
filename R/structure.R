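#' @useDynLib rnadesign, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Bracket alphabets, in the fixed order used for canonical layer assignment.
.bracket_open  <- c("(", "[", "{", "<")
.bracket_close <- c(")", "]", "}", ">")

#' Parse a dot-bracket secondary structure
#'
#' Parses a dot-bracket string into a target-structure object. Base pairs are
#' matched per bracket layer: `()` is the primary (nested) layer and `[]`,
#' `{}`, `<>` encode additional layers whose pairs may cross the primary
#' layer (pseudoknots). All positions are 1-based.
#'
#' @param text A single string over `.`, `()`, `[]`, `{}`, `<>`.
#'
#' @return An object of class `rna_target` with components:
#' \describe{
#'   \item{dotbracket}{the canonical dot-bracket rendering of the pair set}
#'   \item{n}{structure length}
#'   \item{pairs}{integer matrix with columns `i`, `j` (`i < j`), ordered by `i`}
#'   \item{single_sites}{ordered integer vector of unpaired positions}
#'   \item{ell}{number of design sites: base pairs plus free bases (the
#'     maximum depth of the search tree)}
#'   \item{pseudoknotted}{`TRUE` if any two pairs cross}
#' }
#'
#' @examples
#' ts <- parse_dotbracket(".(((.....)).)")
#' ts$ell                      # 3 pairs + 7 free bases = 10
#' parse_dotbracket("([)]")    # a crossing pair (pseudoknot)
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) == 0L)
    stop("empty structure string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)

  bad <- which(!(chars %in% c(".", .bracket_open, .bracket_close)))
  if (length(bad) > 0L)
    stop(sprintf("illegal character '%s' at position %d", chars[bad[1]], bad[1]),
         call. = FALSE)

  pairs_i <- integer(0)
  pairs_j <- integer(0)
  for (layer in seq_along(.bracket_open)) {
    stack <- integer(0)
    op <- .bracket_open[layer]
    cl <- .bracket_close[layer]
    for (pos in seq_len(n)) {
      ch <- chars[pos]
      if (ch == op) {
        stack <- c(stack, pos)
      } else if (ch == cl) {
        if (length(stack) == 0L)
          stop(sprintf("unbalanced '%s' in layer %s%s at position %d",
                       cl, op, cl, pos), call. = FALSE)
        pairs_i <- c(pairs_i, stack[length(stack)])
        pairs_j <- c(pairs_j, pos)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L)
      stop(sprintf("unbalanced '%s' in layer %s%s at position %d",
                   op, op, cl, stack[length(stack)]), call. = FALSE)
  }

  pairs <- .pair_matrix(pairs_i, pairs_j)
  new_rna_target(pairs, n)
}

# Build the canonical (i-ordered) pair matrix.
.pair_matrix <- function(i, j) {
  m <- cbind(i = as.integer(i), j = as.integer(j))
  if (nrow(m) > 0L) m <- m[order(m[, 1L]), , drop = FALSE]
  m
}

# Constructor shared by the parser and the fixture generator.
new_rna_target <- function(pairs, n) {
  paired_pos <- as.integer(pairs[, , drop = FALSE])
  if (anyDuplicated(paired_pos))
    stop("a position participates in two base pairs", call. = FALSE)
  single_sites <- setdiff(seq_len(n), paired_pos)
  structure(
    list(
      dotbracket = canonical_dotbracket(pairs, n),
      n = as.integer(n),
      pairs = pairs,
      single_sites = as.integer(single_sites),
      ell = nrow(pairs) + length(single_sites),
      pseudoknotted = has_crossing(pairs)
    ),
    class = "rna_target"
  )
}

# TRUE if any two pairs cross (i < i' < j < j').
has_crossing <- function(pairs) {
  np <- nrow(pairs)
  if (np < 2L) return(FALSE)
  for (a in seq_len(np - 1L)) {
    for (b in (a + 1L):np) {
      i1 <- pairs[a, 1L]; j1 <- pairs[a, 2L]
      i2 <- pairs[b, 1L]; j2 <- pairs[b, 2L]
      if ((i1 < i2 && i2 < j1 && j1 < j2) || (i2 < i1 && i1 < j2 && j2 < j1))
        return(TRUE)
    }
  }
  FALSE
}

#' Render a pair set as canonical dot-bracket
#'
#' Deterministically renders a set of base pairs: nested pairs use `()`;
#' crossing pairs are placed on the first additional bracket layer
#' (`[]`, `{}`, `<>`, tried in that fixed order) that keeps every layer
#' internally nested. Different folding engines may label pseudoknot layers
#' differently, so structures are always canonicalized before comparison.
#'
#' @param pairs Integer matrix with columns `i`, `j` (`1 <= i < j <= n`),
#'   pairwise disjoint positions; a 0-row matrix or `NULL` for no pairs.
#' @param n Structure length.
#' @return A dot-bracket string of length `n`.
#' @examples
#' canonical_dotbracket(rbind(c(1, 3), c(2, 4)), 4)  # "([)]"
#' @export
canonical_dotbracket <- function(pairs, n) {
  if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2L)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  n <- as.integer(n)
  if (nrow(pairs) > 0L) {
    if (any(pairs[, 1L] >= pairs[, 2L]) || any(pairs < 1L) || any(pairs > n))
      stop("pair coordinates out of range or not i < j", call. = FALSE)
    if (anyDuplicated(as.integer(pairs)))
      stop("pairs share a position", call. = FALSE)
    pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  }
  chars <- rep(".", n)
  layers <- vector("list", length(.bracket_open))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    placed <- FALSE
    for (layer in seq_along(layers)) {
      members <- layers[[layer]]
      crosses <- FALSE
      for (q in seq_len(nrow(pairs))) {
        if (!is.null(members) && q %in% members) {
          i2 <- pairs[q, 1L]; j2 <- pairs[q, 2L]
          if ((i < i2 && i2 < j && j < j2) || (i2 < i && i < j2 && j2 < j)) {
            crosses <- TRUE
            break
          }
        }
      }
      if (!crosses) {
        layers[[layer]] <- c(members, p)
        chars[i] <- .bracket_open[layer]
        chars[j] <- .bracket_close[layer]
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("pair (%d,%d) needs more than %d bracket layers",
                   i, j, length(.bracket_open)), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Hamming distance between two secondary structures
#'
#' Both strings are canonicalized (parsed and re-rendered) before the
#' position-wise comparison, so the distance reflects the pair sets and not
#' the bracket-layer labels an engine happened to emit.
#'
#' @param a,b Dot-bracket strings of equal length.
#' @return Non-negative integer count of differing positions.
#' @examples
#' structure_distance("((....))", "(......)")  # 2
#' @export
structure_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop(sprintf("structure length mismatch: %d vs %d", nchar(a), nchar(b)),
         call. = FALSE)
  ca <- parse_dotbracket(a)$dotbracket
  cb <- parse_dotbracket(b)$dotbracket
  sum(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
}

#' Read a target structure from a plain-text file
#'
#' Accepts a file holding one dot-bracket line. FASTA-like header lines
#' (prefixed `>`) are tolerated; any additional content line beyond the first
#' structure line is ignored with a warning.
#'
#' @param path Path to the file.
#' @return An `rna_target` (see [parse_dotbracket()]).
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, ">")]
  if (length(lines) == 0L)
    stop(sprintf("no structure line found in '%s'", path), call. = FALSE)
  if (length(lines) > 1L)
    warning(sprintf("'%s': using the first structure line; %d further line(s) ignored",
                    path, length(lines) - 1L))
  parse_dotbracket(lines[[1]])
}

#' @export
print.rna_target <- function(x, ...) {
  cat("RNA target structure\n")
  cat("  ", x$dotbracket, "\n", sep = "")
  cat(sprintf("  length %d, %d base pair(s), %d free base(s), %d site(s)%s\n",
              x$n, nrow(x$pairs), length(x$single_sites), x$ell,
              if (x$pseudoknotted) ", pseudoknotted" else ""))
  invisible(x)
}
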
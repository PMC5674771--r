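# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: structure enumeration is exhaustive, matching is
# a plain stack machine.

# All nested pair sets on positions 1..n with a minimum hairpin loop,
# enumerated exhaustively (exponential; for small n only). Cached per
# (n, min_loop).
.structure_cache <- new.env(parent = emptyenv())

enumerate_nested_structures <- function(n, min_loop = 3L) {
  key <- paste(n, min_loop)
  if (!is.null(.structure_cache[[key]])) return(.structure_cache[[key]])
  rec <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), ncol = 2L)))
    res <- rec(i + 1L, j)  # i unpaired
    ts <- if (i + min_loop + 1L > j) integer(0) else
      seq.int(i + min_loop + 1L, j)
    for (t in ts) {
      inner <- rec(i + 1L, t - 1L)
      outer <- rec(t + 1L, j)
      for (a in inner) for (b in outer)
        res[[length(res) + 1L]] <- rbind(c(i, t), a, b)
    }
    res
  }
  out <- rec(1L, n)
  .structure_cache[[key]] <- out
  out
}

# Maximum number of base pairs any nested structure (min loop respected)
# can realize on a sequence, by filtering the exhaustive enumeration.
oracle_max_pairs <- function(sequence, min_loop = 3L) {
  bases <- strsplit(sequence, "")[[1]]
  ok_pair <- function(i, j)
    paste0(bases[i], bases[j]) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  best <- 0L
  for (st in enumerate_nested_structures(length(bases), min_loop)) {
    if (nrow(st) <= best) next
    if (all(mapply(ok_pair, st[, 1L], st[, 2L]))) best <- nrow(st)
  }
  best
}

# Stack-based per-layer bracket matcher, independent of parse_dotbracket().
oracle_pairs <- function(text) {
  chars <- strsplit(text, "")[[1]]
  opens <- c("(" = ")", "[" = "]", "{" = "}", "<" = ">")
  out <- NULL
  for (op in names(opens)) {
    cl <- opens[[op]]
    stack <- integer(0)
    for (p in seq_along(chars)) {
      if (chars[p] == op) stack <- c(stack, p)
      if (chars[p] == cl) {
        out <- rbind(out, c(stack[length(stack)], p))
        stack <- stack[-length(stack)]
      }
    }
  }
  if (is.null(out)) return(matrix(integer(0), ncol = 2L))
  out[order(out[, 1L]), , drop = FALSE]
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

gc_count_of <- function(sequence)
  sum(strsplit(sequence, "")[[1]] %in% c("G", "C"))

pair_set_string <- function(pairs)
  paste(sort(paste(pairs[, 1], pairs[, 2], sep = ",")), collapse = ";")
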
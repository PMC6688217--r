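#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom tibble tibble as_tibble
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Deterministic child seeds: one root seed per run, a distinct stream per
# stage (and per sample for the heterozygous coin). Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% (2^31 - 1))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Replace single bases of a sequence string at 1-based positions.
seq_replace <- function(seq, pos, bases) {
  stopifnot(length(pos) == length(bases))
  if (length(pos) == 0L) {
    return(seq)
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  stopifnot(max(pos) <= length(v))
  v[pos] <- bases
  paste(v, collapse = "")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
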
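#' @keywords internal
"_PACKAGE"

# One root seed drives the whole synthetic world; each operation draws from its
# own derived stream so modules can be re-run independently without disturbing
# each other. Derivation must stay below .Machine$integer.max (32-bit).
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  stream_ids <- c(
    cohort = 11L, panels = 23L, reference_af = 37L, genealogy = 41L,
    batches = 53L, svs = 67L, permute = 71L, bootstrap = 83L, generic = 97L
  )
  if (!stream %in% names(stream_ids)) {
    stop("unknown RNG stream: ", stream)
  }
  (abs(as.integer(seed)) * 1000L + stream_ids[[stream]]) %% 2147483587L
}

# Evaluate `expr` under a temporary RNG state seeded from a derived stream.
with_stream <- function(seed, stream, expr) {
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
  set.seed(derive_seed(seed, stream))
  expr
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(name, " must be an integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

check_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || anyNA(x)) stop(name, " must be numeric in [0,1]", call. = FALSE)
  if (open) {
    if (any(x <= 0 | x >= 1)) stop(name, " must lie strictly in (0,1)", call. = FALSE)
  } else {
    if (any(x < 0 | x > 1)) stop(name, " must lie in [0,1]", call. = FALSE)
  }
  x
}

# Variant key of the form chr:pos:ref:alt used to align tables across modules.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
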
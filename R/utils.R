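#' @keywords internal
"_PACKAGE"

## Lightweight stderr logger used by pipeline stages.
gg_log <- function(..., verbose = getOption("gliograde.verbose", TRUE)) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
  }
  invisible(NULL)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG stream afterwards. All stochastic operations in the package
## go through this so that a master seed plus fixed arithmetic fully
## determines every draw.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

## Derived sub-seeds: fixed arithmetic on a master seed, kept below 2^31.
derive_seed <- function(master_seed, offset) {
  as.integer((as.numeric(master_seed) + as.numeric(offset)) %% 2147483647)
}

## Shannon entropy (bits) of a histogram with `bins` equal-width bins over
## the observed range. A constant vector has zero entropy by convention.
hist_entropy <- function(x, bins = 64L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(0)
  r <- range(x)
  if (r[1] == r[2]) return(0)
  idx <- pmin(floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L, bins)
  p <- tabulate(idx, bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

## md5 of an arbitrary R object (serialized to a temp file); used for the
## run-manifest cache keys.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
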
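`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(..., class = "pragsub_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, ..., class = "pragsub_error") {
  if (!isTRUE(cond)) stop_ps(..., class = class)
  invisible(TRUE)
}

#' @noRd
is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

## Weighted mean/variance used by several modules; variance uses the
## frequency-weight convention (denominator = sum of weights).
wmean <- function(x, w) sum(w * x) / sum(w)

wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

## Effective sample size under weighting (Kish).
effective_n <- function(w) sum(w)^2 / sum(w^2)

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## .Random.seed is untouched. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  expr
}

## Derive a child seed from a master seed and a stage label, deterministically
## and within 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- fnv1a32(paste0(seed, ":", label))
  as.integer(h %% 2147483647)
}

## FNV-1a 32-bit hash over a UTF-8 string, done in double arithmetic (exact
## below 2^53). Used for config hashes and child-seed derivation so the
## package needs no hashing dependency.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s)) %% 256
  h <- 2166136261
  for (b in bytes) {
    ## XOR only touches the low byte since b < 256
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    ## 32-bit modular multiply split into 16-bit halves to stay exact in doubles
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, null = "null",
                           force = TRUE)
  h <- fnv1a32(as.character(json))
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
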
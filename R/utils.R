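# Shared helpers.  All pixel coordinates in the package are 0-based with
# x = column and y = row; pixel centres sit at integer coordinates, so the
# pixel (x, y) of image `im` is im[y + 1, x + 1, ].

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmax(pmin(x, 1), 0)  # x first so dim/names survive

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded generators do not disturb user code.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Nearest-pixel rounding used when sampling dense fields at fractional
# coordinates: round half up, per axis.
round_half_up <- function(x) floor(x + 0.5)

# Deep map over nested lists of numeric arrays (used by the optimizer).
map_leaves <- function(f, ...) {
  args <- list(...)
  x <- args[[1]]
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) {
      out[[i]] <- do.call(map_leaves, c(list(f), lapply(args, `[[`, i)))
    }
    out
  } else {
    do.call(f, args)
  }
}

stopf <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
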